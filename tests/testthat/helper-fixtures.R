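## Shared fixtures, all built in code (no stored binaries).

canonical_transform <- function(params = trajectory_params()) {
  cd <- params$canonical_disc_xy_deg
  geom <- eye_geometry(fd_distance_deg = sqrt(sum(cd^2)),
                       fd_angle_deg = atan2(cd[2], cd[1]) / pi * 180)
  fit_to_eye(params, geom)
}

## Trajectory atlas with exactly mirror-symmetric hemifields (used by the
## symmetry oracles: the published hemifields are deliberately asymmetric).
symmetric_params <- function() {
  p <- trajectory_params()
  p$inferior <- p$superior
  p$inferior$b$sign <- -1
  p$canonical_disc_xy_deg <- c(15, 0)   # symmetric geometry too
  p
}

## Atlas with b == 0 everywhere: straight radial bundles.
radial_params <- function() {
  p <- trajectory_params()
  p$superior$b$sign <- 0
  p$inferior$b$sign <- 0
  p
}

## Geometry with pixel coordinates for an img_px frame at img_mm extent.
pixel_geometry <- function(img_px = 480L, img_mm = 4.5,
                           fd_dist = sqrt(15^2 + 2^2),
                           fd_ang = atan2(2, 15) / pi * 180) {
  mm_per_px <- img_mm / img_px
  deg_per_px <- mm_per_px / mm_per_degree()
  disc <- c((img_px + 1) / 2, (img_px + 1) / 2)
  fovea <- disc - c(fd_dist * cos(fd_ang * pi / 180),
                    -fd_dist * sin(fd_ang * pi / 180)) / deg_per_px
  eye_geometry(fovea_xy = fovea, disc_xy = disc, mm_per_px = mm_per_px)
}

## Small per-location records table with a known linear structure.
toy_records <- function(n = 20, seed = 1, sd = 0.5) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    fcd <- runif(n, 0.05, 0.35)
    frn <- runif(n, 55, 95)
    data.frame(location_index = 1L, subject_id = sprintf("S%02d", seq_len(n)),
               fCD = fcd, fRNFLT = frn,
               fVFD = -30 + 60 * fcd + 0.1 * frn + rnorm(n, 0, sd))
  })
}

## Brute-force OLS via normal equations (independent oracle).
ols_oracle <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  n <- length(y)
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  list(beta = drop(beta), rss = rss, loglik = loglik)
}

## Brute-force segmented least squares: grid search over psi + OLS.
segmented_ols_oracle <- function(x, y, grid_n = 2000) {
  qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = grid_n)
  rss <- vapply(grid, function(ps) {
    X <- cbind(1, x, pmax(x - ps, 0))
    sum(stats::lm.fit(X, y)$residuals^2)
  }, 0)
  ps <- grid[which.min(rss)]
  X <- cbind(1, x, pmax(x - ps, 0))
  b <- stats::lm.fit(X, y)$coefficients
  list(psi = ps, slope_before = unname(b[2]), slope_change = unname(b[3]))
}
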