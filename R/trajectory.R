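## Parametric nerve-fiber bundle trajectory model.
##
## Trajectories live in a disc-centred polar frame ("model frame"): degrees
## of visual angle, x towards nasal, y towards superior, angles phi measured
## counter-clockwise from the nasal horizontal in (-180, 180].  The fovea
## sits temporally, near phi = 180.  A bundle entering the optic disc at
## angle phi0 on the circle r = r0 follows
##
##     phi(r) = phi0 + b(phi0) * (r - r0)^c(phi0),   r >= r0,
##
## with hemifield-specific coefficient tables b(.), c(.) loaded from a
## versioned JSON config, so alternative atlases are drop-in.  Superior
## bundles (phi0 > 0) have b >= 0 (they arc towards the temporal raphe at
## +180), inferior bundles b <= 0.  The temporal raphe at +-180 is the
## model's discontinuity.

#' Load trajectory model parameters
#'
#' @param path Path to a JSON config; `NULL` loads the packaged default
#'   atlas (`inst/extdata/trajectory_default.json`).
#' @return Object of class `trajectory_params`.
#' @export
trajectory_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "trajectory_default.json",
                        package = "focalsf", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("r0", "variability_sd_deg", "canonical_disc_xy_deg",
              "nasal_limit", "superior", "inferior"))
    if (is.null(cfg[[f]])) stopf("trajectory config missing field '%s'", f)
  if (cfg$r0 <= 0 || cfg$variability_sd_deg <= 0)
    stopf("r0 and variability_sd_deg must be positive")
  structure(cfg, class = "trajectory_params")
}

#' @export
print.trajectory_params <- function(x, ...) {
  cat(sprintf("<trajectory_params> atlas '%s': r0 = %g deg, phi0 spread SD = %g deg\n",
              x$atlas, x$r0, x$variability_sd_deg))
  invisible(x)
}

## Coefficient tables, vectorized over phi0.
traj_b <- function(phi0, params) {
  lim <- params$nasal_limit
  bs <- function(p, tab) tab$sign * exp(tab$a0 + tab$a1 * tanh(-(p - tab$center) / tab$width))
  sup <- bs(phi0, params$superior$b)
  inf <- bs(-phi0, params$inferior$b)
  sup_lim <- bs(lim, params$superior$b)
  inf_lim <- bs(lim, params$inferior$b)
  taper <- (abs(phi0) / lim)^params$nasal_taper_pow
  ifelse(phi0 >= lim, sup,
  ifelse(phi0 <= -lim, inf,
  ifelse(phi0 >= 0, sup_lim * taper, inf_lim * taper)))
}

traj_c <- function(phi0, params) {
  lim <- params$nasal_limit
  cf <- function(p, tab) tab$c0 + tab$c1 * tanh((p - tab$center) / tab$width)
  sup <- cf(pmax(phi0, lim), params$superior$c)
  inf <- cf(pmax(-phi0, lim), params$inferior$c)
  ifelse(phi0 >= 0, sup, inf)
}

## phi(r; phi0), vectorized over r and/or phi0 (recycled).
traj_phi <- function(r, phi0, params) {
  dr <- pmax(r - params$r0, 0)
  phi0 + traj_b(phi0, params) * dr^traj_c(phi0, params)
}

#' Trace a nerve-fiber bundle trajectory
#'
#' @param phi0 Disc-entry angle in degrees, in (-180, 180\].
#' @param params A [trajectory_params] object.
#' @return A function `r -> phi(r)` (degrees, unwrapped), valid for
#'   `r >= r0`; it satisfies `phi(r0) == phi0` exactly.
#' @export
trace_trajectory <- function(phi0, params) {
  if (!is_scalar_num(phi0) || phi0 <= -180 || phi0 > 180)
    stopf("phi0 = %g outside the covered range (-180, 180]", phi0)
  force(params)
  f <- function(r) {
    if (any(r < params$r0 - 1e-12))
      stopf("trajectory undefined for r < r0 = %g", params$r0)
    traj_phi(r, phi0, params)
  }
  attr(f, "phi0") <- phi0
  attr(f, "b") <- traj_b(phi0, params)
  attr(f, "c") <- traj_c(phi0, params)
  f
}

#' Eye geometry
#'
#' Fovea and disc centres in image pixel coordinates (origin top-left, x
#' rightward, y downward) plus the physical scale.  The fovea-disc distance
#' and angle are derived (or can be supplied directly when no pixel
#' coordinates exist).  Image x must point nasally, i.e. left eyes are
#' mirrored at ingest.
#'
#' @param fovea_xy,disc_xy Numeric length-2 pixel coordinates.
#' @param mm_per_px Image scale.
#' @param fd_distance_deg,fd_angle_deg Optional direct fovea-disc distance
#'   (degrees) and angle (degrees of the disc centre above the horizontal
#'   through the fovea).
#' @return Object of class `eye_geometry`.
#' @export
eye_geometry <- function(fovea_xy = NULL, disc_xy = NULL, mm_per_px = NULL,
                         fd_distance_deg = NULL, fd_angle_deg = NULL) {
  if (is.null(fd_distance_deg)) {
    if (is.null(fovea_xy) || is.null(disc_xy) || is.null(mm_per_px))
      stopf("need fovea_xy, disc_xy and mm_per_px (or explicit fd distance/angle)")
    d <- (disc_xy - fovea_xy) * mm_per_px / mm_per_degree()
    d[2] <- -d[2]                         # image y is down, model y is up
    fd_distance_deg <- sqrt(sum(d^2))
    ## angle of the disc seen from the fovea, relative to the +x horizontal
    fd_angle_deg <- atan2(d[2], d[1]) / pi * 180
  }
  if (fd_distance_deg <= 0) stopf("degenerate geometry: fovea-disc distance <= 0")
  if (abs(fd_angle_deg) >= 45) stopf("implausible fovea-disc angle %g", fd_angle_deg)
  structure(list(fovea_xy = fovea_xy, disc_xy = disc_xy, mm_per_px = mm_per_px,
                 fd_distance_deg = fd_distance_deg, fd_angle_deg = fd_angle_deg),
            class = "eye_geometry")
}

#' Fit the trajectory model to an individual eye
#'
#' Builds the invertible similarity transform between image pixel
#' coordinates and the model's disc-centred degree frame: translation of the
#' disc centre to the origin, a y-flip (image y down, model y up), rotation
#' so the individual fovea->disc axis coincides with the canonical axis
#' implied by `canonical_disc_xy_deg`, and scaling so the individual
#' fovea-disc distance maps onto the canonical one.
#'
#' @param params A [trajectory_params].
#' @param geom An [eye_geometry].
#' @return Object of class `eye_transform` with fields `px_to_model`,
#'   `model_to_px` (functions on n x 2 matrices), `scale` (canonical deg per
#'   individual deg), `rot_deg`, and angle converters
#'   `eye_angle_to_model` / `model_angle_to_eye`.
#' @export
fit_to_eye <- function(params, geom) {
  stopifnot(inherits(params, "trajectory_params"), inherits(geom, "eye_geometry"))
  cd <- params$canonical_disc_xy_deg
  canon_f <- -c(cd[1], cd[2])             # fovea position in canonical frame
  canon_dist <- sqrt(sum(canon_f^2))
  canon_ang <- atan2(canon_f[2], canon_f[1]) / pi * 180
  ## individual fovea in the disc-centred, y-up degree frame
  ind_ang <- geom$fd_angle_deg + 180      # fovea seen from disc
  ind_dist <- geom$fd_distance_deg
  if (ind_dist <= 0) stopf("degenerate geometry (coincident fovea and disc)")
  k <- canon_dist / ind_dist
  delta <- wrap180(canon_ang - ind_ang)   # rotation, degrees CCW
  dp <- if (is.null(geom$mm_per_px)) NA_real_ else
    geom$mm_per_px / mm_per_degree()      # degrees per pixel
  disc <- geom$disc_xy
  cosd <- cos(delta * pi / 180); sind <- sin(delta * pi / 180)
  px_to_model <- function(px) {
    px <- matrix(px, ncol = 2L)
    u1 <- (px[, 1] - disc[1]) * dp
    u2 <- -(px[, 2] - disc[2]) * dp
    cbind(k * (cosd * u1 - sind * u2), k * (sind * u1 + cosd * u2))
  }
  model_to_px <- function(m) {
    m <- matrix(m, ncol = 2L)
    u1 <- (cosd * m[, 1] + sind * m[, 2]) / k
    u2 <- (-sind * m[, 1] + cosd * m[, 2]) / k
    cbind(u1 / dp + disc[1], -u2 / dp + disc[2])
  }
  structure(list(px_to_model = px_to_model, model_to_px = model_to_px,
                 scale = k, rot_deg = delta, deg_per_px = dp,
                 disc_px = disc,
                 eye_angle_to_model = function(a) wrap360(a + delta),
                 model_angle_to_eye = function(a) wrap360(a - delta)),
            class = "eye_transform")
}

#' @export
print.eye_transform <- function(x, ...) {
  cat(sprintf("<eye_transform> scale %.4f, rotation %+.2f deg\n", x$scale, x$rot_deg))
  invisible(x)
}

## Field point (x temporal+, y superior+, degrees) -> retinal position in the
## model frame (via point reflection through fixation: field superior maps to
## inferior retina, field temporal to nasal retina).
field_to_model <- function(x_deg, y_deg, params) {
  cd <- params$canonical_disc_xy_deg
  fovea <- -c(cd[1], cd[2])
  ## retinal offset from the fovea in (nasal+, superior+) degrees
  cbind(fovea[1] + x_deg, fovea[2] - y_deg)
}

#' Disc-entry angle of the bundle through a visual-field location
#'
#' Reflects the field point through fixation to its retinal position,
#' converts it to the model frame, and solves (1-D root finding over phi0,
#' which is monotone within a hemifield) for the unique trajectory passing
#' through it.
#'
#' @param loc One row of [vf_build_grid()] (or a list with `x_deg`, `y_deg`,
#'   `is_blind_spot`).
#' @param transform An [fit_to_eye()] transform.
#' @param params A [trajectory_params].
#' @return phi0 in degrees; re-tracing the returned trajectory passes
#'   through the point to well below 0.5 degrees.
#' @export
vf_point_to_phi0 <- function(loc, transform, params) {
  if (isTRUE(loc$is_blind_spot)) stopf("location %s is the blind spot", loc$index)
  m <- field_to_model(loc$x_deg, loc$y_deg, params)
  r <- sqrt(sum(m^2))
  psi <- atan2(m[2], m[1]) / pi * 180
  solve_phi0(r, psi, params)
}

## Invert phi(r; .) at radius r for target angle psi (degrees, (-180,180]).
## Uses the monotonicity of phi(r; phi0) in phi0 within a hemifield.
solve_phi0 <- function(r, psi, params, tol = 1e-9) {
  if (r < params$r0)
    stopf("point at r = %.2f deg lies inside the trajectory start radius r0 = %g",
          r, params$r0)
  hemi <- if (psi >= 0) c(0, 180) else c(-180, 0)
  target <- psi
  g <- function(p) traj_phi(r, p, params) - target
  glo <- g(hemi[1]); ghi <- g(hemi[2])
  if (glo > 0 || ghi < 0)
    stopf("no trajectory reaches the point (r = %.2f, psi = %.2f): outside model domain",
          r, psi)
  stats::uniroot(g, hemi, tol = tol)$root
}

## Vectorized inversion for many (r, psi) pairs by bisection.  The b/c
## coefficient tables are tabulated once on a 0.05 degree phi0 grid so each
## iteration is pure indexed arithmetic.
solve_phi0_vec <- function(r, psi, params, iters = 40L) {
  res <- 0.05
  grid <- seq(-180, 180, by = res)
  b_tab <- traj_b(grid, params)
  c_tab <- traj_c(grid, params)
  ldr <- log(pmax(r - params$r0, 1e-12))
  lo <- ifelse(psi >= 0, 0, -180)
  hi <- ifelse(psi >= 0, 180, 0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    idx <- as.integer(round((mid + 180) / res)) + 1L
    val <- mid + b_tab[idx] * exp(c_tab[idx] * ldr)
    up <- val < psi
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
  }
  (lo + hi) / 2
}

#' Per-pixel disc-entry angle field
#'
#' For every pixel of an image frame, the entry angle phi0 of the trajectory
#' passing through it (NA inside r0).  Shared by wedge construction and the
#' synthetic renderer, which keeps structural and functional ground truth
#' consistent by construction.
#'
#' @param transform An [fit_to_eye()] transform.
#' @param params A [trajectory_params].
#' @param shape `c(nrow, ncol)` of the frame.
#' @return List with matrices `phi0`, `r` (model degrees) and `psi`.
#' @export
phi0_field <- function(transform, params, shape) {
  nr <- shape[1]; nc <- shape[2]
  px <- cbind(rep(seq_len(nc), each = nr), rep(seq_len(nr), times = nc))
  m <- transform$px_to_model(px)
  r <- sqrt(m[, 1]^2 + m[, 2]^2)
  psi <- atan2(m[, 2], m[, 1]) / pi * 180
  phi0 <- rep(NA_real_, length(r))
  ok <- r >= params$r0
  phi0[ok] <- solve_phi0_vec(r[ok], psi[ok], params)
  list(phi0 = matrix(phi0, nr, nc), r = matrix(r, nr, nc),
       psi = matrix(psi, nr, nc))
}

#' Build the wedge ROI for a visual-field location
#'
#' The 95% CI wedge: the two bounding trajectories start at
#' phi0 +- 1.96 * variability_sd_deg.  The pixel mask contains every pixel of
#' the normalized OCT-A frame lying between the bounding trajectories at a
#' model radius of at least r0 (outer extent: the scan edge); the ring arc
#' is the angular interval swept by the bounding trajectories at the 3.5-mm
#' ring radius, expressed in the eye frame of the RNFL profile.
#'
#' @inheritParams vf_point_to_phi0
#' @param map_shape `c(nrow, ncol)` of the normalized perfusion map.
#' @param mm_per_px Scale of that map.
#' @param ring_radius_mm Radius of the OCT ring scan (default 1.75 mm, i.e.
#'   the 3.5-mm-diameter circle).
#' @param ci_z Half-width multiplier of the phi0 spread (1.96 for 95% CI).
#' @return Object of class `wedge_roi` with `location_index`, `phi0_lo`,
#'   `phi0_hi`, `pixel_mask`, `ring_arc` (degrees, eye frame, `lo < hi`
#'   unwrapped).
#' @export
build_wedge <- function(loc, transform, params, map_shape,
                        mm_per_px = 4.11 / 960, ring_radius_mm = 1.75,
                        ci_z = 1.96, polar = NULL) {
  phi0 <- vf_point_to_phi0(loc, transform, params)
  half <- ci_z * params$variability_sd_deg
  lo <- phi0 - half; hi <- phi0 + half
  ## clamp at the temporal raphe discontinuity (+-180)
  if (phi0 >= 0) { hi <- min(hi, 180); lo <- max(lo, -180 + 1e-6) }
  else { lo <- max(lo, -180 + 1e-6); hi <- min(hi, 180) }
  nr <- map_shape[1]; nc <- map_shape[2]
  if (is.null(polar)) polar <- polar_grid(transform, map_shape, mm_per_px)
  r <- polar$r; psi <- polar$psi
  inr <- r >= params$r0
  ldr <- log(pmax(r - params$r0, 1e-12))
  blo <- lo + traj_b(lo, params) * exp(traj_c(lo, params) * ldr)
  bhi <- hi + traj_b(hi, params) * exp(traj_c(hi, params) * ldr)
  mask <- inr & ang_diff(psi, blo) >= 0 & ang_diff(psi, bhi) <= 0
  mask <- matrix(mask, nr, nc)
  if (!any(mask)) stopf("ROI outside field for location %s", loc$index)
  ## ring arc: bounding trajectories evaluated at the ring radius (model
  ## frame), mapped back to the eye's profile angle convention
  r_ring <- transform$scale * ring_radius_mm / mm_per_degree()
  arc_m <- c(traj_phi(r_ring, lo, params), traj_phi(r_ring, hi, params))
  arc_eye_lo <- arc_m[1] - transform$rot_deg
  arc <- c(arc_eye_lo, arc_eye_lo + (arc_m[2] - arc_m[1]))
  if (diff(arc) <= 0) stopf("empty ring arc for location %s", loc$index)
  structure(list(location_index = loc$index, phi0 = phi0,
                 phi0_lo = lo, phi0_hi = hi,
                 pixel_mask = mask, ring_arc = arc,
                 r0 = params$r0, mm_per_px = mm_per_px),
            class = "wedge_roi")
}

#' @export
print.wedge_roi <- function(x, ...) {
  cat(sprintf("<wedge_roi> location %s: phi0 = %.1f deg [%.1f, %.1f], %d px, ring arc [%.1f, %.1f] deg\n",
              x$location_index, x$phi0, x$phi0_lo, x$phi0_hi,
              sum(x$pixel_mask), x$ring_arc[1], x$ring_arc[2]))
  invisible(x)
}

#' Wedges for all analysis locations
#'
#' @param locs Data frame from [vf_analysis_locations()].
#' @inheritParams build_wedge
#' @return Named list of [build_wedge()] results (names = location index).
#' @export
build_all_wedges <- function(locs, transform, params, map_shape,
                             mm_per_px = 4.11 / 960, ...) {
  polar <- polar_grid(transform, map_shape, mm_per_px)
  out <- lapply(seq_len(nrow(locs)), function(i)
    build_wedge(locs[i, ], transform, params, map_shape, mm_per_px,
                polar = polar, ...))
  names(out) <- locs$index
  out
}

## Model-frame polar coordinates of every pixel of a disc-centred frame
## (the normalized map is disc-centred by construction of the crop).
polar_grid <- function(transform, map_shape, mm_per_px) {
  nr <- map_shape[1]; nc <- map_shape[2]
  dp <- mm_per_px / mm_per_degree()
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  u1 <- (rep(seq_len(nc), each = nr) - cx) * dp
  u2 <- -(rep(seq_len(nr), times = nc) - cy) * dp
  cosd <- cos(transform$rot_deg * pi / 180)
  sind <- sin(transform$rot_deg * pi / 180)
  k <- transform$scale
  m1 <- k * (cosd * u1 - sind * u2)
  m2 <- k * (sind * u1 + cosd * u2)
  list(r = sqrt(m1^2 + m2^2), psi = atan2(m2, m1) / pi * 180)
}
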