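## Synthetic cohort generator with known ground truth.
##
## The stated world: glaucomatous damage is parameterized on the disc-entry
## angle phi0 (arcuate clusters plus a diffuse component), so structural and
## functional ground truth stay consistent by construction through the same
## trajectory mapping the pipeline uses.  Damage d in [0, 1] maps to
## noiseless focal VF deviation through a two-segment (broken-stick) link
## with a floor, and to capillary density / RNFL thickness through linear
## floors-plus-damage links; per-subject random intercepts and Gaussian
## noise sit on the structural channels, emulating the floor-effect
## behaviour the segmented analysis is designed to detect.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
            else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
    set.seed(seed)
  }
  force(code)
}

#' Synthetic cohort configuration
#'
#' Defaults describe a 46-eye open-angle-glaucoma cohort spanning early to
#' advanced field loss (MD from 0 down to -26 dB, stratified in thirds
#' across the early / moderate / advanced MD bands), with a structural
#' floor: the damage-to-dB link steepens beyond `d_bp` so that, seen on the
#' structure-vs-function plane, the structural slope flattens left of a
#' breakpoint at `-db_per_damage_pre * d_bp` = -9 dB.
#'
#' @param n_subjects Cohort size.
#' @param md_range_db Range of target mean deviations (dB).
#' @param d_bp Damage level at the link breakpoint.
#' @param db_per_damage_pre,db_per_damage_post dB lost per unit damage
#'   before/after the breakpoint (post > pre creates the structural floor).
#' @param db_floor Perimetric floor (clamp) in dB.
#' @param cd_base,cd_floor Healthy capillary density and its floor.
#' @param t_base_mean,t_floor,hump_amp Healthy RNFL profile: mean (um),
#'   floor (um) and amplitude of the double-hump modulation.
#' @param sigma_b_cd,sigma_e_cd,sigma_b_t,sigma_e_t Random-intercept and
#'   residual SDs of the two structural channels (density fraction / um).
#' @param vf_noise_db Test-retest noise of the VF deviations.
#' @param n_arcades,vessel_width_mm Large-vessel arcade count and width.
#' @param fd_dist_sd,fd_angle_sd Geometry jitter (degrees) around the
#'   canonical fovea-disc distance/angle.
#' @param img_px,img_mm Rendered angiogram frame (before normalization).
#' @param n_profile_samples Circumpapillary profile sampling.
#' @param speckle_sd Grayscale noise added to the rendered angiogram.
#' @param qc_fail_rate Fraction of exams rendered with failing reliability.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 46L,
                          md_range_db = c(-26, 0),
                          d_bp = 0.45,
                          db_per_damage_pre = 20,
                          db_per_damage_post = 48,
                          db_floor = -35,
                          cd_base = 0.35, cd_floor = 0.05,
                          t_base_mean = 90, t_floor = 55, hump_amp = 12,
                          sigma_b_cd = 0.02, sigma_e_cd = 0.02,
                          sigma_b_t = 6, sigma_e_t = 5,
                          vf_noise_db = 1.5,
                          n_arcades = 4L, vessel_width_mm = 0.08,
                          fd_dist_sd = 0.7, fd_angle_sd = 2.5,
                          img_px = 480L, img_mm = 4.5,
                          n_profile_samples = 768L,
                          speckle_sd = 0.03,
                          qc_fail_rate = 0) {
  if (n_subjects < 2L) stopf("n_subjects must be >= 2")
  if (cd_floor >= cd_base) stopf("infeasible config: cd_floor >= cd_base")
  if (t_floor >= t_base_mean) stopf("infeasible config: t_floor >= t_base_mean")
  cfg <- as.list(environment())
  cfg$psi_true_db <- -db_per_damage_pre * d_bp
  structure(cfg, class = "cohort_config")
}

## Damage -> noiseless fVFD (dB), two-segment link with floor.
damage_to_db <- function(d, cfg) {
  db <- ifelse(d <= cfg$d_bp, -cfg$db_per_damage_pre * d,
               -cfg$db_per_damage_pre * cfg$d_bp -
                 cfg$db_per_damage_post * (d - cfg$d_bp))
  pmax(db, cfg$db_floor)
}

## Damage -> noiseless capillary density.
damage_to_cd <- function(d, cfg) cfg$cd_floor + (cfg$cd_base - cfg$cd_floor) * (1 - d)

## Healthy circumpapillary thickness template: double hump with peaks at the
## superior/inferior poles (eye-frame angle, degrees).
t_base_profile <- function(theta, cfg) {
  bump <- function(c0, w) exp(-(ang_diff(theta, c0) / w)^2)
  cfg$t_base_mean + cfg$hump_amp * (bump(70, 40) + bump(-70, 40) - 0.4)
}

## Damage + template -> noiseless thickness at eye angle theta.
damage_to_t <- function(d, theta, cfg)
  cfg$t_floor + (t_base_profile(theta, cfg) - cfg$t_floor) * (1 - d)

## One subject's damage field on the disc-entry angle: diffuse component
## plus 1-3 arcuate Gaussian clusters, scaled so the mean noiseless fVFD
## over the analysis locations hits the target MD.
sample_damage_field <- function(target_md, phi0_locs, cfg) {
  nb <- sample(1:3, 1L)
  centers <- sample(c(-1, 1), nb, replace = TRUE) *
    stats::runif(nb, 60, 170)
  widths <- stats::runif(nb, 12, 30)
  amps <- stats::runif(nb, 0.5, 1)
  base <- function(phi0) {
    v <- rep(0.25, length(phi0))
    for (k in seq_len(nb))
      v <- v + amps[k] * exp(-(ang_diff(phi0, centers[k]) / widths[k])^2)
    v
  }
  mean_md <- function(s) mean(damage_to_db(pmin(s * base(phi0_locs), 1), cfg))
  if (target_md >= mean_md(0)) s <- 0
  else if (target_md <= mean_md(60)) s <- 60
  else s <- stats::uniroot(function(s) mean_md(s) - target_md,
                           c(0, 60), tol = 1e-6)$root
  function(phi0) pmin(s * base(phi0), 1)
}

## Stratified target MDs: thirds across early / moderate / advanced bands.
sample_target_mds <- function(n, cfg) {
  lo <- cfg$md_range_db[1]
  bands <- list(c(-6, cfg$md_range_db[2]), c(-12, -6), c(lo, -12))
  band_of <- rep_len(1:3, n)
  vapply(band_of, function(b) stats::runif(1, bands[[b]][1], bands[[b]][2]), 0)
}

## Disc-entry angles and ring-arc mid angles of the analysis locations in
## the canonical frame (identical for all subjects).
canonical_location_geometry <- function(params, locs) {
  geom <- eye_geometry(fd_distance_deg = sqrt(sum(params$canonical_disc_xy_deg^2)),
                       fd_angle_deg = atan2(params$canonical_disc_xy_deg[2],
                                            params$canonical_disc_xy_deg[1]) / pi * 180)
  tr <- fit_to_eye(params, geom)
  phi0 <- vapply(seq_len(nrow(locs)), function(i)
    vf_point_to_phi0(locs[i, ], tr, params), 0)
  r_ring <- 1.75 / mm_per_degree()
  theta <- traj_phi(r_ring, phi0, params)   # canonical frame: eye == model
  list(phi0 = phi0, ring_theta = wrap180(theta))
}

#' Simulate an analysis-table cohort (no image rendering)
#'
#' Fast statistical layer of the generator: per-location damage via the
#' trajectory mapping, broken-stick links, random intercepts and noise, but
#' the structural values are produced directly rather than measured from
#' rendered images.  Used for statistical calibration studies where
#' hundreds of cohorts are needed.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed (same seed, same cohort).
#' @param params Trajectory atlas.
#' @param exclude Extra location exclusions.
#' @return `list(records, truth)`; `records` is the analysis table
#'   (`subject_id, location_index, fVFD, fCD, fRNFLT`), `truth` adds the
#'   noiseless values and damage per row plus per-subject intercepts.
#' @export
simulate_records <- function(config = cohort_config(), seed = 1L,
                             params = trajectory_params(),
                             exclude = integer(0)) {
  locs <- vf_analysis_locations(vf_build_grid("right"), exclude)
  cg <- canonical_location_geometry(params, locs)
  with_seed(seed, {
    mds <- sample_target_mds(config$n_subjects, config)
    rows <- vector("list", config$n_subjects)
    for (i in seq_len(config$n_subjects)) {
      sid <- sprintf("S%03d", i)
      dmg <- sample_damage_field(mds[i], cg$phi0, config)
      d <- dmg(cg$phi0)
      fvfd0 <- damage_to_db(d, config)
      fcd0 <- damage_to_cd(d, config)
      frnflt0 <- damage_to_t(d, cg$ring_theta, config)
      b_cd <- stats::rnorm(1, 0, config$sigma_b_cd)
      b_t <- stats::rnorm(1, 0, config$sigma_b_t)
      fvfd <- pmin(pmax(fvfd0 + stats::rnorm(length(d), 0, config$vf_noise_db),
                        config$db_floor), 5)
      fcd <- pmin(pmax(fcd0 + b_cd + stats::rnorm(length(d), 0, config$sigma_e_cd),
                       0.005), 0.98)
      frnflt <- pmin(pmax(frnflt0 + b_t + stats::rnorm(length(d), 0, config$sigma_e_t),
                          1), 200)
      rows[[i]] <- data.frame(subject_id = sid, location_index = locs$index,
                              fVFD = fvfd, fCD = fcd, fRNFLT = frnflt,
                              d = d, fVFD0 = fvfd0, fCD0 = fcd0,
                              fRNFLT0 = frnflt0, target_md = mds[i],
                              b_cd = b_cd, b_t = b_t)
    }
    all <- do.call(rbind, rows)
    list(records = all[, c("subject_id", "location_index", "fVFD", "fCD", "fRNFLT")],
         truth = all)
  })
}

#' Simulate data directly from the segmented mixed model
#'
#' `y_ij = beta0 + slope_before * x + slope_change * (x - psi)_+ + u_i + e_ij`
#' with per-subject random intercepts; the covariate x emulates fVFD
#' (subject severity plus within-subject spread).  The reference generator
#' for breakpoint-recovery and test-size studies.
#'
#' @param n_subjects,n_per_subject Cohort dimensions.
#' @param psi True breakpoint (dB); on the x axis.
#' @param beta0,slope_before,slope_change Fixed effects (slope_change = 0
#'   gives a straight-line null).
#' @param sigma_b,sigma_e Random-intercept and residual SD.
#' @param x_range Covariate support.
#' @param seed RNG seed.
#' @return data.frame `subject_id, fVFD, y` (plus `fCD`/`fRNFLT` aliases of
#'   `y` so the segmented interface accepts it directly).
#' @export
simulate_segmented_data <- function(n_subjects = 46L, n_per_subject = 74L,
                                    psi = -9, beta0 = 0.33,
                                    slope_before = 0.002, slope_change = 0.013,
                                    sigma_b = 0.02, sigma_e = 0.025,
                                    x_range = c(-30, 2), seed = 1L) {
  with_seed(seed, {
    sid <- rep(sprintf("S%03d", seq_len(n_subjects)), each = n_per_subject)
    center <- rep(stats::runif(n_subjects, x_range[1] + 4, x_range[2] - 2),
                  each = n_per_subject)
    x <- pmin(pmax(center + stats::rnorm(length(sid), 0, 7),
                   x_range[1]), x_range[2])
    u <- rep(stats::rnorm(n_subjects, 0, sigma_b), each = n_per_subject)
    y <- beta0 + slope_before * x + slope_change * pmax(x - psi, 0) +
      u + stats::rnorm(length(sid), 0, sigma_e)
    data.frame(subject_id = sid, fVFD = x, y = y, fCD = y, fRNFLT = y)
  })
}

## ---- image-level rendering -------------------------------------------------

## Stamp a filled disk of radius rad (px) at integer centre (row, col).
stamp_disk <- function(mask, row, col, rad) {
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- max(1L, floor(row - rad)); r1 <- min(nr, ceiling(row + rad))
  c0 <- max(1L, floor(col - rad)); c1 <- min(nc, ceiling(col + rad))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  sub <- outer(rr - row, cc - col, function(a, b) a^2 + b^2 <= rad^2)
  mask[rr, cc] <- mask[rr, cc] | sub
  mask
}

#' Render a synthetic en-face angiogram
#'
#' Capillary texture as short segments oriented along the local nerve-fiber
#' trajectory direction, thinned/filled per (phi0 sector x radius band)
#' cell to match the target density field exactly; large vessels as smooth
#' arcade curves traced along trajectories, stamped at the configured
#' width.  Returns the grayscale image plus the ground-truth large-vessel
#' mask for Dice scoring.
#'
#' @param density Target per-pixel capillary density matrix (values in
#'   \[0, 1\]).
#' @param field `phi0_field()` output for the same frame.
#' @param transform Subject's [fit_to_eye()] transform.
#' @param params Trajectory atlas.
#' @param cfg A [cohort_config()].
#' @param arcade_phi0 Disc-entry angles of the large-vessel arcades.
#' @return `list(img (octa_image), vessel_mask, capillary)`.
#' @export
render_angiogram <- function(density, field, transform, params, cfg,
                             arcade_phi0 = NULL) {
  nr <- nrow(density); nc <- ncol(density)
  mm_per_px <- cfg$img_mm / cfg$img_px
  ## --- large-vessel arcades (drawn first: vessel pixels are excluded from
  ## the capillary budget so wedge densities stay exact around arcades)
  vessel <- matrix(FALSE, nr, nc)
  if (cfg$n_arcades > 0L) {
    if (is.null(arcade_phi0))
      arcade_phi0 <- c(105, 140, -105, -140)[seq_len(min(cfg$n_arcades, 4L))] +
        stats::runif(min(cfg$n_arcades, 4L), -6, 6)
    wpx <- cfg$vessel_width_mm / mm_per_px / 2
    for (p0 in arcade_phi0) {
      rr <- seq(params$r0, cfg$img_mm / mm_per_degree(), by = 0.1)
      phis <- traj_phi(rr, p0, params)
      pxy <- transform$model_to_px(cbind(rr * cos(phis * pi / 180),
                                         rr * sin(phis * pi / 180)))
      keep <- pxy[, 1] >= -wpx & pxy[, 1] <= nc + wpx &
              pxy[, 2] >= -wpx & pxy[, 2] <= nr + wpx
      pxy <- pxy[keep, , drop = FALSE]
      for (j in seq_len(nrow(pxy)))
        vessel <- stamp_disk(vessel, pxy[j, 2], pxy[j, 1], wpx)
    }
  }
  ## --- capillary layer: oriented segments, then exact per-cell correction
  L <- 3L
  seed_p <- pmin(density / L, 1)
  seeds <- which(matrix(stats::runif(nr * nc), nr, nc) < seed_p)
  cap <- matrix(FALSE, nr, nc)
  if (length(seeds)) {
    sr <- (seeds - 1L) %% nr + 1L
    sc <- (seeds - 1L) %/% nr + 1L
    phi0s <- field$phi0[seeds]
    rs <- field$r[seeds]; psis <- field$psi[seeds]
    phi0s[is.na(phi0s)] <- psis[is.na(phi0s)]
    ## trajectory tangent in the model frame, rotated back to the image
    dphidr <- traj_b(phi0s, params) * traj_c(phi0s, params) *
      pmax(rs - params$r0, 1e-3)^(traj_c(phi0s, params) - 1)
    psir <- psis * pi / 180
    tx <- cos(psir) - rs * dphidr * pi / 180 * sin(psir)
    ty <- sin(psir) + rs * dphidr * pi / 180 * cos(psir)
    ang <- atan2(ty, tx) - transform$rot_deg * pi / 180
    dx <- cos(ang); dy <- -sin(ang)      # image y runs downward
    for (stp in 0:(L - 1L)) {
      rr <- pmin(pmax(as.integer(round(sr + stp * dy)), 1L), nr)
      cc <- pmin(pmax(as.integer(round(sc + stp * dx)), 1L), nc)
      cap[cbind(rr, cc)] <- TRUE
    }
  }
  ## exact per-cell thinning/filling: cells on (phi0 sector, radius band)
  cap <- cap & !vessel
  cell_phi <- floor((field$phi0 + 180) / 3.75)  # 3.75 deg entry-angle sectors
  cell_r <- floor(field$r / 0.75)               # 0.75 deg radial bands
  cell <- ifelse(is.na(cell_phi) | vessel, -1, cell_phi * 100 + cell_r)
  for (cl in unique(cell[cell >= 0])) {
    px <- which(cell == cl)
    tgt <- round(sum(density[px]))
    cur <- which(cap[px]); ncur <- length(cur)
    if (ncur > tgt) {
      off <- cur[sample.int(length(cur), ncur - tgt)]
      cap[px[off]] <- FALSE
    } else if (ncur < tgt) {
      empty <- which(!cap[px])
      if (length(empty)) {
        fill <- empty[sample.int(length(empty), min(tgt - ncur, length(empty)))]
        cap[px[fill]] <- TRUE
      }
    }
  }
  ## --- compose grayscale
  img <- matrix(0.08, nr, nc)
  img[cap] <- 0.8
  img[vessel] <- 1.0
  ## dark optic disc
  disc_r <- 0.9 / mm_per_px
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  dmask <- outer(seq_len(nr), seq_len(nc),
                 function(i, j) (i - cy)^2 + (j - cx)^2 <= disc_r^2)
  img[dmask] <- 0.05
  if (cfg$speckle_sd > 0)
    img <- pmin(pmax(img + matrix(stats::rnorm(nr * nc, 0, cfg$speckle_sd),
                                  nr, nc), 0), 1)
  list(img = octa_image(img, mm_per_px = mm_per_px),
       vessel_mask = vessel, capillary = cap)
}

#' Simulate a complete synthetic cohort with rendered inputs
#'
#' For each subject: sampled eye geometry, a trajectory-aligned damage
#' field, a rendered en-face angiogram whose wedge-measured density matches
#' the true focal capillary density, a circumpapillary RNFL profile whose
#' arc means match the true focal thickness, and a 30-2 exam derived from
#' the same damage field through the broken-stick link, plus a per-location
#' ground-truth table.
#'
#' @param config A [cohort_config()] (use small `n_subjects` for tests;
#'   rendering is the slow path).
#' @param seed RNG seed; identical seeds reproduce the bundle exactly.
#' @param params Trajectory atlas.
#' @param exclude Extra location exclusions.
#' @param noise Master switch; `FALSE` zeroes every noise source (random
#'   intercepts, residuals, VF noise, speckle) for closed-loop tests.
#' @return `list(inputs = list(exams, images, profiles, geometry,
#'   vessel_masks), truth = data.frame, config, seed)`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            params = trajectory_params(),
                            exclude = integer(0), noise = TRUE) {
  if (!noise) {
    config$sigma_b_cd <- config$sigma_e_cd <- 0
    config$sigma_b_t <- config$sigma_e_t <- 0
    config$vf_noise_db <- 0; config$speckle_sd <- 0
  }
  grid <- vf_build_grid("right")
  locs <- vf_analysis_locations(grid, exclude)
  cg <- canonical_location_geometry(params, locs)
  canon_dist <- sqrt(sum(params$canonical_disc_xy_deg^2))
  canon_ang <- atan2(params$canonical_disc_xy_deg[2],
                     params$canonical_disc_xy_deg[1]) / pi * 180
  mm_per_px <- config$img_mm / config$img_px
  deg_per_px <- mm_per_px / mm_per_degree()
  with_seed(seed, {
    mds <- sample_target_mds(config$n_subjects, config)
    exams <- list(); images <- list(); profiles <- list()
    vessel_masks <- list(); geom_rows <- list(); truth_rows <- list()
    for (i in seq_len(config$n_subjects)) {
      sid <- sprintf("S%03d", i)
      fd_dist <- stats::rnorm(1, canon_dist, config$fd_dist_sd)
      fd_ang <- stats::rnorm(1, canon_ang, config$fd_angle_sd)
      disc_px <- c((config$img_px + 1) / 2, (config$img_px + 1) / 2)
      fovea_px <- disc_px - c(fd_dist * cos(fd_ang * pi / 180),
                              -fd_dist * sin(fd_ang * pi / 180)) / deg_per_px
      geom <- eye_geometry(fovea_xy = fovea_px, disc_xy = disc_px,
                           mm_per_px = mm_per_px)
      tr <- fit_to_eye(params, geom)
      dmg <- sample_damage_field(mds[i], cg$phi0, config)
      b_cd <- stats::rnorm(1, 0, config$sigma_b_cd)
      b_t <- stats::rnorm(1, 0, config$sigma_b_t)
      ## per-pixel density field (function of phi0 only)
      field <- phi0_field(tr, params, c(config$img_px, config$img_px))
      dpx <- dmg(ifelse(is.na(field$phi0), field$psi, field$phi0))
      density <- matrix(pmin(pmax(damage_to_cd(dpx, config) + b_cd, 0.01), 0.95),
                        config$img_px, config$img_px)
      ren <- render_angiogram(density, field, tr, params, config)
      images[[sid]] <- ren$img
      vessel_masks[[sid]] <- ren$vessel_mask
      ## circumpapillary profile (eye-frame angles)
      theta <- (seq_len(config$n_profile_samples) - 1L) *
        360 / config$n_profile_samples
      r_ring_m <- tr$scale * 1.75 / mm_per_degree()
      phi0_ring <- solve_phi0_vec(rep(r_ring_m, length(theta)),
                                  wrap180(theta + tr$rot_deg), params)
      d_ring <- dmg(phi0_ring)
      t_noiseless <- damage_to_t(d_ring, theta, config)
      thick <- pmin(pmax(t_noiseless + b_t +
                           stats::rnorm(length(theta), 0, config$sigma_e_t), 1), 200)
      profiles[[sid]] <- rnfl_profile(theta, thick)
      ## exam: td over the full grid (blind spot gets near-zero filler)
      d_loc <- dmg(cg$phi0)
      fvfd0 <- damage_to_db(d_loc, config)
      td <- stats::setNames(rep(NA_real_, nrow(grid)), grid$index)
      td[as.character(locs$index)] <-
        pmin(pmax(fvfd0 + stats::rnorm(length(fvfd0), 0, config$vf_noise_db),
                  config$db_floor), 5)
      bs <- grid$index[grid$is_blind_spot]
      td[as.character(bs)] <- round(stats::rnorm(length(bs), -1, 1), 1)
      fail <- stats::runif(1) < config$qc_fail_rate
      exams[[sid]] <- vf_exam(sid, "right", td,
                              fixation_loss_frac = if (fail) 0.5 else stats::runif(1, 0, 0.2),
                              fp_frac = stats::runif(1, 0, 0.1),
                              fn_frac = stats::runif(1, 0, 0.1))
      ## ground truth per location: wedge means on the render frame
      wedges <- build_all_wedges(locs, tr, params,
                                 c(config$img_px, config$img_px), mm_per_px)
      fcd_true <- vapply(wedges, function(w) {
        keep <- w$pixel_mask & !ren$vessel_mask
        if (!sum(keep)) return(NA_real_)
        mean(density[keep])
      }, 0)
      ## independent fine-grid arc means of the noiseless thickness
      fine <- seq(0, 360 - 0.1, by = 0.1)
      phi0_fine <- solve_phi0_vec(rep(r_ring_m, length(fine)),
                                  wrap180(fine + tr$rot_deg), params)
      t_fine <- damage_to_t(dmg(phi0_fine), fine, config) + b_t
      frnflt_true <- vapply(wedges, function(w) {
        rel <- wrap360(fine - w$ring_arc[1])
        mean(t_fine[rel < (w$ring_arc[2] - w$ring_arc[1])])
      }, 0)
      truth_rows[[i]] <- data.frame(
        subject_id = sid, location_index = locs$index, d = d_loc,
        fVFD0 = fvfd0, fCD_true = unname(fcd_true),
        fRNFLT_true = unname(frnflt_true), target_md = mds[i],
        b_cd = b_cd, b_t = b_t)
      geom_rows[[i]] <- data.frame(subject_id = sid, eye = "right",
                                   fovea_x_px = fovea_px[1], fovea_y_px = fovea_px[2],
                                   disc_x_px = disc_px[1], disc_y_px = disc_px[2])
    }
    list(inputs = list(exams = exams, images = images, profiles = profiles,
                       geometry = do.call(rbind, geom_rows),
                       vessel_masks = vessel_masks),
         truth = do.call(rbind, truth_rows),
         config = config, seed = seed)
  })
}

#' Ground-truth table of a simulated cohort
#'
#' @param bundle Output of [simulate_cohort()].
#' @param path Optional CSV path to write.
#' @return The truth data.frame (one row per subject x analysis location).
#' @export
truth_table <- function(bundle, path = NULL) {
  tt <- bundle$truth
  if (!is.null(path)) utils::write.csv(tt, path, row.names = FALSE)
  tt
}

#' Write a simulated cohort to disk in the ingest dialects
#'
#' PGM angiograms with JSON scale sidecars, RNFL profile CSVs, SAP CSV +
#' JSON, geometry CSV, truth table CSV and the generator config.
#'
#' @param bundle Output of [simulate_cohort()].
#' @param out_dir Output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(bundle$inputs$images)) {
    img <- bundle$inputs$images[[sid]]
    write_pgm(img$pixels, file.path(out_dir, paste0(sid, "_octa.pgm")),
              mm_per_px = img$mm_per_px)
    utils::write.csv(bundle$inputs$profiles[[sid]],
                     file.path(out_dir, paste0(sid, "_rnfl.csv")),
                     row.names = FALSE)
  }
  write_sap(bundle$inputs$exams, file.path(out_dir, "sap.csv"),
            file.path(out_dir, "sap.json"))
  utils::write.csv(bundle$inputs$geometry, file.path(out_dir, "geometry.csv"),
                   row.names = FALSE)
  truth_table(bundle, file.path(out_dir, "truth.csv"))
  cfg <- bundle$config
  jsonlite::write_json(cfg[!vapply(cfg, is.function, TRUE)],
                       file.path(out_dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
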