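params <- trajectory_params()
tr <- canonical_transform(params)
grid <- vf_build_grid("right")
locs <- vf_analysis_locations(grid)

test_that("trajectories start exactly at their disc-entry angle", {
  for (phi0 in c(-170, -95, -60.5, -20, 0, 33, 60, 100, 145, 180)) {
    f <- trace_trajectory(phi0, params)
    expect_identical(f(params$r0), phi0)
  }
  expect_error(trace_trajectory(-181, params), "outside the covered range")
  f <- trace_trajectory(90, params)
  expect_error(f(2), "undefined for r")
})

test_that("zero-bend configuration gives straight radial rays", {
  rp <- radial_params()
  f <- trace_trajectory(77, rp)
  expect_equal(f(seq(4, 25, by = 0.5)), rep(77, 43))
})

test_that("phi(r) is strictly monotone in r when b != 0", {
  r <- seq(params$r0 + 1e-6, 30, length.out = 400)
  for (phi0 in c(70, 100, 140, -70, -100, -140)) {
    v <- trace_trajectory(phi0, params)(r)
    expect_true(all(diff(v) > 0) || all(diff(v) < 0))
  }
})

test_that("mirrored entry angles give mirror-image curves under a symmetric atlas", {
  sp <- symmetric_params()
  r <- seq(4, 25, length.out = 100)
  for (phi0 in c(65, 90, 120, 160)) {
    up <- trace_trajectory(phi0, sp)(r)
    dn <- trace_trajectory(-phi0, sp)(r)
    expect_equal(up, -dn, tolerance = 1e-12)
  }
})

test_that("trajectories never cross within a hemifield (1 degree grid, r to 30)", {
  r <- seq(params$r0, 30, length.out = 120)
  for (hemi in list(0:180, -180:0)) {
    M <- vapply(hemi, function(p) focalsf:::traj_phi(r, p, params),
                numeric(length(r)))
    ## phi strictly increasing in phi0 at every radius implies pairwise
    ## angular separation > 0, i.e. non-crossing
    expect_true(all(apply(M, 1L, function(row) all(diff(row) > 0))))
  }
})

test_that("fit_to_eye: canonical geometry gives the identity, rotations invert", {
  expect_equal(tr$scale, 1, tolerance = 1e-12)
  expect_equal(tr$rot_deg, 0, tolerance = 1e-12)
  ## +5 degree fovea-disc angle -> pure rotation of -5 about the disc
  cd <- params$canonical_disc_xy_deg
  g5 <- eye_geometry(fd_distance_deg = sqrt(sum(cd^2)),
                     fd_angle_deg = atan2(cd[2], cd[1]) / pi * 180 + 5)
  t5 <- fit_to_eye(params, g5)
  expect_equal(t5$rot_deg, -5, tolerance = 1e-9)
  expect_equal(t5$scale, 1, tolerance = 1e-12)
  ## px <-> model round trip
  geom <- pixel_geometry()
  t2 <- fit_to_eye(params, geom)
  set.seed(21)
  px <- cbind(runif(50, 1, 480), runif(50, 1, 480))
  back <- t2$model_to_px(t2$px_to_model(px))
  expect_lt(max(abs(back - px)), 1e-9)
  expect_error(eye_geometry(c(1, 1), c(1, 1), 0.01), "distance")
})

test_that("visual-field points invert to disc-entry angles (round trip < 0.5 deg)", {
  for (i in seq_len(nrow(locs))) {
    loc <- locs[i, ]
    phi0 <- vf_point_to_phi0(loc, tr, params)
    m <- focalsf:::field_to_model(loc$x_deg, loc$y_deg, params)
    r <- sqrt(sum(m^2)); psi <- atan2(m[2], m[1]) / pi * 180
    retrace <- trace_trajectory(phi0, params)(r)
    expect_lt(abs(focalsf:::ang_diff(retrace, psi)), 0.5)
  }
  expect_error(vf_point_to_phi0(grid[grid$index == 36, ], tr, params),
               "blind spot")
})

test_that("superior field maps to inferior retina (reflection through fixation)", {
  up <- locs[locs$x_deg == 3 & locs$y_deg == 21, ]
  dn <- locs[locs$x_deg == 3 & locs$y_deg == -21, ]
  expect_lt(vf_point_to_phi0(up, tr, params), 0)   # inferior entry angle
  expect_gt(vf_point_to_phi0(dn, tr, params), 0)
})

test_that("point on the start circle inverts to its own angle (radial atlas)", {
  rp <- radial_params()
  expect_equal(focalsf:::solve_phi0(rp$r0, 37, rp), 37, tolerance = 1e-6)
  expect_equal(focalsf:::solve_phi0(12, -58, rp), -58, tolerance = 1e-6)
})

test_that("wedges shrink towards a single trajectory as the spread vanishes", {
  loc <- locs[locs$x_deg == -15 & locs$y_deg == -9, ]
  areas <- vapply(c(6, 3, 1, 0.25), function(sd) {
    p <- params; p$variability_sd_deg <- sd
    sum(build_wedge(loc, tr, p, c(240, 240), mm_per_px = 4.5 / 240)$pixel_mask)
  }, 0)
  expect_true(all(diff(areas) < 0))
})

test_that("radial atlas: ring arc width equals the phi0 interval", {
  rp <- radial_params()
  loc <- locs[locs$x_deg == -15 & locs$y_deg == -9, ]
  w <- build_wedge(loc, tr, rp, c(240, 240), mm_per_px = 4.5 / 240)
  expect_equal(diff(w$ring_arc), w$phi0_hi - w$phi0_lo, tolerance = 1e-9)
})

test_that("mirror-symmetric locations give mirror-symmetric wedges (symmetric atlas)", {
  sp <- symmetric_params()
  trs <- canonical_transform(sp)
  up <- locs[locs$x_deg == 9 & locs$y_deg == 15, ]
  dn <- locs[locs$x_deg == 9 & locs$y_deg == -15, ]
  wu <- build_wedge(up, trs, sp, c(240, 240), mm_per_px = 4.5 / 240)
  wd <- build_wedge(dn, trs, sp, c(240, 240), mm_per_px = 4.5 / 240)
  expect_equal(wu$phi0, -wd$phi0, tolerance = 1e-6)
  ## pixel mask of one is the vertical reflection of the other
  expect_equal(wu$pixel_mask, wd$pixel_mask[240:1, ], tolerance = 0)
})

test_that("adjacent wedges overlap and masks stay inside their angular bounds", {
  a <- locs[locs$x_deg == -9 & locs$y_deg == 15, ]
  b <- locs[locs$x_deg == -3 & locs$y_deg == 15, ]
  wa <- build_wedge(a, tr, params, c(240, 240), mm_per_px = 4.5 / 240)
  wb <- build_wedge(b, tr, params, c(240, 240), mm_per_px = 4.5 / 240)
  expect_gt(sum(wa$pixel_mask & wb$pixel_mask), 0)
  ## containment: every mask pixel lies between the bounding trajectories
  polar <- focalsf:::polar_grid(tr, c(240, 240), 4.5 / 240)
  sel <- which(wa$pixel_mask)
  blo <- focalsf:::traj_phi(polar$r[sel], wa$phi0_lo, params)
  bhi <- focalsf:::traj_phi(polar$r[sel], wa$phi0_hi, params)
  dpsi_lo <- focalsf:::ang_diff(polar$psi[sel], blo)
  dpsi_hi <- focalsf:::ang_diff(polar$psi[sel], bhi)
  expect_true(all(dpsi_lo >= 0 & dpsi_hi <= 0))
})

test_that("phi0_field agrees with the scalar inversion", {
  geom <- pixel_geometry(img_px = 120L)
  t2 <- fit_to_eye(params, geom)
  f <- phi0_field(t2, params, c(120, 120))
  ok <- which(!is.na(f$phi0))
  set.seed(22)
  for (i in sample(ok, 25)) {
    expect_equal(f$phi0[i],
                 focalsf:::solve_phi0(f$r[i], f$psi[i], params),
                 tolerance = 1e-3)
  }
})

test_that("trajectory config validation catches malformed atlases", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "bad.json")
  jsonlite::write_json(list(r0 = 4), bad, auto_unbox = TRUE)
  expect_error(trajectory_params(bad), "missing field")
})
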