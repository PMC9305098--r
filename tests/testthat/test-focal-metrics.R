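mk_map <- function(perfused, vessels = NULL, mm = 4.11 / 960) {
  if (is.null(vessels)) vessels <- matrix(FALSE, nrow(perfused), ncol(perfused))
  octa_remove_large_vessels(perfused, vessels, mm)
}
mk_roi <- function(mask) {
  structure(list(location_index = 1L, phi0 = 0, phi0_lo = -1, phi0_hi = 1,
                 pixel_mask = mask, ring_arc = c(0, 10), r0 = 4,
                 mm_per_px = 4.11 / 960), class = "wedge_roi")
}

test_that("focal capillary density counts exactly", {
  roi_mask <- matrix(FALSE, 20, 20); roi_mask[1:10, 1:10] <- TRUE  # 100 px
  perf <- matrix(FALSE, 20, 20); perf[1:10, 1:10][sample(100, 37)] <- TRUE
  expect_equal(focal_cd(mk_map(perf), mk_roi(roi_mask)), 0.37)
  ## all-perfused ROI
  expect_equal(focal_cd(mk_map(roi_mask), mk_roi(roi_mask)), 1.0)
  ## ROI fully inside the large-vessel mask: flagged missing, not zero
  vess <- roi_mask
  expect_true(is.na(focal_cd(mk_map(perf & !vess, vess), mk_roi(roi_mask))))
  ## literal reading keeps the vessel area in the denominator
  m <- mk_map(perf, vess)
  expect_false(is.na(focal_cd(m, mk_roi(roi_mask), include_large_vessel_area = TRUE)))
})

test_that("focal_cd ignores pixels outside the ROI and is monotone inside", {
  set.seed(31)
  roi_mask <- matrix(FALSE, 30, 30); roi_mask[5:20, 5:20] <- TRUE
  perf <- matrix(runif(900) < 0.3, 30, 30)
  base <- focal_cd(mk_map(perf), mk_roi(roi_mask))
  out <- perf; out[!roi_mask] <- !out[!roi_mask]       # relabel outside
  expect_equal(focal_cd(mk_map(out), mk_roi(roi_mask)), base)
  more <- perf; more[which(roi_mask & !perf)[1:10]] <- TRUE
  expect_gt(focal_cd(mk_map(more), mk_roi(roi_mask)), base)
})

test_that("focal RNFL thickness averages the samples inside the (wrapping) arc", {
  prof <- rnfl_profile(seq(0, 359.5, by = 0.5), rep(100, 720))
  expect_equal(focal_rnflt(prof, c(12, 57)), 100)
  half <- rnfl_profile(seq(0, 359.5, by = 0.5),
                       ifelse(seq(0, 359.5, by = 0.5) < 180, 50, 150))
  expect_equal(focal_rnflt(half, c(90, 270)), 100)
  ## wrap across 0/360 vs brute-force enumeration on a linear profile
  ang <- seq(0, 359, by = 1)
  lin <- rnfl_profile(ang, 60 + 0.2 * ang)
  arc <- c(350, 370)
  manual <- mean(lin$thickness_um[lin$angle_deg >= 350 | lin$angle_deg < 10])
  expect_equal(focal_rnflt(lin, arc), manual)
  ## half-open membership: adjacent arcs partition the circle
  a1 <- focal_rnflt(lin, c(0, 90)) * 90
  a2 <- focal_rnflt(lin, c(90, 180)) * 90
  a3 <- focal_rnflt(lin, c(180, 270)) * 90
  a4 <- focal_rnflt(lin, c(270, 360)) * 90
  expect_equal((a1 + a2 + a3 + a4) / 360, mean(lin$thickness_um))
  expect_error(focal_rnflt(lin, c(10.2, 10.4)), "sampling step")
  expect_error(focal_rnflt(lin, c(20, 20)), "positive")
})

test_that("full-circle focal thickness equals the global mean exactly", {
  set.seed(32)
  prof <- rnfl_profile(seq(0, 359, by = 1), runif(360, 40, 140))
  expect_identical(focal_rnflt(prof, c(0, 360)), mean(prof$thickness_um))
})

test_that("global metrics: checkerboard density and constant profile", {
  cb <- outer(1:40, 1:40, function(i, j) (i + j) %% 2 == 1)
  gm <- global_metrics(mk_map(cb), rnfl_profile(0:359, rep(62, 360)),
                       disc_radius_mm = 0)
  expect_equal(gm$global_cd, 0.5)
  expect_equal(gm$global_rnflt, 62)
  ## the disc mask removes the centre from the denominator
  centred <- matrix(TRUE, 40, 40)
  gm2 <- global_metrics(mk_map(centred, mm = 0.05), NULL, disc_radius_mm = 0.5)
  expect_equal(gm2$global_cd, 1)
})

test_that("record assembly is the subject x location product with flagged drops", {
  cfg <- cohort_config(n_subjects = 2L, img_px = 240L)
  b <- simulate_cohort(cfg, seed = 3, noise = FALSE)
  params <- trajectory_params()
  locs <- vf_analysis_locations(vf_build_grid("right"))
  maps <- list(); rois <- list()
  for (sid in names(b$inputs$exams)) {
    img <- b$inputs$images[[sid]]
    maps[[sid]] <- preprocess_octa(img, target_px = 480L)
    g <- b$inputs$geometry[b$inputs$geometry$subject_id == sid, ]
    tr <- fit_to_eye(params, eye_geometry(c(g$fovea_x_px, g$fovea_y_px),
                                          c(g$disc_x_px, g$disc_y_px),
                                          img$mm_per_px))
    rois[[sid]] <- build_all_wedges(locs, tr, params, c(480L, 480L),
                                    maps[[sid]]$mm_per_px)
  }
  rec <- assemble_records(b$inputs$exams, maps, b$inputs$profiles, rois)
  expect_equal(nrow(rec), 2L * 74L)
  expect_true(all(rec$fCD >= 0 & rec$fCD <= 1))
  expect_true(all(rec$fRNFLT >= 0))
  ## flag one subject's first wedge as fully vessel-covered -> dropped + logged
  maps2 <- maps
  w1 <- rois[[1]][[1]]$pixel_mask
  maps2[[1]]$large_vessel_mask <- maps2[[1]]$large_vessel_mask | w1
  expect_message(rec2 <- assemble_records(b$inputs$exams, maps2,
                                          b$inputs$profiles, rois),
                 "dropped 1 row")
  expect_equal(nrow(rec2), 2L * 74L - 1L)
  expect_equal(nrow(attr(rec2, "dropped")), 1L)
  ## subject present in one stream only
  expect_error(assemble_records(b$inputs$exams[1], maps, b$inputs$profiles, rois),
               "one input stream only")
  ## empty input
  e <- assemble_records(list(), list(), list(), list())
  expect_equal(nrow(e), 0L)
})
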