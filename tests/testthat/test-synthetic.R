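test_that("same seed reproduces the records cohort exactly", {
  a <- simulate_records(cohort_config(n_subjects = 6L), seed = 77)
  b <- simulate_records(cohort_config(n_subjects = 6L), seed = 77)
  expect_identical(a, b)
  c <- simulate_records(cohort_config(n_subjects = 6L), seed = 78)
  expect_false(identical(a$records$fVFD, c$records$fVFD))
})

test_that("records cohorts have the stated cardinality and plausible ranges", {
  cfg <- cohort_config(n_subjects = 9L)
  sim <- simulate_records(cfg, seed = 2)
  expect_equal(nrow(sim$records), 9L * 74L)
  expect_true(all(sim$records$fCD > 0 & sim$records$fCD < 1))
  expect_true(all(sim$records$fRNFLT >= 0))
  expect_true(all(sim$records$fVFD >= cfg$db_floor - 1e-9 &
                    sim$records$fVFD <= 5))
  ## truth joins 1:1 with the records on (subject, location)
  key <- paste(sim$records$subject_id, sim$records$location_index)
  expect_identical(key, paste(sim$truth$subject_id, sim$truth$location_index))
  expect_true(all(c("d", "fVFD0", "fCD0", "fRNFLT0") %in% names(sim$truth)))
})

test_that("target severities span the range and split into thirds by design", {
  cfg <- cohort_config(n_subjects = 45L)
  sim <- simulate_records(cfg, seed = 4)
  md <- unique(sim$truth[, c("subject_id", "target_md")])$target_md
  expect_equal(length(md), 45L)
  bands <- cut(md, c(-Inf, -12, -6, Inf))
  expect_equal(as.vector(table(bands)), rep(15L, 3))
  expect_true(min(md) >= cfg$md_range_db[1] && max(md) <= cfg$md_range_db[2])
})

test_that("the broken-stick link is exactly recoverable when noise vanishes", {
  cfg <- cohort_config()
  cfg$sigma_b_cd <- cfg$sigma_e_cd <- cfg$sigma_b_t <- cfg$sigma_e_t <- 0
  cfg$vf_noise_db <- 0
  sim <- simulate_records(cfg, seed = 5)
  f <- fit_segmented_lmm(sim$records, "fCD", davies = FALSE)
  expect_true(f$converged)
  expect_lt(abs(f$psi - cfg$psi_true_db), 0.25)
  cd_range <- cfg$cd_base - cfg$cd_floor
  expect_equal(f$slope_before, cd_range / cfg$db_per_damage_post, tolerance = 0.05)
  expect_equal(f$slope_after, cd_range / cfg$db_per_damage_pre, tolerance = 0.05)
})

test_that("damage-to-dB link and structural links honour their design", {
  cfg <- cohort_config()
  expect_equal(focalsf:::damage_to_db(0, cfg), 0)
  expect_equal(focalsf:::damage_to_db(cfg$d_bp, cfg), cfg$psi_true_db)
  expect_equal(focalsf:::damage_to_cd(0, cfg), cfg$cd_base)
  expect_equal(focalsf:::damage_to_cd(1, cfg), cfg$cd_floor)
  expect_error(cohort_config(cd_floor = 0.5, cd_base = 0.4), "infeasible")
})

test_that("rendered angiograms hit their density targets through preprocessing", {
  cfg <- cohort_config(n_subjects = 2L)
  params <- trajectory_params()
  geom <- pixel_geometry()
  tr <- fit_to_eye(params, geom)
  field <- phi0_field(tr, params, c(480L, 480L))
  set.seed(81)
  ren <- render_angiogram(matrix(0.18, 480, 480), field, tr, params, cfg)
  pm <- preprocess_octa(ren$img, target_px = 480L)
  gm <- global_metrics(pm, NULL, disc_radius_mm = 1.2)
  expect_lt(abs(gm$global_cd - 0.18), 0.03)
  ## no arcades requested -> empty true mask; zero density -> blank layer
  cfg0 <- cohort_config(n_subjects = 2L, n_arcades = 0L)
  set.seed(82)
  ren0 <- render_angiogram(matrix(0, 480, 480), field, tr, params, cfg0)
  expect_false(any(ren0$vessel_mask))
  expect_false(any(ren0$capillary))
})

test_that("full cohort bundles are deterministic and complete", {
  cfg <- cohort_config(n_subjects = 3L, img_px = 240L)
  b1 <- simulate_cohort(cfg, seed = 11, noise = TRUE)
  b2 <- simulate_cohort(cfg, seed = 11, noise = TRUE)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$inputs$images[["S002"]]$pixels,
                   b2$inputs$images[["S002"]]$pixels)
  expect_equal(length(b1$inputs$images), 3L)
  expect_equal(length(b1$inputs$profiles), 3L)
  expect_equal(length(b1$inputs$exams), 3L)
  expect_equal(nrow(b1$truth), 3L * 74L)
  ## written bundle round-trips through the ingest readers
  d <- withr::local_tempdir()
  write_cohort(b1, d)
  expect_true(file.exists(file.path(d, "S001_octa.pgm")))
  img <- read_octa_image(file.path(d, "S001_octa.pgm"))
  expect_equal(dim(img$pixels), c(240L, 240L))
  expect_equal(img$mm_per_px, cfg$img_mm / cfg$img_px)
  exams <- read_sap(file.path(d, "sap.csv"), file.path(d, "sap.json"))
  expect_equal(length(exams), 3L)
  tt <- utils::read.csv(file.path(d, "truth.csv"))
  expect_equal(nrow(tt), nrow(b1$truth))
})

test_that("reliability indices pass QC by default; the fail-rate knob works", {
  cfg <- cohort_config(n_subjects = 4L, img_px = 240L)
  b <- simulate_cohort(cfg, seed = 12)
  passes <- vapply(b$inputs$exams, function(e) vf_check_reliability(e)$pass, TRUE)
  expect_true(all(passes))
  cfgf <- cohort_config(n_subjects = 4L, img_px = 240L, qc_fail_rate = 1)
  bf <- simulate_cohort(cfgf, seed = 12)
  failed <- vapply(bf$inputs$exams, function(e) vf_check_reliability(e)$pass, TRUE)
  expect_false(any(failed))
})
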