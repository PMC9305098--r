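test_that("the profiled-REML random-intercept fitter matches lme4", {
  skip_if_not_installed("lme4")
  for (i in 1:4) {
    d <- simulate_segmented_data(n_subjects = 10 + 2 * i, n_per_subject = 12,
                                 sigma_b = 0.02 * i, seed = 50 + i)
    X <- cbind(1, x = d$fVFD)
    mine <- lmm_ranint(d$y, X, d$subject_id, reml = TRUE)
    ref <- lme4::lmer(y ~ fVFD + (1 | subject_id), data = d, REML = TRUE)
    expect_equal(unname(mine$beta), unname(lme4::fixef(ref)), tolerance = 1e-6)
    expect_equal(mine$sigma_e, sigma(ref), tolerance = 1e-4)
    expect_equal(mine$sigma_b, sqrt(unlist(lme4::VarCorr(ref))[[1]]),
                 tolerance = 1e-3)
    expect_equal(unname(sqrt(diag(mine$vcov))),
                 unname(coef(summary(ref))[, "Std. Error"]), tolerance = 1e-4)
    ## ML route too
    mml <- lmm_ranint(d$y, X, d$subject_id, reml = FALSE)
    rml <- lme4::lmer(y ~ fVFD + (1 | subject_id), data = d, REML = FALSE)
    expect_equal(mml$loglik, as.numeric(logLik(rml)), tolerance = 1e-5)
  }
})

test_that("with no random effects the fit collapses to ordinary least squares", {
  set.seed(55)
  n <- 80
  x <- runif(n, -25, 0)
  y <- 0.3 + 0.01 * x + rnorm(n, 0, 0.05)
  sub <- rep(sprintf("S%d", 1:40), each = 2)
  ## data generated with sigma_b = 0: lambda should go to ~0 and beta to OLS
  f <- lmm_ranint(y, cbind(1, x = x), sub)
  o <- ols_oracle(y, cbind(1, x))
  expect_equal(unname(f$beta), unname(o$beta), tolerance = 1e-3)
  expect_lt(f$sigma_b, 0.02)
})

test_that("segmented fit recovers a known breakpoint and matches the grid oracle", {
  d <- simulate_segmented_data(n_subjects = 40, n_per_subject = 40,
                               sigma_b = 0, sigma_e = 0.02, seed = 60)
  ## single record per subject, sigma_b = 0: plain segmented least squares
  d1 <- d[!duplicated(d$subject_id), ]
  d1 <- simulate_segmented_data(n_subjects = 600, n_per_subject = 1,
                                sigma_b = 0, sigma_e = 0.02, seed = 61)
  f <- fit_segmented_lmm(d1, "fCD", davies = FALSE)
  o <- segmented_ols_oracle(d1$fVFD, d1$y)
  span <- diff(range(d1$fVFD))
  expect_lt(abs(f$psi - o$psi) / span, 1e-3)
  expect_equal(f$slope_before, o$slope_before, tolerance = 1e-3)
  expect_equal(f$slope_change, o$slope_change, tolerance = 1e-2)
  ## and the designed truth is recovered
  expect_lt(abs(f$psi - (-9)), 0.5)
  expect_equal(f$fvfd_at_bp, f$psi)
})

test_that("estimates are invariant to subject relabeling and record order", {
  d <- simulate_segmented_data(n_subjects = 20, n_per_subject = 20, seed = 62)
  f1 <- fit_segmented_lmm(d, "fCD", davies = FALSE)
  d2 <- d[rev(seq_len(nrow(d))), ]
  d2$subject_id <- paste0("Z", d2$subject_id)
  f2 <- fit_segmented_lmm(d2, "fCD", davies = FALSE)
  expect_equal(f2$psi, f1$psi, tolerance = 1e-6)
  expect_equal(f2$slope_before, f1$slope_before, tolerance = 1e-8)
  expect_equal(f2$sigma_b, f1$sigma_b, tolerance = 1e-6)
})

test_that("segmented preconditions and errors", {
  d <- simulate_segmented_data(n_subjects = 12, n_per_subject = 10, seed = 63)
  expect_error(fit_segmented_lmm(d, "fVFD"), "fCD")
  expect_error(fit_segmented_lmm(d, "fCD", psi_init = 99), "outside support")
  d1 <- d[d$subject_id == d$subject_id[1], ]
  expect_error(fit_segmented_lmm(d1, "fCD"), "2 subjects")
})

test_that("Davies test: power on a strong break, equivariance, errors", {
  d <- simulate_segmented_data(n_subjects = 20, n_per_subject = 30, seed = 64)
  dv <- davies_test(d, "fCD")
  expect_lt(dv$p_value, 0.001)
  expect_equal(length(dv$candidates), 10L)
  ## positive scaling of the response leaves the p value unchanged
  d2 <- d; d2$fCD <- d2$fCD * 1000
  expect_equal(davies_test(d2, "fCD")$p_value, dv$p_value, tolerance = 1e-8)
  expect_error(davies_test(d, "fCD", k_grid = 3L), "k_grid")
  dflat <- d; dflat$fVFD <- -10
  expect_error(davies_test(dflat, "fCD"), "collinear")
  ## p values live in (0, 1]
  d0 <- simulate_segmented_data(n_subjects = 10, n_per_subject = 10,
                                slope_change = 0, seed = 65)
  p0 <- davies_test(d0, "fCD")$p_value
  expect_gt(p0, 0); expect_lte(p0, 1)
})

test_that("breakpoint report echoes the fits and flags non-convergence", {
  d <- simulate_segmented_data(seed = 66)
  fcd <- fit_segmented_lmm(d, "fCD", davies = FALSE)
  dt <- simulate_segmented_data(beta0 = 95, slope_before = 0.65,
                                slope_change = 0.92, sigma_b = 5, sigma_e = 6,
                                seed = 67)
  ft <- fit_segmented_lmm(dt, "fRNFLT", davies = FALSE)
  tab <- report_table3(ft, fcd)
  expect_equal(tab$parameter, c("fRNFL-T", "fCD"))
  expect_match(tab$fvfd_at_bp[2], sprintf("%.2f", fcd$psi), fixed = TRUE)
  nc <- fcd; nc$converged <- FALSE
  tab2 <- report_table3(ft, nc)
  expect_match(tab2$parameter[2], "not converged")
  bad <- fcd; bad$ci_psi <- fcd$psi + c(1, 2)
  expect_error(report_table3(ft, bad), "CI does not contain")
})

test_that("segmented mixed fit recovers design parameters at cohort scale", {
  d <- simulate_segmented_data(seed = 68)   # defaults: 46 x 74, psi -9
  f <- fit_segmented_lmm(d, "fCD", davies = FALSE)
  expect_true(f$converged)
  expect_lt(abs(f$psi - (-9)), 1.5)
  expect_equal(f$slope_before, 0.002, tolerance = 0.5)
  expect_equal(f$slope_change, 0.013, tolerance = 0.3)
  expect_lt(abs(f$sigma_b - 0.02), 0.01)
  expect_lt(abs(f$sigma_e - 0.025), 0.005)
  ## CIs contain their point estimates
  expect_true(f$ci_psi[1] < f$psi && f$psi < f$ci_psi[2])
  expect_true(f$ci_slope_before[1] < f$slope_before &&
                f$slope_before < f$ci_slope_before[2])
})
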