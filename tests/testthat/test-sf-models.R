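test_that("per-location OLS matches the normal-equations oracle", {
  set.seed(41)
  for (i in 1:20) {
    rec <- toy_records(n = 20, seed = 100 + i, sd = runif(1, 0.2, 3))
    for (mid in c("Mv", "Mt", "Mvt")) {
      f <- fit_location(rec, mid, 1L)
      X <- switch(mid,
                  Mv = cbind(1, rec$fCD),
                  Mt = cbind(1, rec$fRNFLT),
                  Mvt = cbind(1, rec$fCD, rec$fRNFLT, rec$fCD * rec$fRNFLT))
      o <- ols_oracle(rec$fVFD, X)
      expect_equal(unname(f$coefficients), unname(o$beta), tolerance = 1e-8)
      expect_equal(f$rss, o$rss, tolerance = 1e-8)
      expect_equal(f$loglik, o$loglik, tolerance = 1e-8)
    }
  }
})

test_that("loglik and AIC agree with the stats reference implementation", {
  rec <- toy_records(n = 25, seed = 7)
  f <- fit_location(rec, "Mvt", 1L)
  ref <- lm(fVFD ~ fCD * fRNFLT, data = rec)
  expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-10)
  expect_equal(f$aic, AIC(ref), tolerance = 1e-10)
  fs <- summary(ref)$fstatistic
  expect_equal(f$p_value,
               unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
               tolerance = 1e-10)
})

test_that("exact fits and univariate correlation identities", {
  set.seed(42)
  fcd <- runif(20, 0.05, 0.35)
  rec <- data.frame(fVFD = -30 + 80 * fcd, fCD = fcd, fRNFLT = runif(20, 55, 95))
  f <- fit_location(rec, "Mv", 1L)
  expect_equal(f$r_p, 1, tolerance = 1e-10)
  expect_lt(f$rss, 1e-10)
  rec2 <- toy_records(n = 30, seed = 9, sd = 4)
  f2 <- fit_location(rec2, "Mv", 1L)
  expect_equal(f2$r_p, abs(cor(rec2$fCD, rec2$fVFD)), tolerance = 1e-12)
  ## degenerate predictor
  rec3 <- rec2; rec3$fCD <- 0.2
  expect_error(fit_location(rec3, "Mv", 1L), "zero-variance")
  expect_error(fit_location(rec2[1:5, ], "Mv", 1L), "complete records")
})

test_that("model comparison: identities, df and degenerate case", {
  rec <- toy_records(n = 30, seed = 10, sd = 2)
  fv <- fit_location(rec, "Mv", 1L)
  ft <- fit_location(rec, "Mt", 1L)
  fvt <- fit_location(rec, "Mvt", 1L)
  cmp <- compare_models(fvt, fv)
  expect_equal(cmp$lrt_df, 2L)
  ## algebraic identity: 2 dloglik == n log(rss ratio)
  expect_equal(cmp$lrt_stat, fv$n * log(fv$rss / fvt$rss), tolerance = 1e-8)
  expect_equal(cmp$delta_aic, fvt$aic - fv$aic)
  ## identical fits -> stat 0, p 1
  cmp0 <- compare_models(fv, fv)
  expect_equal(cmp0$lrt_stat, 0)
  expect_equal(cmp0$lrt_p, 1)
  fv2 <- fv; fv2$n <- 29L
  expect_error(compare_models(fvt, fv2), "differing n")
  expect_error(compare_models(fv, fvt), "nest")
})

test_that("r_p is invariant to row order and affine predictor rescaling", {
  rec <- toy_records(n = 30, seed = 11, sd = 2)
  f <- fit_location(rec, "Mvt", 1L)
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(fit_location(shuf, "Mvt", 1L)$r_p, f$r_p, tolerance = 1e-12)
  resc <- rec
  resc$fCD <- 100 * rec$fCD - 3
  resc$fRNFLT <- 0.1 * rec$fRNFLT + 7
  expect_equal(fit_location(resc, "Mvt", 1L)$r_p, f$r_p, tolerance = 1e-10)
})

test_that("location maps summarize significance, AIC and LRT winners", {
  sim <- simulate_records(cohort_config(n_subjects = 24L), seed = 3)
  fits <- fit_all_locations(sim$records)
  lm_ <- location_maps(fits, alpha = c(0.05, 0.001))
  expect_equal(nrow(lm_$per_location), 74L)
  expect_named(lm_$summary$r_p_mean, c("Mv", "Mt", "Mvt"))
  ## nesting: the combined model correlates at least as well everywhere
  expect_true(all(lm_$per_location$r_p_Mvt >= lm_$per_location$r_p_Mv - 1e-12))
  expect_true(all(lm_$per_location$r_p_Mvt >= lm_$per_location$r_p_Mt - 1e-12))
  ## significance counts are monotone in alpha
  expect_true(all(lm_$summary$significant$alpha_0.001 <=
                    lm_$summary$significant$alpha_0.05))
  ## AIC favours the full model iff the LRT statistic exceeds 2 df
  pl <- lm_$per_location
  lrt_stat <- qchisq(pl$lrt_p_Mvt_vs_Mv, 2, lower.tail = FALSE)
  expect_equal(pl$aic_Mvt_beats_Mv, lrt_stat > 4, tolerance = 0)
})

test_that("global fits mirror the per-location equations at cohort level", {
  set.seed(44)
  n <- 30
  cd <- runif(n, 0.08, 0.3); t <- runif(n, 50, 90)
  subjects <- data.frame(md = -28 + 60 * cd + rnorm(n, 0, 1.5),
                         global_cd = cd, global_rnflt = t)
  g <- global_fit(subjects)
  expect_named(g$r_p, c("Mv", "Mt", "Mvt"))
  expect_gte(g$r_p["Mvt"], max(g$r_p["Mv"], g$r_p["Mt"]) - 1e-12)
  ## exact linear dependence on CD
  exact <- data.frame(md = -28 + 60 * cd, global_cd = cd, global_rnflt = t)
  expect_equal(unname(global_fit(exact)$r_p["Mv"]), 1, tolerance = 1e-10)
  ## oracle agreement
  o <- ols_oracle(subjects$md, cbind(1, cd, t, cd * t))
  expect_equal(unname(g$Mvt$coefficients), unname(o$beta), tolerance = 1e-8)
})
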