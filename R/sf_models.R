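## Per-location regression models of focal visual-field deviation.
##
## Three nested linear models are fitted across subjects at every analysis
## location:
##   Mv :  fVFD = b0 + b1 * fCD + e
##   Mt :  fVFD = b0 + b1 * fRNFLT + e
##   Mvt:  fVFD = b0 + b1 * fCD + b2 * fRNFLT + b3 * fCD * fRNFLT + e
## and compared by Pearson correlation of fitted vs observed fVFD, AIC and
## likelihood-ratio tests (df = 2 for both nested comparisons).

model_terms <- function(model_id) {
  switch(model_id,
         Mv = "fCD", Mt = "fRNFLT",
         Mvt = c("fCD", "fRNFLT", "fCD:fRNFLT"),
         stopf("unknown model_id '%s'", model_id))
}

## Design matrix for one model on a records data.frame.
model_design <- function(records, model_id) {
  X <- cbind(`(Intercept)` = 1, fCD = records$fCD, fRNFLT = records$fRNFLT,
             `fCD:fRNFLT` = records$fCD * records$fRNFLT)
  X[, c("(Intercept)", model_terms(model_id)), drop = FALSE]
}

#' Fit one structure-function model at one location
#'
#' Ordinary least squares of the chosen equation across subjects.  The
#' log-likelihood is the Gaussian profile log-likelihood and
#' `aic = -2 loglik + 2 (k + 1)` (the error variance counts as a
#' parameter); `r_p` is the Pearson correlation between fitted and observed
#' fVFD, which for a univariate model equals the absolute sample
#' correlation of predictor and response, and for the combined model is the
#' multiple correlation coefficient.
#'
#' @param records data.frame with columns `fVFD`, `fCD`, `fRNFLT` (complete
#'   cases are used; listwise deletion).
#' @param model_id `"Mv"`, `"Mt"` or `"Mvt"`.
#' @param location_index Carried through to the result.
#' @param min_n Minimum complete records required.
#' @return `list(location_index, model_id, coefficients, rss, loglik, aic,
#'   r_p, p_value, n, k)` of class `sf_fit`.
#' @export
fit_location <- function(records, model_id = c("Mv", "Mt", "Mvt"),
                         location_index = records$location_index[1],
                         min_n = 10L) {
  model_id <- match.arg(model_id)
  rec <- records[stats::complete.cases(records[, c("fVFD", "fCD", "fRNFLT")]), ]
  n <- nrow(rec)
  if (n < min_n)
    stopf("location %s: only %d complete records (< %d)", location_index, n, min_n)
  X <- model_design(rec, model_id)
  y <- rec$fVFD
  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(sds == 0))
    stopf("location %s: zero-variance predictor (%s)", location_index,
          paste(colnames(X)[-1][sds == 0], collapse = ", "))
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  rss <- sum(res^2)
  k <- ncol(X) - 1L
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  aic <- -2 * loglik + 2 * (k + 2)       # k slopes + intercept + error variance
  fitted <- y - res
  r_p <- if (stats::sd(fitted) == 0) 0 else stats::cor(fitted, y)
  tss <- sum((y - mean(y))^2)
  fstat <- ((tss - rss) / k) / (rss / (n - k - 1L))
  p_value <- stats::pf(fstat, k, n - k - 1L, lower.tail = FALSE)
  structure(list(location_index = location_index, model_id = model_id,
                 coefficients = fit$coefficients, rss = rss, loglik = loglik,
                 aic = aic, r_p = r_p, p_value = p_value, n = n, k = k),
            class = "sf_fit")
}

#' @export
print.sf_fit <- function(x, ...) {
  cat(sprintf("<sf_fit> %s @ location %s: r_p = %.3f, AIC = %.1f, p = %.2g (n = %d)\n",
              x$model_id, x$location_index, x$r_p, x$aic, x$p_value, x$n))
  invisible(x)
}

#' Compare a full model with a nested reduced model
#'
#' Likelihood-ratio test (`lrt_stat = 2 (ll_full - ll_reduced) =
#' n log(rss_reduced / rss_full)`, chi-square with df = difference in slope
#' counts, which is 2 for both Mvt-vs-Mv and Mvt-vs-Mt) plus the AIC
#' difference.
#'
#' @param full,reduced Two [fit_location()] results on the same records.
#' @param alpha LRT significance level.
#' @return `list(location_index, pair, delta_aic, lrt_stat, lrt_df, lrt_p,
#'   winner_by_aic, lrt_significant)`.
#' @export
compare_models <- function(full, reduced, alpha = 0.05) {
  if (full$n != reduced$n)
    stopf("model fits use differing n (%d vs %d)", full$n, reduced$n)
  if (!identical(full$location_index, reduced$location_index))
    stopf("model fits are for different locations")
  df <- full$k - reduced$k
  if (df < 0) stopf("'full' does not nest 'reduced'")
  lrt <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0L) as.numeric(lrt > 1e-10) * 0 + 1 else
    stats::pchisq(lrt, df, lower.tail = FALSE)
  list(location_index = full$location_index,
       pair = paste0(full$model_id, "_vs_", reduced$model_id),
       delta_aic = full$aic - reduced$aic,
       lrt_stat = lrt, lrt_df = df, lrt_p = p,
       winner_by_aic = if (full$aic < reduced$aic) full$model_id else reduced$model_id,
       lrt_significant = p < alpha)
}

#' Fit all three models at every analysis location
#'
#' @param records Analysis table (`subject_id, location_index, fVFD, fCD,
#'   fRNFLT`).
#' @param min_n Passed to [fit_location()].
#' @return Named list (by location index) of lists `Mv`, `Mt`, `Mvt`.
#' @export
fit_all_locations <- function(records, min_n = 10L) {
  locs <- sort(unique(records$location_index))
  out <- lapply(locs, function(li) {
    rec <- records[records$location_index == li, ]
    lapply(stats::setNames(nm = c("Mv", "Mt", "Mvt")), function(mid)
      fit_location(rec, mid, location_index = li, min_n = min_n))
  })
  names(out) <- locs
  out
}

#' Per-location summary maps and cohort summaries
#'
#' @param fits Output of [fit_all_locations()].
#' @param alpha Significance levels for the per-model maps.
#' @return A list: `per_location` (data.frame with r_p, p, AIC per model,
#'   LRT/AIC comparisons for both pairs), `summary` (mean +- SD r_p and
#'   significance / winner counts per model).
#' @export
location_maps <- function(fits, alpha = c(0.05, 0.001)) {
  rows <- lapply(fits, function(f) {
    cv <- compare_models(f$Mvt, f$Mv)
    ct <- compare_models(f$Mvt, f$Mt)
    data.frame(location_index = f$Mv$location_index,
               n = f$Mv$n,
               r_p_Mv = f$Mv$r_p, r_p_Mt = f$Mt$r_p, r_p_Mvt = f$Mvt$r_p,
               p_Mv = f$Mv$p_value, p_Mt = f$Mt$p_value, p_Mvt = f$Mvt$p_value,
               aic_Mv = f$Mv$aic, aic_Mt = f$Mt$aic, aic_Mvt = f$Mvt$aic,
               aic_Mvt_beats_Mv = cv$delta_aic < 0,
               aic_Mvt_beats_Mt = ct$delta_aic < 0,
               lrt_p_Mvt_vs_Mv = cv$lrt_p, lrt_p_Mvt_vs_Mt = ct$lrt_p)
  })
  per_loc <- do.call(rbind, rows)
  rownames(per_loc) <- NULL
  sig <- lapply(alpha, function(a)
    c(Mv = sum(per_loc$p_Mv < a), Mt = sum(per_loc$p_Mt < a),
      Mvt = sum(per_loc$p_Mvt < a)))
  names(sig) <- paste0("alpha_", alpha)
  summary <- list(
    n_locations = nrow(per_loc),
    r_p_mean = c(Mv = mean(per_loc$r_p_Mv), Mt = mean(per_loc$r_p_Mt),
                 Mvt = mean(per_loc$r_p_Mvt)),
    r_p_sd = c(Mv = stats::sd(per_loc$r_p_Mv), Mt = stats::sd(per_loc$r_p_Mt),
               Mvt = stats::sd(per_loc$r_p_Mvt)),
    significant = sig,
    aic_wins_Mvt_vs_Mv = sum(per_loc$aic_Mvt_beats_Mv),
    aic_wins_Mvt_vs_Mt = sum(per_loc$aic_Mvt_beats_Mt),
    lrt_wins_Mvt_vs_Mv = sum(per_loc$lrt_p_Mvt_vs_Mv < 0.05),
    lrt_wins_Mvt_vs_Mt = sum(per_loc$lrt_p_Mvt_vs_Mt < 0.05))
  list(per_location = per_loc, summary = summary)
}

#' Plot a per-location significance / winner map in field coordinates
#'
#' @param per_location `per_location` table from [location_maps()].
#' @param column Logical column of that table to display.
#' @param grid Grid from [vf_build_grid()].
#' @param main Plot title.
#' @export
plot_location_map <- function(per_location, column, grid = vf_build_grid("right"),
                              main = column) {
  idx <- match(per_location$location_index, grid$index)
  val <- per_location[[column]]
  graphics::plot(grid$x_deg[idx], grid$y_deg[idx], pch = 15, cex = 2,
                 col = ifelse(val, "#2c7fb8", "#d7301f"),
                 xlab = "eccentricity (deg, temporal +)",
                 ylab = "eccentricity (deg, superior +)", main = main,
                 xlim = c(-30, 30), ylim = c(-30, 30), asp = 1)
  graphics::abline(h = 0, v = 0, col = "gray70", lty = 3)
  invisible(NULL)
}

#' Global (cohort-level) structure-function fits
#'
#' The same three equations fitted once across subjects, with mean deviation
#' (MD) as the response and global CD / global RNFL-T as predictors.
#'
#' @param subjects data.frame with columns `md`, `global_cd`,
#'   `global_rnflt`.
#' @param min_n Minimum subjects.
#' @return Named list of [fit_location()]-style results (`Mv`, `Mt`, `Mvt`)
#'   plus `r_p` triple.
#' @export
global_fit <- function(subjects, min_n = 10L) {
  rec <- data.frame(fVFD = subjects$md, fCD = subjects$global_cd,
                    fRNFLT = subjects$global_rnflt)
  fits <- lapply(stats::setNames(nm = c("Mv", "Mt", "Mvt")), function(mid)
    fit_location(rec, mid, location_index = 0L, min_n = min_n))
  fits$r_p <- vapply(fits[c("Mv", "Mt", "Mvt")], function(f) f$r_p, 0)
  fits
}
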