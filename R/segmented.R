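## Segmented (broken-stick) regression on a random-intercept mixed model,
## with the Davies test for the existence of a breakpoint.
##
## The structural channel (fCD or fRNFL-T) is the response and focal
## visual-field deviation (fVFD, dB) the covariate, so the breakpoint psi
## lives directly on the fVFD axis ("fVFD at BP") and the slopes are in
## structure units per dB: this is the parameterization under which a
## floor effect appears as a flatter slope on the severe (left, more
## negative dB) side of the breakpoint.  A per-subject random intercept
## absorbs repeated measurements from the same individual.
##
## Estimation follows the iterative linearization of segmented regression:
## at the current psi the working model adds U = (x - psi) * 1[x > psi] and
## V = -1[x > psi]; the gap coefficient gamma (on V) is zero at a true
## breakpoint, and psi is updated by gamma / deltahat with step halving
## until the update is negligible.  SE(psi) by the delta method:
## SE(gamma)/|deltahat|.

seg_response <- function(records, predictor_id) {
  switch(predictor_id, fCD = records$fCD, fRNFLT = records$fRNFLT,
         stopf("unknown predictor_id '%s' (use 'fCD' or 'fRNFLT')", predictor_id))
}

#' Segmented mixed-model fit of a focal structure-function relationship
#'
#' @param records Analysis table with columns `subject_id`, `fVFD` and the
#'   chosen structural channel (`fCD` or `fRNFLT`).
#' @param predictor_id Structural channel to analyse: `"fCD"` or
#'   `"fRNFLT"`.
#' @param psi_init Initial breakpoint (dB); default the median fVFD.
#' @param max_iter,tol Iteration control; `tol` is the psi update threshold
#'   as a fraction of the fVFD range.
#' @param reml Variance components by REML (default).
#' @param davies Also compute the Davies p value.
#' @return Object of class `segmented_fit`: `predictor_id`, `psi`
#'   (breakpoint, dB), `fvfd_at_bp` (= psi, the breakpoint expressed on the
#'   fVFD axis), `slope_before` (structure/dB left of psi), `slope_change`,
#'   `slope_after`, `ci_psi`, `ci_slope_before`, `ci_slope_change`,
#'   `sigma_b`, `sigma_e`, `value_at_bp` (fixed-effect response at psi),
#'   `davies_p`, `converged`, `n_iter`, `n`.
#' @export
fit_segmented_lmm <- function(records, predictor_id = c("fCD", "fRNFLT"),
                              psi_init = NULL, max_iter = 50L, tol = 1e-4,
                              reml = TRUE, davies = TRUE) {
  predictor_id <- match.arg(predictor_id)
  y <- seg_response(records, predictor_id)
  x <- records$fVFD
  subject <- records$subject_id
  ok <- stats::complete.cases(x, y, subject)
  x <- x[ok]; y <- y[ok]; subject <- droplevels(as.factor(subject[ok]))
  if (nlevels(subject) < 2L) stopf("need records from at least 2 subjects")
  ## with one record per subject the random intercept is unidentifiable and
  ## the REML fit collapses to segmented least squares (lambda -> 0)
  rng <- range(x); span <- diff(rng)
  if (span <= 0) stopf("fVFD has no spread")
  ## the breakpoint is kept inside the central mass of the covariate (as is
  ## standard for segmented estimation: the edges cannot identify a break)
  bounds <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  psi <- if (is.null(psi_init)) stats::median(x) else psi_init
  if (psi <= rng[1] || psi >= rng[2]) stopf("breakpoint outside support")
  if (!any(x <= psi) || !any(x > psi))
    stopf("no spread on both sides of psi_init")
  fit <- NULL; gamma_se <- NA_real_; delta_hat <- NA_real_
  converged <- FALSE; it <- 0L
  prev_step <- 0
  while (it < max_iter) {
    it <- it + 1L
    U <- pmax(x - psi, 0)
    V <- -as.numeric(x > psi)
    X <- cbind(1, x = x, U = U, V = V)
    fit <- lmm_ranint(y, X, subject, reml = reml)
    gamma <- unname(fit$beta[4]); delta_hat <- unname(fit$beta[3])
    gamma_se <- sqrt(fit$vcov[4, 4])
    if (!is.finite(gamma) || !is.finite(delta_hat) || delta_hat == 0) break
    step <- gamma / delta_hat
    if (prev_step != 0 && sign(step) != sign(prev_step))
      step <- step / 2                    # damp oscillation between bends
    new_psi <- psi + step
    half <- 0L
    while ((new_psi <= bounds[1] || new_psi >= bounds[2]) && half < 30L) {
      step <- step / 2; new_psi <- psi + step; half <- half + 1L
    }
    if (half >= 30L) break
    if (abs(step) / span < tol) { psi <- new_psi; converged <- TRUE; break }
    psi <- new_psi
    prev_step <- step
  }
  ## final working fit at the accepted psi (for SE(psi)) and the reduced
  ## final model without the gap term (point estimates of the slopes)
  U <- pmax(x - psi, 0)
  V <- -as.numeric(x > psi)
  fitV <- lmm_ranint(y, cbind(1, x = x, U = U, V = V), subject, reml = reml)
  gamma_se <- sqrt(fitV$vcov[4, 4])
  ffin <- lmm_ranint(y, cbind(1, x = x, U = U), subject, reml = reml)
  slope_before <- unname(ffin$beta[2])
  slope_change <- unname(ffin$beta[3])
  se_b <- sqrt(ffin$vcov[2, 2]); se_c <- sqrt(ffin$vcov[3, 3])
  se_psi <- gamma_se / abs(slope_change)
  z <- stats::qnorm(0.975)
  dav <- if (davies) davies_test(records, predictor_id, reml = reml)$p_value
         else NA_real_
  structure(list(predictor_id = predictor_id, psi = psi, fvfd_at_bp = psi,
                 slope_before = slope_before, slope_change = slope_change,
                 slope_after = slope_before + slope_change,
                 ci_psi = psi + c(-1, 1) * z * se_psi,
                 ci_slope_before = slope_before + c(-1, 1) * z * se_b,
                 ci_slope_change = slope_change + c(-1, 1) * z * se_c,
                 se_psi = se_psi,
                 value_at_bp = unname(ffin$beta[1] + ffin$beta[2] * psi),
                 sigma_b = ffin$sigma_b, sigma_e = ffin$sigma_e,
                 davies_p = dav, converged = converged, n_iter = it,
                 n = length(y), loglik = ffin$loglik),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("<segmented_fit> %s ~ fVFD (broken stick, random intercept)\n",
              x$predictor_id))
  cat(sprintf("  breakpoint (fVFD at BP): %.2f dB [%.2f, %.2f]%s\n",
              x$psi, x$ci_psi[1], x$ci_psi[2],
              if (x$converged) "" else "  (NOT converged)"))
  cat(sprintf("  slope before BP: %.4g [%.4g, %.4g]; slope change: %.4g [%.4g, %.4g]\n",
              x$slope_before, x$ci_slope_before[1], x$ci_slope_before[2],
              x$slope_change, x$ci_slope_change[1], x$ci_slope_change[2]))
  cat(sprintf("  sigma_b = %.4g, sigma_e = %.4g, Davies p = %.3g, n = %d\n",
              x$sigma_b, x$sigma_e, x$davies_p, x$n))
  invisible(x)
}

#' Davies test for the existence of a breakpoint
#'
#' Tests a change in slope when the breakpoint is not identified under the
#' null.  Variance components are estimated once from the linear (no-break)
#' mixed model; at each candidate breakpoint the Wald statistic of the
#' slope-change term is computed by GLS with those components fixed, and
#' the candidate statistics are combined via Davies' upper bound for the
#' supremum of a Gaussian process over the grid (applied to both tails).
#'
#' @inheritParams fit_segmented_lmm
#' @param k_grid Number of candidate breakpoints.
#' @param quantiles Predictor quantiles bracketing the candidate grid.
#' @return `list(p_value, statistics, candidates)`.
#' @export
davies_test <- function(records, predictor_id = c("fCD", "fRNFLT"),
                        k_grid = 10L, quantiles = c(0.05, 0.95), reml = TRUE) {
  predictor_id <- match.arg(predictor_id)
  y <- seg_response(records, predictor_id)
  x <- records$fVFD
  subject <- records$subject_id
  ok <- stats::complete.cases(x, y, subject)
  x <- x[ok]; y <- y[ok]; subject <- droplevels(as.factor(subject[ok]))
  if (k_grid < 5L) stopf("k_grid must be >= 5")
  qs <- stats::quantile(x, quantiles, names = FALSE)
  cand <- seq(qs[1], qs[2], length.out = k_grid)
  if (stats::var(x) == 0) stopf("all candidates collinear")
  null_fit <- lmm_ranint(y, cbind(1, x = x), subject, reml = reml)
  lambda <- null_fit$lambda
  zstat <- vapply(cand, function(ps) {
    U <- pmax(x - ps, 0)
    ## degenerate candidates (all data on one side) are collinear with {1, x}
    if (sum(x > ps) < 3L || sum(x <= ps) < 3L) return(NA_real_)
    g <- gls_fixed_lambda(y, cbind(1, x = x, U = U), subject, lambda)
    z <- unname(g$beta[3] / sqrt(g$vcov[3, 3]))
    if (is.finite(z)) z else NA_real_
  }, 0)
  if (all(is.na(zstat))) stopf("all candidates collinear")
  zs <- zstat[is.finite(zstat)]
  p <- davies_bound(zs)
  list(p_value = p, statistics = zstat, candidates = cand)
}

## Davies (1987) upper bound for the supremum of a Gaussian process over a
## discrete grid, two-sided version: with M = max |z_k| and V the total
## variation of the signed statistic sequence,
##   p <= 2 * [ pnorm(-M) + V exp(-M^2/2) / sqrt(8 pi) ],
## capped at 1.
davies_bound <- function(z) {
  V <- sum(abs(diff(z)))
  M <- max(abs(z))
  p <- min(1, 2 * (stats::pnorm(-M) + V * exp(-M^2 / 2) / sqrt(8 * pi)))
  max(p, .Machine$double.xmin)   # p lives in (0, 1]
}

#' Breakpoint report table
#'
#' Formats the two segmented fits the way a results table would print them:
#' slope before BP, fVFD at BP, and slope change, each with 95% CI.
#'
#' @param fit_t,fit_cd [fit_segmented_lmm()] results for `fRNFLT` and
#'   `fCD`.
#' @param digits Significant digits for slopes.
#' @return data.frame with character columns (annotated when a fit did not
#'   converge).
#' @export
report_table3 <- function(fit_t, fit_cd, digits = 3) {
  fmt1 <- function(v, d = digits) formatC(v, digits = d, format = "g")
  row <- function(f, label) {
    stopifnot(inherits(f, "segmented_fit"))
    cis <- list(f$ci_slope_before, f$ci_psi, f$ci_slope_change)
    pts <- c(f$slope_before, f$psi, f$slope_change)
    for (i in seq_along(cis))
      if (!(cis[[i]][1] <= pts[i] && pts[i] <= cis[[i]][2]))
        stopf("CI does not contain point estimate for %s", label)
    note <- if (f$converged) "" else " [not converged]"
    data.frame(
      parameter = paste0(label, note),
      slope_before_bp = sprintf("%s [%s, %s]", fmt1(pts[1]),
                                fmt1(cis[[1]][1]), fmt1(cis[[1]][2])),
      fvfd_at_bp = sprintf("%.2f [%.2f, %.2f]", pts[2], cis[[2]][1], cis[[2]][2]),
      slope_change = sprintf("%s [%s, %s]", fmt1(pts[3]),
                             fmt1(cis[[3]][1]), fmt1(cis[[3]][2])))
  }
  out <- rbind(row(fit_t, "fRNFL-T"), row(fit_cd, "fCD"))
  rownames(out) <- NULL
  out
}
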