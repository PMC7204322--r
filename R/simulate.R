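# Parametric bootstrap simulation of two-arm trials and the five-test
# battery used to compare the model-based tests with conventional
# approaches.

#' Sample follow-up outcomes under a postulated treatment effect
#'
#' Standard parametric bootstrap: each subject's follow-up score is drawn
#' from the conditional distribution implied by the intercept-only fit,
#' with the transformation shifted by the benefit-scale log odds ratio for
#' treated subjects.  Baselines and strata are left unchanged;
#' `or_benefit > 1` makes treated outcomes stochastically larger, and
#' control subjects are always drawn at `or_benefit = 1`.
#'
#' @param null_fit An [epolr_fit()] with `include_treatment = FALSE`,
#'   estimated on treatment-naive data.
#' @param subjects A [cohort_table()] providing `y0`, `stratum` and `arm`
#'   (the `y3` column is ignored).
#' @param or_benefit Positive benefit odds ratio.
#' @param seed Optional integer seed.
#' @return Integer vector of simulated follow-up scores in `0..k_max`.
#' @export
sample_outcomes <- function(null_fit, subjects, or_benefit, seed = NULL) {
  stopifnot(inherits(null_fit, "epolr_fit"), inherits(subjects, "cohort_table"))
  if (null_fit$include_treatment) {
    stop("'null_fit' must be an intercept-only fit (include_treatment = FALSE)")
  }
  if (!is.numeric(or_benefit) || length(or_benefit) != 1L || or_benefit <= 0) {
    stop("'or_benefit' must be a positive scalar")
  }
  Ci <- .fit_coef_rows(null_fit, subjects$stratum, subjects$y0)
  B <- .fit_prep_grid(null_fit$spec)
  H <- Ci %*% t(B)                       # n x k_max transformation values
  shift <- -log(or_benefit) * as.numeric(subjects$arm)
  cdf <- stats::plogis(H + shift)
  .with_seed(seed, {
    u <- stats::runif(nrow(Ci))
    as.integer(rowSums(cdf < u))
  })
}

#' Wilson score confidence interval for a proportion
#'
#' @param successes Number of successes (vectorized).
#' @param n Number of trials, at least 1.
#' @param level Confidence level (default 0.95).
#' @return For scalar input a named vector `c(lo, hi)`; otherwise a matrix
#'   with columns `lo` and `hi`.  The interval is always contained in
#'   `[0, 1]`.
#' @examples
#' wilson_ci(50, 100)  # (0.4038, 0.5962)
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (any(n < 1)) stop("'n' must be at least 1")
  if (any(successes < 0) || any(successes > n)) {
    stop("'successes' must lie in 0..n")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p_hat <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  lo <- pmax(centre - half, 0)
  hi <- pmin(centre + half, 1)
  if (length(lo) == 1L) c(lo = lo, hi = hi) else cbind(lo = lo, hi = hi)
}

#' Five-test battery for a simulated or observed trial
#'
#' Applies the five significance tests of H0: no treatment effect used in
#' the power study: pooled two-sample t-test on the change scores
#' `y3 - y0`, Wilcoxon rank sum test on the change scores (tie-corrected
#' normal approximation), ANCOVA (`y3 ~ y0 + arm`, two-sided test of the
#' arm coefficient), the asymptotic (Wald) test of the fitted model, and
#' the permutation score test.  A degenerate trial (all outcomes equal, or
#' a test failure) yields p = 1 with a warning rather than an error.
#'
#' @param trial A [cohort_table()] with both arms nonempty.
#' @param spec A [transformation_spec()]; defaults to [default_spec()].
#' @param n_perm Permutations for the score test (default 1000).
#' @param seed Optional integer seed covering the permutation draw.
#' @return Named numeric vector of five two-sided p-values:
#'   `asymptotic_epolr`, `permuted_epolr`, `t_test`, `wilcoxon`, `ancova`.
#' @export
run_test_battery <- function(trial, spec = NULL, n_perm = 1000L,
                             seed = NULL) {
  stopifnot(inherits(trial, "cohort_table"))
  if (length(unique(trial$arm)) < 2L) stop("trial must have both arms")
  p <- c(asymptotic_epolr = NA_real_, permuted_epolr = NA_real_,
         t_test = NA_real_, wilcoxon = NA_real_, ancova = NA_real_)
  guard <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("%s failed (%s); returning p = 1", what,
                      conditionMessage(e)))
      1
    })
  }
  if (stats::var(trial$y3) == 0) {
    warning("degenerate trial: all follow-up outcomes equal; all p = 1")
    p[] <- 1
    return(p)
  }
  change <- trial$y3 - trial$y0
  c1 <- change[trial$arm == 1L]
  c0 <- change[trial$arm == 0L]
  p["t_test"] <- guard({
    if (stats::var(change) == 0) 1
    else stats::t.test(c1, c0, var.equal = TRUE)$p.value
  }, "t-test")
  p["wilcoxon"] <- guard({
    if (stats::var(change) == 0) 1
    else suppressWarnings(
      stats::wilcox.test(c1, c0, exact = FALSE, correct = TRUE)$p.value)
  }, "Wilcoxon test")
  p["ancova"] <- guard({
    fm <- stats::lm(y3 ~ y0 + arm, data = as.data.frame(trial))
    ct <- summary(fm)$coefficients
    if ("arm" %in% rownames(ct)) ct["arm", "Pr(>|t|)"] else 1
  }, "ANCOVA")
  p["asymptotic_epolr"] <- guard({
    fit <- epolr_fit(trial, spec, include_treatment = TRUE, hessian = TRUE)
    wald_inference(fit)$p_two_sided
  }, "asymptotic ePolr test")
  p["permuted_epolr"] <- guard({
    epolr_permutation_test(trial, spec, n_perm = n_perm,
                           seed = seed)$p_value
  }, "permutation ePolr test")
  p
}
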