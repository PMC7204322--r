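# Model-based permutation score test of H0: beta_trt = 0.
#
# The score contribution of subject i is the derivative of its
# log-likelihood with respect to a constant shift alpha added to the
# transformation, evaluated at alpha = 0 under the intercept-only fit:
#   S_i = [w(h(y_i)) - w(h(y_i - 1))] / [expit(h(y_i)) - expit(h(y_i - 1))]
# with w the expit derivative and the +/-Inf boundary conventions.  The
# test statistic T is the sum of the scores of the treated subjects; its
# conditional null distribution is approximated by label permutations.

#' Score contributions under the intercept-only fit
#'
#' @param null_fit An [epolr_fit()] estimated with
#'   `include_treatment = FALSE`.
#' @param data Optional cohort; defaults to the fit's own data and must
#'   match it row-for-row in the analysis columns otherwise.
#' @return Numeric vector of per-subject score contributions.  At the
#'   maximum likelihood solution the contributions sum to (numerically)
#'   zero because a constant shift lies in the span of the transformation
#'   parameters.
#' @export
score_contributions <- function(null_fit, data = NULL) {
  stopifnot(inherits(null_fit, "epolr_fit"))
  if (null_fit$include_treatment || null_fit$beta_hat != 0) {
    stop("'null_fit' must be an intercept-only fit (include_treatment = FALSE)")
  }
  if (is.null(data)) {
    data <- null_fit$data
  } else {
    stopifnot(inherits(data, "cohort_table"))
    same <- nrow(data) == null_fit$n_obs &&
      identical(as.integer(data$y3), as.integer(null_fit$data$y3)) &&
      identical(as.character(data$stratum),
                as.character(null_fit$data$stratum))
    if (!same) stop("'data' does not match the data the null fit was estimated on")
  }
  pr <- .fit_prep(data, null_fit$spec)
  cr <- .ll_core(null_fit$U, null_fit$V, 0, pr)
  sc <- .ll_eta_grad(cr, pr)
  s <- sc$g_u + sc$g_l
  if (any(!is.finite(s))) stop("non-finite score contributions")
  s
}

#' Permutation test of the treatment allocation
#'
#' Tests H0: no treatment effect by comparing the observed statistic
#' `T = sum(scores[arm == 1])` against its distribution under uniform
#' re-randomization of the arm labels (group sizes preserved).  The
#' two-sided p-value uses the permutation-mean-centred absolute statistic
#' and the add-one estimator `(b + 1) / (n_perm + 1)`.
#'
#' @param scores Numeric vector of per-subject scores (see
#'   [score_contributions()] or [wilcoxon_score_transform()]).
#' @param arm Binary treatment indicator, both groups nonempty.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param strata Optional stratum labels: when supplied, labels are
#'   permuted within strata (off by default; the stratification normally
#'   enters through the null model's transformation, not the permutation
#'   scheme).
#' @return An object of class `"epolr_perm"` with `observed_T`, `z`
#'   (standardized against the Monte-Carlo moments), `p_value`, `n_perm`
#'   and `seed`.
#' @export
permutation_test <- function(scores, arm, n_perm = 10000L, seed = NULL,
                             strata = NULL) {
  scores <- as.numeric(scores)
  arm <- as.integer(arm)
  n <- length(scores)
  stopifnot(length(arm) == n, all(arm %in% c(0L, 1L)))
  n1 <- sum(arm)
  if (n1 == 0L || n1 == n) stop("both arms must be nonempty")
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) warning("fewer than 100 permutations; p-value is crude")
  t_obs <- sum(scores[arm == 1L])
  perm_T <- .with_seed(seed, {
    if (is.null(strata)) {
      vapply(seq_len(n_perm),
             function(b) sum(scores[sample.int(n, n1)]), 0)
    } else {
      strata <- as.character(strata)
      stopifnot(length(strata) == n)
      groups <- split(seq_len(n), strata)
      n1_g <- vapply(groups, function(i) sum(arm[i]), 0L)
      vapply(seq_len(n_perm), function(b) {
        tot <- 0
        for (g in seq_along(groups)) {
          i <- groups[[g]]
          tot <- tot + sum(scores[i[sample.int(length(i), n1_g[g])]])
        }
        tot
      }, 0)
    }
  })
  mu <- mean(perm_T)
  sdv <- stats::sd(perm_T)
  scale <- max(abs(perm_T - mu), abs(t_obs - mu), 1)
  p <- (sum(abs(perm_T - mu) >= abs(t_obs - mu) - 1e-12 * scale) + 1) /
    (n_perm + 1)
  structure(list(
    observed_T = t_obs,
    z = if (sdv > 0) (t_obs - mu) / sdv else 0,
    p_value = min(p, 1),
    n_perm = n_perm,
    seed = seed,
    perm_mean = mu,
    perm_sd = sdv
  ), class = "epolr_perm")
}

#' @export
print.epolr_perm <- function(x, ...) {
  cat(sprintf(paste0(
    "Permutation score test (%d permutations)\n",
    "  T = %.4f, Z = %.3f, two-sided p = %.4g\n"),
    x$n_perm, x$observed_T, x$z, x$p_value))
  invisible(x)
}

#' Permutation score test of a cohort
#'
#' Convenience wrapper: fits the intercept-only model, extracts the score
#' contributions and runs the label-permutation test.
#'
#' @param data A [cohort_table()].
#' @param spec A [transformation_spec()]; defaults to [default_spec()].
#' @param n_perm,seed,strata Passed to [permutation_test()].
#' @return An `"epolr_perm"` object with the null fit attached as
#'   `null_fit`.
#' @export
epolr_permutation_test <- function(data, spec = NULL, n_perm = 10000L,
                                   seed = NULL, strata = NULL) {
  null_fit <- epolr_fit(data, spec, include_treatment = FALSE,
                        hessian = FALSE)
  s <- score_contributions(null_fit)
  res <- permutation_test(s, data$arm, n_perm = n_perm, seed = seed,
                          strata = strata)
  res$null_fit <- null_fit
  res
}

#' Rank-based (Wilcoxon) score transformation
#'
#' Score contributions implied by the fixed rank-based transformation
#' `h(m) = logit(R(m) / N)` with upranks `R(m) = #\{j : y_j <= m\}`.  With
#' this transformation the permutation score test reduces to the Wilcoxon
#' rank sum test; the function exists for that equivalence check, not for
#' analysis.
#'
#' @param y Integer outcome vector.
#' @return Numeric vector of scores.
#' @export
wilcoxon_score_transform <- function(y) {
  y <- as.numeric(y)
  n <- length(y)
  upranks <- function(v) vapply(v, function(m) sum(y <= m), 0)
  h_u <- stats::qlogis(upranks(y) / n)
  h_l <- stats::qlogis(upranks(y - 1) / n)
  p_u <- stats::plogis(h_u)
  p_l <- stats::plogis(h_l)
  w_u <- ifelse(is.finite(h_u), p_u * (1 - p_u), 0)
  w_l <- ifelse(is.finite(h_l), p_l * (1 - p_l), 0)
  (w_u - w_l) / (p_u - p_l)
}
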