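# Power estimation over a grid of trial scenarios.

#' Trial scenario grid
#'
#' Builds the scenario grid of the power study: by default five total
#' sample sizes (80, 120, 160, 200, 240; 1:1 allocation) crossed with nine
#' benefit odds ratios (1 to 3 in steps of 0.25), i.e. 45 scenarios.
#'
#' @param n_total Total sample sizes.
#' @param or_benefit Benefit odds ratios (positive).
#' @param n_reps Replicates per scenario.
#' @param seed Master seed of the grid.
#' @return A data frame of class `"trial_scenarios"` with one row per
#'   scenario (`n_total`, `or_benefit`, `n_reps`, `seed`).
#' @export
trial_scenarios <- function(n_total = c(80L, 120L, 160L, 200L, 240L),
                            or_benefit = seq(1, 3, by = 0.25),
                            n_reps = 1000L, seed = 1L) {
  if (any(or_benefit <= 0)) stop("'or_benefit' must be positive")
  if (any(n_total < 4L)) stop("'n_total' too small")
  if (any(n_total %% 2L != 0L)) {
    warning("odd 'n_total': 1:1 allocation uses a floor/ceiling split")
  }
  g <- expand.grid(n_total = as.integer(n_total), or_benefit = or_benefit,
                   KEEP.OUT.ATTRS = FALSE)
  g$n_reps <- as.integer(n_reps)
  g$seed <- as.integer(seed)
  class(g) <- c("trial_scenarios", "data.frame")
  g
}

#' Estimate statistical power over trial scenarios
#'
#' For each scenario, repeatedly (i) draws `n_total` subjects with
#' replacement from the treatment-naive base cohort, (ii) allocates them
#' 1:1 to the arms, (iii) simulates all follow-up outcomes from the
#' intercept-only model fitted once to the base cohort, with the treated
#' arm shifted by the scenario's benefit odds ratio
#' (see [sample_outcomes()]), (iv) applies the five-test battery
#' (the null model is re-estimated on every simulated trial for the
#' permutation test), and records the rejection fraction of each test at
#' level `alpha` together with its Wilson confidence interval.
#'
#' @param scenarios A [trial_scenarios()] grid (or compatible data frame).
#' @param base_cohort A [cohort_table()] of treatment-naive subjects.
#' @param spec A [transformation_spec()]; defaults to
#'   [default_spec()] of the base cohort.
#' @param alpha Nominal level (default 0.05).
#' @param n_perm Permutations per replicate for the score test.
#' @param seed Master seed; per-scenario, per-replicate sub-seeds are
#'   derived deterministically so each scenario is independently
#'   reproducible.
#' @param verbose Print a progress line per scenario.
#' @return A data frame of class `"power_estimate"` with columns
#'   `n_total`, `or_benefit`, `test`, `power`, `wilson_lo`, `wilson_hi`,
#'   `n_reps`.
#' @export
estimate_power <- function(scenarios, base_cohort, spec = NULL,
                           alpha = 0.05, n_perm = 1000L, seed = 1L,
                           verbose = FALSE) {
  stopifnot(is.data.frame(scenarios), inherits(base_cohort, "cohort_table"))
  if (is.null(spec)) spec <- default_spec(base_cohort)
  if (any(scenarios$n_reps < 100L)) {
    warning("fewer than 100 replicates per scenario: Wilson CIs will be wide")
  }
  gen_fit <- epolr_fit(base_cohort, spec, include_treatment = FALSE,
                       hessian = FALSE)
  tests <- c("asymptotic_epolr", "permuted_epolr", "t_test", "wilcoxon",
             "ancova")
  pool <- as.data.frame(base_cohort)
  k_max <- attr(base_cohort, "k_max")
  b_range <- attr(base_cohort, "baseline_range")
  out <- vector("list", nrow(scenarios))
  for (k in seq_len(nrow(scenarios))) {
    n_tot <- scenarios$n_total[k]
    or_b <- scenarios$or_benefit[k]
    n_reps <- scenarios$n_reps[k]
    scen_seed <- .spawn_seed(seed, k * 131071)
    rej <- matrix(FALSE, n_reps, length(tests),
                  dimnames = list(NULL, tests))
    eff <- matrix(FALSE, n_reps, length(tests),
                  dimnames = list(NULL, tests))
    for (r in seq_len(n_reps)) {
      pv <- .with_seed(.spawn_seed(scen_seed, r), {
        idx <- sample.int(nrow(pool), n_tot, replace = TRUE)
        subj <- pool[idx, , drop = FALSE]
        subj$arm <- sample(rep(c(0L, 1L), length.out = n_tot))
        trial <- cohort_table(subj, k_max = k_max,
                              baseline_range = b_range)
        trial$y3 <- sample_outcomes(gen_fit, trial, or_b)
        suppressWarnings(run_test_battery(trial, spec, n_perm = n_perm))
      })
      eff[r, ] <- !is.na(pv)
      rej[r, ] <- !is.na(pv) & pv < alpha
    }
    n_eff <- colSums(eff)
    hits <- colSums(rej)
    ci <- wilson_ci(hits, pmax(n_eff, 1L))
    out[[k]] <- data.frame(
      n_total = n_tot, or_benefit = or_b, test = tests,
      power = hits / pmax(n_eff, 1L),
      wilson_lo = ci[, "lo"], wilson_hi = ci[, "hi"],
      n_reps = as.integer(n_eff), row.names = NULL)
    if (verbose) {
      message(sprintf("scenario %d/%d (N = %d, OR = %.2f) done",
                      k, nrow(scenarios), n_tot, or_b))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("power_estimate", "data.frame")
  res
}
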