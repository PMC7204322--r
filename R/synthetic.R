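# Synthetic treatment-naive cohorts with known ground truth.
#
# The generator emulates the structure of observational spinal-cord-injury
# cohorts: a right-skewed bounded baseline score, a segments-below-motor-
# level count collapsed to three strata, and a follow-up score that is
# positively dependent on the baseline through a smooth monotone
# transformation model of the same cumulative-logit form the package fits.

.COHORT_PRESETS <- list(
  uems = list(k_max = 50L, baseline_range = c(0, 28),
              strata = c("seg4-6", "seg7-8", "seg9-10")),
  scim_total = list(k_max = 100L, baseline_range = c(0, 100),
                    strata = "all"),
  scim_selfcare = list(k_max = 20L, baseline_range = c(0, 20),
                       strata = "all")
)

#' Configuration of a synthetic cohort
#'
#' @param preset Outcome preset: `"uems"` (follow-up 0-50, baseline 0-28,
#'   three segment strata), `"scim_total"` (0-100) or `"scim_selfcare"`
#'   (0-20).
#' @param n_subjects Number of subjects (default 350).
#' @param beta_benefit True benefit log odds ratio applied to treated
#'   subjects (default 0; `exp(beta_benefit) > 1` means treated outcomes
#'   are stochastically larger).
#' @param seed Optional integer seed for [generate_cohort()].
#' @param truth Optional list overriding the generating parameters:
#'   `a0` (global intercept), `a` (per-stratum offsets), `b` (per-stratum
#'   logit slopes, positive), `c_baseline` (coefficient of the rescaled
#'   baseline, non-positive so that follow-up is stochastically
#'   non-decreasing in baseline), `baseline_shape` (Beta parameters of the
#'   discretized baseline law).
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(preset = c("uems", "scim_total", "scim_selfcare"),
                          n_subjects = 350L, beta_benefit = 0,
                          seed = NULL, truth = list()) {
  preset <- match.arg(preset)
  ps <- .COHORT_PRESETS[[preset]]
  n_strata <- length(ps$strata)
  default_truth <- list(
    a0 = 3,
    a = if (n_strata == 3L) c(-1.2, 0, 1.2) else rep(0, n_strata),
    b = if (n_strata == 3L) c(0.9, 1.0, 1.1) else rep(1, n_strata),
    c_baseline = -12,
    baseline_shape = c(1.2, 3.5)
  )
  truth <- utils::modifyList(default_truth, truth)
  if (any(truth$b <= 0)) stop("'b' slopes must be positive")
  if (truth$c_baseline > 0) {
    stop("'c_baseline' must be non-positive (positive dependence)")
  }
  structure(list(
    preset = preset,
    k_max = ps$k_max,
    baseline_range = ps$baseline_range,
    strata = ps$strata,
    n_subjects = as.integer(n_subjects),
    beta_benefit = beta_benefit,
    seed = seed,
    truth = truth
  ), class = "cohort_config")
}

# true transformation values h(y) for y = 0..k_max-1 given covariates
.truth_h <- function(config, stratum_index, m_scaled) {
  tr <- config$truth
  k <- config$k_max
  grid <- stats::qlogis((0:(k - 1L) + 0.5) / (k + 1L))
  outer(tr$b[stratum_index], grid) +
    tr$a0 + tr$a[stratum_index] + tr$c_baseline * m_scaled
}

# true conditional CDF over 0..k_max-1 (the k_max'th value is 1)
.truth_cdf <- function(config, stratum_index, m_scaled, treated = FALSE) {
  shift <- if (treated) -config$beta_benefit else 0
  stats::plogis(.truth_h(config, stratum_index, m_scaled) + shift)
}

#' Generate a synthetic treatment-naive cohort or trial
#'
#' Draws baseline scores from a discretized right-skewed Beta law scaled to
#' the preset range, a segments-below-motor-level count uniform on 4..10
#' mapped to the three strata bands (single stratum for the SCIM presets),
#' allocates subjects 1:1 to the arms, and samples follow-up scores from
#' the true smooth monotone transformation model, shifted by the benefit
#' log odds ratio for treated subjects.
#'
#' @param config A [cohort_config()].
#' @return A list with `cohort` (a [cohort_table()]) and `truth` (the
#'   generating parameters plus a `cdf(baseline, stratum, treated)`
#'   function returning the true conditional CDF over `0..k_max`).
#' @examples
#' g <- generate_cohort(cohort_config("uems", n_subjects = 100, seed = 7))
#' head(g$cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  tr <- config$truth
  .with_seed(config$seed, {
    r <- config$baseline_range
    y0 <- round(r[1L] + stats::rbeta(n, tr$baseline_shape[1L],
                                     tr$baseline_shape[2L]) * (r[2L] - r[1L]))
    if (length(config$strata) == 3L) {
      seg <- sample(4:10, n, replace = TRUE)
      stratum <- config$strata[cut(seg, c(0, 6, 8, 10), labels = FALSE)]
    } else {
      seg <- rep(NA_integer_, n)
      stratum <- rep(config$strata, length.out = n)
    }
    arm <- sample(rep(c(0L, 1L), length.out = n))
    si <- match(stratum, config$strata)
    m_scaled <- (y0 - r[1L]) / (r[2L] - r[1L])
    cdf <- .truth_cdf(config, si, m_scaled) +
      0 * arm  # shape n x k_max
    shift <- -config$beta_benefit * arm
    cdf <- stats::plogis(stats::qlogis(cdf) + shift)
    u <- stats::runif(n)
    y3 <- as.integer(rowSums(cdf < u))
    d <- data.frame(y0 = y0, y3 = y3, stratum = stratum, arm = arm,
                    seg = seg)
    cohort <- cohort_table(d, k_max = config$k_max,
                           baseline_range = config$baseline_range)
    truth <- tr
    truth$beta_benefit <- config$beta_benefit
    truth$cdf <- function(baseline, stratum, treated = FALSE) {
      s <- match(as.character(stratum), config$strata)
      if (is.na(s)) stop("unknown stratum")
      m <- (baseline - r[1L]) / (r[2L] - r[1L])
      c(drop(.truth_cdf(config, s, m, treated)), 1)
    }
    list(cohort = cohort, truth = truth)
  })
}

#' Deterministic 12-subject fixture trial
#'
#' A fixed small trial (6 subjects per arm, outcome scale 0..10, two
#' strata) used by exhaustive-permutation oracles: the
#' `choose(12, 6) = 924` treatment allocations are enumerable instantly.
#'
#' @param seed Integer seed (default 1); the same seed always yields the
#'   identical table.
#' @return A [cohort_table()] with 12 rows.
#' @export
fixture_small_trial <- function(seed = 1L) {
  .with_seed(seed, {
    n <- 12L
    k_max <- 10L
    y0 <- round(stats::rbeta(n, 1.2, 3.5) * 10)
    stratum <- rep(c("A", "B"), 6L)
    arm <- rep(c(0L, 1L), each = 6L)
    a_s <- ifelse(stratum == "B", 0.5, 0)
    grid <- stats::qlogis((0:(k_max - 1L) + 0.5) / (k_max + 1L))
    h <- outer(rep(1, n), grid) + 1.5 + a_s - 6 * (y0 / 10)
    u <- stats::runif(n)
    y3 <- as.integer(rowSums(stats::plogis(h) < u))
    cohort_table(data.frame(y0 = y0, y3 = y3, stratum = stratum, arm = arm),
                 k_max = k_max, baseline_range = c(0, 10))
  })
}
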