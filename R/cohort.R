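#' Per-subject trial records
#'
#' Validates and standardizes a table of per-subject trial records into the
#' four analysis columns used by every fit, test and simulation: baseline
#' score `y0`, follow-up score `y3`, `stratum` and treatment `arm`.
#'
#' @param data A data frame.
#' @param outcome,baseline,stratum,arm Names of the columns holding the
#'   follow-up score, the baseline score, the stratum label and the binary
#'   treatment indicator (0 control, 1 treatment).
#' @param k_max Maximum value of the outcome scale; follow-up scores must
#'   lie in `0..k_max`.
#' @param baseline_range Theoretical range of the baseline score; defaults
#'   to `c(0, max(baseline))`.
#' @return A data frame of class `"cohort_table"` with columns `y0`, `y3`,
#'   `stratum` (factor) and `arm` (integer), and attributes `k_max` and
#'   `baseline_range`.
#' @examples
#' d <- data.frame(y0 = c(1, 4, 2, 5), y3 = c(3, 8, 2, 9),
#'                 stratum = "all", arm = c(0, 0, 1, 1))
#' cohort_table(d, k_max = 10)
#' @export
cohort_table <- function(data, outcome = "y3", baseline = "y0",
                         stratum = "stratum", arm = "arm", k_max,
                         baseline_range = NULL) {
  stopifnot(is.data.frame(data))
  cols <- c(outcome, baseline, stratum, arm)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "))
  }
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 1L) stop("'k_max' must be a positive integer")
  out <- data.frame(
    y0 = as.numeric(data[[baseline]]),
    y3 = as.integer(round(as.numeric(data[[outcome]]))),
    stratum = factor(as.character(data[[stratum]])),
    arm = as.integer(data[[arm]])
  )
  if (anyNA(out)) stop("missing values in the four analysis columns")
  bad <- which(out$y3 < 0L | out$y3 > k_max)
  if (length(bad)) {
    stop(sprintf("follow-up scores outside 0..%d in row(s): %s", k_max,
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  if (!all(out$arm %in% c(0L, 1L))) stop("'arm' must be binary 0/1")
  if (is.null(baseline_range)) baseline_range <- c(0, max(out$y0))
  attr(out, "k_max") <- k_max
  attr(out, "baseline_range") <- as.numeric(baseline_range)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Default transformation spec for a cohort
#'
#' Builds the standard specification used throughout: `order` Bernstein
#' functions on `[0, k_max]`, one block per stratum present in the cohort
#' and the response-varying baseline regressor `(1, baseline)`.
#'
#' @param data A [cohort_table()].
#' @param order Number of Bernstein basis functions (default 7).
#' @param baseline Include the baseline regressor (default `TRUE`).
#' @return A [transformation_spec()].
#' @export
default_spec <- function(data, order = 7L, baseline = TRUE) {
  stopifnot(inherits(data, "cohort_table"))
  transformation_spec(
    k_max = attr(data, "k_max"),
    order = order,
    strata_levels = levels(data$stratum),
    baseline = baseline,
    baseline_range = attr(data, "baseline_range")
  )
}

# identifiability checks: every stratum needs enough observations and at
# least two distinct outcome values
.check_identifiability <- function(data, spec) {
  P <- spec$basis$order
  for (s in spec$strata_levels) {
    ys <- data$y3[as.character(data$stratum) == s]
    if (length(unique(ys)) < 2L) {
      stop(sprintf(
        "stratum '%s' has fewer than 2 distinct outcome values; the
transformation is unidentifiable there", s))
    }
    if (length(ys) < P) {
      warning(sprintf(
        "stratum '%s' has %d observations, fewer than the %d transformation
parameters per covariate", s, length(ys), P))
    }
  }
  invisible(TRUE)
}
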