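# Tabular input and result output.

#' Read a cohort from a delimited text file
#'
#' Reads per-subject trial records from a CSV file with a header, applies
#' the declared column mapping, drops rows with missing analysis fields
#' (reporting the count) and validates score ranges.
#'
#' @param path Path to a CSV file.
#' @param mapping Named list with entries `outcome`, `baseline`, `stratum`
#'   and `arm` giving the corresponding column names.
#' @param k_max Maximum value of the outcome scale.
#' @param baseline_range Optional theoretical baseline range.
#' @return A [cohort_table()].
#' @export
read_cohort_csv <- function(path,
                            mapping = list(outcome = "y3", baseline = "y0",
                                           stratum = "stratum", arm = "arm"),
                            k_max, baseline_range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- unlist(mapping[c("outcome", "baseline", "stratum", "arm")])
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols)) {
    stop("mapped column(s) not present in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  keep <- stats::complete.cases(raw[, cols])
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing analysis fields",
                    sum(!keep)))
    raw <- raw[keep, , drop = FALSE]
  }
  bad <- which(raw[[mapping$outcome]] < 0 | raw[[mapping$outcome]] > k_max)
  if (length(bad)) {
    stop(sprintf("outcome outside 0..%d in row(s): %s", as.integer(k_max),
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  cohort_table(raw, outcome = mapping$outcome, baseline = mapping$baseline,
               stratum = mapping$stratum, arm = mapping$arm, k_max = k_max,
               baseline_range = baseline_range)
}

# flatten the main result types to a plain list for serialization
.results_payload <- function(x) {
  if (inherits(x, "epolr_fit")) {
    w <- if (x$include_treatment && is.finite(x$se_beta)) {
      wald_inference(x)
    }
    list(
      type = "epolr_fit",
      beta = x$beta_hat,
      or_leq_score = round(exp(x$beta_hat), 4),
      or_benefit = round(exp(-x$beta_hat), 4),
      ci_low = if (!is.null(w)) round(w$ci_low, 4),
      ci_high = if (!is.null(w)) round(w$ci_high, 4),
      p_two_sided = if (!is.null(w)) round(w$p_two_sided, 4),
      loglik = x$loglik,
      converged = x$converged,
      n_obs = x$n_obs,
      spec = list(order = x$spec$basis$order,
                  strata = x$spec$strata_levels,
                  baseline = x$spec$baseline,
                  interval = x$spec$basis$interval)
    )
  } else if (inherits(x, "epolr_perm")) {
    list(type = "permutation_test", T = x$observed_T, z = x$z,
         p = x$p_value, n_perm = x$n_perm, seed = x$seed)
  } else if (is.data.frame(x)) {
    x
  } else {
    stop("unsupported results object of class ",
         paste(class(x), collapse = "/"))
  }
}

#' Write results to CSV or JSON
#'
#' Serializes fit summaries, permutation results or power tables with a
#' deterministic layout: power proportions are written to 3 decimals and
#' odds ratios / p-values to 4, and a metadata block (package version,
#' seed) is included in JSON output.  Identical inputs produce
#' byte-identical files.
#'
#' @param x An [epolr_fit()], an `"epolr_perm"` result or a power /
#'   scenario data frame.
#' @param path Output file path.
#' @param format `"csv"` (data frames only) or `"json"`.
#' @param seed Optional seed to record in the metadata block.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json"), seed = NULL) {
  format <- match.arg(format)
  payload <- .results_payload(x)
  if (format == "csv") {
    if (!is.data.frame(payload)) {
      stop("CSV output is only supported for tabular results")
    }
    tab <- payload
    if (inherits(x, "power_estimate")) {
      tab <- tab[, c("n_total", "or_benefit", "test", "power", "wilson_lo",
                     "wilson_hi", "n_reps")]
      for (cl in c("power", "wilson_lo", "wilson_hi")) {
        tab[[cl]] <- round(tab[[cl]], 3)
      }
    }
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    out <- list(
      metadata = list(package = "epolr",
                      version = as.character(utils::packageVersion("epolr")),
                      seed = seed),
      results = payload
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}
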