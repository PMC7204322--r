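#' Stratified transformation function specification
#'
#' Describes the parameterization of the monotone transformation function
#' `h(y | baseline, stratum)`: a Bernstein basis in the (floored) outcome,
#' tensored with a dummy coding of the strata and, optionally, with a
#' response-varying baseline regressor `(1, baseline)`.  With `order` basis
#' functions, `S` strata and the baseline regressor switched on, the
#' transformation carries `order * S * 2` parameters (e.g. 7 x 3 x 2 = 42).
#'
#' The baseline score is internally rescaled to `[0, 1]` by its theoretical
#' range (`baseline_range`) so that the two per-stratum coefficient
#' sequences correspond to the transformation at the two extremes of the
#' baseline scale; reported parameters stay on this internal scale.
#'
#' @param k_max Maximum value of the outcome scale; the support is
#'   `0..k_max` with the conventions `h(-1) = -Inf`, `h(k_max) = +Inf`.
#' @param order Number of Bernstein basis functions (default 7).
#' @param strata_levels Character vector of stratum labels (default a single
#'   stratum `"all"`).
#' @param baseline Logical; include the response-varying baseline regressor
#'   `(1, baseline)` (default `TRUE`).
#' @param baseline_range Theoretical range `c(lo, hi)` of the baseline
#'   score, used for internal rescaling; defaults to `c(0, k_max)`.
#' @param interval Interval of the Bernstein basis; defaults to
#'   `c(0, k_max)`.
#' @return An object of class `"transformation_spec"`.
#' @examples
#' sp <- transformation_spec(50, order = 7,
#'                           strata_levels = c("seg4-6", "seg7-8", "seg9-10"),
#'                           baseline_range = c(0, 28))
#' sp$npar  # 42
#' @export
transformation_spec <- function(k_max, order = 7L, strata_levels = "all",
                                baseline = TRUE,
                                baseline_range = c(0, k_max),
                                interval = c(0, k_max)) {
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 1L) stop("'k_max' must be a positive integer")
  strata_levels <- as.character(strata_levels)
  if (anyDuplicated(strata_levels)) stop("duplicated stratum labels")
  baseline <- isTRUE(baseline)
  baseline_range <- as.numeric(baseline_range)
  if (baseline && (length(baseline_range) != 2L ||
                   baseline_range[1L] >= baseline_range[2L])) {
    stop("'baseline_range' must be c(lo, hi) with lo < hi")
  }
  basis <- bernstein_basis(order, interval)
  n_cov <- 1L + baseline
  structure(list(
    k_max = k_max,
    basis = basis,
    strata_levels = strata_levels,
    baseline = baseline,
    baseline_range = baseline_range,
    n_strata = length(strata_levels),
    n_cov = n_cov,
    npar = basis$order * length(strata_levels) * n_cov
  ), class = "transformation_spec")
}

#' @export
print.transformation_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "Transformation spec: %d Bernstein functions on [%g, %g]\n",
    "  strata (%d): %s\n  covariates: %s\n  parameters: %d\n"),
    x$basis$order, x$basis$interval[1L], x$basis$interval[2L],
    x$n_strata, paste(x$strata_levels, collapse = ", "),
    if (x$baseline) "(1, baseline)" else "(1)", x$npar))
  invisible(x)
}

#' Build a transformation spec from a plain configuration
#'
#' Accepts a named list or a path to a YAML/JSON file with fields
#' `k_max` (or `interval`), `order`, `strata`, `baseline` (logical) and
#' `baseline_range`.
#'
#' @param config Named list or path to a `.yaml`/`.yml`/`.json` file.
#' @return A [transformation_spec()].
#' @export
spec_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = ,
      yml = {
        if (!requireNamespace("yaml", quietly = TRUE)) {
          stop("the 'yaml' package is required to read YAML configs")
        }
        yaml::read_yaml(config)
      },
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      stop("unsupported config format: ", ext)
    )
  }
  if (!is.list(config)) stop("'config' must be a list or a file path")
  k_max <- if (!is.null(config$k_max)) config$k_max else config$interval[2L]
  if (is.null(k_max)) stop("config must provide 'k_max' or 'interval'")
  transformation_spec(
    k_max = k_max,
    order = if (is.null(config$order)) 7L else config$order,
    strata_levels = if (is.null(config$strata)) "all" else config$strata,
    baseline = if (is.null(config$baseline)) TRUE else isTRUE(config$baseline),
    baseline_range = if (is.null(config$baseline_range)) c(0, k_max)
                     else config$baseline_range,
    interval = if (is.null(config$interval)) c(0, k_max) else config$interval
  )
}

# rescale baseline scores to [0, 1] by the theoretical range
.scale_baseline <- function(b, spec) {
  if (!spec$baseline) return(rep(0, length(b)))
  r <- spec$baseline_range
  m <- (as.numeric(b) - r[1L]) / (r[2L] - r[1L])
  if (any(m < -1e-9 | m > 1 + 1e-9)) {
    warning("baseline scores outside the declared range were clamped")
  }
  pmin(pmax(m, 0), 1)
}

#' Design row(s) of the transformation function
#'
#' Returns the Kronecker product `bernstein_row(floor(y)) (x) stratum-dummy
#' (x) (1, baseline)` used to evaluate `h`.  Entries outside the active
#' stratum block are zero.
#'
#' @param y Outcome values inside the basis interval (floored internally).
#' @param stratum Stratum labels, recycled against `y`.
#' @param baseline Baseline scores (ignored when the spec has no baseline
#'   regressor), recycled against `y`.
#' @param spec A [transformation_spec()].
#' @return A vector of length `spec$npar` for a single observation,
#'   otherwise a matrix with one row per observation.
#' @export
design_row <- function(y, stratum, baseline = NULL, spec) {
  stopifnot(inherits(spec, "transformation_spec"))
  A <- bernstein_row(floor_discretize(y), spec$basis)
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  n <- nrow(A)
  P <- spec$basis$order
  S <- spec$n_strata
  C <- spec$n_cov
  si <- match(as.character(stratum), spec$strata_levels)
  if (anyNA(si)) {
    stop("unknown stratum label: ",
         paste(unique(stratum[is.na(si)]), collapse = ", "))
  }
  si <- rep_len(si, n)
  if (C == 2L) {
    if (is.null(baseline)) stop("spec expects a baseline score")
    cv <- cbind(1, rep_len(.scale_baseline(baseline, spec), n))
  } else {
    cv <- matrix(1, n, 1L)
  }
  out <- matrix(0, n, spec$npar)
  for (p in seq_len(P)) {
    for (cc in seq_len(C)) {
      cols <- ((p - 1L) * S + si - 1L) * C + cc
      out[cbind(seq_len(n), cols)] <- A[, p] * cv[, cc]
    }
  }
  if (n == 1L) drop(out) else out
}

#' Evaluate the transformation function
#'
#' Evaluates `h(y | baseline, stratum)` for integer `y` in
#' `{-1, 0, ..., k_max}` under the boundary conventions `h(-1) = -Inf` and
#' `h(k_max) = +Inf`.
#'
#' @inheritParams design_row
#' @param theta Coefficient vector of length `spec$npar`.
#' @return Numeric vector of (extended-real) transformation values.
#' @export
eval_h <- function(y, stratum, baseline = NULL, theta, spec) {
  stopifnot(inherits(spec, "transformation_spec"))
  if (length(theta) != spec$npar) {
    stop(sprintf("'theta' must have length %d", spec$npar))
  }
  y <- as.numeric(y)
  n <- max(length(y), length(stratum),
           if (is.null(baseline)) 0L else length(baseline))
  y <- rep_len(y, n)
  stratum <- rep_len(stratum, n)
  if (!is.null(baseline)) baseline <- rep_len(baseline, n)
  out <- numeric(n)
  lo_b <- y <= -1
  hi_b <- y >= spec$k_max
  out[lo_b] <- -Inf
  out[hi_b] <- Inf
  fin <- !(lo_b | hi_b)
  if (any(fin)) {
    X <- design_row(y[fin], stratum[fin],
                    if (is.null(baseline)) NULL else baseline[fin], spec)
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    out[fin] <- drop(X %*% theta)
  }
  out
}

#' Monotonicity constraints of the transformation parameters
#'
#' The transformation must be non-decreasing in the outcome.  A Bernstein
#' polynomial is monotone whenever its coefficient sequence is increasing,
#' so the constraint set consists of the `order - 1` coefficient orderings
#' per stratum; with a response-varying baseline effect the orderings are
#' imposed at both extremes of the (rescaled) baseline range, which is
#' sufficient because `h` is affine in the baseline score.
#'
#' @param spec A [transformation_spec()].
#' @return An object of class `"monotonicity_constraints"` containing the
#'   constraint matrix `ui` such that a coefficient vector `theta` is
#'   admissible when all entries of `ui %*% theta` are positive.
#' @export
monotonicity_constraints <- function(spec) {
  stopifnot(inherits(spec, "transformation_spec"))
  P <- spec$basis$order
  S <- spec$n_strata
  C <- spec$n_cov
  extremes <- if (C == 2L) c(0, 1) else 0
  rows <- list()
  labs <- character(0)
  for (s in seq_len(S)) {
    for (e in extremes) {
      for (p in seq_len(P - 1L)) {
        r <- numeric(spec$npar)
        i_lo <- ((p - 1L) * S + s - 1L) * C
        i_hi <- (p * S + s - 1L) * C
        r[i_lo + 1L] <- -1
        r[i_hi + 1L] <- 1
        if (C == 2L) {
          r[i_lo + 2L] <- -e
          r[i_hi + 2L] <- e
        }
        rows[[length(rows) + 1L]] <- r
        labs <- c(labs, sprintf("%s:m%g:%d<%d", spec$strata_levels[s], e,
                                p, p + 1L))
      }
    }
  }
  ui <- do.call(rbind, rows)
  rownames(ui) <- labs
  structure(list(ui = ui, n_constraints = nrow(ui), spec = spec),
            class = "monotonicity_constraints")
}

#' @export
print.monotonicity_constraints <- function(x, ...) {
  cat(sprintf("%d linear monotonicity constraints (ui %%*%% theta > 0)\n",
              x$n_constraints))
  invisible(x)
}

#' Check a coefficient vector against the monotonicity constraints
#'
#' @param theta Coefficient vector of length `spec$npar`.
#' @param spec A [transformation_spec()].
#' @param tol Strictness tolerance; orderings must exceed `tol`.
#' @return `TRUE` if all constraints hold.
#' @export
check_monotonicity <- function(theta, spec, tol = 0) {
  con <- monotonicity_constraints(spec)
  all(con$ui %*% theta > tol)
}
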