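# Constrained maximum likelihood for the baseline-adjusted proportional
# odds model  P(Y <= y | y0, stratum, x) = expit(h(y | y0, stratum) + beta x).
#
# Internally each stratum carries two increasing Bernstein coefficient
# sequences: u (transformation at the lower extreme of the rescaled
# baseline) and v (at the upper extreme); the per-subject coefficient
# vector is the affine blend c_i = (1 - m) u + m v with m in [0, 1], so
# monotonicity at both extremes implies monotonicity for every baseline
# value.  Each sequence is reparameterized as (first value, log-increments)
# and the resulting unconstrained problem is solved by quasi-Newton
# optimization with an analytic gradient.

.EPS_INC <- 1e-8  # strictness floor of the coefficient increments

# -- reparameterization ------------------------------------------------------

.block_to_seq <- function(b) {
  b[1L] + c(0, cumsum(.EPS_INC + exp(b[-1L])))
}

# gradient wrt the block (first, log-increments) given the gradient wrt the
# increasing sequence
.seq_grad_to_block <- function(gs, b) {
  tails <- rev(cumsum(rev(gs)))
  c(tails[1L], exp(b[-1L]) * tails[-1L])
}

# inverse map: strictly increasing sequence -> block
.seq_to_block <- function(u) {
  d <- pmax(diff(u), .EPS_INC + 1e-12)
  c(u[1L], log(d - .EPS_INC + 1e-12))
}

.n_xi <- function(spec, include_treatment) {
  spec$basis$order * spec$n_strata * spec$n_cov + as.integer(include_treatment)
}

# unpack xi into U (S x P), V (S x P or NULL) and beta
.unpack_xi <- function(xi, spec, include_treatment) {
  P <- spec$basis$order
  S <- spec$n_strata
  U <- matrix(0, S, P)
  for (s in seq_len(S)) {
    U[s, ] <- .block_to_seq(xi[((s - 1L) * P + 1L):(s * P)])
  }
  V <- NULL
  if (spec$n_cov == 2L) {
    V <- matrix(0, S, P)
    off <- S * P
    for (s in seq_len(S)) {
      V[s, ] <- .block_to_seq(xi[off + ((s - 1L) * P + 1L):(s * P)])
    }
  }
  beta <- if (include_treatment) xi[length(xi)] else 0
  list(U = U, V = V, beta = beta)
}

# natural-scale theta (layout ((p-1)*S + s-1)*C + c) from U, V
.uv_to_theta <- function(U, V, spec) {
  P <- spec$basis$order
  S <- spec$n_strata
  C <- spec$n_cov
  theta <- numeric(spec$npar)
  nm <- character(spec$npar)
  for (p in seq_len(P)) {
    for (s in seq_len(S)) {
      i <- ((p - 1L) * S + s - 1L) * C
      theta[i + 1L] <- U[s, p]
      nm[i + 1L] <- sprintf("h:%s:icpt:%d", spec$strata_levels[s], p)
      if (C == 2L) {
        theta[i + 2L] <- V[s, p] - U[s, p]
        nm[i + 2L] <- sprintf("h:%s:bl:%d", spec$strata_levels[s], p)
      }
    }
  }
  names(theta) <- nm
  theta
}

# -- data preparation --------------------------------------------------------

.fit_prep <- function(data, spec) {
  k_max <- spec$k_max
  P <- spec$basis$order
  n <- nrow(data)
  if (n == 0L) stop("empty cohort")
  y <- as.integer(data$y3)
  si <- match(as.character(data$stratum), spec$strata_levels)
  if (anyNA(si)) {
    stop("cohort contains strata not declared in the transformation spec")
  }
  mb <- if (spec$n_cov == 2L) .scale_baseline(data$y0, spec) else rep(0, n)
  Bgrid <- bernstein_row(0:(k_max - 1L), spec$basis)
  if (is.null(dim(Bgrid))) Bgrid <- matrix(Bgrid, ncol = P)
  up_inf <- y == k_max
  lo_inf <- y == 0L
  Bu <- matrix(0, n, P)
  Bu[!up_inf, ] <- Bgrid[y[!up_inf] + 1L, , drop = FALSE]
  Bl <- matrix(0, n, P)
  Bl[!lo_inf, ] <- Bgrid[y[!lo_inf], , drop = FALSE]
  list(n = n, P = P, S = spec$n_strata, y = y, si = si, mb = mb,
       wu = 1 - mb, x = as.numeric(data$arm), Bu = Bu, Bl = Bl,
       up_inf = up_inf, lo_inf = lo_inf, fin = !(up_inf | lo_inf),
       Bgrid = Bgrid)
}

# per-subject linear predictors and log-likelihood contributions
.ll_core <- function(U, V, beta, pr) {
  Ci <- U[pr$si, , drop = FALSE]
  if (!is.null(V)) {
    Ci <- Ci * pr$wu + V[pr$si, , drop = FALSE] * pr$mb
  }
  eta_u <- rowSums(pr$Bu * Ci) + beta * pr$x
  eta_l <- rowSums(pr$Bl * Ci) + beta * pr$x
  ll <- numeric(pr$n)
  ll[pr$fin] <- .logdiffexpit(eta_l[pr$fin], eta_u[pr$fin])
  ll[pr$lo_inf] <- -.log1pexp(-eta_u[pr$lo_inf])
  ll[pr$up_inf] <- -.log1pexp(eta_l[pr$up_inf])
  list(ll = ll, eta_u = eta_u, eta_l = eta_l)
}

# derivatives of the log-likelihood contributions wrt the two linear
# predictors; boundary sides contribute zero
.ll_eta_grad <- function(cr, pr) {
  g_u <- numeric(pr$n)
  g_l <- numeric(pr$n)
  fin <- pr$fin
  g_u[fin] <- exp(.logdexpit(cr$eta_u[fin]) - cr$ll[fin])
  g_l[fin] <- -exp(.logdexpit(cr$eta_l[fin]) - cr$ll[fin])
  g_u[pr$lo_inf] <- stats::plogis(-cr$eta_u[pr$lo_inf])
  g_l[pr$up_inf] <- -stats::plogis(cr$eta_l[pr$up_inf])
  list(g_u = g_u, g_l = g_l)
}

# objective closures for the unconstrained problem
.make_objective <- function(pr, spec, include_treatment) {
  P <- pr$P
  S <- pr$S
  has_v <- spec$n_cov == 2L
  fn <- function(xi) {
    uv <- .unpack_xi(xi, spec, include_treatment)
    if (any(!is.finite(uv$U)) || (has_v && any(!is.finite(uv$V))) ||
        !is.finite(uv$beta)) {
      return(1e10)
    }
    val <- -sum(.ll_core(uv$U, uv$V, uv$beta, pr)$ll)
    if (!is.finite(val)) val <- 1e10
    val
  }
  gr <- function(xi) {
    uv <- .unpack_xi(xi, spec, include_treatment)
    if (any(!is.finite(uv$U)) || (has_v && any(!is.finite(uv$V))) ||
        !is.finite(uv$beta)) {
      return(numeric(length(xi)))
    }
    cr <- .ll_core(uv$U, uv$V, uv$beta, pr)
    sc <- .ll_eta_grad(cr, pr)
    Gc <- pr$Bu * sc$g_u + pr$Bl * sc$g_l
    out <- numeric(length(xi))
    gU <- rowsum(Gc * pr$wu, pr$si, reorder = TRUE)
    for (s in seq_len(S)) {
      idx <- ((s - 1L) * P + 1L):(s * P)
      out[idx] <- .seq_grad_to_block(gU[s, ], xi[idx])
    }
    if (has_v) {
      off <- S * P
      gV <- rowsum(Gc * pr$mb, pr$si, reorder = TRUE)
      for (s in seq_len(S)) {
        idx <- ((s - 1L) * P + 1L):(s * P)
        out[off + idx] <- .seq_grad_to_block(gV[s, ], xi[off + idx])
      }
    }
    if (include_treatment) {
      out[length(xi)] <- sum(pr$x * (sc$g_u + sc$g_l))
    }
    -out
  }
  list(fn = fn, gr = gr)
}

# initialize the transformation near the per-stratum empirical marginal
# logit-CDF evaluated on the Bernstein node grid; zero baseline slope
.init_xi <- function(pr, spec, include_treatment) {
  P <- pr$P
  lo <- spec$basis$interval[1L]
  hi <- spec$basis$interval[2L]
  nodes <- floor(seq(lo, hi, length.out = P))
  blocks <- lapply(seq_len(pr$S), function(s) {
    ys <- pr$y[pr$si == s]
    ns <- length(ys)
    Fh <- (vapply(nodes, function(t) sum(ys <= t), 0) + 0.5) / (ns + 1)
    Fh <- pmin(pmax(Fh, 0.02), 0.98)
    g <- stats::qlogis(Fh)
    d <- pmax(diff(g), 0.05)
    c(g[1L], log(d))
  })
  xi_u <- unlist(blocks)
  c(xi_u, if (spec$n_cov == 2L) xi_u, if (include_treatment) 0)
}

# Jacobian d(beta, theta)/d(xi) for the delta-method covariance
.xi_jacobian <- function(xi, spec, include_treatment) {
  P <- spec$basis$order
  S <- spec$n_strata
  C <- spec$n_cov
  nxi <- length(xi)
  nnat <- as.integer(include_treatment) + spec$npar
  J <- matrix(0, nnat, nxi)
  row0 <- as.integer(include_treatment)
  if (include_treatment) J[1L, nxi] <- 1
  block_L <- function(b) {
    L <- matrix(0, P, P)
    L[, 1L] <- 1
    for (j in 2L:P) L[j:P, j] <- exp(b[j])
    L
  }
  for (s in seq_len(S)) {
    idx <- ((s - 1L) * P + 1L):(s * P)
    Lu <- block_L(xi[idx])
    rows1 <- row0 + ((seq_len(P) - 1L) * S + s - 1L) * C + 1L
    J[rows1, idx] <- Lu
    if (C == 2L) {
      off <- S * P
      Lv <- block_L(xi[off + idx])
      rows2 <- rows1 + 1L
      J[rows2, idx] <- -Lu
      J[rows2, off + idx] <- Lv
    }
  }
  J
}

# -- exported likelihood utilities ------------------------------------------

#' Likelihood contribution of a single observation
#'
#' `expit(h(y) + beta x) - expit(h(y - 1) + beta x)` with the boundary
#' conventions `h(-1) = -Inf` and `h(k_max) = +Inf`.
#'
#' @param y Outcome value(s) in `0..k_max`.
#' @param baseline,stratum Covariates of the observation(s).
#' @param x Treatment indicator(s), 0 or 1.
#' @param theta Transformation coefficients (length `spec$npar`).
#' @param beta Treatment log-odds-ratio (scalar).
#' @param spec A [transformation_spec()].
#' @return Probabilities in `(0, 1]`.
#' @export
likelihood_contribution <- function(y, baseline = NULL, stratum, x, theta,
                                    beta, spec) {
  if (any(!is.finite(theta)) || !is.finite(beta)) {
    stop("non-finite 'theta' or 'beta'")
  }
  y <- as.integer(y)
  if (any(y < 0L | y > spec$k_max)) stop("'y' outside 0..k_max")
  hu <- eval_h(y, stratum, baseline, theta, spec) + beta * x
  hl <- eval_h(y - 1L, stratum, baseline, theta, spec) + beta * x
  stats::plogis(hu) - stats::plogis(hl)
}

#' Log-likelihood of a cohort
#'
#' Sum of the log likelihood contributions over all subjects, computed with
#' a numerically stable log-difference-of-expits formulation.  A
#' non-positive probability difference (non-monotone `theta`) yields a
#' large negative sentinel rather than `NaN`.
#'
#' @param data A [cohort_table()].
#' @param theta Transformation coefficients (length `spec$npar`).
#' @param beta Treatment log-odds-ratio.
#' @param spec A [transformation_spec()].
#' @return The log-likelihood (a finite scalar, at most 0).
#' @export
epolr_loglik <- function(data, theta, beta, spec) {
  stopifnot(inherits(data, "cohort_table"))
  if (nrow(data) == 0L) stop("empty cohort")
  hu <- eval_h(data$y3, data$stratum, data$y0, theta, spec) +
    beta * data$arm
  hl <- eval_h(data$y3 - 1L, data$stratum, data$y0, theta, spec) +
    beta * data$arm
  ll <- numeric(nrow(data))
  fin <- is.finite(hu) & is.finite(hl)
  bad <- fin & (hu <= hl)
  ok <- fin & !bad
  ll[ok] <- .logdiffexpit(hl[ok], hu[ok])
  ll[!is.finite(hl) & is.finite(hu)] <-
    -.log1pexp(-hu[!is.finite(hl) & is.finite(hu)])
  ll[!is.finite(hu) & is.finite(hl)] <-
    -.log1pexp(hl[!is.finite(hu) & is.finite(hl)])
  ll[bad] <- -1e10
  sum(ll)
}

# -- model fitting -----------------------------------------------------------

#' Fit the baseline-adjusted proportional odds model
#'
#' Maximizes the cohort log-likelihood over the transformation coefficients
#' (subject to monotonicity) and, optionally, the treatment log-odds-ratio
#' `beta`.  With `include_treatment = FALSE` the intercept-only model is
#' fitted (`beta` fixed at 0); this is the null model used by the
#' permutation score test and by the parametric bootstrap simulator.
#'
#' The reported `beta` follows the distribution-function convention:
#' `exp(beta)` is the odds of `Y <= y` for treated versus control, so
#' negative `beta` (benefit odds ratio `exp(-beta) > 1`) means
#' stochastically larger outcomes under treatment.
#'
#' @param data A [cohort_table()].
#' @param spec A [transformation_spec()]; defaults to [default_spec()] of
#'   the cohort.
#' @param include_treatment Estimate the treatment effect (default `TRUE`).
#' @param hessian Compute the observed-information covariance (default: only
#'   when the treatment effect is estimated).
#' @param control Optional list overriding the `optim` control parameters
#'   (`maxit = 500`, `reltol = 1e-10`).
#' @return An object of class `"epolr_fit"` with elements `beta_hat`,
#'   `theta_hat`, `vcov` (over `(beta, theta)`, delta-method back-transform
#'   of the inverse observed information), `se_beta`, `loglik`, `converged`,
#'   `spec`, `n_obs` and the fitted per-stratum coefficient matrices.
#' @examples
#' cfg <- cohort_config("scim_selfcare", n_subjects = 150, seed = 1)
#' coh <- generate_cohort(cfg)$cohort
#' fit <- epolr_fit(coh, default_spec(coh, order = 4))
#' wald_inference(fit)
#' @export
epolr_fit <- function(data, spec = NULL, include_treatment = TRUE,
                      hessian = include_treatment, control = list()) {
  stopifnot(inherits(data, "cohort_table"))
  if (is.null(spec)) spec <- default_spec(data)
  present <- spec$strata_levels %in% unique(as.character(data$stratum))
  if (!all(present)) {
    warning("dropping spec strata absent from the data: ",
            paste(spec$strata_levels[!present], collapse = ", "))
    spec <- transformation_spec(
      k_max = spec$k_max, order = spec$basis$order,
      strata_levels = spec$strata_levels[present],
      baseline = spec$baseline, baseline_range = spec$baseline_range,
      interval = spec$basis$interval)
  }
  .check_identifiability(data, spec)
  pr <- .fit_prep(data, spec)
  obj <- .make_objective(pr, spec, include_treatment)
  xi0 <- .init_xi(pr, spec, include_treatment)
  ctrl <- utils::modifyList(list(maxit = 1000L, reltol = 1e-10), control)
  opt <- stats::optim(xi0, obj$fn, obj$gr, method = "BFGS", control = ctrl)
  xi <- opt$par
  value <- opt$value
  converged <- opt$convergence == 0L
  vcov_nat <- NULL
  se_beta <- NA_real_
  if (hessian) {
    inv_hess <- function(xi_at) {
      H <- stats::optimHess(xi_at, obj$fn, obj$gr)
      H <- (H + t(H)) / 2
      tryCatch(solve(H), error = function(e) MASS::ginv(H))
    }
    Vxi <- inv_hess(xi)
    # Damped Newton polish: sharpen the optimum beyond the line-search
    # stopping rule of BFGS (the binary-logistic equivalence relies on
    # this); backtracking guards against near-flat directions
    moved <- 0
    for (it in 1:8) {
      g <- obj$gr(xi)
      if (max(abs(g)) < 1e-8) break
      step <- drop(Vxi %*% g)
      if (!all(is.finite(step))) break
      accepted <- FALSE
      for (damp in 0:6) {
        cand <- xi - step / 2^damp
        cval <- obj$fn(cand)
        if (is.finite(cval) && cval < value) {
          moved <- moved + sqrt(sum((step / 2^damp)^2))
          xi <- cand
          value <- cval
          accepted <- TRUE
          break
        }
      }
      if (!accepted) break
    }
    if (moved > 1e-6) Vxi <- inv_hess(xi)
    J <- .xi_jacobian(xi, spec, include_treatment)
    vcov_nat <- J %*% Vxi %*% t(J)
    vcov_nat <- (vcov_nat + t(vcov_nat)) / 2
    nm <- c(if (include_treatment) "beta",
            names(.uv_to_theta(matrix(0, spec$n_strata, spec$basis$order),
                               if (spec$n_cov == 2L)
                                 matrix(0, spec$n_strata, spec$basis$order)
                               else NULL, spec)))
    dimnames(vcov_nat) <- list(nm, nm)
    if (include_treatment) se_beta <- sqrt(max(Vxi[length(xi), length(xi)], 0))
  }
  if (!converged) {
    warning("optimizer did not converge; inspect 'converged' and 'counts'")
  }
  uv <- .unpack_xi(xi, spec, include_treatment)
  theta <- .uv_to_theta(uv$U, uv$V, spec)
  structure(list(
    beta_hat = uv$beta,
    theta_hat = theta,
    U = uv$U,
    V = uv$V,
    vcov = vcov_nat,
    se_beta = se_beta,
    loglik = -value,
    converged = converged,
    counts = opt$counts,
    include_treatment = include_treatment,
    spec = spec,
    n_obs = pr$n,
    data = data,
    xi = xi,
    call = match.call()
  ), class = "epolr_fit")
}

# per-subject Bernstein coefficient matrix implied by a fit for arbitrary
# covariates
.fit_coef_rows <- function(fit, stratum, baseline) {
  si <- match(as.character(stratum), fit$spec$strata_levels)
  if (anyNA(si)) stop("stratum not seen at fit time: ",
                      paste(unique(stratum[is.na(si)]), collapse = ", "))
  Ci <- fit$U[si, , drop = FALSE]
  if (!is.null(fit$V)) {
    m <- .scale_baseline(baseline, fit$spec)
    Ci <- Ci * (1 - m) + fit$V[si, , drop = FALSE] * m
  }
  Ci
}

#' Predicted conditional outcome distribution
#'
#' Probability mass function of the follow-up score over `0..k_max` for one
#' covariate combination, implied by a fitted model; the corresponding CDF
#' is `expit(h(y) + beta x)`.
#'
#' @param fit An [epolr_fit()] object.
#' @param baseline Baseline score.
#' @param stratum Stratum label (must have been present at fit time).
#' @param x Treatment indicator, 0 or 1.
#' @return Numeric vector of `k_max + 1` probabilities summing to 1.
#' @export
predict_distribution <- function(fit, baseline = NULL, stratum, x = 0) {
  stopifnot(inherits(fit, "epolr_fit"))
  Ci <- .fit_coef_rows(fit, stratum[1L], baseline[1L])
  h <- drop(.fit_prep_grid(fit$spec) %*% t(Ci))
  cdf <- stats::plogis(h + fit$beta_hat * x)
  pmf <- diff(c(0, cdf, 1))
  names(pmf) <- 0:fit$spec$k_max
  pmf
}

.fit_prep_grid <- function(spec) {
  B <- bernstein_row(0:(spec$k_max - 1L), spec$basis)
  if (is.null(dim(B))) B <- matrix(B, ncol = spec$basis$order)
  B
}

#' Wald inference for the treatment odds ratio
#'
#' Asymptotic-normal inference for the treatment effect of a fitted model.
#' Both directions of the odds ratio are reported: `or_hat = exp(beta)` is
#' the odds of a lower-or-equal score (treated : control), and
#' `or_benefit = exp(-beta)` is the conventional benefit odds ratio (> 1
#' means stochastically larger outcomes under treatment).
#'
#' @param fit An [epolr_fit()] with an estimated treatment effect and
#'   covariance.
#' @param level Confidence level (default 0.95).
#' @return An object of class `"epolr_wald"`: a list with `or_hat`,
#'   `ci_low`, `ci_high`, `z`, `p_two_sided`, the benefit-direction fields
#'   `or_benefit`, `ci_benefit_low`, `ci_benefit_high`, and `direction`
#'   labels.
#' @export
wald_inference <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "epolr_fit"))
  if (!fit$include_treatment) {
    stop("fit has no treatment effect (include_treatment = FALSE)")
  }
  if (!is.finite(fit$se_beta)) stop("fit carries no covariance; refit with hessian = TRUE")
  if (fit$se_beta <= 0) stop("non-positive variance estimate for beta")
  z_q <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$beta_hat
  se <- fit$se_beta
  z <- b / se
  structure(list(
    or_hat = exp(b),
    ci_low = exp(b - z_q * se),
    ci_high = exp(b + z_q * se),
    z = z,
    p_two_sided = 2 * stats::pnorm(-abs(z)),
    or_benefit = exp(-b),
    ci_benefit_low = exp(-b - z_q * se),
    ci_benefit_high = exp(-b + z_q * se),
    beta_hat = b,
    se_beta = se,
    level = level,
    direction = c(
      or_hat = "odds of lower-or-equal score, treated:control",
      or_benefit = "benefit odds ratio (treated outcomes stochastically larger when > 1)")
  ), class = "epolr_wald")
}

#' @export
print.epolr_wald <- function(x, ...) {
  cat(sprintf(
    paste0("Asymptotic (Wald) inference for the treatment effect\n",
           "  OR (odds of <= score, treated:control): %.4f  [%.4f, %.4f]\n",
           "  benefit OR exp(-beta):                  %.4f  [%.4f, %.4f]\n",
           "  z = %.3f, two-sided p = %.4g (level %.2f)\n"),
    x$or_hat, x$ci_low, x$ci_high,
    x$or_benefit, x$ci_benefit_low, x$ci_benefit_high,
    x$z, x$p_two_sided, x$level))
  invisible(x)
}

#' @export
print.epolr_fit <- function(x, ...) {
  cat("Baseline-adjusted proportional odds model\n")
  cat(sprintf("  n = %d, strata: %s\n", x$n_obs,
              paste(x$spec$strata_levels, collapse = ", ")))
  cat(sprintf("  transformation: %d parameters (%d Bernstein functions)\n",
              x$spec$npar, x$spec$basis$order))
  if (x$include_treatment) {
    cat(sprintf("  beta (log-OR of <= score, trt:ctrl) = %.4f", x$beta_hat))
    if (is.finite(x$se_beta)) cat(sprintf(" (se %.4f)", x$se_beta))
    cat(sprintf("; benefit OR = %.4f\n", exp(-x$beta_hat)))
  } else {
    cat("  intercept-only model (beta fixed at 0)\n")
  }
  cat(sprintf("  log-likelihood: %.4f%s\n", x$loglik,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
coef.epolr_fit <- function(object, ...) {
  c(if (object$include_treatment) c(beta = object$beta_hat),
    object$theta_hat)
}

#' @export
logLik.epolr_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$xi),
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.epolr_fit <- function(object, ...) {
  object$vcov
}
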