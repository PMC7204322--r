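test_that("binary-outcome fits reproduce logistic regression", {
  set.seed(3)
  n <- 60
  x <- rep(0:1, each = n / 2)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
  d <- cohort_table(data.frame(y0 = 0, y3 = y, stratum = "all", arm = x),
                    k_max = 1, baseline_range = c(0, 1))
  sp <- transformation_spec(1, order = 2, strata_levels = "all",
                            baseline = FALSE)
  f <- epolr_fit(d, sp)
  gl <- glm(I(y == 0) ~ x, family = binomial)
  expect_equal(f$beta_hat, unname(coef(gl)[2]), tolerance = 1e-6)
  expect_equal(f$se_beta, summary(gl)$coefficients[2, 2], tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(gl)), tolerance = 1e-8)
})

test_that("intercept-only fits pin beta at zero and are nested", {
  coh <- make_small_cohort(n = 120, k_max = 10, seed = 10,
                           beta_benefit = log(2))
  sp <- default_spec(coh, order = 5)
  f0 <- epolr_fit(coh, sp, include_treatment = FALSE, hessian = FALSE)
  f1 <- epolr_fit(coh, sp, hessian = FALSE)
  expect_identical(f0$beta_hat, 0)
  expect_false(f0$include_treatment)
  expect_lte(f0$loglik, f1$loglik + 1e-8)
})

test_that("fitted transformations satisfy the monotonicity constraints", {
  g <- generate_cohort(cohort_config("uems", n_subjects = 150, seed = 12))
  f <- epolr_fit(g$cohort, hessian = FALSE)
  expect_true(check_monotonicity(f$theta_hat, f$spec, tol = -1e-10))
  for (s in f$spec$strata_levels) {
    for (b in c(0, 14, 28)) {
      h <- eval_h(0:49, s, b, f$theta_hat, f$spec)
      expect_true(all(diff(h) >= -1e-10))
    }
  }
})

test_that("predicted distributions are proper and proportional-odds ordered", {
  coh <- make_small_cohort(n = 150, k_max = 20, seed = 13,
                           beta_benefit = log(2))
  f <- epolr_fit(coh)
  set.seed(14)
  for (i in 1:20) {
    b <- sample(0:20, 1)
    p0 <- predict_distribution(f, b, "all", x = 0)
    p1 <- predict_distribution(f, b, "all", x = 1)
    expect_equal(sum(p0), 1, tolerance = 1e-10)
    expect_equal(sum(p1), 1, tolerance = 1e-10)
    expect_true(all(p0 >= 0))
    d_cdf <- cumsum(p1)[-21] - cumsum(p0)[-21]
    # one arm's CDF dominates uniformly (sign set by the sign of beta)
    expect_true(all(d_cdf >= -1e-12) || all(d_cdf <= 1e-12))
    # and the log-odds gap equals beta at every cut-point
    lo <- qlogis(pmin(pmax(cumsum(p1)[1:20], 1e-12), 1 - 1e-12)) -
      qlogis(pmin(pmax(cumsum(p0)[1:20], 1e-12), 1 - 1e-12))
    expect_equal(unname(lo), rep(f$beta_hat, 20), tolerance = 1e-6)
  }
  expect_error(predict_distribution(f, 3, "unseen", 0), "not seen")
})

test_that("beta-free predictions coincide across arms", {
  coh <- make_small_cohort(n = 80, k_max = 10, seed = 15)
  f0 <- epolr_fit(coh, include_treatment = FALSE, hessian = FALSE)
  expect_equal(predict_distribution(f0, 4, "all", 0),
               predict_distribution(f0, 4, "all", 1))
})

test_that("Wald inference follows the normal-theory algebra", {
  coh <- make_small_cohort(n = 100, k_max = 10, seed = 16)
  f <- epolr_fit(coh)
  # overwrite the estimate to check the algebra at known values
  f$beta_hat <- 0.5
  f$se_beta <- 0.1
  w <- wald_inference(f)
  expect_equal(w$z, 5)
  expect_equal(w$p_two_sided, 2 * pnorm(-5), tolerance = 1e-12)
  expect_equal(w$ci_low * w$ci_high, w$or_hat^2, tolerance = 1e-10)
  expect_equal(w$or_benefit, 1 / w$or_hat, tolerance = 1e-12)
  f$beta_hat <- 0
  w0 <- wald_inference(f)
  expect_equal(w0$or_hat, 1)
  expect_equal(w0$p_two_sided, 1)
  f$se_beta <- 0
  expect_error(wald_inference(f), "variance")
})

test_that("permuting arm labels centres the estimate at zero", {
  g <- generate_cohort(cohort_config("scim_selfcare", n_subjects = 250,
                                     beta_benefit = log(2), seed = 17))
  d <- as.data.frame(g$cohort)
  set.seed(18)
  betas <- replicate(15, {
    d$arm <- sample(d$arm)
    coh <- cohort_table(d, k_max = 20, baseline_range = c(0, 20))
    epolr_fit(coh, hessian = FALSE)$beta_hat
  })
  # mean of the null betas is within 4 MC standard errors of zero
  expect_lt(abs(mean(betas)), 4 * sd(betas) / sqrt(length(betas)))
})

test_that("degenerate strata are rejected or flagged", {
  d <- data.frame(y0 = rep(2, 12), y3 = c(rep(5, 6), 1:6),
                  stratum = rep(c("a", "b"), each = 6),
                  arm = rep(0:1, 6))
  coh <- cohort_table(d, k_max = 10, baseline_range = c(0, 10))
  sp <- transformation_spec(10, order = 4,
                            strata_levels = c("a", "b"),
                            baseline = FALSE)
  expect_error(epolr_fit(coh, sp), "distinct outcome")
  d$y3[1] <- 7  # two distinct values but fewer rows than parameters
  coh2 <- cohort_table(d, k_max = 10, baseline_range = c(0, 10))
  sp2 <- transformation_spec(10, order = 7,
                             strata_levels = c("a", "b"),
                             baseline = FALSE)
  w <- capture_warnings(epolr_fit(coh2, sp2, hessian = FALSE))
  expect_true(any(grepl("fewer than", w)))
})
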