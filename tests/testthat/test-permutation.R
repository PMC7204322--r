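test_that("binary-outcome scores match the symbolic derivative", {
  set.seed(20)
  n <- 40
  y <- rbinom(n, 1, 0.4)
  d <- cohort_table(data.frame(y0 = 0, y3 = y, stratum = "all",
                               arm = rep(0:1, n / 2)),
                    k_max = 1, baseline_range = c(0, 1))
  sp <- transformation_spec(1, order = 2, strata_levels = "all",
                            baseline = FALSE)
  f0 <- epolr_fit(d, sp, include_treatment = FALSE, hessian = FALSE)
  s <- score_contributions(f0)
  h0 <- eval_h(0, "all", NULL, f0$theta_hat, sp)
  # d/d-alpha log(expit(h0 + a)) at 0 is 1 - expit(h0) for y = 0 and
  # d/d-alpha log(1 - expit(h0 + a)) is -expit(h0) for y = 1
  expect_equal(s[y == 0], rep(1 - plogis(h0), sum(y == 0)),
               tolerance = 1e-8)
  expect_equal(s[y == 1], rep(-plogis(h0), sum(y == 1)),
               tolerance = 1e-8)
})

test_that("scores sum to zero at the null maximum likelihood solution", {
  g <- generate_cohort(cohort_config("uems", n_subjects = 200, seed = 21))
  f0 <- epolr_fit(g$cohort, include_treatment = FALSE, hessian = FALSE)
  s <- score_contributions(f0)
  expect_lt(abs(sum(s)), 1e-3)
  expect_true(all(is.finite(s)))
  expect_length(s, 200)
})

test_that("scores equal the finite-difference derivative of the shift", {
  coh <- make_small_cohort(n = 50, k_max = 10, seed = 22)
  sp <- default_spec(coh, order = 4)
  f0 <- epolr_fit(coh, sp, include_treatment = FALSE, hessian = FALSE)
  s <- score_contributions(f0)
  h <- 1e-6
  ll_shift <- function(a) {
    vapply(seq_len(nrow(coh)), function(i) {
      log(likelihood_contribution(coh$y3[i], coh$y0[i],
                                  as.character(coh$stratum[i]), 1,
                                  f0$theta_hat, a, sp))
    }, 0)
  }
  s_fd <- (ll_shift(h) - ll_shift(-h)) / (2 * h)
  expect_equal(s, s_fd, tolerance = 1e-5)
})

test_that("identical outcomes produce identical scores and p = 1", {
  d <- data.frame(y0 = 3, y3 = 4, stratum = "all", arm = rep(0:1, 10))
  s <- rep(2.5, 20)
  res <- permutation_test(s, d$arm, n_perm = 500, seed = 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$z, 0)
})

test_that("the permutation test is deterministic given a seed", {
  coh <- fixture_small_trial(seed = 3)
  f0 <- epolr_fit(coh, default_spec(coh, order = 3, baseline = FALSE),
                  include_treatment = FALSE, hessian = FALSE)
  s <- score_contributions(f0)
  r1 <- permutation_test(s, coh$arm, n_perm = 1500, seed = 99)
  r2 <- permutation_test(s, coh$arm, n_perm = 1500, seed = 99)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$z, r2$z)
  r3 <- permutation_test(s, coh$arm, n_perm = 1500, seed = 100)
  expect_false(identical(r3$perm_mean, r1$perm_mean))
})

test_that("swapping the arm coding flips z and preserves p", {
  coh <- make_small_cohort(n = 40, k_max = 10, seed = 23)
  f0 <- epolr_fit(coh, default_spec(coh, order = 4),
                  include_treatment = FALSE, hessian = FALSE)
  s <- score_contributions(f0)
  r1 <- permutation_test(s, coh$arm, n_perm = 2000, seed = 7)
  r2 <- permutation_test(s, 1L - coh$arm, n_perm = 2000, seed = 7)
  # z is standardized with Monte-Carlo moments, so the flip holds up to
  # the moment noise ~ 2/sqrt(n_perm)
  expect_equal(r2$z, -r1$z, tolerance = 0.08)
  # under exhaustive enumeration (balanced arms) the two-sided p is
  # exactly invariant to the coding swap
  fx <- fixture_small_trial(seed = 2)
  f0x <- epolr_fit(fx, default_spec(fx, order = 3, baseline = FALSE),
                   include_treatment = FALSE, hessian = FALSE)
  sx <- score_contributions(f0x)
  expect_equal(exact_perm_p(sx, fx$arm), exact_perm_p(sx, 1L - fx$arm),
               tolerance = 1e-12)
})

test_that("Monte-Carlo p matches exhaustive enumeration on the fixture", {
  coh <- fixture_small_trial(seed = 1)
  expect_identical(nrow(coh), 12L)
  expect_identical(sum(coh$arm), 6L)
  expect_identical(choose(12, 6), 924)
  f0 <- epolr_fit(coh, default_spec(coh, order = 3, baseline = FALSE),
                  include_treatment = FALSE, hessian = FALSE)
  s <- score_contributions(f0)
  p_exact <- exact_perm_p(s, coh$arm)
  r <- permutation_test(s, coh$arm, n_perm = 10000, seed = 31)
  expect_lt(abs(r$p_value - p_exact),
            2 * sqrt(p_exact * (1 - p_exact) / 10000) + 2e-4)
})

test_that("misuse of the score extraction is caught", {
  coh <- make_small_cohort(n = 30, k_max = 10, seed = 24)
  f1 <- epolr_fit(coh, default_spec(coh, order = 4), hessian = FALSE)
  expect_error(score_contributions(f1), "intercept-only")
  f0 <- epolr_fit(coh, default_spec(coh, order = 4),
                  include_treatment = FALSE, hessian = FALSE)
  other <- make_small_cohort(n = 30, k_max = 10, seed = 25)
  expect_error(score_contributions(f0, other), "does not match")
  expect_error(permutation_test(1:5, rep(1L, 5)), "both arms")
})

test_that("rank-transform scores are rank-invariant and symmetric", {
  y <- c(3, 9)
  s <- wilcoxon_score_transform(y)
  expect_equal(s[1] + s[2], 0, tolerance = 1e-12)
  set.seed(26)
  y2 <- sample(20, 10)
  s2 <- wilcoxon_score_transform(y2)
  s3 <- wilcoxon_score_transform(y2^3)  # monotone transformation
  expect_equal(s2, s3, tolerance = 1e-12)
  # scores follow the distribution-function sign convention: decreasing in y
  expect_equal(order(s2), order(-y2))
})
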