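test_that("the Wilson interval matches its closed form", {
  ci <- wilson_ci(50, 100)
  expect_equal(unname(round(ci, 4)), c(0.4038, 0.5962))
  expect_equal(unname(wilson_ci(0, 100))[1], 0)
  set.seed(40)
  for (i in 1:20) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_true(ci["lo"] >= 0 && ci["hi"] <= 1 && ci["lo"] <= ci["hi"])
    expect_true(k / n >= ci["lo"] - 1e-12 && k / n <= ci["hi"] + 1e-12)
  }
  expect_error(wilson_ci(1, 0), "at least 1")
  expect_error(wilson_ci(5, 3), "0..n")
})

test_that("bootstrap draws at OR = 1 reproduce the null fit's CDF", {
  coh <- make_small_cohort(n = 250, k_max = 20, seed = 41)
  f0 <- epolr_fit(coh, include_treatment = FALSE, hessian = FALSE)
  # one covariate combination, many replicate draws
  one <- as.data.frame(coh)[which(coh$y0 == stats::median(coh$y0))[1], ]
  subj <- cohort_table(one[rep(1, 50000), ], k_max = 20,
                       baseline_range = c(0, 20))
  y <- sample_outcomes(f0, subj, or_benefit = 1, seed = 42)
  cdf_hat <- cumsum(predict_distribution(f0, one$y0,
                                         as.character(one$stratum), 0))
  cdf_emp <- vapply(0:20, function(k) mean(y <= k), 0)
  expect_lt(max(abs(cdf_emp - cdf_hat)), 0.01)
})

test_that("simulated outcomes are stochastically increasing in the OR", {
  coh <- make_small_cohort(n = 200, k_max = 20, seed = 43)
  f0 <- epolr_fit(coh, include_treatment = FALSE, hessian = FALSE)
  subj <- as.data.frame(coh)[rep(seq_len(nrow(coh)), 50), ]
  subj$arm <- 1L
  subj <- cohort_table(subj, k_max = 20, baseline_range = c(0, 20))
  means <- vapply(c(1, 2, 3), function(or) {
    mean(sample_outcomes(f0, subj, or, seed = 44))
  }, 0)
  expect_true(all(diff(means) > 0))
  expect_error(sample_outcomes(f0, subj, 0), "positive")
})

test_that("a large simulated trial recovers the postulated effect", {
  coh <- make_small_cohort(n = 400, k_max = 20, seed = 45)
  f0 <- epolr_fit(coh, include_treatment = FALSE, hessian = FALSE)
  pool <- as.data.frame(coh)
  set.seed(46)
  idx <- sample(nrow(pool), 5000, replace = TRUE)
  subj <- pool[idx, ]
  subj$arm <- rep(c(0L, 1L), 2500)
  trial <- cohort_table(subj, k_max = 20, baseline_range = c(0, 20))
  trial$y3 <- sample_outcomes(f0, trial, or_benefit = 2, seed = 47)
  f1 <- epolr_fit(trial)
  expect_lt(abs(-f1$beta_hat - log(2)), 3 * f1$se_beta)
})

test_that("the battery returns five named p-values in (0, 1]", {
  g <- generate_cohort(cohort_config("uems", n_subjects = 100, seed = 48))
  p <- suppressWarnings(run_test_battery(g$cohort, n_perm = 300, seed = 49))
  expect_named(p, c("asymptotic_epolr", "permuted_epolr", "t_test",
                    "wilcoxon", "ancova"))
  expect_true(all(p > 0 & p <= 1))
})

test_that("identical arms leave every test non-significant", {
  base <- data.frame(y0 = c(2, 5, 8, 11, 3, 6), y3 = c(4, 9, 12, 15, 5, 10),
                     stratum = "all", arm = 0L)
  dup <- base
  dup$arm <- 1L
  trial <- cohort_table(rbind(base, dup), k_max = 20,
                        baseline_range = c(0, 20))
  # intercept-covariate spec: the duplicated-arm symmetry then pins the
  # treatment effect at exactly zero
  sp <- default_spec(trial, order = 3, baseline = FALSE)
  p <- suppressWarnings(run_test_battery(trial, sp, n_perm = 2000,
                                         seed = 50))
  expect_gte(p[["t_test"]], 0.999)
  expect_gte(p[["wilcoxon"]], 0.999)
  expect_gte(p[["ancova"]], 0.999)
  expect_gte(p[["asymptotic_epolr"]], 0.99)
  expect_gte(p[["permuted_epolr"]], 0.99)
})

test_that("degenerate trials give p = 1 with a warning", {
  d <- data.frame(y0 = rep(1:5, 4), y3 = 7, stratum = "all",
                  arm = rep(0:1, 10))
  trial <- cohort_table(d, k_max = 10, baseline_range = c(0, 10))
  expect_warning(p <- run_test_battery(trial, n_perm = 200), "degenerate")
  expect_true(all(p == 1))
})

test_that("the t-test in the battery uses N - 2 degrees of freedom", {
  g <- generate_cohort(cohort_config("uems", n_subjects = 60, seed = 51))
  ch <- g$cohort$y3 - g$cohort$y0
  tt <- t.test(ch[g$cohort$arm == 1], ch[g$cohort$arm == 0],
               var.equal = TRUE)
  expect_equal(unname(tt$parameter), 58)
})
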