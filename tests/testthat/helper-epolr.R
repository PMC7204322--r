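# Shared fixtures and independent oracles for the test-suite.

# small single-stratum cohort on a short scale, drawn from the package's
# own generator family but with hand-set parameters
make_small_cohort <- function(n = 40, k_max = 10, seed = 1, beta_benefit = 0) {
  cfg <- cohort_config("scim_selfcare", n_subjects = n,
                       beta_benefit = beta_benefit, seed = seed)
  g <- generate_cohort(cfg)
  coh <- g$cohort
  # rescale the self-care preset (0..20) down to 0..k_max for speed
  if (k_max != 20) {
    d <- as.data.frame(coh)
    d$y3 <- round(d$y3 * k_max / 20)
    d$y0 <- round(d$y0 * k_max / 20)
    coh <- cohort_table(d, k_max = k_max, baseline_range = c(0, k_max))
  }
  coh
}

# exhaustive permutation p-value: enumerate all allocations of n1 treated
# labels among n subjects (feasible for n <= 12)
exact_perm_p <- function(scores, arm) {
  n <- length(scores)
  n1 <- sum(arm)
  combs <- utils::combn(n, n1)
  t_all <- colSums(matrix(scores[combs], nrow = n1))
  t_obs <- sum(scores[arm == 1])
  mu <- mean(t_all)
  scale <- max(abs(t_all - mu), 1)
  mean(abs(t_all - mu) >= abs(t_obs - mu) - 1e-12 * scale)
}

# central finite difference of a scalar function
fd_grad <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x))
    e[j] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, 0)
}
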