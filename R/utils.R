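# Shared numerically stable primitives.  The likelihood works on the logit
# scale with boundary values at +/-Inf, so every log-probability is computed
# without ever forming expit differences in the linear domain.

# log(1 + exp(x)); for x > 33 log1p(exp(x)) == x in double precision
.log1pexp <- function(x) {
  out <- x
  small <- which(x <= 33)
  out[small] <- log1p(exp(x[small]))
  out
}

# log(expm1(d)) for d > 0, tolerating very large d
.logexpm1 <- function(d) {
  out <- d
  small <- which(d <= 33)
  out[small] <- log(expm1(d[small]))
  out
}

# log(expit(b) - expit(a)) for finite a < b
.logdiffexpit <- function(a, b) {
  a + .logexpm1(b - a) - .log1pexp(a) - .log1pexp(b)
}

# log of the logistic density (the derivative of expit) at eta
.logdexpit <- function(eta) {
  -.log1pexp(eta) - .log1pexp(-eta)
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.  seed = NULL uses the ambient stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seeds derived from a master seed, kept inside the
# 32-bit integer range expected by set.seed()
.spawn_seed <- function(seed, index) {
  as.integer((as.double(seed) + 9973 * as.double(index)) %% 2147483629)
}
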