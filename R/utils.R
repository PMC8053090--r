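# Internal helpers shared across the simulators and estimators.

# Run `expr` under a locally-seeded RNG when `seed` is non-NULL; otherwise use
# the ambient RNG stream. Fixing the RNG kind makes seeded output byte-stable
# across sessions.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr,
    .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

# Deterministically derive a child seed from a parent seed and a stream index,
# staying inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629L) + 1L
}

# Multiplicative log-normal noise with unit mean and the stated coefficient of
# variation. cv = 0 returns exact ones, so noise-free runs are truly exact.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Truncated-exponential sampler used for fragment lengths (nt). Inverse-CDF on
# the truncated support keeps the draw exact rather than rejection-based.
rexp_trunc <- function(n, mean, lower, upper) {
  rate <- 1 / mean
  p_lo <- 1 - exp(-rate * lower)
  p_hi <- 1 - exp(-rate * upper)
  u <- runif(n, p_lo, p_hi)
  -log(1 - u) / rate
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be a positive finite number.", name))
  }
  invisible(x)
}

assert_non_negative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative and finite.", name))
  }
  invisible(x)
}

assert_probability <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}
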