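# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                          integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("`%s` must be a whole number (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

.check_fraction <- function(x, name) {
  .check_scalar(x, name)
  if (x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1] (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

# Evaluate `code` under a local, seeded RNG stream; the global RNG state is
# untouched (restored afterwards). All generator randomness flows through here.
.with_seed <- function(seed, code) {
  .check_scalar(seed, "seed", integerish = TRUE)
  withr::with_seed(as.integer(seed), code)
}

# Zero-phase Gaussian smoother. `cutoff_hz` is the -3 dB frequency of the
# Gaussian transfer function exp(-2 pi^2 sigma_t^2 f^2), giving
# sigma_t = 0.1325 / cutoff_hz seconds. Edges are renormalized against the
# truncated kernel so constant inputs pass through unchanged.
.gauss_lowpass <- function(x, rate_hz, cutoff_hz) {
  sigma_t <- 0.1325 / cutoff_hz
  sigma_n <- sigma_t * rate_hz
  if (sigma_n < 0.3) return(x) # cutoff at/above Nyquist scale: no-op
  half <- ceiling(4 * sigma_n)
  k <- stats::dnorm(seq(-half, half), sd = sigma_n)
  k <- k / sum(k)
  n <- length(x)
  num <- stats::convolve(x, rev(k), type = "open")
  den <- stats::convolve(rep(1, n), rev(k), type = "open")
  (num / den)[(half + 1L):(half + n)]
}

# Round a percentage according to the reporting conventions used in the
# literature this package mirrors: "nearest" (round half away handled by R's
# round), "floor" (truncate downward), or "none".
.apply_rounding <- function(x, rounding = c("none", "nearest", "floor")) {
  rounding <- match.arg(rounding)
  switch(rounding,
    none = x,
    nearest = round(x),
    floor = floor(x)
  )
}
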