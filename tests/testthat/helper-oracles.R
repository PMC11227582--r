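# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# O(n*w) per-index median over centered, edge-truncated windows
oracle_rolling_median <- function(x, w) {
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# O(na * nb) nearest-neighbor distances via explicit double loop
oracle_nnd <- function(ax, ay, bx, by) {
  vapply(seq_along(ax), function(i) {
    best <- Inf
    for (j in seq_along(bx)) {
      d <- sqrt((ax[i] - bx[j])^2 + (ay[i] - by[j])^2)
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}

# two-sample KS statistic by enumeration over all breakpoints
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(p) {
    abs(mean(a <= p) - mean(b <= p))
  }, numeric(1)))
}

# two-sided Fisher exact p by full enumeration of tables with fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# local maxima + threshold scan used to cross-check detect_events
oracle_peak_scan <- function(z, rate_hz, window_s = 10, filter_k = 2,
                             peak_k = 3, mad_scale = 1.4826) {
  rm <- oracle_rolling_median(z, round(window_s * rate_hz))
  r <- z - rm
  mad1 <- mad_scale * stats::median(abs(r - stats::median(r)))
  zf <- z[r <= filter_k * mad1]
  m_f <- stats::median(zf)
  mad2 <- mad_scale * stats::median(abs(zf - m_f))
  thr <- m_f + peak_k * mad2
  idx <- which(vapply(seq_along(z), function(i) {
    i > 1 && i < length(z) && z[i] > z[i - 1] && z[i] > z[i + 1]
  }, logical(1)))
  idx[z[idx] > thr]
}

# textbook one-way ANOVA F from between/within mean squares
oracle_oneway_F <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  (ssb / (k - 1)) / (ssw / (n - k))
}
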