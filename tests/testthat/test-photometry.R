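# Photometry preprocessing chain and MAD-based transient detection.

make_rec <- function(sig, ctl, rate = 10, af_s = 0, af_c = 0) {
  n <- length(sig)
  photometry_recording((seq_len(n) - 1) / rate, sig, ctl, rate,
                       autofluorescence_signal = af_s,
                       autofluorescence_control = af_c)
}

test_that("rolling_median matches the brute-force oracle and its edge conventions", {
  # constants pass through; an isolated spike is rejected
  expect_equal(rolling_median(rep(3.5, 20), rate_hz = 1, window_s = 5),
               rep(3.5, 20))
  expect_equal(rolling_median(c(1, 2, 100, 2, 1), rate_hz = 1, window_s = 5)[3],
               2)
  # exact agreement with the O(n*w) oracle on 100 random series
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    w <- sample(2:15, 1)
    x <- stats::rnorm(n)
    expect_identical(rolling_median(x, rate_hz = 1, window_s = w),
                     oracle_rolling_median(x, w))
  }
  expect_error(rolling_median(numeric(0), 1, 5), "empty")
})

test_that("preprocessing applies the documented stages and degenerates loudly", {
  # identical channels (same artifact): post-subtraction variance is zero
  set.seed(1)
  t <- seq(0, 120, by = 0.1)[-1]
  shared <- 100 + 20 * exp(-t / 60) + stats::rnorm(length(t))
  rec <- make_rec(shared, shared, rate = 10)
  expect_error(preprocess_trace(rec, target_rate_hz = 10, lowpass_hz = NULL),
               "zero variance")

  # constant channels degenerate the same way
  const <- make_rec(rep(110, 1200), rep(110, 1200), rate = 10,
                    af_s = 10, af_c = 10)
  expect_error(preprocess_trace(const, target_rate_hz = 10), "zero variance")

  # downsampling must divide the rate; target must not exceed it
  ok <- make_rec(shared, shared + stats::rnorm(length(t)), rate = 10)
  expect_error(preprocess_trace(ok, target_rate_hz = 3), "integer multiple")
  expect_error(preprocess_trace(ok, target_rate_hz = 20), "not exceed")

  pt <- preprocess_trace(ok, target_rate_hz = 5, lowpass_hz = NULL)
  expect_s3_class(pt, "processed_trace")
  expect_equal(mean(pt$z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(pt$z), 1, tolerance = 1e-10)
  expect_length(pt$z, length(t) %/% 2)
  expect_true(any(grepl("downsample", pt$provenance)))
  expect_true(any(grepl("z-score", pt$provenance)))
})

test_that("exponential detrend matches a brute-force grid-search fit", {
  set.seed(7)
  t <- seq(0, 1200, length.out = 6000)
  y <- 100 + 30 * exp(-t / 600) + stats::rnorm(length(t), sd = 0.5)
  fit <- striatools:::.fit_exp_trend(t, y)
  expect_true(fit$ok)

  # grid search over tau; a and c by least squares given tau
  rss_for_tau <- function(tau) {
    X <- cbind(1, exp(-t / tau))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  taus <- exp(seq(log(50), log(5000), length.out = 400))
  best <- min(vapply(taus, rss_for_tau, numeric(1)))
  expect_lte(sum((y - fit$fitted)^2), best * 1.0001)

  # residual trend slope is < 1% of the bleach slope at t = 0 (30/600 per s)
  slope <- stats::coef(stats::lm((y - fit$fitted) ~ t))[2]
  expect_lt(abs(slope), 0.01 * 30 / 600)
})

test_that("detector finds inserted transients exactly and matches the threshold-scan oracle", {
  set.seed(42)
  rate <- 5
  t <- (0:1999) / rate  # 400 s
  noise <- striatools:::.gauss_lowpass(stats::rnorm(length(t)), rate, 0.12)
  z <- noise / stats::sd(noise)
  kern <- striatools:::.transient_kernel(seq(0, 10, by = 1 / rate), 0.3, 1.2)
  for (at in c(100, 200, 300)) {
    idx <- which(t >= at)[1] + seq_along(kern) - 1
    idx <- idx[idx <= length(z)]
    z[idx] <- z[idx] + 10 * kern[seq_along(idx)]
  }
  pt <- processed_trace(t, z, rate)
  ev <- detect_events(pt)
  expect_identical(length(ev$peak_times_s), 3L)
  # each peak within one kernel rise time + peak offset of its insertion point
  offset <- 0.3 * log1p(1.2 / 0.3)
  expect_true(all(abs(ev$peak_times_s - (c(100, 200, 300) + offset)) <= 0.61))
  expect_true(all(ev$peak_amplitudes > ev$detection$threshold -
                    ev$detection$median_filtered))

  # independent scan oracle: same peaks before min-separation pruning
  idx_oracle <- oracle_peak_scan(z, rate)
  expect_true(all(ev$peak_times_s %in% t[idx_oracle]))
  # min_sep only removes oracle peaks within 0.5 s of a larger accepted one
  dropped <- setdiff(t[idx_oracle], ev$peak_times_s)
  expect_true(all(vapply(dropped, function(d) {
    min(abs(ev$peak_times_s - d)) < 0.5
  }, logical(1))))

  # a flat trace yields no events
  flat <- processed_trace(t, rep(0, length(t)), rate)
  expect_identical(length(detect_events(flat)$peak_times_s), 0L)
})

test_that("detection is invariant under positive affine transforms of the raw channels", {
  sim <- simulate_photometry(photometry_sim_config(
    duration_s = 300, rate_hz = 600, event_rate_per_min = 2, seed = 33))
  rec <- sim$recording
  a <- 2.5; b <- 7
  rec2 <- photometry_recording(
    rec$time_s, a * rec$f_signal + b, a * rec$f_control + b, rec$rate_hz,
    autofluorescence_signal = a * rec$autofluorescence_signal + b,
    autofluorescence_control = a * rec$autofluorescence_control + b)
  e1 <- detect_events(preprocess_trace(rec))
  e2 <- detect_events(preprocess_trace(rec2))
  expect_equal(e1$peak_times_s, e2$peak_times_s)
  expect_equal(e1$peak_amplitudes, e2$peak_amplitudes, tolerance = 1e-6)
})

test_that("event summaries and KS comparisons behave as specified", {
  e <- event_train(c(60, 120, 180), c(5, 6, 7), duration_s = 1200)
  sm <- summarize_events(e)
  expect_equal(sm$frequency, 3 / 1200 * 60)
  expect_equal(sm$ieis_s, c(60, 60))

  e10 <- event_train(seq(60, 600, length.out = 10), rep(5, 10),
                     duration_s = 1200)
  expect_equal(summarize_events(e10)$frequency, 0.5)

  none <- event_train(numeric(0), numeric(0), duration_s = 600)
  sm0 <- summarize_events(none)
  expect_equal(sm0$frequency, 0)
  expect_length(sm0$ieis_s, 0)
  expect_true(is.na(sm0$mean_amplitude))

  expect_equal(compare_event_trains(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(compare_event_trains(c(1, 2, 3), c(10, 20, 30))$D, 1)
  ab <- compare_event_trains(c(1, 2), c(1.5, 2.5))
  expect_equal(ab$D, oracle_ks_D(c(1, 2), c(1.5, 2.5)))
  set.seed(5)
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:12, 1)); y <- stats::rnorm(sample(3:12, 1), 0.5)
    expect_equal(compare_event_trains(x, y)$D, oracle_ks_D(x, y))
  }
  expect_error(compare_event_trains(numeric(0), 1:3), "non-empty")
})

test_that("estimated event frequency is monotone in the true rate", {
  freqs <- vapply(c(0.25, 0.5, 1, 2), function(lam) {
    sim <- simulate_photometry(photometry_sim_config(
      event_rate_per_min = lam, seed = 77))
    summarize_events(detect_events(preprocess_trace(sim$recording)))$frequency
  }, numeric(1))
  expect_true(all(diff(freqs) >= 0))
})
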