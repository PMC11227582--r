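# Synthetic-data generators: determinism, degenerate cases, and recovery of
# the parameters they are seeded with.

test_that("seeded generators are bit-reproducible and leave the global RNG alone", {
  cfg <- photometry_sim_config(duration_s = 20, rate_hz = 100, seed = 7)
  set.seed(123)
  before <- .Random.seed
  a <- simulate_photometry(cfg)
  expect_identical(before, .Random.seed)
  b <- simulate_photometry(cfg)
  expect_identical(a$recording$f_signal, b$recording$f_signal)
  expect_identical(a$truth, b$truth)

  f1 <- simulate_spot_field(spot_field_sim_config(seed = 3))
  f2 <- simulate_spot_field(spot_field_sim_config(seed = 3))
  expect_identical(f1$spots_b, f2$spots_b)

  s1 <- simulate_behavior_scores(behavior_sim_config(seed = 5))
  s2 <- simulate_behavior_scores(behavior_sim_config(seed = 5))
  expect_identical(s1, s2)
})

test_that("photometry generator: rate-zero and fully deterministic degenerate cases", {
  sim <- simulate_photometry(photometry_sim_config(
    duration_s = 60, rate_hz = 100, event_rate_per_min = 0, seed = 2))
  expect_equal(nrow(sim$truth), 0)
  # channels differ only by independent noise (and the autofluorescence offsets)
  diff <- (sim$recording$f_signal - sim$recording$autofluorescence_signal) -
    (sim$recording$f_control - sim$recording$autofluorescence_control)
  expect_lt(abs(mean(diff)), 0.05)
  expect_lt(stats::sd(diff), 2 * sqrt(2))  # 2 independent unit-noise channels

  det <- simulate_photometry(photometry_sim_config(
    duration_s = 60, rate_hz = 100, event_rate_per_min = 0, bleach_amp = 0,
    artifact_sd = 0, noise_sd = 0, seed = 2))
  expect_equal(det$recording$f_signal,
               rep(100 + 12, 6000), tolerance = 1e-12)
  expect_equal(det$recording$f_control,
               rep(100 + 8, 6000), tolerance = 1e-12)
})

test_that("photometry generator recovers the Poisson event rate", {
  counts <- vapply(1:50, function(s) {
    nrow(simulate_photometry(photometry_sim_config(
      duration_s = 1200, rate_hz = 100, event_rate_per_min = 1,
      seed = s))$truth)
  }, numeric(1))
  # mean of 50 Poisson(20) draws: se = sqrt(20/50)
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 50))
  expect_gt(stats::var(counts), 20 / 3)  # variance of the right order
  expect_lt(stats::var(counts), 3 * 20)
})

test_that("control-channel residual variance matches artifact_sd^2 + noise_sd^2", {
  cfg <- photometry_sim_config(duration_s = 600, rate_hz = 200,
                               artifact_sd = 1.5, noise_sd = 1, seed = 11)
  sim <- simulate_photometry(cfg)
  t <- sim$recording$time_s
  known <- cfg$autofluorescence[["control"]] + cfg$baseline_f +
    cfg$bleach_amp * exp(-t / cfg$bleach_tau_s)
  resid <- sim$recording$f_control - known
  expect_equal(stats::var(resid), 1.5^2 + 1^2, tolerance = 0.15)
})

test_that("spot-field generator honors pairing ground truth and Rayleigh displacement", {
  # exact paired count, zero-displacement and empty-channel degenerates
  f <- simulate_spot_field(spot_field_sim_config(
    n_primary = 57, paired_fraction = 0.43, seed = 1))
  expect_identical(sum(!is.na(f$spots_a$truth_pair_id)), as.integer(round(0.43 * 57)))

  tight <- simulate_spot_field(spot_field_sim_config(
    n_primary = 40, paired_fraction = 1, pair_sigma_nm = 1e-9,
    n_singleton_b = 0, seed = 2))
  d <- nearest_neighbor_distances(tight)$distances_nm
  expect_true(all(d < 1e-6))

  none <- simulate_spot_field(spot_field_sim_config(
    n_primary = 10, paired_fraction = 0, n_singleton_b = 0, seed = 3))
  expect_identical(nrow(none$spots_b), 0L)

  # Rayleigh CDF at 95 nm for sigma = 35: 1 - exp(-95^2 / (2*35^2))
  big <- simulate_spot_field(spot_field_sim_config(
    field_w_nm = 1e6, field_h_nm = 1e6, n_primary = 10000,
    paired_fraction = 1, pair_sigma_nm = 35, n_singleton_b = 0, seed = 4))
  disp <- sqrt((big$spots_a$x_nm[match(big$spots_b$truth_pair_id,
                                       big$spots_a$truth_pair_id)] -
                  big$spots_b$x_nm)^2 +
               (big$spots_a$y_nm[match(big$spots_b$truth_pair_id,
                                       big$spots_a$truth_pair_id)] -
                  big$spots_b$y_nm)^2)
  p_expected <- 1 - exp(-95^2 / (2 * 35^2))
  mc_se <- sqrt(p_expected * (1 - p_expected) / 10000)
  expect_equal(mean(disp <= 95), p_expected, tolerance = 4 * mc_se / p_expected)

  expect_error(spot_field_sim_config(paired_fraction = 1.2), "\\[0, 1\\]")
})

test_that("uptake generator: exact sd-zero case, sampling recovery, preconditions", {
  cells <- tibble::tibble(genotype = "WT", condition = "basal",
                          mean = 10, sd = 0)
  tbl <- simulate_uptake(uptake_sim_config(cells, n_replicates = 4, seed = 1))
  expect_true(all(tbl$value == 10))

  # mean 11.9, sd 1.2*sqrt(8), n = 8: sample mean ~ 11.9, SEM ~ 1.2
  cells <- tibble::tibble(genotype = "WT", condition = "basal",
                          mean = 11.9, sd = 1.2 * sqrt(8))
  stats <- vapply(1:200, function(s) {
    tb <- simulate_uptake(uptake_sim_config(cells, n_replicates = 8, seed = s))
    sm <- summarize_uptake(tb)
    c(sm$mean, sm$sem)
  }, numeric(2))
  expect_equal(mean(stats[1, ]), 11.9, tolerance = 0.03)
  expect_equal(mean(stats[2, ]), 1.2, tolerance = 0.1)
  expect_true(all(simulate_uptake(uptake_sim_config(
    tibble::tibble(genotype = "a", condition = "b", mean = 0.1, sd = 5),
    n_replicates = 50, seed = 2))$value >= 0))

  expect_error(uptake_sim_config(
    tibble::tibble(genotype = "WT", condition = "basal", mean = -1, sd = 1)),
    ">= 0")
})

test_that("behavior generator: empty table, independence, genotype symmetry", {
  empty <- simulate_behavior_scores(behavior_sim_config(n_per_genotype = 0))
  expect_identical(nrow(empty), 0L)

  # diagonal covariance -> criteria uncorrelated at large n
  cfg <- behavior_sim_config(
    n_per_genotype = 3000, genotypes = "WT",
    means = list(WT = c(50, 50, 50)),
    sigma = list(WT = diag(c(25, 25, 25))), seed = 9)
  tb <- simulate_behavior_scores(cfg)
  expect_lt(abs(stats::cor(tb$persistence, tb$motivation)), 0.06)
  expect_lt(abs(stats::cor(tb$persistence, tb$compulsivity)), 0.06)

  # identical genotype distributions -> equal addicted prevalence (MC error)
  cfg2 <- behavior_sim_config(n_per_genotype = 4000, seed = 21)
  tb2 <- simulate_behavior_scores(cfg2)
  thr <- criterion_thresholds(tb2[tb2$genotype == "WT", ])
  cls <- classify_addiction(tb2, thr)$animals
  prev <- tapply(cls$label == "addicted", cls$genotype, mean)
  expect_equal(unname(prev["WT"]), unname(prev["mutant"]),
               tolerance = 5 * sqrt(2 * 0.25 / 4000) / max(prev))
})
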