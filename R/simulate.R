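# Seeded generators for every input kind the analysis pipeline consumes.
# Each generator returns known ground truth alongside the data so that
# parameter-recovery tests can score the downstream estimators.

# ---- photometry -------------------------------------------------------------

#' Configuration for the two-channel photometry simulator
#'
#' Describes a fiber-photometry recording of a fluorescent ACh sensor with an
#' isosbestic control channel. The generative model is
#' `autofluorescence + baseline + bleach_amp * exp(-t/tau) + transients +
#' shared motion artifact + independent Gaussian noise`; the control channel is
#' identical except that it carries no transients.
#'
#' Default kinetics (0.3 s rise, 1.2 s decay) reflect the seconds-scale
#' response of genetically encoded ACh sensors in vivo; amplitudes and rates
#' are in arbitrary fluorescence units since absolute event statistics for
#' spontaneous striatal ACh release are not standardized.
#'
#' @param duration_s Recording length in seconds.
#' @param rate_hz Acquisition rate in samples/s; `duration_s * rate_hz` must be
#'   a whole number of samples.
#' @param baseline_f Baseline fluorescence (a.u.) common to both channels.
#' @param bleach_amp,bleach_tau_s Amplitude (a.u.) and time constant (s) of the
#'   exponential photobleaching decay shared by both channels.
#' @param event_rate_per_min Homogeneous Poisson rate of ACh transients
#'   (events/min). May be 0.
#' @param event_amp Peak transient amplitude (a.u.).
#' @param event_rise_s,event_decay_s Rise and decay time constants (s) of the
#'   difference-of-exponentials transient kernel.
#' @param artifact_sd Standard deviation (a.u.) of the slow motion artifact
#'   added identically to both channels.
#' @param noise_sd Standard deviation (a.u.) of per-sample Gaussian noise,
#'   independent between channels.
#' @param autofluorescence Length-2 numeric (signal, control): the
#'   autofluorescence offset (a.u.) of each channel, measured with the patch
#'   cord disconnected from the animal.
#' @param seed Integer seed; the generator never touches the global RNG state.
#' @return A list of class `photometry_sim_config`.
#' @export
photometry_sim_config <- function(duration_s = 1200, rate_hz = 600,
                                  baseline_f = 100, bleach_amp = 30,
                                  bleach_tau_s = 600,
                                  event_rate_per_min = 1, event_amp = 8,
                                  event_rise_s = 0.3, event_decay_s = 1.2,
                                  artifact_sd = 1.5, noise_sd = 1,
                                  autofluorescence = c(signal = 12, control = 8),
                                  seed = 1) {
  .check_scalar(duration_s, "duration_s", positive = TRUE)
  .check_scalar(rate_hz, "rate_hz", positive = TRUE)
  n <- duration_s * rate_hz
  if (abs(n - round(n)) > 1e-6) {
    stop("duration_s * rate_hz must be an integer sample count", call. = FALSE)
  }
  .check_scalar(baseline_f, "baseline_f", nonneg = TRUE)
  .check_scalar(bleach_amp, "bleach_amp", nonneg = TRUE)
  .check_scalar(bleach_tau_s, "bleach_tau_s", positive = TRUE)
  .check_scalar(event_rate_per_min, "event_rate_per_min", nonneg = TRUE)
  .check_scalar(event_amp, "event_amp", nonneg = TRUE)
  .check_scalar(event_rise_s, "event_rise_s", positive = TRUE)
  .check_scalar(event_decay_s, "event_decay_s", positive = TRUE)
  .check_scalar(artifact_sd, "artifact_sd", nonneg = TRUE)
  .check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (length(autofluorescence) != 2L || !is.numeric(autofluorescence)) {
    stop("autofluorescence must be numeric length 2 (signal, control)",
         call. = FALSE)
  }
  structure(list(
    duration_s = duration_s, rate_hz = rate_hz, baseline_f = baseline_f,
    bleach_amp = bleach_amp, bleach_tau_s = bleach_tau_s,
    event_rate_per_min = event_rate_per_min, event_amp = event_amp,
    event_rise_s = event_rise_s, event_decay_s = event_decay_s,
    artifact_sd = artifact_sd, noise_sd = noise_sd,
    autofluorescence = stats::setNames(as.numeric(autofluorescence),
                                       c("signal", "control")),
    seed = as.integer(seed)
  ), class = "photometry_sim_config")
}

# Peak-normalized difference-of-exponentials transient kernel evaluated at
# times t (>= 0): (1 - exp(-t/tau_r)) * exp(-t/tau_d), scaled to unit peak.
.transient_kernel <- function(t, rise_s, decay_s) {
  t_peak <- rise_s * log1p(decay_s / rise_s)
  peak <- (1 - exp(-t_peak / rise_s)) * exp(-t_peak / decay_s)
  k <- (1 - exp(-t / rise_s)) * exp(-t / decay_s) / peak
  k[t < 0] <- 0
  k
}

#' Simulate a two-channel photometry recording with known event times
#'
#' @param cfg A [photometry_sim_config()].
#' @return A list with `recording` (a [photometry_recording()]) and `truth`, a
#'   tibble of ground-truth transients (`onset_s`, `peak_s`, `amplitude`).
#' @export
simulate_photometry <- function(cfg) {
  stopifnot(inherits(cfg, "photometry_sim_config"))
  n <- round(cfg$duration_s * cfg$rate_hz)
  t <- (seq_len(n) - 1) / cfg$rate_hz
  .with_seed(cfg$seed, {
    bleach <- cfg$bleach_amp * exp(-t / cfg$bleach_tau_s)
    base <- cfg$baseline_f + bleach

    # shared slow motion artifact: Gaussian noise smoothed to ~0.3 s timescale,
    # rescaled so its per-sample sd equals artifact_sd
    artifact <- rep(0, n)
    if (cfg$artifact_sd > 0) {
      a <- .gauss_lowpass(stats::rnorm(n), cfg$rate_hz, cutoff_hz = 0.44)
      artifact <- cfg$artifact_sd * a / stats::sd(a)
    }

    n_ev <- stats::rpois(1, cfg$event_rate_per_min * cfg$duration_s / 60)
    onsets <- sort(stats::runif(n_ev, 0, cfg$duration_s))
    transients <- rep(0, n)
    t_peak_off <- cfg$event_rise_s * log1p(cfg$event_decay_s / cfg$event_rise_s)
    support_s <- t_peak_off + 8 * cfg$event_decay_s
    for (on in onsets) {
      i0 <- floor(on * cfg$rate_hz) + 1L
      i1 <- min(n, ceiling((on + support_s) * cfg$rate_hz))
      if (i0 > n) next
      idx <- i0:i1
      transients[idx] <- transients[idx] +
        cfg$event_amp * .transient_kernel(t[idx] - on, cfg$event_rise_s,
                                          cfg$event_decay_s)
    }

    f_signal <- cfg$autofluorescence[["signal"]] + base + transients +
      artifact + stats::rnorm(n, sd = cfg$noise_sd)
    f_control <- cfg$autofluorescence[["control"]] + base +
      artifact + stats::rnorm(n, sd = cfg$noise_sd)

    rec <- photometry_recording(
      time_s = t, f_signal = f_signal, f_control = f_control,
      rate_hz = cfg$rate_hz,
      autofluorescence_signal = cfg$autofluorescence[["signal"]],
      autofluorescence_control = cfg$autofluorescence[["control"]]
    )
    truth <- tibble::tibble(
      onset_s = onsets,
      peak_s = onsets + t_peak_off,
      amplitude = rep(cfg$event_amp, n_ev)
    )
    list(recording = rec, truth = truth)
  })
}

# ---- STED spot fields -------------------------------------------------------

#' Configuration for the two-channel spot-field simulator
#'
#' Emulates two-color STED localizations of transporter-immunopositive spots on
#' isolated synaptic vesicles: a fraction `paired_fraction` of channel-A spots
#' carries a channel-B partner displaced by a Rayleigh-distributed distance at
#' uniform angle (co-expressing vesicles), the remainder of channel B is
#' complete spatial randomness (singleton vesicles).
#'
#' @param field_w_nm,field_h_nm Field dimensions in nm.
#' @param n_primary Number of channel-A spots, placed uniformly.
#' @param paired_fraction Fraction of A spots given a B partner; exactly
#'   `round(paired_fraction * n_primary)` partners are created.
#' @param pair_sigma_nm Rayleigh scale (nm) of the paired displacement.
#' @param n_singleton_b Number of unpaired channel-B spots placed uniformly.
#' @param seed Integer seed.
#' @return A list of class `spot_field_sim_config`.
#' @export
spot_field_sim_config <- function(field_w_nm = 10000, field_h_nm = 10000,
                                  n_primary = 200, paired_fraction = 0.4,
                                  pair_sigma_nm = 40, n_singleton_b = 20,
                                  seed = 1) {
  .check_scalar(field_w_nm, "field_w_nm", positive = TRUE)
  .check_scalar(field_h_nm, "field_h_nm", positive = TRUE)
  .check_scalar(n_primary, "n_primary", nonneg = TRUE, integerish = TRUE)
  .check_fraction(paired_fraction, "paired_fraction")
  .check_scalar(pair_sigma_nm, "pair_sigma_nm", nonneg = TRUE)
  .check_scalar(n_singleton_b, "n_singleton_b", nonneg = TRUE,
                integerish = TRUE)
  structure(list(
    field_w_nm = field_w_nm, field_h_nm = field_h_nm,
    n_primary = as.integer(n_primary), paired_fraction = paired_fraction,
    pair_sigma_nm = pair_sigma_nm, n_singleton_b = as.integer(n_singleton_b),
    seed = as.integer(seed)
  ), class = "spot_field_sim_config")
}

#' Simulate a two-channel spot field with known pairing ground truth
#'
#' @param cfg A [spot_field_sim_config()].
#' @return A [spot_field()] whose `spots_a`/`spots_b` tibbles carry a
#'   `truth_pair_id` column (`NA` for unpaired spots). Paired B spots may land
#'   slightly outside the nominal field bounds; they are kept, since clipping
#'   would bias the displacement distribution.
#' @export
simulate_spot_field <- function(cfg) {
  stopifnot(inherits(cfg, "spot_field_sim_config"))
  .with_seed(cfg$seed, {
    na <- cfg$n_primary
    ax <- stats::runif(na, 0, cfg$field_w_nm)
    ay <- stats::runif(na, 0, cfg$field_h_nm)
    n_pair <- round(cfg$paired_fraction * na)
    paired_idx <- if (n_pair > 0) sample.int(na, n_pair) else integer(0)

    # Rayleigh displacement at uniform angle
    r <- cfg$pair_sigma_nm * sqrt(-2 * log(stats::runif(n_pair)))
    th <- stats::runif(n_pair, 0, 2 * pi)
    bx <- ax[paired_idx] + r * cos(th)
    by <- ay[paired_idx] + r * sin(th)

    sx <- stats::runif(cfg$n_singleton_b, 0, cfg$field_w_nm)
    sy <- stats::runif(cfg$n_singleton_b, 0, cfg$field_h_nm)

    pair_id_a <- rep(NA_integer_, na)
    pair_id_a[paired_idx] <- seq_len(n_pair)
    spots_a <- tibble::tibble(x_nm = ax, y_nm = ay, truth_pair_id = pair_id_a)
    spots_b <- tibble::tibble(
      x_nm = c(bx, sx), y_nm = c(by, sy),
      truth_pair_id = c(seq_len(n_pair), rep(NA_integer_, cfg$n_singleton_b))
    )
    spot_field(spots_a, spots_b,
               bounds = c(0, cfg$field_w_nm, 0, cfg$field_h_nm))
  })
}

# ---- uptake replicates ------------------------------------------------------

#' Configuration for the vesicular-uptake replicate simulator
#'
#' @param cells A data frame / tibble with columns `genotype`, `condition`,
#'   `mean`, `sd` (all in pmol per mg protein per 10 min). Means must be >= 0.
#' @param n_replicates Independent determinations per cell (>= 2).
#' @param seed Integer seed.
#' @return A list of class `uptake_sim_config`.
#' @export
uptake_sim_config <- function(cells, n_replicates = 6, seed = 1) {
  cells <- tibble::as_tibble(cells)
  need <- c("genotype", "condition", "mean", "sd")
  if (!all(need %in% names(cells))) {
    stop("`cells` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(cells$mean)) || any(cells$mean < 0)) {
    stop("uptake means must be finite and >= 0", call. = FALSE)
  }
  if (any(cells$sd < 0)) stop("uptake sds must be >= 0", call. = FALSE)
  .check_scalar(n_replicates, "n_replicates", integerish = TRUE)
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  structure(list(cells = cells, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "uptake_sim_config")
}

#' Simulate an uptake replicate table
#'
#' Replicates are drawn Normal(mean, sd) and truncated at zero (resampled),
#' mirroring the non-negative scintillation counts of a filter-binding assay.
#'
#' @param cfg An [uptake_sim_config()].
#' @return A tibble (`genotype`, `condition`, `replicate`, `value`).
#' @export
simulate_uptake <- function(cfg) {
  stopifnot(inherits(cfg, "uptake_sim_config"))
  .with_seed(cfg$seed, {
    out <- lapply(seq_len(nrow(cfg$cells)), function(i) {
      row <- cfg$cells[i, ]
      v <- stats::rnorm(cfg$n_replicates, row$mean, row$sd)
      while (any(v < 0)) {
        v[v < 0] <- stats::rnorm(sum(v < 0), row$mean, row$sd)
      }
      tibble::tibble(genotype = row$genotype, condition = row$condition,
                     replicate = seq_len(cfg$n_replicates), value = v)
    })
    dplyr::bind_rows(out)
  })
}

# ---- behavioral scores ------------------------------------------------------

#' Configuration for the behavioral-score simulator
#'
#' Per-genotype multivariate-normal scores for the three food-addiction
#' criteria (persistence, motivation, compulsivity). Default means/covariance
#' give overdispersed, mildly correlated operant counts typical of long
#' fixed-ratio training.
#'
#' @param n_per_genotype Animals per genotype (may be 0).
#' @param genotypes Character vector of genotype labels.
#' @param means Named list: per genotype, numeric length-3 mean vector
#'   (persistence, motivation, compulsivity).
#' @param sigma Named list: per genotype, 3x3 symmetric positive-semidefinite
#'   covariance matrix.
#' @param seed Integer seed.
#' @return A list of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(n_per_genotype = 14,
                                genotypes = c("WT", "mutant"),
                                means = NULL, sigma = NULL, seed = 1) {
  .check_scalar(n_per_genotype, "n_per_genotype", nonneg = TRUE,
                integerish = TRUE)
  if (is.null(means)) {
    means <- stats::setNames(
      rep(list(c(persistence = 25, motivation = 15, compulsivity = 10)),
          length(genotypes)), genotypes)
  }
  if (is.null(sigma)) {
    s <- diag(c(8, 5, 4))
    r <- matrix(c(1, 0.3, 0.3, 0.3, 1, 0.3, 0.3, 0.3, 1), 3)
    sigma <- stats::setNames(rep(list(s %*% r %*% s), length(genotypes)),
                             genotypes)
  }
  for (g in genotypes) {
    S <- sigma[[g]]
    if (is.null(S) || !isSymmetric(unname(S)) ||
        any(eigen(S, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
      stop("covariance for genotype ", g,
           " must be symmetric positive-semidefinite", call. = FALSE)
    }
    if (length(means[[g]]) != 3L) {
      stop("mean vector for genotype ", g, " must have length 3", call. = FALSE)
    }
  }
  structure(list(n_per_genotype = as.integer(n_per_genotype),
                 genotypes = genotypes, means = means, sigma = sigma,
                 seed = as.integer(seed)),
            class = "behavior_sim_config")
}

#' Simulate a behavioral score table
#'
#' @param cfg A [behavior_sim_config()].
#' @return A score tibble (`animal`, `genotype`, `persistence`, `motivation`,
#'   `compulsivity`). Scores are clamped at 0 (operant counts cannot be
#'   negative); with the defaults clamping is rare.
#' @export
simulate_behavior_scores <- function(cfg) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  .with_seed(cfg$seed, {
    out <- lapply(cfg$genotypes, function(g) {
      n <- cfg$n_per_genotype
      if (n == 0L) {
        return(tibble::tibble(animal = character(0), genotype = character(0),
                              persistence = numeric(0), motivation = numeric(0),
                              compulsivity = numeric(0)))
      }
      x <- MASS::mvrnorm(n, mu = cfg$means[[g]], Sigma = cfg$sigma[[g]])
      x <- matrix(pmax(x, 0), nrow = n)
      tibble::tibble(animal = paste0(g, "_", seq_len(n)), genotype = g,
                     persistence = x[, 1], motivation = x[, 2],
                     compulsivity = x[, 3])
    })
    dplyr::bind_rows(out)
  })
}
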