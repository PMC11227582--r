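# Orchestration: validated run configurations, stage dispatch, provenance.

#' Validate a pipeline run configuration
#'
#' @param subcommand One of `"simulate"`, `"photometry"`, `"coloc"`,
#'   `"uptake"`, `"behavior"`.
#' @param input Input file path (stages other than `simulate`).
#' @param out_dir Output directory (created if absent).
#' @param params Named list of stage parameters; unknown names are rejected.
#'   Recognized: `kind` (simulate), `target_rate_hz`, `lowpass_hz`,
#'   `window_s`, `filter_k`, `peak_k`, `min_sep_s`, `mad_scale`,
#'   `threshold_nm`, `rounding`, `percentile_method`.
#' @param seed Integer seed for stages that draw random numbers.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(subcommand, input = NULL, out_dir = "striatools_out",
                       params = list(), seed = 1) {
  subcommand <- match.arg(subcommand, c("simulate", "photometry", "coloc",
                                        "uptake", "behavior"))
  known <- c("kind", "target_rate_hz", "lowpass_hz", "window_s", "filter_k",
             "peak_k", "min_sep_s", "mad_scale", "threshold_nm", "rounding",
             "percentile_method")
  unknown <- setdiff(names(params), known)
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("target_rate_hz", "window_s", "filter_k", "peak_k",
               "threshold_nm")) {
    if (!is.null(params[[nm]])) .check_scalar(params[[nm]], nm,
                                              positive = TRUE)
  }
  if (subcommand != "simulate") {
    if (is.null(input)) stop("`input` required for ", subcommand,
                             call. = FALSE)
    if (!file.exists(input)) stop("input not found: ", input, call. = FALSE)
  }
  .check_scalar(seed, "seed", integerish = TRUE)
  structure(list(subcommand = subcommand, input = input, out_dir = out_dir,
                 params = params, seed = as.integer(seed)),
            class = "run_config")
}

.write_provenance <- function(cfg, out_dir, artifacts) {
  jsonlite::write_json(
    list(subcommand = cfg$subcommand,
         input = cfg$input,
         params = cfg$params,
         seed = cfg$seed,
         package = "striatools",
         version = as.character(utils::packageVersion("striatools")),
         r_version = as.character(getRversion()),
         artifacts = artifacts),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
}

#' Run one pipeline stage
#'
#' Executes the configured stage, writes machine-readable outputs (CSV/JSON)
#' plus a `provenance.json` (parameters, seed, package version) to
#' `out_dir`, and returns the artifact paths. Inputs on disk are never
#' modified.
#'
#' Stages: `simulate` (kind = `photometry`/`spots`/`uptake`/`behavior`)
#' writes the synthetic inputs and their ground truth; `photometry` runs
#' preprocessing + event detection on a trace CSV and writes an event table
#' and summary JSON; `coloc` computes NNDs and the threshold classification
#' for a spot TSV; `uptake` summarizes a replicate CSV (with per-genotype
#' synergy when `basal`/`glutamate` conditions are present); `behavior`
#' derives control thresholds, classifies animals and writes correlations.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a named list of written artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  artifacts <- switch(cfg$subcommand,
    simulate = .stage_simulate(cfg, p),
    photometry = .stage_photometry(cfg, p),
    coloc = .stage_coloc(cfg, p),
    uptake = .stage_uptake(cfg, p),
    behavior = .stage_behavior(cfg, p)
  )
  .write_provenance(cfg, cfg$out_dir, artifacts)
  invisible(c(artifacts, provenance = file.path(cfg$out_dir,
                                                "provenance.json")))
}

.stage_simulate <- function(cfg, p) {
  kind <- p$kind %||% "photometry"
  kind <- match.arg(kind, c("photometry", "spots", "uptake", "behavior"))
  out <- cfg$out_dir
  if (kind == "photometry") {
    sim <- simulate_photometry(photometry_sim_config(seed = cfg$seed))
    trace <- file.path(out, "trace.csv")
    truth <- file.path(out, "trace_truth.csv")
    write_photometry_trace(sim$recording, trace)
    write_table_csv(sim$truth, truth)
    list(trace = trace, truth = truth)
  } else if (kind == "spots") {
    field <- simulate_spot_field(spot_field_sim_config(seed = cfg$seed))
    path <- file.path(out, "spots.tsv")
    write_spot_field(field, path)
    list(spots = path)
  } else if (kind == "uptake") {
    cells <- tibble::tibble(
      genotype = c("WT", "WT", "mutant", "mutant"),
      condition = c("basal", "glutamate", "basal", "glutamate"),
      mean = c(11.9, 25.3, 9.27, 16.21),
      sd = c(1.2 * sqrt(8), 2.5 * sqrt(7), 1.15 * sqrt(8), 0.68 * sqrt(7)))
    tbl <- simulate_uptake(uptake_sim_config(cells, n_replicates = 8,
                                             seed = cfg$seed))
    path <- file.path(out, "uptake.csv")
    write_table_csv(tbl, path)
    list(uptake = path)
  } else {
    tbl <- simulate_behavior_scores(behavior_sim_config(seed = cfg$seed))
    path <- file.path(out, "scores.csv")
    write_table_csv(tbl, path)
    list(scores = path)
  }
}

.stage_photometry <- function(cfg, p) {
  rec <- read_photometry_trace(cfg$input)
  pt <- preprocess_trace(rec,
                         target_rate_hz = p$target_rate_hz %||% 120,
                         lowpass_hz = p$lowpass_hz %||% 0.12)
  ev <- detect_events(pt,
                      window_s = p$window_s %||% 10,
                      filter_k = p$filter_k %||% 2,
                      peak_k = p$peak_k %||% 3,
                      min_sep_s = p$min_sep_s %||% 0.5,
                      mad_scale = p$mad_scale %||% 1.4826)
  sm <- summarize_events(ev)
  events_path <- file.path(cfg$out_dir, "events.csv")
  write_table_csv(tibble::tibble(time_s = ev$peak_times_s,
                                 amplitude_z = ev$peak_amplitudes),
                  events_path)
  summary_path <- file.path(cfg$out_dir, "photometry_summary.json")
  jsonlite::write_json(
    list(n_events = sm$n_events, mean_amplitude = sm$mean_amplitude,
         frequency_per_min = sm$frequency,
         threshold = ev$detection$threshold,
         median_filtered = ev$detection$median_filtered,
         provenance = pt$provenance),
    summary_path, auto_unbox = TRUE, digits = NA, na = "null")
  list(events = events_path, summary = summary_path)
}

.stage_coloc <- function(cfg, p) {
  field <- read_spot_field(cfg$input)
  prof <- nearest_neighbor_distances(field)
  cls <- classify_coexpression(prof, threshold_nm = p$threshold_nm %||% 95)
  nnd_path <- file.path(cfg$out_dir, "nnd.csv")
  hist_path <- file.path(cfg$out_dir, "nnd_histogram.csv")
  cls_path <- file.path(cfg$out_dir, "coexpression.json")
  write_table_csv(tibble::tibble(distance_nm = prof$distances_nm), nnd_path)
  write_table_csv(prof$histogram, hist_path)
  jsonlite::write_json(
    list(n_below = cls$n_below, n_above = cls$n_above,
         fraction_below = cls$fraction_below,
         threshold_nm = cls$threshold_nm),
    cls_path, auto_unbox = TRUE, digits = NA)
  list(nnd = nnd_path, histogram = hist_path, classification = cls_path)
}

.stage_uptake <- function(cfg, p) {
  tbl <- read_uptake_table(cfg$input)
  sm <- summarize_uptake(tbl)
  sm_path <- file.path(cfg$out_dir, "uptake_summary.csv")
  write_table_csv(sm, sm_path)
  artifacts <- list(summary = sm_path)
  conds <- unique(tbl$condition)
  if (all(c("basal", "glutamate") %in% conds)) {
    syn <- lapply(split(sm, sm$genotype), function(g) {
      basal <- g$mean[g$condition == "basal"]
      stim <- g$mean[g$condition == "glutamate"]
      if (length(basal) == 1 && length(stim) == 1) {
        list(basal_mean = basal, stimulated_mean = stim,
             percent_increase = percent_change(basal, stim,
                                               p$rounding %||% "none"))
      }
    })
    syn_path <- file.path(cfg$out_dir, "synergy.json")
    jsonlite::write_json(syn, syn_path, auto_unbox = TRUE, digits = NA)
    artifacts$synergy <- syn_path
  }
  artifacts
}

.stage_behavior <- function(cfg, p) {
  scores <- read_score_table(cfg$input)
  wt <- scores[scores$genotype == "WT", ]
  thr <- criterion_thresholds(wt, method = p$percentile_method %||%
                                "empirical")
  cls <- classify_addiction(scores, thr)
  cor_tbl <- correlate_criteria(cls, scores)
  cls_path <- file.path(cfg$out_dir, "classification.csv")
  cor_path <- file.path(cfg$out_dir, "criteria_correlations.csv")
  sum_path <- file.path(cfg$out_dir, "behavior_summary.json")
  write_table_csv(cls$animals, cls_path)
  write_table_csv(cor_tbl, cor_path)
  ok <- !cls$animals$excluded
  counts <- table(factor(cls$animals$genotype[ok]),
                  factor(cls$animals$label[ok],
                         levels = c("addicted", "non-addicted")))
  jsonlite::write_json(
    list(thresholds = as.list(thr),
         addicted_by_genotype = lapply(
           rownames(counts), function(g) {
             list(genotype = g,
                  addicted = unname(counts[g, "addicted"]),
                  non_addicted = unname(counts[g, "non-addicted"]))
           })),
    sum_path, auto_unbox = TRUE, digits = NA)
  list(classification = cls_path, correlations = cor_path,
       summary = sum_path)
}
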