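# Summary statistics and arithmetic for vesicular-uptake and synergy
# experiments, plus the generic percent-change helper used for voltammetry
# and uptake effect sizes. Values are in pmol per mg protein per 10 min.

#' Per-cell summary of an uptake replicate table
#'
#' @param tbl Tibble/data frame with columns `genotype`, `condition`, `value`
#'   (replicate uptake, pmol mg^-1 10 min^-1). Values must be >= 0.
#' @return Tibble with one row per (genotype, condition): `n`, `mean`, `sd`,
#'   `sem` (sample sd / sqrt(n), `NA` and `flag = "sem_undefined"` when n < 2).
#' @export
summarize_uptake <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("genotype", "condition", "value")
  if (!all(need %in% names(tbl))) {
    stop("`tbl` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tbl$value)) || any(tbl$value < 0)) {
    stop("uptake values must be finite and >= 0", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data$genotype, .data$condition),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    .groups = "drop"
  )
  out$sem <- ifelse(out$n >= 2, out$sd / sqrt(out$n), NA_real_)
  out$flag <- ifelse(out$n >= 2, NA_character_, "sem_undefined")
  out
}

#' Percent change of a value relative to a reference
#'
#' `100 * (value - reference) / reference`, with an explicit rounding
#' convention because published percent effects mix conventions (e.g. a +113%
#' synergy from 11.9 -> 25.3 is rounded to nearest; a +74% from 9.27 -> 16.21
#' is truncated downward).
#'
#' @param reference Baseline value (> 0).
#' @param value Comparison value.
#' @param rounding `"none"` (default), `"nearest"`, or `"floor"`.
#' @return Percent change (scalar).
#' @export
percent_change <- function(reference, value,
                           rounding = c("none", "nearest", "floor")) {
  .check_scalar(reference, "reference")
  .check_scalar(value, "value")
  if (reference <= 0) stop("reference must be > 0", call. = FALSE)
  .apply_rounding(100 * (value - reference) / reference, rounding)
}

#' Transporter-attributable uptake from total and residual means
#'
#' Decomposes total vesicular uptake into the share attributable to one
#' transporter: `absolute = total - residual` (the knockout residual reflects
#' the remaining transporters) and `percent = 100 * absolute / total`.
#'
#' @param total_mean Mean uptake with the transporter present.
#' @param residual_mean Mean uptake with the transporter absent;
#'   `0 <= residual_mean <= total_mean`.
#' @param rounding Rounding convention, as in [percent_change()].
#' @return List with `absolute` (pmol mg^-1 10 min^-1) and `percent`.
#' @export
transporter_contribution <- function(total_mean, residual_mean,
                                     rounding = c("none", "nearest",
                                                  "floor")) {
  .check_scalar(total_mean, "total_mean", nonneg = TRUE)
  .check_scalar(residual_mean, "residual_mean", nonneg = TRUE)
  if (total_mean == 0) stop("total_mean must be > 0", call. = FALSE)
  if (residual_mean > total_mean) {
    stop("residual_mean must not exceed total_mean", call. = FALSE)
  }
  absolute <- total_mean - residual_mean
  list(absolute = .apply_rounding(absolute, rounding),
       percent = .apply_rounding(100 * absolute / total_mean, rounding))
}

#' Group comparison for uptake designs
#'
#' Routine ANOVA machinery for replicate tables: one-way (factor `group`) with
#' Tukey HSD post hoc, or two-way with interaction (factors `genotype`,
#' `condition`) with Bonferroni-corrected pairwise cell comparisons —
#' matching the post hoc methods conventionally paired with each design.
#'
#' @param tbl Tibble with `value` plus `group` (one-way) or `genotype` and
#'   `condition` (two-way). Each cell needs n >= 2.
#' @param design `"one_way"` or `"two_way"`.
#' @return List with `anova` (data frame of F, df, p), `posthoc` (tibble of
#'   pairwise comparisons) and `flag` (`"degenerate_variance"` when the
#'   residual variance is zero, in which case F/p are `NA`).
#' @export
compare_groups <- function(tbl, design = c("one_way", "two_way")) {
  design <- match.arg(design)
  tbl <- tibble::as_tibble(tbl)
  if (!"value" %in% names(tbl)) stop("`tbl` needs a `value` column",
                                     call. = FALSE)
  if (design == "one_way") {
    if (!"group" %in% names(tbl)) stop("one-way design needs `group`",
                                       call. = FALSE)
    tbl$group <- factor(tbl$group)
    if (nlevels(tbl$group) < 2) stop("need >= 2 groups", call. = FALSE)
    if (any(table(tbl$group) < 2)) stop("each group needs n >= 2",
                                        call. = FALSE)
    fit <- stats::aov(value ~ group, data = tbl)
  } else {
    if (!all(c("genotype", "condition") %in% names(tbl))) {
      stop("two-way design needs `genotype` and `condition`", call. = FALSE)
    }
    tbl$genotype <- factor(tbl$genotype)
    tbl$condition <- factor(tbl$condition)
    if (any(table(tbl$genotype, tbl$condition) < 2)) {
      stop("each genotype x condition cell needs n >= 2", call. = FALSE)
    }
    fit <- stats::aov(value ~ genotype * condition, data = tbl)
  }
  an <- suppressWarnings(stats::anova(fit))
  ms_resid <- an["Residuals", "Mean Sq"]
  degenerate <- !is.finite(ms_resid) ||
    ms_resid <= 1e-12 * max(stats::var(tbl$value), .Machine$double.eps)
  if (degenerate) {
    an[["F value"]][] <- NA_real_
    an[["Pr(>F)"]][] <- NA_real_
    posthoc <- tibble::tibble()
  } else if (design == "one_way") {
    tk <- stats::TukeyHSD(fit)$group
    posthoc <- tibble::tibble(comparison = rownames(tk),
                              diff = tk[, "diff"],
                              lwr = tk[, "lwr"], upr = tk[, "upr"],
                              p_adj = tk[, "p adj"], method = "tukey")
  } else {
    cell <- interaction(tbl$genotype, tbl$condition, sep = ":")
    pt <- stats::pairwise.t.test(tbl$value, cell,
                                 p.adjust.method = "bonferroni")$p.value
    pairs <- which(!is.na(pt), arr.ind = TRUE)
    posthoc <- tibble::tibble(
      comparison = paste(rownames(pt)[pairs[, 1]], "-",
                         colnames(pt)[pairs[, 2]]),
      p_adj = pt[pairs], method = "bonferroni")
  }
  list(anova = as.data.frame(an),
       posthoc = posthoc,
       flag = if (degenerate) "degenerate_variance" else NA_character_)
}
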