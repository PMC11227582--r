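# Food-addiction criterion classification (75th-percentile rule, 2-of-3
# decision) and cohort frequency arithmetic for rare-variant carriers.

.CRITERIA <- c("persistence", "motivation", "compulsivity")

.check_score_table <- function(scores) {
  scores <- tibble::as_tibble(scores)
  need <- c("animal", "genotype", .CRITERIA)
  if (!all(need %in% names(scores))) {
    stop("score table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  scores
}

#' Per-criterion 75th-percentile thresholds from the WT control group
#'
#' An animal is positive for a criterion when its score exceeds the 75th
#' percentile of the WT control distribution. By default the empirical
#' percentile (linear interpolation between order statistics,
#' `quantile(type = 7)`) is used; `method = "gaussian"` instead uses the
#' Gaussian quantile `mean + 0.6745 * sd`, for the reading of the rule as a
#' percentile of a fitted normal distribution.
#'
#' @param wt_scores Score table restricted to the control group (>= 4
#'   animals).
#' @param method `"empirical"` (default) or `"gaussian"`.
#' @return Named numeric vector of thresholds (persistence, motivation,
#'   compulsivity).
#' @export
criterion_thresholds <- function(wt_scores,
                                 method = c("empirical", "gaussian")) {
  method <- match.arg(method)
  wt_scores <- .check_score_table(wt_scores)
  if (nrow(wt_scores) < 4) {
    stop("need >= 4 control animals to anchor the 75th percentile",
         call. = FALSE)
  }
  vapply(.CRITERIA, function(cr) {
    x <- wt_scores[[cr]]
    if (any(is.na(x))) stop("missing scores in control group for ", cr,
                            call. = FALSE)
    if (method == "empirical") {
      unname(stats::quantile(x, 0.75, type = 7))
    } else {
      mean(x) + stats::qnorm(0.75) * stats::sd(x)
    }
  }, numeric(1))
}

#' Classify animals as food-addicted by the 2-of-3 criterion rule
#'
#' A criterion is met when the score is strictly above its threshold; animals
#' meeting 2 or 3 criteria are labeled `"addicted"`, otherwise
#' `"non-addicted"`. Animals with any missing score are flagged `excluded` and
#' carry `NA` classification.
#'
#' @param scores A score table.
#' @param thresholds Named thresholds from [criterion_thresholds()].
#' @return A list of class `addiction_classification`: `animals` (tibble with
#'   per-criterion logicals, `criteria_met`, `label`, `excluded`) and
#'   `thresholds`.
#' @export
classify_addiction <- function(scores, thresholds) {
  scores <- .check_score_table(scores)
  if (!all(.CRITERIA %in% names(thresholds))) {
    stop("thresholds must be named for all three criteria", call. = FALSE)
  }
  pos <- vapply(.CRITERIA, function(cr) scores[[cr]] > thresholds[[cr]],
                logical(nrow(scores)))
  pos <- matrix(pos, ncol = 3, dimnames = list(NULL, .CRITERIA))
  excluded <- apply(is.na(pos), 1, any)
  met <- ifelse(excluded, NA_integer_, rowSums(pos))
  out <- tibble::tibble(
    animal = scores$animal, genotype = scores$genotype,
    persistence_pos = pos[, 1], motivation_pos = pos[, 2],
    compulsivity_pos = pos[, 3],
    criteria_met = as.integer(met),
    label = ifelse(excluded, NA_character_,
                   ifelse(met >= 2, "addicted", "non-addicted")),
    excluded = excluded
  )
  structure(list(animals = out, thresholds = thresholds),
            class = "addiction_classification")
}

#' Pearson correlation between criteria met and raw criterion scores
#'
#' Per genotype and criterion, the Pearson correlation (two-sided test)
#' between the number of addiction-like criteria met and the raw score.
#'
#' @param classification An [classify_addiction()] result.
#' @param scores The score table the classification was computed from.
#' @return Tibble (`genotype`, `criterion`, `n`, `r`, `r_squared`, `p_value`,
#'   `flag`); zero-variance cells are flagged with `NA` statistics.
#' @export
correlate_criteria <- function(classification, scores) {
  stopifnot(inherits(classification, "addiction_classification"))
  scores <- .check_score_table(scores)
  cls <- classification$animals
  merged <- dplyr::inner_join(
    cls[!cls$excluded, c("animal", "genotype", "criteria_met")],
    scores[, c("animal", .CRITERIA)], by = "animal")
  out <- lapply(split(merged, merged$genotype), function(g) {
    dplyr::bind_rows(lapply(.CRITERIA, function(cr) {
      x <- g$criteria_met; y <- g[[cr]]
      bad <- nrow(g) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0
      if (bad) {
        tibble::tibble(genotype = g$genotype[1], criterion = cr, n = nrow(g),
                       r = NA_real_, r_squared = NA_real_,
                       p_value = NA_real_, flag = "zero_variance")
      } else {
        ct <- stats::cor.test(x, y)
        tibble::tibble(genotype = g$genotype[1], criterion = cr, n = nrow(g),
                       r = unname(ct$estimate),
                       r_squared = unname(ct$estimate)^2,
                       p_value = ct$p.value, flag = NA_character_)
      }
    }))
  })
  dplyr::bind_rows(out)
}

#' Cohort counts for rare-variant frequency arithmetic
#'
#' @param n_carriers,n_total Carrier and total person counts
#'   (`n_carriers <= n_total`).
#' @param n_risk_alleles,n_ref_alleles Risk and reference allele counts.
#' @return A list of class `cohort_counts`.
#' @export
cohort_counts <- function(n_carriers, n_total, n_risk_alleles = NA,
                          n_ref_alleles = NA) {
  .check_scalar(n_carriers, "n_carriers", nonneg = TRUE, integerish = TRUE)
  .check_scalar(n_total, "n_total", positive = TRUE, integerish = TRUE)
  if (n_carriers > n_total) stop("n_carriers must be <= n_total",
                                 call. = FALSE)
  structure(list(n_carriers = n_carriers, n_total = n_total,
                 n_risk_alleles = n_risk_alleles,
                 n_ref_alleles = n_ref_alleles),
            class = "cohort_counts")
}

#' Carrier frequency as a printed percentage
#'
#' `100 * n_carriers / n_total`, rendered to one decimal (e.g. 9 carriers of
#' 793 cases -> 1.1).
#'
#' @param c A [cohort_counts()].
#' @return Percent, rounded to 1 decimal.
#' @export
carrier_frequency <- function(c) {
  stopifnot(inherits(c, "cohort_counts"))
  round(100 * c$n_carriers / c$n_total, 1)
}

#' Minor allele frequency as a fraction
#'
#' `risk / (risk + reference)`. Note that for 9 risk vs 1595 reference
#' alleles this evaluates to 0.0056 (0.56%), not the 0.8% sometimes printed
#' alongside such counts; the function reports the direct quotient.
#'
#' @param c A [cohort_counts()] with allele counts set.
#' @return Allele frequency in `[0, 1]`.
#' @export
allele_frequency <- function(c) {
  stopifnot(inherits(c, "cohort_counts"))
  risk <- c$n_risk_alleles; ref <- c$n_ref_alleles
  if (is.na(risk) || is.na(ref)) stop("allele counts not set", call. = FALSE)
  if (risk + ref <= 0) stop("allele total must be > 0", call. = FALSE)
  risk / (risk + ref)
}

#' Fisher exact test on a 2x2 table
#'
#' Conditional hypergeometric two-sided p-value (the sum of the probabilities
#' of all tables, with margins fixed, no more probable than the observed one)
#' together with the sample odds ratio `(a*d)/(b*c)`.
#'
#' @param a,b,c,d Non-negative integer counts of the 2x2 table
#'   `rbind(c(a, b), c(c, d))`; both row and column margins must be positive.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  for (nm in c("a", "b", "c", "d")) {
    .check_scalar(get(nm), nm, nonneg = TRUE, integerish = TRUE)
  }
  m <- rbind(c(a, b), c(c, d))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("Fisher exact test undefined: zero margin", call. = FALSE)
  }
  ft <- stats::fisher.test(m)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p_value = ft$p.value)
}
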