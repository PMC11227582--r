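# Nearest-neighbor-distance analysis of two-channel STED spot fields and
# threshold-based co-expression classification.

#' Construct a two-channel spot field
#'
#' @param spots_a,spots_b Data frames / tibbles with numeric `x_nm`, `y_nm`
#'   columns: channel A (e.g. VGLUT3-immunopositive spots) and channel B
#'   (e.g. VAChT-immunopositive spots).
#' @param bounds Numeric length 4, `c(xmin, xmax, ymin, ymax)` in nm: the
#'   nominal imaging field. Spots are not hard-rejected for lying slightly
#'   outside (simulated pair partners may overhang the field edge).
#' @return An object of class `spot_field`.
#' @export
spot_field <- function(spots_a, spots_b, bounds) {
  spots_a <- tibble::as_tibble(spots_a)
  spots_b <- tibble::as_tibble(spots_b)
  for (nm in c("x_nm", "y_nm")) {
    if (!nm %in% names(spots_a) || !nm %in% names(spots_b)) {
      stop("spot tables need numeric columns x_nm, y_nm", call. = FALSE)
    }
  }
  if (length(bounds) != 4 || bounds[2] <= bounds[1] || bounds[4] <= bounds[3]) {
    stop("bounds must be c(xmin, xmax, ymin, ymax) with positive extent",
         call. = FALSE)
  }
  structure(list(spots_a = spots_a, spots_b = spots_b,
                 bounds = as.numeric(bounds)),
            class = "spot_field")
}

#' @export
print.spot_field <- function(x, ...) {
  cat(sprintf("<spot_field> %d A spots, %d B spots in %g x %g nm\n",
              nrow(x$spots_a), nrow(x$spots_b),
              x$bounds[2] - x$bounds[1], x$bounds[4] - x$bounds[3]))
  invisible(x)
}

#' Directional nearest-neighbor distances (A to B)
#'
#' For every channel-A spot, the Euclidean distance to its nearest channel-B
#' spot. Directional and uncorrected for edge effects: spots near the field
#' border see a censored B neighborhood, which biases long distances upward
#' (bounded via [chance_colocalization()]).
#'
#' @param field A [spot_field()].
#' @param bin_width_nm,max_nm Histogram bin width and upper edge (nm); the
#'   final bin is open-ended so counts always sum to the number of A spots.
#' @return A list of class `nnd_profile`: `distances_nm` (one per A spot, in
#'   A-spot order) and `histogram` (tibble with `lower_nm`, `upper_nm`,
#'   `count`).
#' @export
nearest_neighbor_distances <- function(field, bin_width_nm = 10,
                                       max_nm = 500) {
  stopifnot(inherits(field, "spot_field"))
  na <- nrow(field$spots_a)
  nb <- nrow(field$spots_b)
  if (nb == 0) {
    stop("channel B of the spot field is empty; nearest-neighbor distances ",
         "are undefined", call. = FALSE)
  }
  if (na == 0) {
    d <- numeric(0)
  } else {
    ax <- field$spots_a$x_nm; ay <- field$spots_a$y_nm
    bx <- field$spots_b$x_nm; by <- field$spots_b$y_nm
    # chunked all-pairs minima; exact, memory-bounded
    chunk <- max(1L, floor(4e6 / nb))
    d <- numeric(na)
    i <- 1L
    while (i <= na) {
      j <- min(na, i + chunk - 1L)
      dx <- outer(ax[i:j], bx, "-")
      dy <- outer(ay[i:j], by, "-")
      d[i:j] <- sqrt(.rowMins(dx * dx + dy * dy))
      i <- j + 1L
    }
  }
  breaks <- c(seq(0, max_nm, by = bin_width_nm), Inf)
  cnt <- if (na) {
    as.vector(table(cut(d, breaks = breaks, right = FALSE,
                        include.lowest = TRUE)))
  } else rep(0L, length(breaks) - 1L)
  hist <- tibble::tibble(lower_nm = breaks[-length(breaks)],
                         upper_nm = breaks[-1], count = cnt)
  structure(list(distances_nm = d, histogram = hist), class = "nnd_profile")
}

.rowMins <- function(m) {
  if (is.null(dim(m))) return(min(m))
  do.call(pmin, as.data.frame(m))
}

#' Classify co-expression at an NND threshold
#'
#' A channel-A spot counts as co-expressing when its nearest channel-B
#' neighbor lies at or below `threshold_nm` (ties count as co-expressing).
#' The 95 nm default is the published cutoff separating vesicles bearing both
#' transporters from single-transporter vesicles.
#'
#' @param p An `nnd_profile`.
#' @param threshold_nm Positive distance threshold (nm).
#' @return A list of class `coexpression_result`: `n_below`, `n_above`,
#'   `fraction_below`, `threshold_nm`.
#' @export
classify_coexpression <- function(p, threshold_nm = 95) {
  stopifnot(inherits(p, "nnd_profile"))
  .check_scalar(threshold_nm, "threshold_nm", positive = TRUE)
  n_below <- sum(p$distances_nm <= threshold_nm)
  n <- length(p$distances_nm)
  structure(list(n_below = n_below, n_above = n - n_below,
                 fraction_below = if (n) n_below / n else NA_real_,
                 threshold_nm = threshold_nm),
            class = "coexpression_result")
}

#' Chi-squared comparison of two co-expression classifications
#'
#' Pearson chi-squared on the 2x2 table (below/above threshold x group),
#' 1 df, without continuity correction by default.
#'
#' @param r1,r2 `coexpression_result` objects.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A list with `chi_squared`, `df`, `p_value`.
#' @export
compare_coexpression <- function(r1, r2, correct = FALSE) {
  stopifnot(inherits(r1, "coexpression_result"),
            inherits(r2, "coexpression_result"))
  m <- rbind(c(r1$n_below, r1$n_above), c(r2$n_below, r2$n_above))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-squared undefined: a margin of the 2x2 table is zero",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(chi_squared = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Kolmogorov-Smirnov comparison of two NND distributions
#'
#' Shared implementation with [compare_event_trains()]: two-sided, asymptotic.
#'
#' @param d1,d2 Numeric distance samples.
#' @return A list with `D` and `p_value`.
#' @export
compare_nnd_distributions <- function(d1, d2) {
  compare_event_trains(d1, d2)
}

#' Expected chance co-localization under complete spatial randomness
#'
#' For channel-B density `density_b` (spots/nm^2), the probability that a
#' random point has a B spot within `threshold_nm` is
#' `1 - exp(-density_b * pi * threshold_nm^2)`. Used to calibrate the
#' simulator and to bound the edge-effect / singleton bias of the 95 nm
#' classifier.
#'
#' @param density_b B-spot density (spots per nm^2), >= 0.
#' @param threshold_nm Distance threshold (nm).
#' @return Expected co-localizing fraction in `[0, 1]`.
#' @export
chance_colocalization <- function(density_b, threshold_nm = 95) {
  .check_scalar(density_b, "density_b", nonneg = TRUE)
  .check_scalar(threshold_nm, "threshold_nm", positive = TRUE)
  1 - exp(-density_b * pi * threshold_nm^2)
}
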