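# Delimited-table I/O with schema validation. Conventions: comma-separated
# CSV with "." decimal for tables, tab-separated TSV for spot fields, a JSON
# sidecar for photometry trace metadata.

.read_delim_checked <- function(path, columns, sep = ",", what = "table") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = NA)
  missing_cols <- setdiff(names(columns), names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s %s: missing column(s): %s", what, path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(columns)) {
    if (columns[[nm]] == "numeric" && !is.numeric(df[[nm]])) {
      suppressWarnings(v <- as.numeric(df[[nm]]))
      bad <- which(is.na(v) & !is.na(df[[nm]]) & df[[nm]] != "NA")
      if (length(bad)) {
        stop(sprintf("%s %s: non-numeric value in column `%s`, row(s) %s",
                     what, path, nm,
                     paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      }
      df[[nm]] <- v
    }
  }
  tibble::as_tibble(df)
}

#' Write / read a photometry trace as delimited text with a metadata sidecar
#'
#' The trace file has columns `time_s`, `f465`, `f405`; `<path>.meta.json`
#' stores the sampling rate and per-channel autofluorescence scalars.
#'
#' @param rec A [photometry_recording()].
#' @param path Output CSV path.
#' @return `write_photometry_trace` returns `path` invisibly;
#'   `read_photometry_trace` returns a `photometry_recording`.
#' @export
write_photometry_trace <- function(rec, path) {
  stopifnot(inherits(rec, "photometry_recording"))
  utils::write.csv(data.frame(time_s = rec$time_s, f465 = rec$f_signal,
                              f405 = rec$f_control),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(rate_hz = rec$rate_hz,
         autofluorescence_signal = rec$autofluorescence_signal,
         autofluorescence_control = rec$autofluorescence_control),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_photometry_trace
#' @export
read_photometry_trace <- function(path) {
  df <- .read_delim_checked(path, c(time_s = "numeric", f465 = "numeric",
                                    f405 = "numeric"),
                            what = "photometry trace")
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  photometry_recording(df$time_s, df$f465, df$f405, rate_hz = meta$rate_hz,
                       autofluorescence_signal =
                         meta$autofluorescence_signal %||% 0,
                       autofluorescence_control =
                         meta$autofluorescence_control %||% 0)
}

#' Write / read a two-channel spot field as TSV
#'
#' Columns: `channel` (`"A"`/`"B"`), `x_nm`, `y_nm`, `truth_pair_id` (`NA`
#' when unknown). Field bounds are taken from the data extent on read unless
#' a `<path>.meta.json` sidecar (written alongside) provides them.
#'
#' @param field A [spot_field()].
#' @param path Output TSV path.
#' @return `write_spot_field` returns `path` invisibly; `read_spot_field`
#'   returns a `spot_field`.
#' @export
write_spot_field <- function(field, path) {
  stopifnot(inherits(field, "spot_field"))
  grab <- function(tb, ch) {
    data.frame(channel = rep(ch, nrow(tb)), x_nm = tb$x_nm, y_nm = tb$y_nm,
               truth_pair_id = if ("truth_pair_id" %in% names(tb)) {
                 tb$truth_pair_id
               } else rep(NA_integer_, nrow(tb)))
  }
  utils::write.table(rbind(grab(field$spots_a, "A"), grab(field$spots_b, "B")),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(bounds = field$bounds), paste0(path, ".meta.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_spot_field
#' @export
read_spot_field <- function(path) {
  df <- .read_delim_checked(path, c(channel = "character", x_nm = "numeric",
                                    y_nm = "numeric"),
                            sep = "\t", what = "spot field")
  meta_path <- paste0(path, ".meta.json")
  bounds <- if (file.exists(meta_path)) {
    unlist(jsonlite::read_json(meta_path, simplifyVector = TRUE)$bounds)
  } else {
    c(min(df$x_nm), max(df$x_nm), min(df$y_nm), max(df$y_nm))
  }
  if (!"truth_pair_id" %in% names(df)) df$truth_pair_id <- NA_integer_
  spot_field(df[df$channel == "A", c("x_nm", "y_nm", "truth_pair_id")],
             df[df$channel == "B", c("x_nm", "y_nm", "truth_pair_id")],
             bounds = bounds)
}

#' Read an uptake replicate table (CSV: genotype, condition, value)
#' @param path CSV path.
#' @return Tibble with `genotype`, `condition`, `value`.
#' @export
read_uptake_table <- function(path) {
  .read_delim_checked(path, c(genotype = "character", condition = "character",
                              value = "numeric"), what = "uptake table")
}

#' Read a behavioral score table
#' (CSV: animal, genotype, persistence, motivation, compulsivity)
#' @param path CSV path.
#' @return A score tibble.
#' @export
read_score_table <- function(path) {
  .read_delim_checked(path, c(animal = "character", genotype = "character",
                              persistence = "numeric",
                              motivation = "numeric",
                              compulsivity = "numeric"),
                      what = "score table")
}

#' Write a tibble as CSV (round-trip stable within float text precision)
#' @param tbl Data frame. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE)
  invisible(path)
}
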