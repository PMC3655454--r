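#' Construct a single-channel time series
#'
#' The basic data type of the package: an ordered vector of real samples
#' with optional sampling-rate metadata and a free-text label. Sample
#' indices are 1-based in every user-facing report, matching the usual
#' narration of forecasting protocols ("uses time points 476 to 480 to
#' forecast 481").
#'
#' @param values numeric vector of samples; must be non-empty and finite.
#' @param sampling_rate_hz optional positive sampling rate in Hz (EEG corpus
#'   segments are sampled at 173.61 Hz).
#' @param label free-text identifier, e.g. subject/electrode.
#' @return a numeric vector of class `caar_series` carrying
#'   `sampling_rate_hz` and `label` attributes.
#' @examples
#' x <- caar_series(sin(1:100), sampling_rate_hz = 173.61, label = "demo")
#' x
#' @export
caar_series <- function(values, sampling_rate_hz = NULL, label = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("a caar_series needs at least one sample", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop(sprintf("non-finite sample at position %d", bad), call. = FALSE)
  }
  if (!is.null(sampling_rate_hz)) {
    stopifnot(is.numeric(sampling_rate_hz), length(sampling_rate_hz) == 1L,
              sampling_rate_hz > 0)
    attr(values, "sampling_rate_hz") <- as.numeric(sampling_rate_hz)
  }
  if (!is.null(label)) attr(values, "label") <- as.character(label)[1L]
  class(values) <- c("caar_series", "numeric")
  values
}

#' Coerce to a caar_series
#'
#' @param x numeric vector or `caar_series`.
#' @param ... passed to [caar_series()].
#' @return a `caar_series`.
#' @export
as_caar_series <- function(x, ...) {
  if (inherits(x, "caar_series")) return(x)
  caar_series(x, ...)
}

#' @export
print.caar_series <- function(x, ...) {
  lab <- attr(x, "label")
  sr <- attr(x, "sampling_rate_hz")
  cat(sprintf("<caar_series> %d samples%s%s\n", length(x),
              if (is.null(lab)) "" else paste0(", label '", lab, "'"),
              if (is.null(sr)) "" else sprintf(", %.6g Hz", sr)))
  n <- min(length(x), 8L)
  cat(" head:", paste(signif(unclass(x)[seq_len(n)], 6), collapse = " "),
      if (length(x) > n) "...\n" else "\n")
  invisible(x)
}

#' Read a plain-text signal segment
#'
#' Reads the one-value-per-line segment format in which single-channel EEG
#' corpus files circulate. Blank lines and lines starting with `#`
#' (metadata headers written by this package's own tools) are skipped.
#' Parsing is whitespace- and CRLF-tolerant; values are stored as doubles.
#'
#' @param path path to the segment file.
#' @param sampling_rate_hz optional positive sampling rate to attach.
#' @param label label for the series; defaults to the file stem.
#' @return a [caar_series()].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("1", "2", "3"), f)
#' read_segment(f)
#' @export
read_segment <- function(path, sampling_rate_hz = NULL, label = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read segment file '%s': no such file", path),
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop(sprintf("segment file '%s' contains no samples", path), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(trimws(lines[idx])))
  if (anyNA(vals) || !all(is.finite(vals))) {
    bad <- idx[which(!is.finite(vals))[1L]]
    stop(sprintf("segment file '%s': line %d is not a finite number (\"%s\")",
                 path, bad, trimws(lines[bad])), call. = FALSE)
  }
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  caar_series(vals, sampling_rate_hz = sampling_rate_hz, label = label)
}

#' Write a signal segment
#'
#' Writes one value per line with full double precision (17 significant
#' digits), so `read_segment(write_segment(x))` returns the values exactly.
#' An optional header of `# key=value` comment lines may be prepended.
#'
#' @param x a [caar_series()] or numeric vector.
#' @param path output path.
#' @param header optional character vector of comment lines (written with a
#'   leading `# `).
#' @return `path`, invisibly.
#' @export
write_segment <- function(x, path, header = NULL) {
  x <- as_caar_series(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("%.17g", unclass(x)), con)
  invisible(path)
}

#' Read one column of a CSV file as a time series
#'
#' @param path path to a CSV file with a header row.
#' @param column column name, or 1-based column index.
#' @param sampling_rate_hz,label as in [caar_series()].
#' @return a [caar_series()] with the column values in row order.
#' @export
read_csv_column <- function(path, column, sampling_rate_hz = NULL,
                            label = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read CSV file '%s': no such file", path),
         call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (is.numeric(column)) {
    if (column < 1 || column > ncol(df)) {
      stop(sprintf("column index %d out of range; file has %d columns (%s)",
                   column, ncol(df), paste(names(df), collapse = ", ")),
           call. = FALSE)
    }
    col <- df[[column]]
    cname <- names(df)[column]
  } else {
    if (!column %in% names(df)) {
      stop(sprintf("no column '%s'; available columns: %s", column,
                   paste(names(df), collapse = ", ")), call. = FALSE)
    }
    col <- df[[column]]
    cname <- column
  }
  col <- col[!is.na(col)]
  if (length(col) == 0L) {
    stop(sprintf("column '%s' of '%s' holds no values", cname, path),
         call. = FALSE)
  }
  if (is.null(label)) label <- cname
  caar_series(as.numeric(col), sampling_rate_hz = sampling_rate_hz,
              label = label)
}

#' Write a forecast result as CSV
#'
#' One row per forecast step with columns `step_index` (1-based absolute
#' sample index), `predicted`, `actual` (blank when unknown) and `error`
#' (actual minus predicted, blank when the actual is unknown). The
#' `predicted` column round-trips through [read_csv_column()].
#'
#' @param result a [forecast_result()].
#' @param path output path.
#' @param header optional comment lines written with a leading `# ` before
#'   the CSV header.
#' @return `path`, invisibly.
#' @export
write_forecast <- function(result, path, header = NULL) {
  stopifnot(inherits(result, "caar_forecast_result"))
  n <- result$horizon
  df <- data.frame(
    step_index = result$origin + seq_len(n) - 1L,
    predicted = sprintf("%.17g", result$predicted),
    actual = if (is.null(result$actual)) rep("", n)
             else sprintf("%.17g", result$actual),
    error = if (is.null(result$errors)) rep("", n)
            else sprintf("%.17g", result$errors),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
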