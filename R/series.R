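#' Fixed-rate time series
#'
#' A `ts_series` is the elementary signal container of the package: an ordered
#' vector of numeric samples recorded at a fixed sampling period. Sample
#' indices are 0-based throughout the package and intervals are half-open
#' `[start, end)`, so the sample with index `i` lives at time
#' `i * sampling_period_ms` and corresponds to `values[i + 1]` in R.
#'
#' @param values numeric vector of samples, in recording order.
#' @param sampling_period_ms sampling period in milliseconds (default 10, i.e.
#'   100 Hz).
#' @param series_id identifier carried through annotations and reports.
#' @param domain_tag one of `"eeg"`, `"stabilometry"`, `"generic"`; selects
#'   domain defaults elsewhere (e.g. feature weights).
#'
#' @return an object of class `ts_series`.
#' @examples
#' s <- ts_series(sin(seq(0, 2 * pi, length.out = 100)), sampling_period_ms = 10)
#' n_samples(s)
#' @export
ts_series <- function(values, sampling_period_ms = 10, series_id = "series",
                      domain_tag = c("generic", "eeg", "stabilometry")) {
  domain_tag <- match.arg(domain_tag)
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("empty series: a ts_series needs at least one sample", call. = FALSE)
  }
  if (!is.numeric(sampling_period_ms) || length(sampling_period_ms) != 1L ||
      !is.finite(sampling_period_ms) || sampling_period_ms <= 0) {
    stop("sampling_period_ms must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      series_id = as.character(series_id),
      domain_tag = domain_tag,
      sampling_period_ms = sampling_period_ms,
      values = values
    ),
    class = "ts_series"
  )
}

#' @export
print.ts_series <- function(x, ...) {
  cat(sprintf(
    "<ts_series '%s'> %d samples @ %g ms (%s), %.1f s\n",
    x$series_id, length(x$values), x$sampling_period_ms, x$domain_tag,
    length(x$values) * x$sampling_period_ms / 1000
  ))
  invisible(x)
}

#' Number of samples in a series
#' @param series a [ts_series()].
#' @return integer sample count.
#' @export
n_samples <- function(series) {
  stopifnot(inherits(series, "ts_series"))
  length(series$values)
}

#' Tidy a series into a sample table
#'
#' @param x a [ts_series()].
#' @param ... unused.
#' @return a tibble with columns `index` (0-based), `time_ms` and `value`.
#' @export
tidy.ts_series <- function(x, ...) {
  idx <- seq_along(x$values) - 1L
  tibble::tibble(
    index = idx,
    time_ms = idx * x$sampling_period_ms,
    value = x$values
  )
}

# Shortest round-trippable decimal text for doubles, so write -> read is exact.
format_sample <- function(x) {
  vapply(x, function(v) {
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Read a one-column CSV of samples
#'
#' The file holds one numeric sample per line, oldest first. A single
#' non-numeric first line is accepted as a header; any other non-numeric line
#' is an error.
#'
#' @param path file to read.
#' @inheritParams ts_series
#' @return a [ts_series()].
#' @seealso [write_series_csv()]
#' @export
read_series_csv <- function(path, sampling_period_ms = 10, series_id = NULL,
                            domain_tag = "generic") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty series: ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1]) && !is.na(suppressWarnings(as.numeric(lines[2])))) {
    # header line
    lines <- lines[-1]
    vals <- vals[-1]
  }
  if (length(vals) == 0L) stop("empty series: ", path, call. = FALSE)
  bad <- which(is.na(vals) & !grepl("^(na|nan)$", tolower(lines)))
  if (length(bad) > 0L) {
    stop(sprintf("unparseable sample on line %d: '%s'", bad[1], lines[bad[1]]),
         call. = FALSE)
  }
  if (is.null(series_id)) {
    series_id <- sub("\\.[^.]*$", "", basename(path))
  }
  ts_series(vals, sampling_period_ms, series_id, domain_tag)
}

#' Write a series as a one-column CSV
#'
#' Samples are written in shortest round-trippable decimal form, so
#' `read_series_csv()` recovers the exact doubles.
#'
#' @param series a [ts_series()].
#' @param path output file.
#' @param header write a `value` header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path, header = TRUE) {
  stopifnot(inherits(series, "ts_series"))
  lines <- format_sample(series$values)
  if (header) lines <- c("value", lines)
  writeLines(lines, path)
  invisible(path)
}
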