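#' Trim noisy edges from a series
#'
#' Recordings often carry noise or missing data at the very start and end
#' (electrode settling, the subject stepping on/off the platform). Those
#' fragments are removed wholesale before any event analysis; this is the
#' manual edge-elimination step of the cleaning policy.
#'
#' @param series a [ts_series()].
#' @param start_index,end_index 0-based half-open range `[start_index,
#'   end_index)` of samples to keep.
#' @return the sub-series as a [ts_series()].
#' @export
trim_edges <- function(series, start_index, end_index) {
  stopifnot(inherits(series, "ts_series"))
  n <- n_samples(series)
  if (start_index < 0 || end_index > n || start_index >= end_index) {
    stop(sprintf(
      "invalid trim range [%s, %s) for a series of %d samples",
      start_index, end_index, n
    ), call. = FALSE)
  }
  out <- series
  out$values <- series$values[(start_index + 1L):end_index]
  out
}

#' Screen a series for missing and inconsistent values
#'
#' Applies the automatic cleaning policy: samples equal to the missing-value
#' sentinel (for pressure platforms, a sensor reading of exactly 0) or falling
#' outside the domain's plausible range are dropped, and the series is kept
#' for downstream modelling only if at least `validity_threshold` of the
#' original samples survive (default 70%, inclusive). Dropped interior values
#' are removed, not interpolated, so downstream event timestamps live on the
#' cleaned index space.
#'
#' @param series a [ts_series()].
#' @param missing_sentinel value marking a missing sample, or `NULL` if the
#'   domain has none. Non-finite samples are always treated as missing.
#' @param valid_range length-2 numeric `c(lo, hi)` of plausible values, or
#'   `NULL` to skip range screening.
#' @param validity_threshold minimum retained fraction for the series to count
#'   as valid; the comparison is inclusive (`>=`).
#' @return a `clean_result`: list with `series` (retained values; zero-length
#'   values if everything was dropped), `retained_fraction`, `valid`, and
#'   `dropped_indices` (0-based indices into the original series).
#' @examples
#' s <- ts_series(c(1, 0, 2, 0, 3, 4, 5, 0, 6, 7))
#' clean_series(s, missing_sentinel = 0)$retained_fraction # 0.7 -> valid
#' @export
clean_series <- function(series, missing_sentinel = NULL, valid_range = NULL,
                         validity_threshold = 0.70) {
  stopifnot(inherits(series, "ts_series"))
  if (!is.numeric(validity_threshold) || validity_threshold <= 0 ||
      validity_threshold > 1) {
    stop("validity_threshold must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(valid_range)) {
    if (length(valid_range) != 2L || valid_range[1] >= valid_range[2]) {
      stop("valid_range must be c(lo, hi) with lo < hi", call. = FALSE)
    }
  }
  v <- series$values
  drop <- !is.finite(v)
  if (!is.null(missing_sentinel)) drop <- drop | v == missing_sentinel
  if (!is.null(valid_range)) {
    drop <- drop | (is.finite(v) & (v < valid_range[1] | v > valid_range[2]))
  }
  retained <- v[!drop]
  frac <- length(retained) / length(v)
  out <- series
  out$values <- retained
  structure(
    list(
      series = out,
      retained_fraction = frac,
      valid = frac >= validity_threshold,
      dropped_indices = which(drop) - 1L
    ),
    class = "clean_result"
  )
}

#' @export
print.clean_result <- function(x, ...) {
  cat(sprintf(
    "<clean_result> retained %d/%d samples (%.1f%%) -> %s\n",
    length(x$series$values),
    length(x$series$values) + length(x$dropped_indices),
    100 * x$retained_fraction,
    if (x$valid) "valid" else "EXCLUDED"
  ))
  invisible(x)
}

#' @rdname clean_series
#' @param x a `clean_result`.
#' @param ... unused.
#' @return for `glance()`: a one-row tibble with `retained_fraction`, `valid`
#'   and `n_dropped`.
#' @export
glance.clean_result <- function(x, ...) {
  tibble::tibble(
    retained_fraction = x$retained_fraction,
    valid = x$valid,
    n_dropped = length(x$dropped_indices)
  )
}
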