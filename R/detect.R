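#' Construct an event table
#'
#' Events are plain tibbles throughout the package, one row per event, with
#' 0-based half-open sample intervals. `event_table()` builds and validates
#' one; `empty_events()` returns the zero-row prototype.
#'
#' @param event_type character vector of type names.
#' @param start,end 0-based half-open sample indices.
#' @param magnitude event magnitude: peak amplitude for waves, mean
#'   suprathreshold intensity for falls.
#' @param anchor 0-based index of the extremum within each event.
#' @param sampling_period_ms sampling period used to derive `duration_ms` and
#'   `anchor_ms`.
#' @return a tibble with columns `event_type`, `start`, `end`, `duration_ms`,
#'   `magnitude`, `anchor`, `anchor_ms`, sorted by `start` then `event_type`.
#' @export
event_table <- function(event_type = character(), start = integer(),
                        end = integer(), magnitude = numeric(),
                        anchor = integer(), sampling_period_ms = 10) {
  start <- as.integer(start); end <- as.integer(end); anchor <- as.integer(anchor)
  if (any(start >= end)) stop("event intervals must satisfy start < end", call. = FALSE)
  if (any(anchor < start | anchor >= end)) {
    stop("event anchor must lie inside [start, end)", call. = FALSE)
  }
  tibble::tibble(
    event_type = as.character(event_type),
    start = start,
    end = end,
    duration_ms = (end - start) * sampling_period_ms,
    magnitude = as.numeric(magnitude),
    anchor = anchor,
    anchor_ms = anchor * sampling_period_ms
  ) |>
    dplyr::arrange(.data$start, .data$event_type)
}

#' @rdname event_table
#' @export
empty_events <- function() {
  tibble::tibble(
    event_type = character(), start = integer(), end = integer(),
    duration_ms = numeric(), magnitude = numeric(), anchor = integer(),
    anchor_ms = numeric()
  )
}

#' An annotated series: signal plus its detected (or planted) events
#'
#' @param series a [ts_series()].
#' @param events an event table (see [event_table()]).
#' @return an object of class `annotated_series`.
#' @export
annotated_series <- function(series, events = empty_events()) {
  stopifnot(inherits(series, "ts_series"), is.data.frame(events))
  if (nrow(events) > 0) {
    if (any(events$end > n_samples(series)) || any(events$start < 0)) {
      stop("event indices fall outside the series", call. = FALSE)
    }
    events <- dplyr::arrange(events, .data$start, .data$event_type)
    # non-overlap within one event type
    by_type <- split(events, events$event_type)
    for (tt in by_type) {
      if (nrow(tt) > 1 && any(tt$start[-1] < tt$end[-nrow(tt)])) {
        stop("events of one type must not overlap", call. = FALSE)
      }
    }
  }
  structure(list(series = series, events = events), class = "annotated_series")
}

#' @export
print.annotated_series <- function(x, ...) {
  print(x$series)
  cnt <- table(x$events$event_type)
  if (length(cnt) == 0) {
    cat("  no events\n")
  } else {
    cat("  events:", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.annotated_series <- function(x, ...) x$events

#' Segment a series into waves
#'
#' The mean-centred signal is cut at its zero crossings; each maximal run of
#' one sign is a wave carrying its extremum and period. Samples within
#' numerical tolerance of the centred mean are treated as boundary points and
#' attached to the following wave (trailing ones to the preceding wave).
#' A constant series has no waves.
#'
#' @param series a cleaned [ts_series()].
#' @return a tibble with one row per wave: `start`, `end` (0-based,
#'   half-open), `sign`, `peak_index`, `peak_amplitude` (absolute deviation
#'   from the series mean), `period_ms`.
#' @export
segment_waves <- function(series) {
  stopifnot(inherits(series, "ts_series"))
  x <- series$values
  n <- length(x)
  ctr <- x - mean(x)
  amax <- max(abs(ctr))
  proto <- tibble::tibble(
    start = integer(), end = integer(), sign = integer(),
    peak_index = integer(), peak_amplitude = numeric(), period_ms = numeric()
  )
  if (amax == 0) return(proto)
  tol <- 1e-9 * amax
  s <- as.integer(sign(ctr))
  s[abs(ctr) <= tol] <- 0L
  if (all(s == 0L)) return(proto)
  # boundary samples adopt the sign of the next wave; trailing ones the previous
  nxt <- 0L
  for (i in n:1) if (s[i] == 0L) s[i] <- nxt else nxt <- s[i]
  prv <- 0L
  for (i in 1:n) if (s[i] == 0L) s[i] <- prv else prv <- s[i]
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  peak_index <- integer(length(ends))
  peak_amp <- numeric(length(ends))
  for (w in seq_along(ends)) {
    idx <- (starts[w] + 1L):ends[w]
    p <- idx[which.max(abs(ctr[idx]))]
    peak_index[w] <- p - 1L
    peak_amp[w] <- abs(ctr[p])
  }
  tibble::tibble(
    start = starts, end = as.integer(ends), sign = r$values,
    peak_index = peak_index, peak_amplitude = peak_amp,
    period_ms = (ends - starts) * series$sampling_period_ms
  )
}

baseline_scale <- function(series, stat = c("mad", "std")) {
  stat <- match.arg(stat)
  ctr <- series$values - mean(series$values)
  if (stat == "mad") stats::mad(ctr) else stats::sd(ctr)
}

#' Detect events in a series
#'
#' Applies each event definition to a cleaned series and returns the series
#' annotated with every region that satisfies a definition. Relative-amplitude
#' definitions are evaluated on the waves of [segment_waves()]; absolute
#' thresholds on maximal suprathreshold runs. Detection is deterministic.
#'
#' @param series a cleaned [ts_series()].
#' @param definitions a list of [event_definition()]s (e.g. from
#'   [parse_definitions()], [eeg_definitions()], [fall_definition()]).
#' @return an [annotated_series()] whose event table is sorted by start.
#' @examples
#' x <- rep(0, 300); x[101:150] <- 120
#' s <- ts_series(x, sampling_period_ms = 10, domain_tag = "stabilometry")
#' tidy(detect_events(s, fall_definition(threshold = 50)))
#' @export
detect_events <- function(series, definitions) {
  stopifnot(inherits(series, "ts_series"))
  if (inherits(definitions, "event_definition")) definitions <- list(definitions)
  if (length(definitions) == 0) stop("definitions must be non-empty", call. = FALSE)
  types <- vapply(definitions, function(d) d$event_type, character(1))
  if (anyDuplicated(types)) {
    stop("event types must be unique within a rule set", call. = FALSE)
  }
  waves <- NULL
  out <- list()
  for (def in definitions) {
    if (!inherits(def, "event_definition")) stop("not an event_definition", call. = FALSE)
    if (def$trigger == "relative_amplitude") {
      if (is.null(waves)) waves <- segment_waves(series)
      out[[def$event_type]] <- detect_relative(series, waves, def)
    } else {
      out[[def$event_type]] <- detect_threshold(series, def)
    }
  }
  events <- dplyr::bind_rows(out)
  if (nrow(events) > 0) events <- dplyr::arrange(events, .data$start, .data$event_type)
  annotated_series(series, events)
}

detect_relative <- function(series, waves, def) {
  if (nrow(waves) == 0) return(empty_events())
  scale <- baseline_scale(series, def$baseline_stat)
  if (scale == 0) return(empty_events())
  ok <- waves$peak_amplitude > def$k * scale &
    waves$period_ms >= def$min_period_ms &
    waves$period_ms <= def$max_period_ms
  if (def$polarity_change_required) {
    nw <- nrow(waves)
    flank_amp <- def$polarity_factor * scale
    prev_ok <- c(FALSE, waves$peak_amplitude[-nw] > flank_amp)
    next_ok <- c(waves$peak_amplitude[-1] > flank_amp, FALSE)
    # consecutive waves have opposite sign by construction
    ok <- ok & (prev_ok | next_ok)
  }
  w <- waves[ok, , drop = FALSE]
  if (nrow(w) == 0) return(empty_events())
  event_table(
    event_type = def$event_type, start = w$start, end = w$end,
    magnitude = w$peak_amplitude, anchor = w$peak_index,
    sampling_period_ms = series$sampling_period_ms
  )
}

detect_threshold <- function(series, def) {
  x <- series$values
  sp <- series$sampling_period_ms
  above <- x > def$threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0) return(empty_events())
  if (def$merge_gap_ms > 0 && nrow(runs) > 1) {
    gap_samples <- def$merge_gap_ms / sp
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] <= gap_samples) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  keep <- (runs$end - runs$start) * sp >= def$min_duration_ms
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_events())
  mag <- numeric(nrow(runs)); anc <- integer(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    idx <- (runs$start[i] + 1L):runs$end[i]
    vals <- x[idx]
    supra <- vals[vals > def$threshold]
    mag[i] <- mean(supra)
    anc[i] <- idx[which.max(vals)] - 1L
  }
  event_table(
    event_type = def$event_type, start = runs$start, end = runs$end,
    magnitude = mag, anchor = anc, sampling_period_ms = sp
  )
}

#' Re-check detected events against their definitions
#'
#' Independent post-hoc verifier: for every event in an annotated series,
#' re-evaluates the defining predicates (period/duration bounds, prominence
#' over the recomputed baseline scale, suprathreshold values, the duration
#' arithmetic and anchor containment) without reusing the detector's
#' intermediate state.
#'
#' @param annotated an [annotated_series()].
#' @param definitions the definitions the events were detected with.
#' @return a logical vector, one entry per event row.
#' @export
check_events <- function(annotated, definitions) {
  stopifnot(inherits(annotated, "annotated_series"))
  if (inherits(definitions, "event_definition")) definitions <- list(definitions)
  defs <- stats::setNames(definitions,
                          vapply(definitions, function(d) d$event_type, character(1)))
  series <- annotated$series
  ev <- annotated$events
  sp <- series$sampling_period_ms
  ctr <- series$values - mean(series$values)
  vapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    def <- defs[[e$event_type]]
    if (is.null(def)) return(FALSE)
    dur_ok <- isTRUE(all.equal(e$duration_ms, (e$end - e$start) * sp))
    anchor_ok <- e$start <= e$anchor && e$anchor < e$end
    if (!dur_ok || !anchor_ok) return(FALSE)
    if (def$trigger == "relative_amplitude") {
      scale <- baseline_scale(series, def$baseline_stat)
      seg <- ctr[(e$start + 1L):e$end]
      e$magnitude > def$k * scale &&
        abs(abs(ctr[e$anchor + 1L]) - e$magnitude) <= 1e-9 * max(1, e$magnitude) &&
        e$duration_ms >= def$min_period_ms && e$duration_ms <= def$max_period_ms &&
        max(abs(seg)) <= e$magnitude + 1e-9
    } else {
      vals <- series$values[(e$start + 1L):e$end]
      supra <- vals[vals > def$threshold]
      length(supra) > 0 &&
        vals[1] > def$threshold && vals[length(vals)] > def$threshold &&
        e$duration_ms >= def$min_duration_ms &&
        isTRUE(all.equal(e$magnitude, mean(supra)))
    }
  }, logical(1))
}

#' Write and read event annotations
#'
#' Annotations are a flat comma-delimited table with columns
#' `type,start,end,duration_ms,magnitude,anchor` (plus `anchor_ms` on
#' read-back, derived from `sampling_period_ms`). Numeric fields use shortest
#' round-trippable decimals, so a write/read round trip is exact.
#'
#' @param annotated an [annotated_series()] (or a bare event table).
#' @param path output file.
#' @return `path` invisibly for the writer; an event table for the reader.
#' @export
write_annotations <- function(annotated, path) {
  ev <- if (inherits(annotated, "annotated_series")) annotated$events else annotated
  lines <- c(
    "type,start,end,duration_ms,magnitude,anchor",
    sprintf("%s,%d,%d,%s,%s,%d",
            ev$event_type, ev$start, ev$end,
            format_sample(ev$duration_ms), format_sample(ev$magnitude), ev$anchor)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotations
#' @param sampling_period_ms sampling period used to reconstruct `anchor_ms`.
#' @export
read_annotations <- function(path, sampling_period_ms = 10) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("type", "start", "end", "duration_ms", "magnitude", "anchor")
  if (!all(need %in% names(df))) {
    stop("annotation file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) return(empty_events())
  tibble::tibble(
    event_type = as.character(df$type),
    start = as.integer(df$start),
    end = as.integer(df$end),
    duration_ms = as.numeric(df$duration_ms),
    magnitude = as.numeric(df$magnitude),
    anchor = as.integer(df$anchor),
    anchor_ms = as.integer(df$anchor) * sampling_period_ms
  ) |>
    dplyr::arrange(.data$start, .data$event_type)
}
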