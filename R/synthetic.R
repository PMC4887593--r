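#' Specification of a synthetic subject class
#'
#' Describes the per-class event statistics a synthetic cohort should
#' reproduce: how many events a series carries on average (Poisson), how
#' long they last (lognormal, keeping durations positive), how large they
#' are (normal), and the baseline noise they sit in. Event waveforms are
#' stylised: EEG-like paroxysms are single half-sine deflections (with an
#' opposite-polarity flank for spicules), falls are suprathreshold plateaus.
#'
#' Standard deviations default to 20% of the mean (published cohort tables
#' report means only).
#'
#' @param label class label.
#' @param event_type planted event type name.
#' @param shape `"half_sine"` (EEG-like deflection) or `"plateau"`
#'   (pressure-like excursion).
#' @param n_events_mean Poisson mean of events per series.
#' @param duration_mean_ms,duration_sd_ms lognormal duration moments (ms).
#' @param magnitude_mean,magnitude_sd normal magnitude moments (amplitude
#'   for deflections, plateau intensity for falls).
#' @param noise_sd baseline Gaussian noise standard deviation.
#' @param n_samples series length in samples.
#' @param sampling_period_ms sampling period (default 10 ms).
#' @param domain_tag domain tag for the generated series.
#' @param polarity `"alternating"` (random sign per event, EEG) or
#'   `"positive"` (pressure).
#' @param spicule_fraction fraction of half-sine events planted with an
#'   opposite-polarity flank (default 0).
#' @return an object of class `class_spec`.
#' @export
class_spec <- function(label, event_type = "paroxysm",
                       shape = c("half_sine", "plateau"),
                       n_events_mean,
                       duration_mean_ms, duration_sd_ms = 0.2 * duration_mean_ms,
                       magnitude_mean, magnitude_sd = 0.2 * magnitude_mean,
                       noise_sd = 10,
                       n_samples = 1000,
                       sampling_period_ms = 10,
                       domain_tag = c("generic", "eeg", "stabilometry"),
                       polarity = c("alternating", "positive"),
                       spicule_fraction = 0) {
  shape <- match.arg(shape)
  domain_tag <- match.arg(domain_tag)
  polarity <- match.arg(polarity)
  stopifnot(
    n_events_mean >= 0, duration_mean_ms > 0, duration_sd_ms > 0,
    magnitude_mean > 0, magnitude_sd > 0, noise_sd > 0, n_samples >= 1,
    sampling_period_ms > 0, spicule_fraction >= 0, spicule_fraction <= 1
  )
  if (n_samples * sampling_period_ms < 4 * duration_mean_ms) {
    stop("series too short for the requested event durations", call. = FALSE)
  }
  structure(
    list(
      label = label, event_type = event_type, shape = shape,
      n_events_mean = n_events_mean,
      duration_mean_ms = duration_mean_ms, duration_sd_ms = duration_sd_ms,
      magnitude_mean = magnitude_mean, magnitude_sd = magnitude_sd,
      noise_sd = noise_sd, n_samples = as.integer(n_samples),
      sampling_period_ms = sampling_period_ms, domain_tag = domain_tag,
      polarity = polarity, spicule_fraction = spicule_fraction
    ),
    class = "class_spec"
  )
}

#' @export
print.class_spec <- function(x, ...) {
  cat(sprintf(
    "<class_spec '%s'> %s (%s): %.2f events/series, duration %g±%g ms, magnitude %g±%g, noise sd %g, %d samples @ %g ms\n",
    x$label, x$event_type, x$shape, x$n_events_mean,
    x$duration_mean_ms, x$duration_sd_ms, x$magnitude_mean, x$magnitude_sd,
    x$noise_sd, x$n_samples, x$sampling_period_ms
  ))
  invisible(x)
}

#' Built-in class specifications for the two study domains
#'
#' `eeg_class_specs()` mirrors the per-class EEG event statistics (epileptic:
#' 9.47 events/series, 195 ms, amplitude 78; healthy: 5.49, 56 ms, 54) on
#' 10-second series; `stabilometry_class_specs()` mirrors the unilateral-
#' stance cohorts (basketball: 3.37 falls/series, 754 ms, intensity 107;
#' skating: 1.45, 346 ms, 83) on 30-second series.
#'
#' @return a named list of [class_spec()]s.
#' @export
eeg_class_specs <- function() {
  list(
    epileptic = class_spec("epileptic", "paroxysm", "half_sine",
                           n_events_mean = 9.47,
                           duration_mean_ms = 195, magnitude_mean = 78,
                           noise_sd = 10, n_samples = 1000,
                           domain_tag = "eeg", polarity = "alternating"),
    healthy = class_spec("healthy", "paroxysm", "half_sine",
                         n_events_mean = 5.49,
                         duration_mean_ms = 56, magnitude_mean = 54,
                         noise_sd = 10, n_samples = 1000,
                         domain_tag = "eeg", polarity = "alternating")
  )
}

#' @rdname eeg_class_specs
#' @export
stabilometry_class_specs <- function() {
  list(
    basketball = class_spec("basketball", "fall", "plateau",
                            n_events_mean = 3.37,
                            duration_mean_ms = 754, magnitude_mean = 107,
                            noise_sd = 5, n_samples = 3000,
                            domain_tag = "stabilometry", polarity = "positive"),
    skating = class_spec("skating", "fall", "plateau",
                         n_events_mean = 1.45,
                         duration_mean_ms = 346, magnitude_mean = 83,
                         noise_sd = 5, n_samples = 3000,
                         domain_tag = "stabilometry", polarity = "positive")
  )
}

lognormal_pars <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one synthetic series with planted events
#'
#' Draws the event count, durations, magnitudes and non-overlapping anchor
#' positions from the class specification, plants the stylised waveforms in
#' Gaussian baseline noise, and records every planted event as exact
#' ground truth. Deterministic given `seed`.
#'
#' @param spec a [class_spec()].
#' @param seed RNG seed (optional; when `NULL` the current RNG stream is
#'   used).
#' @param series_id identifier for the generated series.
#' @return an [annotated_series()] whose event table is the ground truth.
#' @export
generate_series <- function(spec, seed = NULL, series_id = spec$label) {
  stopifnot(inherits(spec, "class_spec"))
  gen <- function() generate_series_impl(spec, series_id)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

generate_series_impl <- function(spec, series_id) {
  n <- spec$n_samples
  sp <- spec$sampling_period_ms
  x <- stats::rnorm(n, 0, spec$noise_sd)
  n_ev <- stats::rpois(1, spec$n_events_mean)
  truth <- empty_events()
  if (n_ev > 0) {
    lp <- lognormal_pars(spec$duration_mean_ms, spec$duration_sd_ms)
    dur_ms <- stats::rlnorm(n_ev, lp$meanlog, lp$sdlog)
    len <- pmax(2L, pmin(as.integer(round(dur_ms / sp)), n %/% 3))
    mag <- abs(stats::rnorm(n_ev, spec$magnitude_mean, spec$magnitude_sd))
    sign_ev <- if (spec$polarity == "alternating") {
      sample(c(-1, 1), n_ev, replace = TRUE)
    } else rep(1, n_ev)
    spic <- stats::runif(n_ev) < spec$spicule_fraction
    margin <- 3L  # noise gap between events so waves stay separable
    occupied <- rep(FALSE, n)
    starts <- integer(n_ev)
    for (i in seq_len(n_ev)) {
      flank <- if (spic[i]) max(2L, len[i] %/% 3L) else 0L
      need <- len[i] + flank
      placed <- FALSE
      for (try in 1:500) {
        s0 <- sample.int(n - need - 2L * margin, 1) + margin  # 0-based start
        span <- (s0 - margin + 1L):min(n, s0 + need + margin)
        if (!any(occupied[span])) {
          occupied[span] <- TRUE
          starts[i] <- s0
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", n_ev, " non-overlapping events in ", n,
             " samples after 500 retries", call. = FALSE)
      }
      idx <- (s0 + 1L):(s0 + len[i])
      if (spec$shape == "half_sine") {
        wave <- sin(pi * (seq_len(len[i]) - 0.5) / len[i])
        x[idx] <- x[idx] + sign_ev[i] * mag[i] * wave
        if (spic[i]) {
          fidx <- (s0 + len[i] + 1L):(s0 + len[i] + flank)
          fwave <- sin(pi * (seq_len(flank) - 0.5) / flank)
          x[fidx] <- x[fidx] - sign_ev[i] * 0.8 * mag[i] * fwave
        }
      } else {
        x[idx] <- x[idx] + mag[i]
      }
    }
    anchors <- starts + (len - 1L) %/% 2L
    truth <- event_table(
      event_type = spec$event_type, start = starts, end = starts + len,
      magnitude = mag, anchor = anchors, sampling_period_ms = sp
    )
  }
  annotated_series(
    ts_series(x, sp, series_id, spec$domain_tag),
    truth
  )
}

#' Generate a labelled synthetic cohort
#'
#' Builds `n_per_class` subjects per class from the given specifications,
#' optionally injecting outlier subjects whose duration and magnitude means
#' are shifted by `outlier_shift_sd` generator standard deviations (with an
#' independent random sign per feature, so anomalies can point either way).
#' Each subject is a one-series [subject_record()]
#' (register > measurement > condition > series) carrying its ground-truth
#' events on the series leaf; the manifest lists every subject with its true
#' outlier status.
#'
#' @param specs named list of [class_spec()]s.
#' @param n_per_class subjects per class (>= 2).
#' @param outlier_fraction fraction of each class planted as outliers, in
#'   \[0, 0.5).
#' @param outlier_shift_sd shift applied to outlier feature means, in
#'   generator-sd units (default 5).
#' @param seed RNG seed; the whole cohort is deterministic given the seed.
#' @return an object of class `synthetic_cohort`: `subjects` (list of
#'   subject records with ground-truth annotations), `manifest` (tibble
#'   `subject_id`, `class_label`, `is_outlier`), `specs`, `seed`.
#' @export
generate_cohort <- function(specs, n_per_class, outlier_fraction = 0,
                            outlier_shift_sd = 5, seed = NULL) {
  if (n_per_class < 2) stop("n_per_class must be at least 2", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    stop("outlier_fraction must be in [0, 0.5)", call. = FALSE)
  }
  gen <- function() generate_cohort_impl(specs, n_per_class, outlier_fraction,
                                         outlier_shift_sd)
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out$seed <- seed
  out
}

generate_cohort_impl <- function(specs, n_per_class, outlier_fraction,
                                 outlier_shift_sd) {
  subjects <- list()
  manifest <- list()
  for (spec in specs) {
    n_out <- as.integer(round(outlier_fraction * n_per_class))
    out_idx <- if (n_out > 0) sample.int(n_per_class, n_out) else integer()
    for (i in seq_len(n_per_class)) {
      sid <- sprintf("%s_%02d", spec$label, i)
      is_out <- i %in% out_idx
      sp_i <- spec
      if (is_out) {
        sp_i$duration_mean_ms <- max(
          spec$sampling_period_ms * 2,
          spec$duration_mean_ms + sample(c(-1, 1), 1) * outlier_shift_sd * spec$duration_sd_ms
        )
        sp_i$magnitude_mean <- max(
          spec$noise_sd,
          spec$magnitude_mean + sample(c(-1, 1), 1) * outlier_shift_sd * spec$magnitude_sd
        )
      }
      ann <- generate_series_impl(sp_i, paste0(sid, "_s1"))
      subj <- subject_record(
        sid,
        list(measurement_node(spec$domain_tag, list(
          condition_node("baseline", list(series_leaf(ann$series, ann$events)))
        ))),
        class_label = spec$label
      )
      subjects[[sid]] <- subj
      manifest[[sid]] <- tibble::tibble(
        subject_id = sid, class_label = spec$label, is_outlier = is_out
      )
    }
  }
  structure(
    list(subjects = unname(subjects), manifest = dplyr::bind_rows(manifest),
         specs = specs, seed = NULL),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d classes, %d planted outliers%s\n",
              nrow(x$manifest), length(unique(x$manifest$class_label)),
              sum(x$manifest$is_outlier),
              if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)))
  invisible(x)
}

#' @export
tidy.synthetic_cohort <- function(x, ...) x$manifest

#' Re-annotate a cohort's subjects by detection
#'
#' Replaces each subject's ground-truth annotations with events detected by
#' the given definitions, yielding the cohort as the pipeline would actually
#' see it.
#'
#' @param cohort a [generate_cohort()] result.
#' @param definitions event definitions for [detect_events()].
#' @return the list of re-annotated subjects.
#' @export
annotate_cohort <- function(cohort, definitions) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  lapply(cohort$subjects, annotate_subject, definitions = definitions)
}
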