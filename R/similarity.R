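#' Feature scaling for event comparison
#'
#' Event similarity compares three features — duration, magnitude and anchor
#' time — each normalised by a range and combined by weights. Ranges put the
#' features on a common \[0, 1\] footing; weights express how much each
#' feature matters in the domain. For posturography the anchor (when a fall
#' happened) is usually irrelevant, so its weight defaults to zero there;
#' for EEG all three features weigh equally.
#'
#' @param duration_range_ms,magnitude_range,anchor_range_ms positive
#'   normalisation ranges; feature differences at or beyond the range score 0.
#' @param weights numeric length-3 vector of non-negative weights for
#'   (duration, magnitude, anchor); rescaled to sum to 1.
#' @return an object of class `feature_scaling`.
#' @seealso [scaling_from_events()]
#' @export
feature_scaling <- function(duration_range_ms, magnitude_range, anchor_range_ms,
                            weights = c(1, 1, 1)) {
  ranges <- c(duration_ms = duration_range_ms, magnitude = magnitude_range,
              anchor_ms = anchor_range_ms)
  if (any(!is.finite(ranges)) || any(ranges <= 0)) {
    stop("scaling ranges must be positive and finite", call. = FALSE)
  }
  if (length(weights) != 3 || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be 3 non-negative numbers with a positive sum", call. = FALSE)
  }
  structure(
    list(ranges = ranges,
         weights = stats::setNames(weights / sum(weights),
                                   c("duration_ms", "magnitude", "anchor_ms"))),
    class = "feature_scaling"
  )
}

#' @export
print.feature_scaling <- function(x, ...) {
  cat(sprintf(
    "<feature_scaling> ranges: duration %g ms, magnitude %g, anchor %g ms | weights %.2f/%.2f/%.2f\n",
    x$ranges[1], x$ranges[2], x$ranges[3],
    x$weights[1], x$weights[2], x$weights[3]
  ))
  invisible(x)
}

#' Derive feature scaling from observed events
#'
#' Sets each normalisation range to the observed spread (max - min) of the
#' feature over a pool of events, floored at a small positive value so that a
#' degenerate pool (all features identical) still yields a valid scaling.
#'
#' @param events an event table, typically pooled over a cohort.
#' @param weights feature weights as in [feature_scaling()]; the default
#'   picks equal weights, or zero anchor weight when `domain` is
#'   `"stabilometry"`.
#' @param domain `"eeg"`, `"stabilometry"` or `"generic"`; only used to pick
#'   default weights.
#' @return a [feature_scaling()].
#' @export
scaling_from_events <- function(events, weights = NULL,
                                domain = c("generic", "eeg", "stabilometry")) {
  domain <- match.arg(domain)
  if (is.null(weights)) {
    weights <- if (domain == "stabilometry") c(1, 1, 0) else c(1, 1, 1)
  }
  if (nrow(events) == 0) stop("cannot derive scaling from an empty event pool",
                              call. = FALSE)
  rng <- function(x) max(max(x) - min(x), 1e-9)
  feature_scaling(rng(events$duration_ms), rng(events$magnitude),
                  rng(events$anchor_ms), weights)
}

#' Similarity between two events
#'
#' Zero when the event types differ; otherwise the weighted mean over the
#' three features of `max(0, 1 - |f_a - f_b| / range_f)`. Identical events
#' score 1.
#'
#' @param a,b single events: one-row event tables (or lists with fields
#'   `event_type`, `duration_ms`, `magnitude`, `anchor_ms`).
#' @param scaling a [feature_scaling()].
#' @return a number in \[0, 1\].
#' @export
event_similarity <- function(a, b, scaling) {
  stopifnot(inherits(scaling, "feature_scaling"))
  if (!identical(as.character(a$event_type), as.character(b$event_type))) return(0)
  f <- function(feat) {
    max(0, 1 - abs(a[[feat]] - b[[feat]]) / scaling$ranges[[feat]])
  }
  w <- scaling$weights
  unname(w["duration_ms"] * f("duration_ms") +
         w["magnitude"] * f("magnitude") +
         w["anchor_ms"] * f("anchor_ms"))
}

sort_events <- function(e) {
  pos <- if ("start" %in% names(e)) e$start else e$anchor_ms
  if (is.unsorted(pos, strictly = FALSE)) e <- e[order(pos, e$event_type), ]
  e
}

# na x nb matrix of pairwise event similarities (vectorised)
event_similarity_matrix <- function(a, b, scaling) {
  w <- scaling$weights; r <- scaling$ranges
  gate <- outer(a$event_type, b$event_type, "==")
  feat <- function(name) {
    pmax(0, 1 - abs(outer(a[[name]], b[[name]], "-")) / r[[name]])
  }
  s <- w[["duration_ms"]] * feat("duration_ms") +
    w[["magnitude"]] * feat("magnitude") +
    w[["anchor_ms"]] * feat("anchor_ms")
  s * gate
}

# maximum-weight one-to-one assignment between rows and columns of S.
# Returns list(pairs = tibble(i, j, weight), total).
max_weight_assignment <- function(S, eps = 1e-10, want_pairs = TRUE) {
  empty <- tibble::tibble(i = integer(), j = integer(), weight = numeric())
  edges <- which(S > 0, arr.ind = TRUE)
  if (nrow(edges) == 0) return(list(pairs = empty, total = 0))
  na <- nrow(S); nb <- ncol(S)
  g <- igraph::make_bipartite_graph(
    c(rep(FALSE, na), rep(TRUE, nb)),
    as.vector(t(cbind(edges[, 1], na + edges[, 2])))
  )
  m <- igraph::max_bipartite_match(g, weights = S[edges], eps = eps)
  mate <- m$matching[seq_len(na)]
  matched <- which(!is.na(mate))
  w <- S[cbind(matched, as.integer(mate[matched] - na))]
  pairs <- if (want_pairs) {
    tibble::tibble(i = matched, j = as.integer(mate[matched] - na), weight = w)
  } else empty
  list(pairs = pairs, total = sum(w))
}

#' Similarity between two event sets (series-level)
#'
#' Events of the two series are paired by a maximum-weight one-to-one
#' assignment under [event_similarity()]; the score is the Dice-style
#' normalisation `2 * sum(matched weights) / (n_a + n_b)`, which penalises
#' unmatched events on either side symmetrically. Two empty sets score 1;
#' an empty set against a non-empty one scores 0.
#'
#' @param a,b event tables.
#' @param scaling a [feature_scaling()].
#' @param details if `TRUE`, return a list with `score` and the matched
#'   `pairs` tibble instead of a bare number.
#' @return a number in \[0, 1\] (or a list when `details = TRUE`).
#' @export
series_similarity <- function(a, b, scaling, details = FALSE) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 && nb == 0) {
    score <- 1
    pairs <- tibble::tibble(i = integer(), j = integer(), weight = numeric())
  } else if (na == 0 || nb == 0) {
    score <- 0
    pairs <- tibble::tibble(i = integer(), j = integer(), weight = numeric())
  } else {
    # stable order so assignment ties resolve by position, then type
    # (reference-model event sets carry anchor_ms but no start)
    a <- sort_events(a)
    b <- sort_events(b)
    S <- event_similarity_matrix(a, b, scaling)
    sol <- max_weight_assignment(S, want_pairs = details)
    score <- 2 * sol$total / (na + nb)
    pairs <- sol$pairs
  }
  if (details) list(score = score, pairs = pairs) else score
}

#' Similarity between two subjects
#'
#' Compares two subjects with identical record structure, bottom-up: series
#' leaves score by [series_similarity()] of their event sets, quantitative
#' leaves by `max(0, 1 - |a - b| / range)`, qualitative leaves 1 if equal
#' else 0; each internal node averages its children (equal weights) and the
#' register root's score is the overall similarity. The result annotates
#' every node of the shared tree.
#'
#' @param p,q annotated [subject_record()]s with the same
#'   measurement/condition structure.
#' @param scaling a [feature_scaling()] for the event comparisons.
#' @param value_ranges optional named numeric vector giving the
#'   normalisation range of quantitative leaves by leaf name; leaves without
#'   an entry use `max(|a|, |b|, 1)`.
#' @return a `similarity_report`: list with `overall`, `node_scores` (tibble
#'   `path`, `kind`, `score`) and `matched_event_pairs` (named list per
#'   series leaf).
#' @export
subject_similarity <- function(p, q, scaling, value_ranges = NULL) {
  stopifnot(inherits(p, "subject_record"), inherits(q, "subject_record"))
  if (length(p$measurements) != length(q$measurements)) {
    stop("structural mismatch at /register: different number of measurements",
         call. = FALSE)
  }
  acc <- list(path = character(), kind = character(), score = numeric())
  pairs <- list()
  add <- function(path, kind, score) {
    i <- length(acc$path) + 1L
    acc$path[i] <<- path; acc$kind[i] <<- kind; acc$score[i] <<- score
  }
  leaf_score <- function(lp, lq, path) {
    # series ids are subject-specific; structure is the kind (and, for single
    # values, the variable name), not the leaf label
    if (lp$kind != lq$kind ||
        (lp$kind != "time_series" && lp$name != lq$name)) {
      stop("structural mismatch at ", path, ": ", lp$name, " (", lp$kind,
           ") vs ", lq$name, " (", lq$kind, ")", call. = FALSE)
    }
    if (lp$kind == "time_series") {
      if (is.null(lp$events) || is.null(lq$events)) {
        stop("series leaf '", path, "' is not annotated; run annotate_subject() first",
             call. = FALSE)
      }
      res <- series_similarity(lp$events, lq$events, scaling, details = TRUE)
      pairs[[path]] <<- res$pairs
      res$score
    } else if (lp$kind == "quantitative") {
      rng <- value_ranges[[lp$name]] %||% max(abs(lp$value), abs(lq$value), 1)
      max(0, 1 - abs(lp$value - lq$value) / rng)
    } else {
      as.numeric(identical(lp$value, lq$value))
    }
  }
  m_scores <- purrr::map2_dbl(p$measurements, q$measurements, function(mp, mq) {
    mpath <- paste0("register/", mp$name)
    if (mp$name != mq$name || length(mp$conditions) != length(mq$conditions)) {
      stop("structural mismatch at ", mpath, call. = FALSE)
    }
    c_scores <- purrr::map2_dbl(mp$conditions, mq$conditions, function(cp, cq) {
      cpath <- paste0(mpath, "/", cp$name)
      if (cp$name != cq$name || length(cp$leaves) != length(cq$leaves)) {
        stop("structural mismatch at ", cpath, call. = FALSE)
      }
      l_scores <- purrr::map2_dbl(cp$leaves, cq$leaves, function(lp, lq) {
        lpath <- paste0(cpath, "/", lp$name)
        sc <- leaf_score(lp, lq, lpath)
        add(lpath, lp$kind, sc)
        sc
      })
      sc <- mean(l_scores)
      add(cpath, "condition", sc)
      sc
    })
    sc <- mean(c_scores)
    add(mpath, "measurement", sc)
    sc
  })
  overall <- mean(m_scores)
  add("register", "register", overall)
  scores <- tibble::tibble(path = acc$path, kind = acc$kind, score = acc$score)
  structure(
    list(overall = overall, node_scores = scores, matched_event_pairs = pairs,
         subjects = c(p$subject_id, q$subject_id)),
    class = "similarity_report"
  )
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> %s vs %s: overall %.4f\n",
              x$subjects[1], x$subjects[2], x$overall))
  print(x$node_scores, n = 20)
  invisible(x)
}

#' @export
tidy.similarity_report <- function(x, ...) x$node_scores

#' @export
glance.similarity_report <- function(x, ...) {
  tibble::tibble(overall = x$overall, n_nodes = nrow(x$node_scores))
}
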