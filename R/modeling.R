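#' Pairwise subject similarity matrix
#'
#' @param subjects list of annotated [subject_record()]s sharing one record
#'   structure (at least 2).
#' @param scaling a [feature_scaling()].
#' @param value_ranges passed to [subject_similarity()].
#' @return a symmetric numeric matrix in \[0, 1\] with unit diagonal, with
#'   subject ids as dimnames.
#' @export
pairwise_similarity_matrix <- function(subjects, scaling, value_ranges = NULL) {
  n <- length(subjects)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  S <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- subject_similarity(subjects[[i]], subjects[[j]], scaling,
                              value_ranges)$overall
      S[i, j] <- s
      S[j, i] <- s
    }
  }
  dimnames(S) <- list(ids, ids)
  S
}

#' Outlier screening on a similarity matrix
#'
#' Flags subjects that do not belong to their cohort, emulating how a person
#' eyeballing a cluster picture spots strays. Four criteria vote:
#'
#' * **C1 (low average affinity)** — the subject's mean similarity to the
#'   others falls more than `z` robust standard deviations (MAD) below the
#'   cohort median of those row means. Median/MAD rather than mean/sd, so
#'   that one gross outlier cannot inflate the spread and mask a second one.
#' * **C2 (isolation)** — the subject's *best* similarity to anyone is below
#'   `isolation`: it has no near neighbour at all.
#' * **C3 (tiny cluster)** — average-linkage clustering of `1 - S`, cut at
#'   `tau_c`, leaves the subject in a cluster smaller than
#'   `min_cluster_size`.
#' * **C4 (cohesion damage)** — removing the subject raises the mean
#'   within-cluster similarity of its own cluster by more than `delta`; when
#'   the subject's cluster is too small for that comparison, the whole cohort
#'   plays the role of the cluster.
#'
#' A subject is an outlier when at least `vote_threshold` criteria fire.
#'
#' @param S symmetric similarity matrix from
#'   [pairwise_similarity_matrix()] (n >= 3).
#' @param z standard-deviation multiplier for C1 (default 2).
#' @param isolation neighbour threshold for C2 (default 0.5).
#' @param tau_c dissimilarity cut height for the C3/C4 clustering
#'   (default 0.3).
#' @param min_cluster_size minimum non-outlier cluster size for C3
#'   (default 2).
#' @param delta cohesion-gain threshold for C4 (default 0.05).
#' @param vote_threshold criteria needed to call an outlier (default 2).
#' @return a tibble with one row per subject: `subject_id`, `c1`..`c4`,
#'   `n_criteria`, `is_outlier`.
#' @export
detect_outliers <- function(S, z = 2, isolation = 0.5, tau_c = 0.3,
                            min_cluster_size = 2, delta = 0.05,
                            vote_threshold = 2) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be square", call. = FALSE)
  n <- nrow(S)
  if (n < 3) stop("outlier screening needs at least 3 subjects", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric", call. = FALSE)
  ids <- rownames(S) %||% as.character(seq_len(n))
  off <- S; diag(off) <- NA
  row_means <- rowMeans(off, na.rm = TRUE)
  c1 <- row_means < stats::median(row_means) - z * stats::mad(row_means)
  c2 <- apply(off, 1, max, na.rm = TRUE) < isolation
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  cl <- stats::cutree(hc, h = tau_c)
  sizes <- table(cl)
  c3 <- as.vector(sizes[as.character(cl)]) < min_cluster_size
  within <- function(m) {
    sub <- S[m, m, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  c4 <- vapply(seq_len(n), function(i) {
    members <- which(cl == cl[i])
    if (length(members) < 3) members <- seq_len(n) # fall back to the cohort
    within(setdiff(members, i)) - within(members) > delta
  }, logical(1))
  hits <- cbind(c1, c2, c3, c4)
  tibble::tibble(
    subject_id = ids,
    c1 = c1, c2 = c2, c3 = c3, c4 = c4,
    n_criteria = rowSums(hits),
    is_outlier = rowSums(hits) >= vote_threshold
  )
}

#' Build a class reference model by clustering events
#'
#' Pools every event of every training subject (outlier screening is assumed
#' to have been applied already), clusters them per event type by
#' average-linkage agglomerative clustering on the scaled feature distance
#' `1 - event_similarity`, cuts the tree at `tau_m`, and keeps the clusters
#' whose *support* — the fraction of training series contributing at least
#' one event — reaches `min_support`. Each retained cluster contributes one
#' model event: its medoid, a real observed event, with support and cluster
#' size recorded. The model plays the role of an archetypal subject of the
#' class.
#'
#' @param training list of annotated [subject_record()]s of one class.
#' @param class_label label of the class being modelled.
#' @param scaling a [feature_scaling()].
#' @param tau_m dissimilarity cut height in normalised feature units
#'   (default 0.3).
#' @param min_support minimum fraction of training series a cluster must draw
#'   from (default 0.5, i.e. events "often found").
#' @return an object of class `reference_model`: `class_label`, `events`
#'   (tibble sorted by `anchor_ms`, with `support` and `cluster_size`),
#'   `provenance`.
#' @export
build_reference_model <- function(training, class_label, scaling,
                                  tau_m = 0.3, min_support = 0.5) {
  if (length(training) == 0) stop("training set is empty", call. = FALSE)
  pooled <- dplyr::bind_rows(lapply(training, subject_events))
  all_series <- unlist(lapply(training, function(s) {
    names(walk_leaves(s, function(l, p) if (l$kind == "time_series") p else NULL))
  }))
  n_series <- length(unique(all_series))
  model_events <- list()
  for (tt in unique(pooled$event_type)) {
    ev <- pooled[pooled$event_type == tt, , drop = FALSE]
    if (nrow(ev) == 1) {
      cl <- 1L
    } else {
      D <- 1 - event_similarity_matrix(ev, ev, scaling)
      hc <- stats::hclust(stats::as.dist(D), method = "average")
      cl <- stats::cutree(hc, h = tau_m)
    }
    for (g in unique(cl)) {
      members <- which(cl == g)
      support <- length(unique(ev$series_path[members])) / n_series
      if (support < min_support) next
      if (length(members) == 1) {
        med <- members
      } else {
        Dg <- 1 - event_similarity_matrix(ev[members, ], ev[members, ], scaling)
        tot <- rowSums(Dg)
        # tie-break: smallest total distance, then earliest anchor
        med <- members[order(tot, ev$anchor_ms[members])[1]]
      }
      model_events[[length(model_events) + 1]] <- dplyr::mutate(
        ev[med, c("event_type", "duration_ms", "magnitude", "anchor", "anchor_ms")],
        support = support, cluster_size = length(members)
      )
    }
  }
  if (length(model_events) == 0) {
    stop("degenerate model for class '", class_label,
         "': no event cluster reaches min_support = ", min_support, call. = FALSE)
  }
  events <- dplyr::arrange(dplyr::bind_rows(model_events), .data$anchor_ms)
  structure(
    list(
      class_label = as.character(class_label),
      events = events,
      provenance = list(
        subject_ids = vapply(training, function(s) s$subject_id, character(1)),
        n_series = n_series,
        n_pooled_events = nrow(pooled),
        tau_m = tau_m, min_support = min_support,
        scaling = scaling
      )
    ),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model '%s'> %d model events from %d series (%d pooled events)\n",
              x$class_label, nrow(x$events), x$provenance$n_series,
              x$provenance$n_pooled_events))
  print(tidy(x))
  invisible(x)
}

#' Tidy a reference model into its event table
#'
#' One row per model event, mirroring the published model tables: event
#' number, duration, magnitude (amplitude/intensity) and anchor timestamp,
#' plus support diagnostics.
#'
#' @param x a [build_reference_model()] result.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.reference_model <- function(x, ...) {
  dplyr::mutate(x$events, event = dplyr::row_number(), .before = 1)
}

#' @export
glance.reference_model <- function(x, ...) {
  tibble::tibble(
    class_label = x$class_label,
    n_model_events = nrow(x$events),
    n_training_series = x$provenance$n_series,
    n_pooled_events = x$provenance$n_pooled_events,
    min_support = x$provenance$min_support,
    tau_m = x$provenance$tau_m
  )
}

#' Similarity between a subject and a reference model
#'
#' The model's events are treated as the event set of an archetypal
#' pseudo-subject and compared to the subject's pooled events with
#' [series_similarity()].
#'
#' @param subject an annotated [subject_record()].
#' @param model a [build_reference_model()] result.
#' @param scaling a [feature_scaling()]; defaults to the scaling the model
#'   was built with.
#' @return a number in \[0, 1\].
#' @export
model_similarity <- function(subject, model, scaling = NULL) {
  stopifnot(inherits(model, "reference_model"))
  scaling <- scaling %||% model$provenance$scaling
  series_similarity(subject_events(subject), model$events, scaling)
}
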