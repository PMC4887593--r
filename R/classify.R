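#' Train a reference-model classifier
#'
#' Strategy step I: for every class, screen the training subjects for
#' outliers on their within-class similarity matrix (see
#' [detect_outliers()]), drop the flagged ones, and build one reference
#' model per class from the remainder. Feature scaling is derived once from
#' the pooled training events so that every comparison — screening, model
#' building and later classification — uses the same normalisation.
#'
#' @param subjects list of annotated [subject_record()]s with `class_label`
#'   set; every class needs at least 2 subjects surviving screening.
#' @param scaling optional [feature_scaling()]; derived from the pooled
#'   training events when `NULL`.
#' @param domain passed to [scaling_from_events()] when deriving scaling.
#' @param screen_outliers apply outlier screening per class (default TRUE;
#'   classes with fewer than 3 subjects are never screened).
#' @param tau_m,min_support model-building parameters, see
#'   [build_reference_model()].
#' @param ... further arguments passed to [detect_outliers()].
#' @return an object of class `event_classifier`: `models` (named list of
#'   reference models), `scaling`, `screened` (outlier verdicts per class).
#' @export
train_classifier <- function(subjects, scaling = NULL,
                             domain = c("generic", "eeg", "stabilometry"),
                             screen_outliers = TRUE,
                             tau_m = 0.3, min_support = 0.5, ...) {
  domain <- match.arg(domain)
  labels <- vapply(subjects, function(s) {
    if (is.null(s$class_label)) {
      stop("subject '", s$subject_id, "' has no class_label", call. = FALSE)
    }
    s$class_label
  }, character(1))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training needs at least 2 classes", call. = FALSE)
  if (is.null(scaling)) {
    pooled <- dplyr::bind_rows(lapply(subjects, subject_events))
    scaling <- scaling_from_events(pooled, domain = domain)
  }
  screened <- list()
  models <- list()
  for (cls in classes) {
    members <- subjects[labels == cls]
    if (screen_outliers && length(members) >= 3) {
      S <- pairwise_similarity_matrix(members, scaling)
      verdicts <- detect_outliers(S, ...)
      screened[[cls]] <- verdicts
      keep <- !verdicts$is_outlier
      if (sum(keep) < 2) {
        stop("class '", cls, "': fewer than 2 subjects survive outlier screening",
             call. = FALSE)
      }
      members <- members[keep]
    }
    if (length(members) < 2) {
      stop("class '", cls, "' needs at least 2 training subjects", call. = FALSE)
    }
    models[[cls]] <- build_reference_model(members, cls, scaling,
                                           tau_m = tau_m, min_support = min_support)
  }
  structure(
    list(models = models, scaling = scaling, screened = screened,
         classes = classes),
    class = "event_classifier"
  )
}

#' @export
print.event_classifier <- function(x, ...) {
  cat(sprintf("<event_classifier> %d classes: %s\n", length(x$models),
              paste(x$classes, collapse = ", ")))
  for (m in x$models) {
    cat(sprintf("  %s: %d model events\n", m$class_label, nrow(m$events)))
  }
  invisible(x)
}

#' @export
tidy.event_classifier <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, function(m) {
    dplyr::mutate(tidy(m), class_label = m$class_label, .before = 1)
  }))
}

#' @export
glance.event_classifier <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$models),
    classes = paste(x$classes, collapse = ","),
    n_model_events = sum(vapply(x$models, function(m) nrow(m$events), numeric(1)))
  )
}

#' Classify a subject by maximum model similarity
#'
#' Strategy steps II-III: the new subject is compared with every class
#' reference model and assigned to the class whose model is most similar.
#' Exact ties are broken towards the lexicographically first class label and
#' flagged.
#'
#' @param subject an annotated [subject_record()].
#' @param classifier an [train_classifier()] result.
#' @return a list with `class_label`, `scores` (tibble `class_label`,
#'   `similarity`), and `tie`.
#' @export
classify_subject <- function(subject, classifier) {
  stopifnot(inherits(classifier, "event_classifier"))
  ev <- subject_events(subject)
  sims <- vapply(classifier$models, function(m) {
    series_similarity(ev, m$events, classifier$scaling)
  }, numeric(1))
  best <- max(sims)
  winners <- sort(names(sims)[sims >= best - 1e-12])
  list(
    class_label = winners[1],
    scores = tibble::tibble(class_label = names(sims), similarity = unname(sims)),
    tie = length(winners) > 1
  )
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Subjects are partitioned into `k` folds stratified by class (each fold's
#' class proportions match the cohort's within one subject). For each fold
#' the classifier is trained on the remaining folds — outlier screening runs
#' inside each training split only, never on held-out subjects — and the
#' held-out subjects are classified. Accuracy is the fraction of correct
#' assignments, pooled over folds, overall and per class.
#'
#' @param subjects list of annotated, labelled [subject_record()]s.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold partition (stored in the result).
#' @param ... passed to [train_classifier()].
#' @return an object of class `cv_result`: `assignments` (tibble
#'   `subject_id`, `class_label`, `predicted`, `fold`, `tie`), `per_class`,
#'   `overall_accuracy` (percent), `k`, `seed`.
#' @export
cross_validate <- function(subjects, k = 10, seed = NULL, ...) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  labels <- vapply(subjects, function(s) s$class_label %||%
                     stop("unlabelled subject", call. = FALSE), character(1))
  n <- length(subjects)
  counts <- table(labels)
  if (any(counts < k)) {
    warning("some classes have fewer than k subjects; folds are stratified ",
            "as evenly as the data allow")
  }
  fold <- integer(n)
  assign_folds <- function() {
    for (cls in names(counts)) {
      idx <- which(labels == cls)
      fold[sample(idx)] <<- rep_len(seq_len(k), length(idx))
    }
  }
  if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
  rows <- list()
  for (f in sort(unique(fold))) {
    train_set <- subjects[fold != f]
    test_set <- subjects[fold == f]
    clf <- train_classifier(train_set, ...)
    for (s in test_set) {
      res <- classify_subject(s, clf)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = s$subject_id, class_label = s$class_label,
        predicted = res$class_label, fold = f, tie = res$tie
      )
    }
  }
  assignments <- dplyr::bind_rows(rows)
  per_class <- assignments |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(
      n = dplyr::n(),
      correct = sum(.data$predicted == .data$class_label),
      accuracy = 100 * .data$correct / .data$n,
      .groups = "drop"
    )
  structure(
    list(
      assignments = assignments,
      per_class = per_class,
      overall_accuracy = 100 * mean(assignments$predicted == assignments$class_label),
      k = k, seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV, %d subjects, overall accuracy %.2f%%\n",
              x$k, nrow(x$assignments), x$overall_accuracy))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$assignments

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = nrow(x$assignments),
    overall_accuracy = x$overall_accuracy,
    n_ties = sum(x$assignments$tie),
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}
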