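# Similarity matrices, outlier screening, reference models.

make_cohort_subjects <- function(n, seed, spec = eeg_class_specs()$epileptic) {
  coh <- generate_cohort(stats::setNames(list(spec), spec$label), n, seed = seed)
  annotate_cohort(coh, paroxysm_definition())
}

test_that("pairwise similarity matrix is symmetric with unit diagonal", {
  subj <- make_cohort_subjects(4, seed = 51)
  sc <- scaling_from_events(dplyr::bind_rows(lapply(subj, subject_events)),
                            domain = "eeg")
  S <- pairwise_similarity_matrix(subj, sc)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_true(all(S >= 0 & S <= 1))

  # duplicated subject: off-diagonal 1
  dup <- subj[c(1, 1, 2)]
  dup[[2]]$subject_id <- "copy"
  S2 <- pairwise_similarity_matrix(dup, sc)
  expect_equal(S2[1, 2], 1)

  S3 <- pairwise_similarity_matrix(subj[c(1, 1, 1)], sc)
  expect_true(all(S3 == 1))
})

test_that("an isolated subject trips all four outlier criteria", {
  n <- 10
  S <- matrix(0.95, n, n)
  S[n, ] <- 0.15; S[, n] <- 0.15
  diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("s", 1:n)
  v <- detect_outliers(S)
  expect_true(v$is_outlier[n])
  expect_equal(sum(v$is_outlier), 1)
  expect_equal(unname(v$n_criteria[n]), 4)
})

test_that("a homogeneous cohort has no outliers", {
  S <- matrix(1, 5, 5)
  v <- detect_outliers(S)
  expect_false(any(v$is_outlier))
  expect_error(detect_outliers(S[1:2, 1:2]), "at least 3")
})

test_that("injected 5-sigma outliers are recovered from a seeded cohort", {
  coh <- generate_cohort(eeg_class_specs()["epileptic"], 20,
                         outlier_fraction = 0.1, outlier_shift_sd = 5,
                         seed = 4202)
  subj <- annotate_cohort(coh, paroxysm_definition())
  sc <- scaling_from_events(dplyr::bind_rows(lapply(subj, subject_events)),
                            domain = "eeg")
  v <- detect_outliers(pairwise_similarity_matrix(subj, sc))
  truth <- coh$manifest$is_outlier
  expect_equal(sum(truth), 2)
  expect_true(all(v$is_outlier[truth]))       # both planted outliers flagged
  expect_equal(sum(v$is_outlier & !truth), 0) # and no false positives
})

test_that("identical training events collapse to one full-support model event", {
  mk <- function(id) {
    s <- ts_series(rep(0, 500), 10, paste0(id, "_s"), "eeg")
    ev <- event_table("spike", 100, 105, 80, 102)
    subject_record(id, list(measurement_node("eeg", list(
      condition_node("rest", list(series_leaf(s, ev)))
    ))), class_label = "c")
  }
  subj <- lapply(paste0("t", 1:4), mk)
  sc <- default_test_scaling()
  model <- build_reference_model(subj, "c", sc)
  expect_equal(nrow(model$events), 1)
  expect_equal(model$events$support, 1)
  expect_equal(model$events$cluster_size, 4L)
  expect_equal(model$events$duration_ms, 50)
  expect_equal(model$events$magnitude, 80)
})

test_that("model keeps frequent event populations and drops rare ones", {
  # population A in all 10 subjects, B in 8, C in 2
  mk <- function(id, with_b, with_c) {
    s <- ts_series(rep(0, 2000), 10, paste0(id, "_s"), "eeg")
    ev <- event_table("spike", 100, 110, 80, 104)
    if (with_b) {
      ev <- dplyr::bind_rows(ev, event_table("spike", 1000, 1020, 30, 1009))
    }
    if (with_c) {
      ev <- dplyr::bind_rows(ev, event_table("spike", 1800, 1803, 150, 1801))
    }
    subject_record(id, list(measurement_node("eeg", list(
      condition_node("rest", list(series_leaf(s, dplyr::arrange(ev, start))))
    ))), class_label = "c")
  }
  subj <- lapply(1:10, function(i) mk(paste0("t", i), i <= 8, i <= 2))
  sc <- default_test_scaling()
  model <- build_reference_model(subj, "c", sc, min_support = 0.5)
  expect_equal(nrow(model$events), 2)
  expect_equal(sort(model$events$support), c(0.8, 1.0))
  # the rare population is absent
  expect_false(any(model$events$magnitude > 100))
})

test_that("model medoids are real observed events within the cluster hull", {
  coh <- generate_cohort(eeg_class_specs()["epileptic"], 8, seed = 77)
  subj <- annotate_cohort(coh, paroxysm_definition())
  pooled <- dplyr::bind_rows(lapply(subj, subject_events))
  sc <- scaling_from_events(pooled, domain = "eeg")
  model <- build_reference_model(subj, "epileptic", sc)
  expect_gt(nrow(model$events), 0)
  for (i in seq_len(nrow(model$events))) {
    me <- model$events[i, ]
    hit <- pooled$duration_ms == me$duration_ms &
      pooled$magnitude == me$magnitude & pooled$anchor_ms == me$anchor_ms
    expect_true(any(hit)) # medoid is an actual pooled event
    expect_gte(me$duration_ms, min(pooled$duration_ms))
    expect_lte(me$duration_ms, max(pooled$duration_ms))
  }
  # events are sorted by anchor timestamp, support recorded
  expect_false(is.unsorted(model$events$anchor_ms))
  expect_true(all(model$events$support >= 0.5 & model$events$support <= 1))
})

test_that("an unreachable support threshold is a degenerate-model error", {
  subj <- make_cohort_subjects(4, seed = 81)
  sc <- scaling_from_events(dplyr::bind_rows(lapply(subj, subject_events)),
                            domain = "eeg")
  expect_error(build_reference_model(subj, "epileptic", sc, min_support = 1.01),
               "degenerate model")
})

test_that("adding a duplicate subject never removes a model event", {
  subj <- make_cohort_subjects(6, seed = 83)
  sc <- scaling_from_events(dplyr::bind_rows(lapply(subj, subject_events)),
                            domain = "eeg")
  m1 <- build_reference_model(subj, "epileptic", sc)
  dup <- subj[[1]]
  dup$subject_id <- "dup" # series paths stay unique via the subject id
  m2 <- build_reference_model(c(subj, list(dup)), "epileptic", sc)
  # every m1 event feature row still present in m2
  key <- function(e) paste(round(e$duration_ms, 6), round(e$magnitude, 6),
                           round(e$anchor_ms, 6))
  expect_true(all(key(m1$events) %in% key(m2$events)))
})

test_that("subject-vs-model similarity has the expected fixed points", {
  subj <- make_cohort_subjects(5, seed = 85)
  sc <- scaling_from_events(dplyr::bind_rows(lapply(subj, subject_events)),
                            domain = "eeg")
  model <- build_reference_model(subj, "epileptic", sc)

  # a pseudo-subject holding exactly the model events scores 1
  s <- ts_series(rep(0, 2000), 10, "pseudo_s", "eeg")
  pseudo <- subject_record("pseudo", list(measurement_node("eeg", list(
    condition_node("rest", list(series_leaf(s, model$events))))
  )), class_label = "epileptic")
  expect_equal(model_similarity(pseudo, model), 1)

  empty <- subject_record("empty", list(measurement_node("eeg", list(
    condition_node("rest", list(series_leaf(s, empty_events()))))
  )))
  expect_equal(model_similarity(empty, model), 0)

  # small instance agrees with brute force
  two <- subj[[1]]
  ev2 <- subject_events(two)[1:2, ]
  W <- tsevents:::event_similarity_matrix(ev2, model$events, sc)
  expect_equal(
    series_similarity(ev2, model$events, sc),
    2 * brute_force_match(W) / (2 + nrow(model$events)),
    tolerance = 1e-8
  )
})
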