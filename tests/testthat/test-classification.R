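# Classifier training, max-similarity assignment, cross-validation.

test_that("training builds one model per class and screens injected outliers", {
  coh <- generate_cohort(eeg_class_specs(), 10, outlier_fraction = 0.1,
                         outlier_shift_sd = 5, seed = 91)
  subj <- annotate_cohort(coh, paroxysm_definition())
  clf <- train_classifier(subj, domain = "eeg")
  expect_setequal(names(clf$models), c("epileptic", "healthy"))
  flagged <- dplyr::bind_rows(clf$screened)$subject_id[
    dplyr::bind_rows(clf$screened)$is_outlier]
  planted <- coh$manifest$subject_id[coh$manifest$is_outlier]
  expect_gte(length(intersect(flagged, planted)), 1)
  # screened-out subjects never contribute to their class model
  for (m in clf$models) {
    expect_false(any(flagged %in% m$provenance$subject_ids))
  }
})

test_that("training is deterministic given identical input", {
  coh <- generate_cohort(eeg_class_specs(), 5, seed = 93)
  subj <- annotate_cohort(coh, paroxysm_definition())
  c1 <- train_classifier(subj, domain = "eeg")
  c2 <- train_classifier(subj, domain = "eeg")
  expect_identical(rlang::hash(c1), rlang::hash(c2))
})

test_that("a subject matching a model exactly gets that class with score 1", {
  coh <- generate_cohort(eeg_class_specs(), 6, seed = 95)
  subj <- annotate_cohort(coh, paroxysm_definition())
  clf <- train_classifier(subj, domain = "eeg", screen_outliers = FALSE)
  s <- ts_series(rep(0, 2000), 10, "pseudo_s", "eeg")
  pseudo <- subject_record("pseudo", list(measurement_node("eeg", list(
    condition_node("rest", list(series_leaf(s, clf$models$healthy$events))))
  )))
  res <- classify_subject(pseudo, clf)
  expect_equal(res$class_label, "healthy")
  expect_equal(res$scores$similarity[res$scores$class_label == "healthy"], 1)
  expect_false(res$tie)
})

test_that("exact ties break lexicographically and are flagged", {
  s <- ts_series(rep(0, 500), 10, "s", "eeg")
  mk_model <- function(label) {
    subjects <- lapply(1:2, function(i) {
      subject_record(paste0(label, i), list(measurement_node("eeg", list(
        condition_node("rest", list(series_leaf(s, event_table("spike", 100, 110, 80, 104))))
      ))), class_label = label)
    })
    build_reference_model(subjects, label, default_test_scaling())
  }
  clf <- structure(
    list(models = list(beta = mk_model("beta"), alpha = mk_model("alpha")),
         scaling = default_test_scaling(), screened = list(),
         classes = c("alpha", "beta")),
    class = "event_classifier"
  )
  empty_subj <- subject_record("none", list(measurement_node("eeg", list(
    condition_node("rest", list(series_leaf(s, empty_events())))
  ))))
  res <- classify_subject(empty_subj, clf)
  expect_true(res$tie)
  expect_equal(res$class_label, "alpha")
})

test_that("folds partition every subject exactly once, stratified by class", {
  coh <- generate_cohort(eeg_class_specs(), 10, seed = 97)
  subj <- annotate_cohort(coh, paroxysm_definition())
  cv <- cross_validate(subj, k = 5, seed = 97, domain = "eeg")
  a <- cv$assignments
  expect_equal(sort(a$subject_id),
               sort(vapply(subj, function(s) s$subject_id, character(1))))
  # stratification: each fold holds 2 of each class
  per_fold <- dplyr::count(a, fold, class_label)
  expect_true(all(per_fold$n == 2))
  expect_equal(cv$overall_accuracy,
               100 * mean(a$predicted == a$class_label))
})

test_that("a separable synthetic cohort cross-validates perfectly", {
  # classes far apart in both event features: no fold can confuse them
  specs <- list(
    slow = class_spec("slow", "paroxysm", "half_sine", n_events_mean = 8,
                      duration_mean_ms = 300, magnitude_mean = 100,
                      noise_sd = 5, n_samples = 1000, domain_tag = "eeg"),
    fast = class_spec("fast", "paroxysm", "half_sine", n_events_mean = 2,
                      duration_mean_ms = 40, magnitude_mean = 40,
                      noise_sd = 5, n_samples = 1000, domain_tag = "eeg")
  )
  coh <- generate_cohort(specs, 6, seed = 99)
  subj <- annotate_cohort(coh, paroxysm_definition())
  cv <- cross_validate(subj, k = 3, seed = 99, domain = "eeg",
                       screen_outliers = FALSE)
  expect_equal(cv$overall_accuracy, 100)
  expect_true(all(cv$per_class$accuracy == 100))
})

test_that("permuted labels drive accuracy to chance", {
  coh <- generate_cohort(eeg_class_specs(), 8, seed = 103)
  subj <- annotate_cohort(coh, paroxysm_definition())
  withr::with_seed(103, {
    labs <- sample(vapply(subj, function(s) s$class_label, character(1)))
  })
  for (i in seq_along(subj)) subj[[i]]$class_label <- labs[i]
  cv <- cross_validate(subj, k = 4, seed = 103, domain = "eeg",
                       screen_outliers = FALSE)
  # 16 subjects, 2 classes: binomial(16, 0.5) 99% band
  expect_gte(cv$overall_accuracy, 100 * 2 / 16)
  expect_lte(cv$overall_accuracy, 100 * 14 / 16)
})

test_that("cv result tidiers expose assignments and summary", {
  coh <- generate_cohort(eeg_class_specs(), 5, seed = 107)
  subj <- annotate_cohort(coh, paroxysm_definition())
  cv <- cross_validate(subj, k = 5, seed = 107, domain = "eeg",
                       screen_outliers = FALSE)
  expect_s3_class(tidy(cv), "tbl_df")
  g <- glance(cv)
  expect_equal(g$n, 10)
  expect_equal(g$k, 5)
  expect_equal(g$seed, 107)
})
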