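# Event-, series- and subject-level similarity.

test_that("event similarity follows the weighted normalised-L1 form", {
  sc <- feature_scaling(200, 100, 10000, weights = c(1, 1, 1))
  e1 <- event_table("spike", 10, 20, 50, 15)
  e2 <- event_table("spike", 10, 25, 50, 15)   # durations 100 vs 150 ms
  expect_equal(event_similarity(e1, e1, sc), 1)
  expect_equal(event_similarity(e1, e2, sc), 1 - (50 / 200) / 3)

  fall <- event_table("fall", 10, 20, 50, 15)
  expect_equal(event_similarity(e1, fall, sc), 0)

  # differences at or beyond the range floor at 0, never go negative
  far <- event_table("spike", 10, 11, 500, 10)
  expect_gte(event_similarity(e1, far, sc), 0)
})

test_that("series similarity has the right fixed points", {
  sc <- default_test_scaling()
  withr::with_seed(29, {
    ev <- random_events(4)
  })
  expect_equal(series_similarity(ev, ev, sc), 1)
  expect_equal(series_similarity(ev, empty_events(), sc), 0)
  expect_equal(series_similarity(empty_events(), ev, sc), 0)
  expect_equal(series_similarity(empty_events(), empty_events(), sc), 1)
})

test_that("assignment scores equal exhaustive brute force on small sets", {
  sc <- default_test_scaling()
  withr::with_seed(37, {
    for (i in 1:60) {
      a <- random_events(sample(1:6, 1))
      b <- random_events(sample(1:6, 1))
      W <- tsevents:::event_similarity_matrix(a, b, sc)
      expect_equal(
        series_similarity(a, b, sc),
        2 * brute_force_match(W) / (nrow(a) + nrow(b)),
        tolerance = 1e-8
      )
    }
  })
})

test_that("similarities are symmetric and bounded over random sets", {
  sc <- default_test_scaling()
  withr::with_seed(43, {
    for (i in 1:30) {
      a <- random_events(sample(0:8, 1))
      b <- random_events(sample(0:8, 1))
      sab <- series_similarity(a, b, sc)
      sba <- series_similarity(b, a, sc)
      expect_equal(sab, sba, tolerance = 1e-9)
      expect_gte(sab, 0); expect_lte(sab, 1)
    }
  })
})

test_that("with 0/1 event weights the series score reduces to the agreement metric", {
  # identical features so event similarity is exactly the type gate
  mk <- function(types) {
    event_table(types, seq(0, by = 20, length.out = length(types)),
                seq(10, by = 20, length.out = length(types)),
                50, seq(5, by = 20, length.out = length(types)))
  }
  sc <- feature_scaling(1e9, 1e9, 1e9) # huge ranges: feature term always 1
  a <- mk(c("x", "x", "y", "z"))
  b <- mk(c("x", "y", "y", "w", "w"))
  matched <- 2 # one x and one y
  expect_equal(series_similarity(a, b, sc),
               sim_exp_lang(evaluation_counts(4, 5, matched)))
})

test_that("subject similarity aggregates leaf scores through the tree", {
  p <- toy_subject("p1", sin(2 * pi * (0:199) / 20), rep(0, 100), age = 30)
  q <- toy_subject("p2", sin(2 * pi * (0:199) / 20), rep(0, 100), age = 30)
  p <- annotate_subject(p, eeg_definitions())
  q <- annotate_subject(q, eeg_definitions())
  sc <- default_test_scaling()

  self <- subject_similarity(p, p, sc)
  expect_equal(self$overall, 1)
  expect_true(all(self$node_scores$score == 1))

  rep2 <- subject_similarity(p, q, sc)
  expect_equal(rep2$overall, 1) # identical content, different ids

  # change the age leaf: condition mean moves, root mean follows
  q2 <- toy_subject("p3", sin(2 * pi * (0:199) / 20), rep(0, 100), age = 60)
  q2 <- annotate_subject(q2, eeg_definitions())
  rep3 <- subject_similarity(p, q2, sc)
  age_score <- rep3$node_scores$score[grepl("/age$", rep3$node_scores$path)]
  expect_equal(age_score, 1 - 30 / 60)
  cond <- rep3$node_scores$score[rep3$node_scores$kind == "condition"][1]
  expect_equal(cond, mean(c(1, age_score)))
  expect_equal(rep3$overall, mean(c(mean(c(1, age_score)), 1)))
})

test_that("structural mismatches name the divergent path", {
  p <- toy_subject("p1", rnorm(50), rnorm(50))
  q <- subject_record("q1", list(
    measurement_node("eeg", list(condition_node("rest", list(
      value_leaf("weight", 70)
    )))),
    measurement_node("followup", list(condition_node("rest", list(
      series_leaf(ts_series(rnorm(50)))
    ))))
  ))
  expect_error(subject_similarity(p, q, default_test_scaling()),
               "register/eeg/rest")
})

test_that("scaling derived from events floors degenerate ranges", {
  ev <- event_table(rep("x", 3), c(0, 50, 100), c(10, 60, 110),
                    rep(5, 3), c(4, 54, 104))
  sc <- scaling_from_events(ev, domain = "eeg")
  expect_gt(sc$ranges[["magnitude"]], 0)
  s2 <- scaling_from_events(ev, domain = "stabilometry")
  expect_equal(unname(s2$weights["anchor_ms"]), 0)
  expect_error(scaling_from_events(empty_events()), "empty")
})
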