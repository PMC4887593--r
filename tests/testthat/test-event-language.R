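# Wave segmentation, rule parsing, and event detection.

test_that("one full sine cycle segments into two 50 ms waves", {
  s <- ts_series(sin(2 * pi * (0:9) / 10), sampling_period_ms = 10)
  w <- segment_waves(s)
  expect_equal(nrow(w), 2)
  expect_equal(w$period_ms, c(50, 50))
  expect_equal(w$sign, c(1L, -1L))
  expect_equal(w$start, c(0L, 5L))
  expect_equal(w$end, c(5L, 10L))
})

test_that("a constant series has no waves", {
  expect_equal(nrow(segment_waves(ts_series(rep(3.3, 50)))), 0)
})

test_that("wave periods partition at most the series duration", {
  withr::with_seed(11, {
    for (i in 1:15) {
      n <- sample(50:500, 1)
      s <- ts_series(rnorm(n), sampling_period_ms = 10)
      w <- segment_waves(s)
      expect_lte(sum(w$period_ms), n * 10)
      expect_true(all(w$start < w$end))
      expect_true(all(w$peak_index >= w$start & w$peak_index < w$end))
      # waves tile the whole centred signal contiguously
      expect_equal(w$start[-1], w$end[-nrow(w)])
    }
  })
})

test_that("a suprathreshold square pulse becomes one fall event", {
  x <- rep(0, 300)
  x[101:150] <- 120 # 0-based samples 100..149
  s <- ts_series(x, sampling_period_ms = 10, domain_tag = "stabilometry")
  ev <- tidy(detect_events(s, fall_definition(threshold = 50)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 100L)
  expect_equal(ev$end, 150L)
  expect_equal(ev$duration_ms, 500)
  expect_equal(ev$magnitude, 120)
})

test_that("pure noise yields no spike events at a high prominence bar", {
  withr::with_seed(99, {
    s <- ts_series(rnorm(1000, sd = 1), sampling_period_ms = 10,
                   domain_tag = "eeg")
  })
  defs <- list(spike = event_definition("spike", "relative_amplitude", k = 4,
                                        min_period_ms = 20, max_period_ms = 70))
  expect_equal(nrow(tidy(detect_events(s, defs))), 0)
})

test_that("a planted sharp wave is found once and never as a spike", {
  withr::with_seed(21, {
    x <- rnorm(1000, sd = 2)
  })
  idx <- 501:510 # 100 ms deflection
  x[idx] <- x[idx] + 60 * sin(pi * (seq_along(idx) - 0.5) / length(idx))
  s <- ts_series(x, sampling_period_ms = 10, domain_tag = "eeg")
  ev <- tidy(detect_events(s, eeg_definitions(k = 4)[c("spike", "sharp_wave")]))
  expect_equal(sum(ev$event_type == "sharp_wave"), 1)
  expect_equal(sum(ev$event_type == "spike"), 0)
  sw <- ev[ev$event_type == "sharp_wave", ]
  expect_gte(sw$duration_ms, 70)
  expect_lte(sw$duration_ms, 200)
})

test_that("spicules require a prominent opposite-polarity flank", {
  base <- rep(0.5, 600) * rep(c(1, -1), 300) # small alternating background
  plant <- function(x, at, len, amp) {
    x[at:(at + len - 1)] <- amp * sin(pi * (seq_len(len) - 0.5) / len)
    x
  }
  # lone sharp wave: no spicule
  x1 <- plant(base, 301, 10, 50)
  s1 <- ts_series(x1, 10, "lone", "eeg")
  ev1 <- tidy(detect_events(s1, eeg_definitions()))
  expect_equal(sum(ev1$event_type == "spicule"), 0)
  expect_equal(sum(ev1$event_type == "sharp_wave"), 1)

  # sharp wave followed directly by a large opposite deflection: spicule
  x2 <- plant(base, 301, 10, 50)
  x2[311:320] <- -40 * sin(pi * (1:10 - 0.5) / 10)
  s2 <- ts_series(x2, 10, "spic", "eeg")
  ev2 <- tidy(detect_events(s2, eeg_definitions()))
  expect_equal(sum(ev2$event_type == "spicule"), 2) # both flanks qualify
})

test_that("threshold runs merge across short gaps and honour min duration", {
  x <- rep(0, 200)
  x[51:60] <- 80; x[63:70] <- 90   # 20 ms gap
  x[150] <- 75                     # 10 ms blip
  s <- ts_series(x, 10, domain_tag = "stabilometry")
  ev <- tidy(detect_events(
    s, fall_definition(50, min_duration_ms = 100, merge_gap_ms = 30)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 50L)
  expect_equal(ev$end, 70L)
  # magnitude averages only the suprathreshold samples
  expect_equal(ev$magnitude, mean(c(rep(80, 10), rep(90, 8))))
})

test_that("detection is deterministic and self-consistent on re-check", {
  withr::with_seed(31, {
    ann <- generate_series(eeg_class_specs()$epileptic)
  })
  defs <- paroxysm_definition()
  d1 <- detect_events(ann$series, defs)
  d2 <- detect_events(ann$series, defs)
  expect_identical(d1$events, d2$events)
  expect_true(all(check_events(d1, defs)))

  x <- rep(0, 300); x[101:150] <- 120
  sf <- ts_series(x, 10, domain_tag = "stabilometry")
  df <- detect_events(sf, fall_definition(50))
  expect_true(all(check_events(df, fall_definition(50))))
})

test_that("planted events inside definition bounds are fully recalled", {
  defs <- paroxysm_definition()
  withr::with_seed(41, {
    for (i in 1:5) {
      ann <- generate_series(eeg_class_specs()$epileptic)
      det <- detect_events(ann$series, defs)
      counts <- match_event_sets(ann$events, det$events, min_overlap = 0.5)
      expect_equal(counts$n_match, counts$n_exp) # recall 1
      expect_setequal(unique(det$events$event_type),
                      intersect(unique(det$events$event_type), "paroxysm"))
    }
  })
})

test_that("rule files parse into validated definitions", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "fall:",
    "  trigger: threshold",
    "  threshold: 50",
    "  min_duration_ms: 100",
    "spike:",
    "  trigger: amplitude",
    "  k: 3",
    "  period_min_ms: 20",
    "  period_max_ms: 70"
  ), p)
  defs <- parse_definitions(p)
  expect_equal(defs$fall$trigger, "absolute_threshold")
  expect_equal(defs$fall$threshold, 50)
  expect_equal(defs$fall$min_duration_ms, 100)
  expect_equal(defs$spike$trigger, "relative_amplitude")
  expect_equal(defs$spike$k, 3)
  expect_equal(defs$spike$min_period_ms, 20)
  expect_equal(defs$spike$max_period_ms, 70)

  writeLines(c("bad:", "  trigger: amplitude", "  period_min_ms: 100",
               "  period_max_ms: 50"), p)
  expect_error(parse_definitions(p), "bad")

  for (f in c("eeg_rules.yaml", "stabilometry_rules.yaml", "paroxysm_rules.yaml")) {
    defs <- parse_definitions(system.file("extdata", f, package = "tsevents"))
    expect_gte(length(defs), 1)
  }
})

test_that("definitions reject contradictory trigger configuration", {
  expect_error(event_definition("x", "absolute_threshold"), "threshold")
  expect_error(event_definition("x", "relative_amplitude", threshold = 5),
               "one trigger mode")
  expect_error(event_definition("x", min_period_ms = 100, max_period_ms = 50),
               "exceeds")
})
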