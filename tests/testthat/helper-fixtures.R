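# Shared fixtures, built in code at test time.

# deterministic pseudo-random event table
random_events <- function(n, types = c("spike", "fall"), n_samples = 1000,
                          sampling_period_ms = 10) {
  if (n == 0) return(empty_events())
  start <- sort(sample.int(n_samples - 20, n))
  len <- sample(2:15, n, replace = TRUE)
  end <- pmin(start + len, n_samples)
  event_table(
    event_type = sample(types, n, replace = TRUE),
    start = start, end = end,
    magnitude = stats::runif(n, 10, 120),
    anchor = start + (end - start - 1L) %/% 2L,
    sampling_period_ms = sampling_period_ms
  )
}

# brute-force maximum-weight one-to-one assignment score over all injective
# maps from the smaller side into the larger (exhaustive; n <= 6 per side)
brute_force_match <- function(W) {
  na <- nrow(W); nb <- ncol(W)
  if (na == 0 || nb == 0) return(0)
  if (na > nb) return(brute_force_match(t(W)))
  best <- 0
  cols <- seq_len(nb)
  rec <- function(row, used, acc) {
    if (row > na) {
      best <<- max(best, acc)
      return()
    }
    # leave this row unmatched
    rec(row + 1L, used, acc)
    for (j in cols[!used]) {
      used[j] <- TRUE
      rec(row + 1L, used, acc + W[row, j])
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, nb), 0)
  best
}

# brute-force maximum-cardinality matching under an admissibility matrix
brute_force_cardinality <- function(adm) {
  brute_force_match(adm * 1)
}

# tiny two-measurement subject used in tree-structure tests
toy_subject <- function(id, values1, values2, label = NULL, age = 30) {
  s1 <- ts_series(values1, 10, paste0(id, "_a"), "eeg")
  s2 <- ts_series(values2, 10, paste0(id, "_b"), "eeg")
  subject_record(
    id,
    list(
      measurement_node("eeg", list(
        condition_node("rest", list(series_leaf(s1), value_leaf("age", age)))
      )),
      measurement_node("followup", list(
        condition_node("rest", list(series_leaf(s2)))
      ))
    ),
    class_label = label
  )
}

default_test_scaling <- function(weights = c(1, 1, 1)) {
  feature_scaling(200, 100, 10000, weights)
}
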