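#' Run the event-discovery pipeline
#'
#' One entry point behind the command-line tool, executing
#' clean -> detect -> (simulate | evaluate | compare | model | classify | cv)
#' and writing JSON results. Every run validates its configuration up front,
#' is seeded explicitly, and records the configuration hash and seed in the
#' result bundle so it can be reproduced exactly.
#'
#' Configuration keys (all optional unless a command needs them):
#' `rules` (rule file path, or one of `"eeg"`, `"stabilometry"`,
#' `"paroxysm"`), `domain`, `subjects` (character vector of subject XML
#' paths), `series` (one-column CSV path), `sampling_period_ms`,
#' `annotations` (two annotation files for `evaluate`), `min_overlap`,
#' `missing_sentinel`, `valid_range`, `validity_threshold`, `class_label`,
#' `tau_m`, `min_support`, `k` (CV folds), `n_per_class`,
#' `outlier_fraction`, `outlier_shift_sd`.
#'
#' @param command one of `"simulate"`, `"detect"`, `"evaluate"`,
#'   `"compare"`, `"model"`, `"classify"`, `"cv"`.
#' @param config configuration list, or path to a YAML file of the same.
#' @param seed integer seed for every stochastic step.
#' @param out_dir directory for result files; created if needed. `NULL`
#'   suppresses writing.
#' @return the result bundle (a list; contents depend on the command),
#'   invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(command = c("simulate", "detect", "evaluate",
                                     "compare", "model", "classify", "cv"),
                         config = list(), seed = 1L, out_dir = NULL) {
  command <- match.arg(command)
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  result <- switch(command,
    simulate = pipe_simulate(cfg, seed, out_dir),
    detect = pipe_detect(cfg, out_dir),
    evaluate = pipe_evaluate(cfg),
    compare = pipe_compare(cfg),
    model = pipe_model(cfg),
    classify = pipe_classify(cfg),
    cv = pipe_cv(cfg, seed)
  )
  bundle <- list(
    command = command,
    seed = seed,
    config_hash = rlang::hash(cfg),
    result = result
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      bundle, file.path(out_dir, paste0(command, "_result.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
    )
    invisible(bundle)
  } else {
    bundle
  }
}

validate_config <- function(config) {
  defaults <- list(
    domain = "generic", sampling_period_ms = 10, min_overlap = 0.5,
    validity_threshold = 0.70, tau_m = 0.3, min_support = 0.5, k = 10,
    n_per_class = 20, outlier_fraction = 0, outlier_shift_sd = 5
  )
  cfg <- utils::modifyList(defaults, config)
  in_range <- function(key, lo, hi, lo_open = FALSE) {
    v <- cfg[[key]]
    bad <- !is.numeric(v) || length(v) != 1 ||
      (if (lo_open) v <= lo else v < lo) || v > hi
    if (bad) {
      stop("config error: ", key, " = ", deparse(v), " outside (",
           lo, ", ", hi, "]", call. = FALSE)
    }
  }
  in_range("min_overlap", 0, 1, lo_open = TRUE)
  in_range("validity_threshold", 0, 1, lo_open = TRUE)
  in_range("tau_m", 0, 1)
  in_range("min_support", 0, 1, lo_open = TRUE)
  in_range("outlier_fraction", 0, 0.499999)
  if (cfg$k < 2) stop("config error: k must be >= 2", call. = FALSE)
  cfg
}

pipeline_rules <- function(cfg) {
  r <- cfg$rules %||% stop("config error: 'rules' is required", call. = FALSE)
  switch(r,
    eeg = eeg_definitions(),
    stabilometry = fall_definition(),
    paroxysm = paroxysm_definition(),
    parse_definitions(r)
  )
}

load_subjects <- function(cfg, definitions = NULL) {
  paths <- cfg$subjects %||% stop("config error: 'subjects' is required",
                                  call. = FALSE)
  subjects <- lapply(paths, read_subject_xml)
  subjects <- lapply(subjects, function(s) {
    map_leaves(s, function(l) {
      if (l$kind != "time_series") return(l)
      cl <- clean_series(l$series, cfg$missing_sentinel, cfg$valid_range,
                         cfg$validity_threshold)
      if (!cl$valid) {
        stop("series '", l$series$series_id, "' of subject '", s$subject_id,
             "' fails the ", 100 * cfg$validity_threshold,
             "% validity rule and cannot enter modelling", call. = FALSE)
      }
      l$series <- cl$series
      l
    })
  })
  if (!is.null(definitions)) {
    subjects <- lapply(subjects, annotate_subject, definitions = definitions)
  }
  subjects
}

pipeline_scaling <- function(subjects, cfg) {
  pooled <- dplyr::bind_rows(lapply(subjects, subject_events))
  scaling_from_events(pooled, domain = cfg$domain)
}

pipe_simulate <- function(cfg, seed, out_dir) {
  specs <- switch(cfg$domain,
    eeg = eeg_class_specs(),
    stabilometry = stabilometry_class_specs(),
    stop("config error: simulate needs domain 'eeg' or 'stabilometry'",
         call. = FALSE)
  )
  cohort <- generate_cohort(specs, cfg$n_per_class, cfg$outlier_fraction,
                            cfg$outlier_shift_sd, seed = seed)
  if (!is.null(out_dir)) {
    for (s in cohort$subjects) {
      write_subject_xml(s, file.path(out_dir, paste0(s$subject_id, ".xml")))
      truth <- subject_events(s)
      write_annotations(truth, file.path(out_dir, paste0(s$subject_id, "_truth.csv")))
    }
    jsonlite::write_json(cohort$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(manifest = cohort$manifest, n_subjects = nrow(cohort$manifest),
       cohort_hash = rlang::hash(cohort$subjects))
}

pipe_detect <- function(cfg, out_dir) {
  defs <- pipeline_rules(cfg)
  if (!is.null(cfg$series)) {
    series <- read_series_csv(cfg$series, cfg$sampling_period_ms)
    cl <- clean_series(series, cfg$missing_sentinel, cfg$valid_range,
                       cfg$validity_threshold)
    if (!cl$valid) stop("series fails the validity rule", call. = FALSE)
    ann <- detect_events(cl$series, defs)
    if (!is.null(out_dir)) {
      write_annotations(ann, file.path(out_dir, paste0(series$series_id,
                                                       "_events.csv")))
    }
    list(n_events = nrow(ann$events), events = ann$events)
  } else {
    subjects <- load_subjects(cfg, defs)
    evs <- lapply(subjects, subject_events)
    if (!is.null(out_dir)) {
      for (i in seq_along(subjects)) {
        write_annotations(evs[[i]], file.path(
          out_dir, paste0(subjects[[i]]$subject_id, "_events.csv")))
      }
    }
    list(n_events = sum(vapply(evs, nrow, numeric(1))))
  }
}

pipe_evaluate <- function(cfg) {
  paths <- cfg$annotations
  if (length(paths) != 2) {
    stop("config error: evaluate needs exactly 2 annotation files", call. = FALSE)
  }
  ref <- read_annotations(paths[1], cfg$sampling_period_ms)
  det <- read_annotations(paths[2], cfg$sampling_period_ms)
  counts <- match_event_sets(ref, det, cfg$min_overlap)
  list(
    n_exp = counts$n_exp, n_lang = counts$n_lang, n_match = counts$n_match,
    sim = sim_exp_lang(counts),
    sim_display = sim_display(sim_exp_lang(counts))
  )
}

pipe_compare <- function(cfg) {
  defs <- pipeline_rules(cfg)
  subjects <- load_subjects(cfg, defs)
  if (length(subjects) != 2) {
    stop("config error: compare needs exactly 2 subjects", call. = FALSE)
  }
  scaling <- pipeline_scaling(subjects, cfg)
  rep <- subject_similarity(subjects[[1]], subjects[[2]], scaling)
  list(overall = rep$overall, node_scores = rep$node_scores)
}

pipe_model <- function(cfg) {
  defs <- pipeline_rules(cfg)
  subjects <- load_subjects(cfg, defs)
  label <- cfg$class_label %||% stop("config error: 'class_label' is required",
                                     call. = FALSE)
  scaling <- pipeline_scaling(subjects, cfg)
  if (length(subjects) >= 3) {
    S <- pairwise_similarity_matrix(subjects, scaling)
    verdicts <- detect_outliers(S)
    subjects <- subjects[!verdicts$is_outlier]
  }
  model <- build_reference_model(subjects, label, scaling,
                                 tau_m = cfg$tau_m, min_support = cfg$min_support)
  list(class_label = label, events = tidy(model), summary = glance(model))
}

pipe_classify <- function(cfg) {
  defs <- pipeline_rules(cfg)
  subjects <- load_subjects(cfg, defs)
  new_path <- cfg$new_subject %||% stop("config error: 'new_subject' is required",
                                        call. = FALSE)
  p_new <- annotate_subject(read_subject_xml(new_path), defs)
  clf <- train_classifier(subjects, domain = cfg$domain,
                          tau_m = cfg$tau_m, min_support = cfg$min_support)
  res <- classify_subject(p_new, clf)
  list(subject_id = p_new$subject_id, class_label = res$class_label,
       tie = res$tie, scores = res$scores)
}

pipe_cv <- function(cfg, seed) {
  defs <- pipeline_rules(cfg)
  subjects <- load_subjects(cfg, defs)
  cv <- cross_validate(subjects, k = cfg$k, seed = seed, domain = cfg$domain,
                       tau_m = cfg$tau_m, min_support = cfg$min_support)
  list(overall_accuracy = cv$overall_accuracy, per_class = cv$per_class,
       assignments = cv$assignments)
}
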