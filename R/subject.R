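#' Hierarchical subject records
#'
#' A subject is modelled as a fixed three-level tree mirroring how clinical
#' examinations are organised: a *register* (the subject's record) contains
#' *measurements* (e.g. an EEG recording, a posturographic test), each
#' containing *conditions* (e.g. eyes open / eyes closed), each holding
#' leaves — time series or single quantitative/qualitative values.
#'
#' `measurement_node()`, `condition_node()`, `series_leaf()` and
#' `value_leaf()` build the tree; `subject_record()` assembles it.
#'
#' @param subject_id register identifier.
#' @param measurements list of `measurement_node()`s (at least one).
#' @param class_label optional class label (e.g. "epileptic").
#' @return an object of class `subject_record`.
#' @examples
#' s <- ts_series(rnorm(50), 10, "s1", "eeg")
#' subj <- subject_record(
#'   "p1",
#'   list(measurement_node("eeg", list(
#'     condition_node("rest", list(series_leaf(s), value_leaf("age", 31)))
#'   ))),
#'   class_label = "healthy"
#' )
#' @export
subject_record <- function(subject_id, measurements, class_label = NULL) {
  if (!is.list(measurements) || length(measurements) == 0) {
    stop("a subject needs at least one measurement", call. = FALSE)
  }
  for (m in measurements) {
    if (!identical(m$kind, "measurement")) {
      stop("measurements must be built with measurement_node()", call. = FALSE)
    }
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      class_label = if (is.null(class_label)) NULL else as.character(class_label),
      measurements = measurements
    ),
    class = "subject_record"
  )
}

#' @rdname subject_record
#' @param name node name.
#' @param conditions list of `condition_node()`s.
#' @export
measurement_node <- function(name, conditions) {
  for (cn in conditions) {
    if (!identical(cn$kind, "condition")) {
      stop("conditions must be built with condition_node()", call. = FALSE)
    }
  }
  list(kind = "measurement", name = as.character(name), conditions = conditions)
}

#' @rdname subject_record
#' @param leaves list of `series_leaf()` / `value_leaf()` objects.
#' @export
condition_node <- function(name, leaves) {
  for (l in leaves) {
    if (!l$kind %in% c("time_series", "quantitative", "qualitative")) {
      stop("leaves must be series_leaf() or value_leaf()", call. = FALSE)
    }
  }
  list(kind = "condition", name = as.character(name), leaves = leaves)
}

#' @rdname subject_record
#' @param series a [ts_series()].
#' @param events optional event table annotating the series.
#' @export
series_leaf <- function(series, events = NULL) {
  stopifnot(inherits(series, "ts_series"))
  list(kind = "time_series", name = series$series_id, series = series,
       events = events)
}

#' @rdname subject_record
#' @param value a single value.
#' @param kind `"quantitative"` (numeric) or `"qualitative"` (categorical).
#' @export
value_leaf <- function(name, value, kind = c("quantitative", "qualitative")) {
  kind <- match.arg(kind)
  if (kind == "quantitative" && !is.numeric(value)) {
    stop("quantitative leaf '", name, "' needs a numeric value", call. = FALSE)
  }
  list(kind = kind, name = as.character(name),
       value = if (kind == "quantitative") as.numeric(value) else as.character(value))
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record '%s'>%s\n", x$subject_id,
              if (is.null(x$class_label)) "" else paste0(" class=", x$class_label)))
  for (m in x$measurements) {
    cat("  measurement:", m$name, "\n")
    for (cn in m$conditions) {
      leaves <- vapply(cn$leaves, function(l) {
        if (l$kind == "time_series") {
          sprintf("%s[%d samples%s]", l$name, n_samples(l$series),
                  if (is.null(l$events)) "" else sprintf(", %d events", nrow(l$events)))
        } else sprintf("%s=%s", l$name, l$value)
      }, character(1))
      cat("    condition:", cn$name, "->", paste(leaves, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

# Apply fn(leaf, path) over all leaves, collecting results in a list.
walk_leaves <- function(subject, fn) {
  out <- list()
  for (m in subject$measurements) {
    for (cn in m$conditions) {
      for (l in cn$leaves) {
        path <- paste(subject$subject_id, m$name, cn$name, l$name, sep = "/")
        out[[path]] <- fn(l, path)
      }
    }
  }
  out
}

# Transform every leaf in place with fn(leaf).
map_leaves <- function(subject, fn) {
  subject$measurements <- lapply(subject$measurements, function(m) {
    m$conditions <- lapply(m$conditions, function(cn) {
      cn$leaves <- lapply(cn$leaves, fn)
      cn
    })
    m
  })
  subject
}

#' Detect events in every series of a subject
#'
#' Runs [detect_events()] on each time-series leaf and stores the resulting
#' event table on the leaf, making the subject comparable with
#' [subject_similarity()] and usable for modelling.
#'
#' @param subject a [subject_record()].
#' @param definitions event definitions (see [detect_events()]).
#' @return the subject with annotated series leaves.
#' @export
annotate_subject <- function(subject, definitions) {
  stopifnot(inherits(subject, "subject_record"))
  map_leaves(subject, function(l) {
    if (l$kind == "time_series") {
      l$events <- detect_events(l$series, definitions)$events
    }
    l
  })
}

#' Pool all events of a subject
#'
#' @param subject an annotated [subject_record()].
#' @return an event table with an extra `series_path` column identifying the
#'   contributing series leaf.
#' @export
subject_events <- function(subject) {
  stopifnot(inherits(subject, "subject_record"))
  parts <- walk_leaves(subject, function(l, path) {
    if (l$kind != "time_series") return(NULL)
    if (is.null(l$events)) {
      stop("series leaf '", path, "' is not annotated; run annotate_subject() first",
           call. = FALSE)
    }
    dplyr::mutate(l$events, series_path = path)
  })
  parts <- purrr::compact(parts)
  if (length(parts) == 0) return(dplyr::mutate(empty_events(), series_path = character()))
  dplyr::bind_rows(parts)
}

#' Read and write subject XML documents
#'
#' The canonical subject document mirrors the register/measurement/condition
#' hierarchy:
#'
#' ```xml
#' <register id="p1" class="healthy">
#'   <measurement name="eeg">
#'     <condition name="rest">
#'       <series id="s1" sampling_period_ms="10" domain="eeg">0.5 1 -2 ...</series>
#'       <value name="age" kind="quantitative">31</value>
#'     </condition>
#'   </measurement>
#' </register>
#' ```
#'
#' Series samples are whitespace-separated and written in shortest
#' round-trippable decimal form, so a write/read round trip preserves values
#' exactly. Structural violations are reported with the path of the offending
#' element.
#'
#' @param path file path.
#' @return `read_subject_xml()`: a [subject_record()];
#'   `write_subject_xml()`: `path` invisibly.
#' @export
read_subject_xml <- function(path) {
  if (!file.exists(path)) stop("subject file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  if (root != "register") {
    stop("schema violation at /", root, ": document root must be <register>",
         call. = FALSE)
  }
  id <- xml2::xml_attr(doc, "id")
  if (is.na(id)) stop("schema violation at /register: missing 'id' attribute",
                      call. = FALSE)
  cls <- xml2::xml_attr(doc, "class")
  meas_nodes <- xml2::xml_children(doc)
  if (length(meas_nodes) == 0) {
    stop("schema violation at /register: no <measurement> children", call. = FALSE)
  }
  measurements <- lapply(meas_nodes, function(m) {
    mpath <- paste0("/register/", xml2::xml_name(m))
    if (xml2::xml_name(m) != "measurement") {
      stop("schema violation at ", mpath, ": expected <measurement>", call. = FALSE)
    }
    mname <- xml2::xml_attr(m, "name")
    if (is.na(mname)) stop("schema violation at ", mpath, ": missing 'name'",
                           call. = FALSE)
    conds <- lapply(xml2::xml_children(m), function(cn) {
      cpath <- paste0("/register/measurement[", mname, "]/", xml2::xml_name(cn))
      if (xml2::xml_name(cn) != "condition") {
        stop("schema violation at ", cpath, ": expected <condition>", call. = FALSE)
      }
      cname <- xml2::xml_attr(cn, "name")
      if (is.na(cname)) stop("schema violation at ", cpath, ": missing 'name'",
                             call. = FALSE)
      leaves <- lapply(xml2::xml_children(cn), function(l) {
        lname <- xml2::xml_name(l)
        lpath <- paste0(cpath, "[", cname, "]/", lname)
        if (lname == "series") {
          sid <- xml2::xml_attr(l, "id")
          sp <- as.numeric(xml2::xml_attr(l, "sampling_period_ms"))
          if (is.na(sp)) sp <- 10
          dom <- xml2::xml_attr(l, "domain")
          if (is.na(dom)) dom <- "generic"
          toks <- strsplit(trimws(xml2::xml_text(l)), "\\s+")[[1]]
          vals <- suppressWarnings(as.numeric(toks))
          if (length(vals) == 0 || anyNA(vals)) {
            stop("schema violation at ", lpath, ": samples must be numeric",
                 call. = FALSE)
          }
          series_leaf(ts_series(vals, sp, if (is.na(sid)) "series" else sid,
                                domain_tag = dom))
        } else if (lname == "value") {
          vname <- xml2::xml_attr(l, "name")
          kind <- xml2::xml_attr(l, "kind")
          if (is.na(vname) || is.na(kind) ||
              !kind %in% c("quantitative", "qualitative")) {
            stop("schema violation at ", lpath,
                 ": <value> needs name and kind in {quantitative, qualitative}",
                 call. = FALSE)
          }
          txt <- trimws(xml2::xml_text(l))
          value_leaf(vname,
                     if (kind == "quantitative") as.numeric(txt) else txt,
                     kind)
        } else {
          stop("schema violation at ", lpath, ": expected <series> or <value>",
               call. = FALSE)
        }
      })
      condition_node(cname, leaves)
    })
    measurement_node(mname, conds)
  })
  subject_record(id, measurements, class_label = if (is.na(cls)) NULL else cls)
}

#' @rdname read_subject_xml
#' @param subject a [subject_record()].
#' @export
write_subject_xml <- function(subject, path) {
  stopifnot(inherits(subject, "subject_record"))
  doc <- xml2::xml_new_root("register", id = subject$subject_id)
  if (!is.null(subject$class_label)) {
    xml2::xml_set_attr(doc, "class", subject$class_label)
  }
  for (m in subject$measurements) {
    mn <- xml2::xml_add_child(doc, "measurement", name = m$name)
    for (cn in m$conditions) {
      cnn <- xml2::xml_add_child(mn, "condition", name = cn$name)
      for (l in cn$leaves) {
        if (l$kind == "time_series") {
          sn <- xml2::xml_add_child(
            cnn, "series", id = l$series$series_id,
            sampling_period_ms = format_sample(l$series$sampling_period_ms),
            domain = l$series$domain_tag
          )
          xml2::xml_set_text(sn, paste(format_sample(l$series$values),
                                       collapse = " "))
        } else {
          vn <- xml2::xml_add_child(cnn, "value", name = l$name, kind = l$kind)
          xml2::xml_set_text(vn, if (is.numeric(l$value)) {
            format_sample(l$value)
          } else as.character(l$value))
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
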