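#' Event-count agreement bookkeeping
#'
#' Holds the three counts entering the agreement metric: the number of events
#' in a reference (expert) annotation, the number found by the detector
#' ("language"), and the number matched between the two.
#'
#' @param n_exp events in the expert/reference set.
#' @param n_lang events in the detected set.
#' @param n_match matched events (at most `min(n_exp, n_lang)`).
#' @return an object of class `evaluation_counts`.
#' @export
evaluation_counts <- function(n_exp, n_lang, n_match) {
  n_exp <- as.integer(n_exp); n_lang <- as.integer(n_lang); n_match <- as.integer(n_match)
  if (any(c(n_exp, n_lang, n_match) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (n_match > min(n_exp, n_lang)) {
    stop("n_match cannot exceed min(n_exp, n_lang)", call. = FALSE)
  }
  structure(list(n_exp = n_exp, n_lang = n_lang, n_match = n_match),
            class = "evaluation_counts")
}

#' @export
print.evaluation_counts <- function(x, ...) {
  cat(sprintf("<evaluation_counts> expert %d | detected %d | matched %d | SIM %.4f\n",
              x$n_exp, x$n_lang, x$n_match, sim_exp_lang(x)))
  invisible(x)
}

#' Match a detected event set against a reference set
#'
#' Finds the one-to-one matching of maximum size between a reference
#' (expert) event set and a detected set, where a pair is admissible when the
#' two events have the same type and their intervals overlap by at least
#' `min_overlap` of the shorter event. Solved as maximum-cardinality
#' bipartite matching.
#'
#' @param reference,detected event tables (see [event_table()]).
#' @param min_overlap required overlap fraction of the shorter event, in
#'   (0, 1]; default 0.5.
#' @return an [evaluation_counts()] with `n_exp = nrow(reference)`,
#'   `n_lang = nrow(detected)` and the matched count.
#' @seealso [sim_exp_lang()]
#' @export
match_event_sets <- function(reference, detected, min_overlap = 0.5) {
  if (!is.numeric(min_overlap) || min_overlap <= 0 || min_overlap > 1) {
    stop("min_overlap must be in (0, 1]", call. = FALSE)
  }
  na <- nrow(reference); nb <- nrow(detected)
  if (na == 0 || nb == 0) return(evaluation_counts(na, nb, 0))
  ov <- overlap_fraction(reference, detected)
  adm <- ov >= min_overlap &
    outer(reference$event_type, detected$event_type, "==")
  n_match <- max_cardinality_matching(adm)
  evaluation_counts(na, nb, n_match)
}

# fraction of the shorter event covered by the intersection, as a na x nb matrix
overlap_fraction <- function(a, b) {
  inter_lo <- outer(a$start, b$start, pmax)
  inter_hi <- outer(a$end, b$end, pmin)
  inter <- pmax(inter_hi - inter_lo, 0)
  shorter <- outer(a$end - a$start, b$end - b$start, pmin)
  inter / shorter
}

max_cardinality_matching <- function(adm) {
  edges <- which(adm, arr.ind = TRUE)
  if (nrow(edges) == 0) return(0L)
  na <- nrow(adm); nb <- ncol(adm)
  g <- igraph::make_bipartite_graph(
    c(rep(FALSE, na), rep(TRUE, nb)),
    as.vector(t(cbind(edges[, 1], na + edges[, 2])))
  )
  igraph::max_bipartite_match(g)$matching_size
}

#' Agreement between expert and detected event sets
#'
#' The Dice-style agreement metric
#' \deqn{SIM = \frac{2\,\#matched}{\#expert + \#detected}}
#' normalised to \[0, 1\], where 1 means every expert event was detected and
#' nothing extra was reported. When both sets are empty the metric is defined
#' as 1 (vacuous perfect agreement).
#'
#' @param counts an [evaluation_counts()], or `n_exp` when the three counts
#'   are given separately.
#' @param n_lang,n_match optional separate counts.
#' @return a number in \[0, 1\].
#' @examples
#' sim_exp_lang(evaluation_counts(1446, 1496, 1412)) # 0.9599...
#' @export
sim_exp_lang <- function(counts, n_lang = NULL, n_match = NULL) {
  if (!inherits(counts, "evaluation_counts")) {
    counts <- evaluation_counts(counts, n_lang, n_match)
  }
  tot <- counts$n_exp + counts$n_lang
  if (tot == 0) return(1)
  2 * counts$n_match / tot
}

#' Display rounding for similarity values
#'
#' Published agreement tables truncate (rather than round) to three decimals;
#' both conventions are provided.
#'
#' @param x numeric values.
#' @param digits decimal places (default 3).
#' @param method `"truncate"` (default) or `"round"`.
#' @return numeric values cut to `digits` decimals.
#' @export
sim_display <- function(x, digits = 3, method = c("truncate", "round")) {
  method <- match.arg(method)
  f <- 10^digits
  if (method == "truncate") trunc(x * f + 1e-12) / f else round(x, digits)
}

#' Confusion-matrix indicators
#'
#' Precision, recall (sensitivity), specificity and accuracy from a 2x2
#' confusion matrix, as percentages on the 0-100 scale. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param tp,fn,fp,tn confusion-matrix cells (true/false positives/negatives).
#' @return a tibble with columns `metric`, `value` (exact percentage) and
#'   `display` (rounded to 1 decimal).
#' @examples
#' confusion_metrics(tp = 11, fn = 1, fp = 3, tn = 185)
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion-matrix cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  vals <- c(
    precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy = ratio(tp + tn, tp + tn + fp + fn)
  )
  tibble::tibble(
    metric = names(vals),
    value = unname(vals),
    display = round(unname(vals), 1)
  )
}
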