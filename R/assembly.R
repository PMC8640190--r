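#' Per-word classifier scores
#'
#' Token classifiers built on sub-word tokenizers emit one score vector per
#' sub-token; span assembly needs them in a simple tabular form that any
#' external model can export: one row per sub-token with the word's character
#' interval, the sub-token index within the word, and one numeric column per
#' entity class (plus a no-entity class in softmax mode). Words are identified
#' by their `(doc_id, word_start, word_end)` interval; intervals of a document
#' must be non-overlapping and are processed in offset order.
#'
#' `token_scores()` validates such a table and returns it with the label
#' columns recorded in the `score_labels` attribute.
#'
#' @param scores A data frame with columns `doc_id`, `word_start`, `word_end`,
#'   `subtoken`, plus one numeric column per label.
#' @param labels Character vector naming the score columns; defaults to every
#'   column that is not a coordinate column.
#'
#' @return A tibble with attribute `score_labels`.
#' @export
token_scores <- function(scores, labels = NULL) {
  scores <- as_tibble(scores)
  coord <- c("doc_id", "word_start", "word_end", "subtoken")
  missing_cols <- setdiff(coord, names(scores))
  if (length(missing_cols)) {
    abort_config(paste0(
      "token scores need columns ",
      paste0("`", missing_cols, "`", collapse = ", "), "."
    ))
  }
  labels <- labels %||% setdiff(names(scores), coord)
  if (!length(labels)) abort_config("token scores need at least one label column.")
  bad <- labels[!vapply(scores[labels], is.numeric, logical(1))]
  if (length(bad)) {
    abort_config(paste0("score columns must be numeric: ", paste(bad, collapse = ", ")))
  }
  scores$doc_id <- as.character(scores$doc_id)
  scores$word_start <- as.integer(scores$word_start)
  scores$word_end <- as.integer(scores$word_end)
  attr(scores, "score_labels") <- labels
  scores
}

score_labels <- function(scores) {
  attr(scores, "score_labels") %||%
    setdiff(names(scores), c("doc_id", "word_start", "word_end", "subtoken"))
}

#' Pool sub-token scores to word-level scores
#'
#' A word split into several sub-tokens carries several score vectors; the
#' word's label is decided from a single pooled vector. The default pools by
#' the per-label maximum across the word's sub-tokens; `"mean"` and `"first"`
#' (the first sub-token's vector, as many transformer taggers use) are
#' offered as alternatives.
#'
#' @param scores A [token_scores()] table.
#' @param method Pooling rule: `"max"` (default), `"mean"` or `"first"`.
#'
#' @return A tibble with one row per word (columns `doc_id`, `word_start`,
#'   `word_end`, then the pooled label columns), ordered by document and word
#'   offset, `score_labels` attribute preserved.
#' @export
pool_subtokens <- function(scores, method = c("max", "mean", "first")) {
  method <- match.arg(method)
  scores <- token_scores(scores)
  if (!nrow(scores)) {
    abort_config("cannot pool an empty sub-token collection.")
  }
  labels <- score_labels(scores)
  scores <- arrange(scores, .data$doc_id, .data$word_start, .data$subtoken)
  fun <- switch(method,
    max = function(x) max(x),
    mean = function(x) mean(x),
    first = function(x) x[[1]]
  )
  pooled <- summarise(
    group_by(scores, .data$doc_id, .data$word_start, .data$word_end),
    across(all_of(labels), fun),
    .groups = "drop"
  )
  pooled <- arrange(pooled, .data$doc_id, .data$word_start)
  ov <- pooled$doc_id == lag(pooled$doc_id) &
    pooled$word_start < lag(pooled$word_end)
  if (any(ov, na.rm = TRUE)) {
    abort_integrity("word intervals within a document must be non-overlapping.")
  }
  attr(pooled, "score_labels") <- labels
  pooled
}

# argmax with deterministic tie-breaking by column order (inventory order,
# no-entity class expected last); reports how many ties were resolved
argmax_labels <- function(mat, labels) {
  idx <- max.col(mat, ties.method = "first")
  n_ties <- sum(rowSums(mat == mat[cbind(seq_len(nrow(mat)), idx)]) > 1L)
  if (n_ties > 0L) {
    inform(sprintf(
      "%d word(s) had tied top scores; resolved by class-inventory order.", n_ties
    ))
  }
  labels[idx]
}

# maximal runs of adjacent active words -> spans; `active` logical per word
runs_to_spans <- function(words, active, label) {
  if (!any(active)) {
    return(tibble(
      doc_id = character(), start = integer(), end = integer(), label = character()
    ))
  }
  new_doc <- words$doc_id != lag(words$doc_id, default = "\r\r")
  run_id <- cumsum(new_doc | active != lag(active, default = FALSE) | !active)
  w <- words[active, ]
  g <- run_id[active]
  tibble(
    doc_id = tapply(w$doc_id, g, `[`, 1L)[as.character(unique(g))],
    start = as.integer(tapply(w$word_start, g, min)[as.character(unique(g))]),
    end = as.integer(tapply(w$word_end, g, max)[as.character(unique(g))]),
    label = label
  )
}

#' Decode single-label (softmax) token scores into entity spans
#'
#' Each word receives the label with the highest pooled score; maximal runs of
#' adjacent words sharing the same entity label are merged into one span (the
#' phrase rule: adjacency is word adjacency in the sequence, whatever
#' characters lie between), and words decoded as the no-entity class emit
#' nothing. The resulting spans never overlap. Exact ties at the argmax are
#' resolved deterministically by class-inventory column order (no-entity
#' last) and reported via a message.
#'
#' @param scores A [token_scores()] table whose label columns form a
#'   probability distribution per sub-token (checked to sum to 1 within
#'   `1e-6`).
#' @param none_label Name of the no-entity score column (default `"O"`).
#' @param pooling Sub-token pooling rule, see [pool_subtokens()].
#' @param corpus Optional corpus used to fill span surfaces.
#'
#' @return An [annotation_set()] whose inventory is the label columns minus
#'   `none_label`.
#' @export
decode_softmax <- function(scores, none_label = "O",
                           pooling = c("max", "mean", "first"),
                           corpus = NULL) {
  scores <- token_scores(scores)
  labels <- score_labels(scores)
  if (!none_label %in% labels) {
    abort_config(sprintf("no-entity column %s not found in the scores.", dQuote(none_label)))
  }
  entity_labels <- setdiff(labels, none_label)
  if (nrow(scores)) {
    sums <- rowSums(as.matrix(scores[labels]))
    if (any(abs(sums - 1) > 1e-6)) {
      abort_integrity("softmax score vectors must sum to 1 (tolerance 1e-6).")
    }
  } else {
    return(annotation_set(NULL, class_inventory = entity_labels))
  }
  pooled <- pool_subtokens(scores, method = pooling)
  ordered_labels <- c(entity_labels, none_label)  # no-entity loses ties
  mat <- as.matrix(pooled[ordered_labels])
  word_label <- argmax_labels(mat, ordered_labels)
  spans <- bind_rows(lapply(entity_labels, function(lb) {
    runs_to_spans(pooled, word_label == lb, lb)
  }))
  res <- annotation_set(spans, class_inventory = entity_labels)
  if (!is.null(corpus)) {
    res <- annotation_set(fill_surfaces(as_tibble(res), corpus), entity_labels)
    check_surfaces(res, corpus)
  }
  res
}

#' Decode multi-label (sigmoid) token scores into entity spans
#'
#' Each label is decoded independently: words whose pooled score reaches the
#' cutoff are active, and maximal runs of adjacent active words become one
#' span. Spans of different labels may overlap or nest — this is the decoder
#' used for nested-entity corpora — while spans of the same label never
#' overlap.
#'
#' @param scores A [token_scores()] table of independent per-label
#'   probabilities in `[0, 1]`.
#' @param cutoff Activation threshold, strictly between 0 and 1 (default 0.5).
#' @inheritParams decode_softmax
#'
#' @return An [annotation_set()] over the score labels.
#' @export
decode_sigmoid <- function(scores, cutoff = 0.5,
                           pooling = c("max", "mean", "first"),
                           corpus = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1) {
    abort_config("`cutoff` must be a single probability strictly between 0 and 1.")
  }
  scores <- token_scores(scores)
  labels <- score_labels(scores)
  if (!nrow(scores)) return(annotation_set(NULL, class_inventory = labels))
  mat <- as.matrix(scores[labels])
  if (any(mat < 0 | mat > 1)) {
    abort_integrity("sigmoid scores must lie in [0, 1].")
  }
  pooled <- pool_subtokens(scores, method = pooling)
  spans <- bind_rows(lapply(labels, function(lb) {
    runs_to_spans(pooled, pooled[[lb]] >= cutoff, lb)
  }))
  res <- annotation_set(spans, class_inventory = labels)
  if (!is.null(corpus)) {
    res <- annotation_set(fill_surfaces(as_tibble(res), corpus), labels)
    check_surfaces(res, corpus)
  }
  res
}
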