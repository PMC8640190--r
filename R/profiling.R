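#' Normalize a surface form
#'
#' Passage identity for label-consistency and frequency profiling is the
#' normalized surface form: case-folded, internal whitespace collapsed to a
#' single space, leading/trailing whitespace stripped.
#'
#' @param x Character vector of surface strings.
#' @return Normalized character vector.
#' @export
normalize_surface <- function(x) {
  trimws(gsub("\\s+", " ", tolower(x), perl = TRUE))
}

#' Entity class distribution
#'
#' Per-label span counts and percentage shares (share = 100 * count / total,
#' rounded to one decimal for presentation, as in corpus summary tables).
#' Every inventory label appears, including zero-count ones; the result is
#' independent of document order.
#'
#' @param gold An [annotation_set()].
#' @return A tibble with columns `label`, `count`, `share`, ordered by label;
#'   the grand total is attached as attribute `total`.
#' @export
entity_distribution <- function(gold) {
  inv <- class_inventory(gold)
  counts <- as.integer(table(factor(gold$label, levels = inv)))
  total <- sum(counts)
  tibble(
    label = inv,
    count = counts,
    share = if (total > 0) round(100 * counts / total, 1) else rep(NA_real_, length(inv))
  ) -> out
  attr(out, "total") <- total
  out
}

# word count of a surface string (whitespace-delimited)
surface_word_count <- function(x) {
  lengths(strsplit(trimws(x), "\\s+", perl = TRUE))
}

# label integer bins by lower edges (last bin open-ended)
bin_by_edges <- function(x, edges) {
  edges <- sort(unique(as.integer(edges)))
  labels <- vapply(seq_along(edges), function(i) {
    lo <- edges[i]
    hi <- if (i < length(edges)) edges[i + 1L] - 1L else NA_integer_
    if (is.na(hi)) paste0(lo, "+") else if (hi == lo) as.character(lo) else paste0(lo, "-", hi)
  }, character(1))
  idx <- findInterval(x, edges)
  if (any(idx == 0L)) {
    abort_config("values below the first bin edge; extend `bins` downward.")
  }
  factor(labels[idx], levels = labels)
}

# shared engine: score predictions against gold within bins defined per span.
# gold_bin: factor over gold spans; pred_bin: factor over pred spans (used for
# unmatched predictions; matched predictions inherit their gold span's bin).
binned_scores <- function(pred, gold, gold_bin, pred_bin) {
  pk <- span_key(pred)
  gk <- span_key(gold)
  hit <- pk %in% gk
  lv <- levels(gold_bin)
  tp_bin <- gold_bin[match(pk[hit], gk)]
  fp_bin <- pred_bin[!hit]
  fn_bin <- gold_bin[!(gk %in% pk)]
  out <- tibble(
    bin = factor(lv, levels = lv),
    tp = as.integer(table(tp_bin)),
    fp = as.integer(table(fp_bin)),
    fn = as.integer(table(fn_bin))
  )
  ner_score(out)
}

#' Scoring stratified by entity length
#'
#' Gold spans are binned by their length in whitespace-delimited words
#' (character length available via `unit = "chars"`); exact-match scoring is
#' then computed within each bin. Matched predictions inherit the bin of the
#' gold span they match; unmatched predictions (FPs) are binned by their own
#' length. Bins partition the gold spans, so per-bin TP+FN totals sum to the
#' global gold count.
#'
#' @param pred,gold [annotation_set()]s with surfaces available (needed to
#'   measure length in words).
#' @param bins Integer lower bin edges; the last bin is open-ended. Default
#'   `c(1, 2, 3, 6, 11)` gives bins 1, 2, 3–5, 6–10, 11+.
#' @param unit `"words"` (default) or `"chars"`.
#'
#' @return A tibble with one row per bin: `bin`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
score_by_length <- function(pred, gold, bins = c(1, 2, 3, 6, 11),
                            unit = c("words", "chars")) {
  unit <- match.arg(unit)
  measure <- function(x) {
    if (anyNA(x$surface)) {
      abort_config("surfaces are required to measure entity length.")
    }
    if (unit == "words") surface_word_count(x$surface) else nchar(x$surface)
  }
  binned_scores(
    pred, gold,
    gold_bin = bin_by_edges(measure(gold), bins),
    pred_bin = bin_by_edges(measure(pred), bins)
  )
}

#' Scoring stratified by training-corpus entity frequency
#'
#' Each test gold span is binned by how often its normalized surface form
#' occurs as a gold annotation in the training set (0 for unseen forms);
#' scoring within bins as in [score_by_length()], with unmatched predictions
#' binned by their own surface form's training frequency.
#'
#' @param pred,gold_test [annotation_set()]s over the evaluation corpus.
#' @param gold_train The training gold [annotation_set()] supplying the
#'   frequency counts.
#' @param bins Integer lower bin edges over occurrence counts; default
#'   `c(0, 1, 2, 6, 21)` gives bins 0, 1, 2–5, 6–20, 21+.
#'
#' @return A tibble as in [score_by_length()].
#' @export
score_by_frequency <- function(pred, gold_test, gold_train,
                               bins = c(0, 1, 2, 6, 21)) {
  if (anyNA(gold_train$surface) || anyNA(gold_test$surface) || anyNA(pred$surface)) {
    abort_config("surfaces are required for frequency profiling.")
  }
  train_counts <- table(normalize_surface(gold_train$surface))
  freq_of <- function(x) {
    n <- train_counts[normalize_surface(x$surface)]
    as.integer(ifelse(is.na(n), 0L, n))
  }
  binned_scores(
    pred, gold_test,
    gold_bin = bin_by_edges(freq_of(gold_test), bins),
    pred_bin = bin_by_edges(freq_of(pred), bins)
  )
}

#' Label consistency of passages
#'
#' A passage is a normalized surface form that carries an annotation
#' somewhere in the corpus. The profile records, per distinct form, the set
#' of distinct labels it was ever assigned, together with a histogram of
#' forms by number of distinct labels — the share of forms with two or more
#' labels measures the annotation ambiguity of the corpus.
#'
#' @param gold An [annotation_set()] with surfaces.
#' @return A list with `forms` (tibble: `surface`, `labels` list-column,
#'   `n_labels`, `n_occurrences`) and `histogram` (tibble: `n_labels`,
#'   `n_forms`, `share` in percent of distinct forms).
#' @export
multilabel_passages <- function(gold) {
  if (nrow(gold) && anyNA(gold$surface)) {
    abort_config("surfaces are required for passage profiling.")
  }
  if (!nrow(gold)) {
    return(list(
      forms = tibble(surface = character(), labels = list(),
                     n_labels = integer(), n_occurrences = integer()),
      histogram = tibble(n_labels = integer(), n_forms = integer(), share = numeric())
    ))
  }
  norm <- normalize_surface(gold$surface)
  by_form <- split(gold$label, norm)
  forms <- tibble(
    surface = names(by_form),
    labels = unname(lapply(by_form, function(x) sort(unique(x)))),
    n_labels = unname(vapply(by_form, function(x) length(unique(x)), integer(1))),
    n_occurrences = unname(lengths(by_form))
  )
  hist_tab <- table(forms$n_labels)
  histogram <- tibble(
    n_labels = as.integer(names(hist_tab)),
    n_forms = as.integer(hist_tab),
    share = 100 * as.integer(hist_tab) / nrow(forms)
  )
  list(forms = forms, histogram = histogram)
}
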