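#' Exact span matching against a gold standard
#'
#' A prediction counts as a true positive only when its document, start
#' offset, end offset and label all equal a gold annotation's — the strict
#' matching condition of the challenge metrics. Per label: TP is the number
#' of predicted spans present in gold, FP the predicted spans absent from
#' gold, FN the gold spans absent from the predictions. Every label of the
#' shared class inventory gets a row, including labels with no spans at all.
#'
#' @param pred,gold [annotation_set()]s sharing a class inventory. Exact
#'   duplicate spans were already collapsed by the annotation-set invariant,
#'   so duplicated gold artifacts count once.
#'
#' @return A tibble with columns `label`, `tp`, `fp`, `fn`.
#' @export
match_exact <- function(pred, gold) {
  inv <- sort(union(class_inventory(pred), class_inventory(gold)))
  pk <- span_key(pred)
  gk <- span_key(gold)
  hit <- pk %in% gk
  counts_of <- function(labels) {
    t <- table(factor(labels, levels = inv))
    as.integer(t)
  }
  tibble(
    label = inv,
    tp = counts_of(pred$label[hit]),
    fp = counts_of(pred$label[!hit]),
    fn = counts_of(gold$label[!(gk %in% pk)])
  )
}

#' Precision, recall and F1 from match counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), reported on the percent
#' scale used by the challenge leaderboards. A zero denominator yields 0 (and
#' F1 is 0 when P+R = 0); values are not rounded — round at presentation
#' time only.
#'
#' @param counts A tibble with columns `tp`, `fp`, `fn` (one row per label or
#'   a single aggregate row), e.g. from [match_exact()].
#'
#' @return `counts` with added numeric columns `precision`, `recall`, `f1`
#'   in `[0, 100]`.
#' @export
ner_score <- function(counts) {
  p <- ifelse(counts$tp + counts$fp > 0, 100 * counts$tp / (counts$tp + counts$fp), 0)
  r <- ifelse(counts$tp + counts$fn > 0, 100 * counts$tp / (counts$tp + counts$fn), 0)
  counts$precision <- p
  counts$recall <- r
  counts$f1 <- f1_score(p, r)
  counts
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Numeric vectors on the same scale (typically
#'   percent).
#' @return `2*P*R/(P+R)`, or 0 where `P + R = 0`.
#' @export
#' @examples
#' f1_score(93.78, 90.87)
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' Aggregate per-label scores
#'
#' Micro averaging pools TP/FP/FN over the labels before computing the
#' metrics; macro averaging takes the unweighted mean of the per-label
#' precision, recall and F1 over the labels that occur at all (TP+FP+FN > 0)
#' — inventory labels absent from both prediction and gold carry no signal
#' and are excluded rather than counted as zeros. With no active label at
#' all, the macro scores are 0.
#'
#' @param counts Per-label counts from [match_exact()].
#' @param mode `"micro"` or `"macro"`.
#'
#' @return A one-row tibble with `precision`, `recall`, `f1` (and the pooled
#'   `tp`, `fp`, `fn` for micro).
#' @export
aggregate_scores <- function(counts, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  if (!nrow(counts)) abort_config("cannot aggregate zero labels.")
  if (mode == "micro") {
    pooled <- tibble(
      tp = sum(counts$tp), fp = sum(counts$fp), fn = sum(counts$fn)
    )
    ner_score(pooled)
  } else {
    active <- counts$tp + counts$fp + counts$fn > 0
    if (!any(active)) {
      return(tibble(precision = 0, recall = 0, f1 = 0))
    }
    scored <- ner_score(counts[active, , drop = FALSE])
    tibble(
      precision = mean(scored$precision),
      recall = mean(scored$recall),
      f1 = mean(scored$f1)
    )
  }
}

#' Score predictions against gold in one call
#'
#' Convenience wrapper producing the per-label table plus both aggregates.
#'
#' @inheritParams match_exact
#' @return A list with `per_label` (scored counts), `micro`, `macro`.
#' @export
evaluate_ner <- function(pred, gold) {
  counts <- match_exact(pred, gold)
  list(
    per_label = ner_score(counts),
    micro = aggregate_scores(counts, "micro"),
    macro = aggregate_scores(counts, "macro")
  )
}

#' Per-document F1 scores
#'
#' The unit vector for significance testing: one F1 value per document,
#' computed over the union of documents seen in either set.
#'
#' @inheritParams match_exact
#' @param mode Aggregation within each document, `"macro"` (default) or
#'   `"micro"`.
#' @return A tibble with columns `doc_id` and `f1`.
#' @export
per_document_f1 <- function(pred, gold, mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  docs <- sort(union(unique(pred$doc_id), unique(gold$doc_id)))
  inv_p <- class_inventory(pred)
  inv_g <- class_inventory(gold)
  f1 <- vapply(docs, function(d) {
    p <- annotation_set(as_tibble(pred)[pred$doc_id == d, ], inv_p)
    g <- annotation_set(as_tibble(gold)[gold$doc_id == d, ], inv_g)
    aggregate_scores(match_exact(p, g), mode)$f1
  }, numeric(1))
  tibble(doc_id = docs, f1 = unname(f1))
}

#' Paired significance test between two systems
#'
#' Two-sided paired Student's t-test over matched per-unit F1 scores
#' (typically per-document, see [per_document_f1()]; per-class vectors work
#' the same way). Differences with zero variance, or fewer than two units,
#' leave the test undefined and raise an error rather than returning a
#' fabricated p-value.
#'
#' @param scores_a,scores_b Equal-length numeric vectors of paired scores.
#' @return The two-sided p-value (numeric scalar), with the t statistic and
#'   degrees of freedom attached as attributes `statistic` and `df`.
#' @export
compare_systems <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    abort_config("paired score vectors must have equal length.")
  }
  if (length(scores_a) < 2L) {
    abort_config("need at least two paired units for a t-test.")
  }
  d <- scores_a - scores_b
  if (isTRUE(all.equal(stats::sd(d), 0)) || stats::sd(d) == 0) {
    abort_config("zero variance of the paired differences: t-test undefined.")
  }
  ht <- t.test(scores_a, scores_b, paired = TRUE)
  structure(
    unname(ht$p.value),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter)
  )
}
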