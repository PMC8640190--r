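# Fixture builders and independent brute-force oracles. The oracles never
# call the code paths they check: set operations are done by explicit
# row-by-row comparison, metrics by direct formula arithmetic.

# random annotation set over synthetic word-grid documents: spans sit at
# arbitrary (start, end) integer intervals; surfaces are left NA
random_spans <- function(n, docs = c("d1", "d2"), labels = c("A", "B", "C"),
                         max_pos = 40L) {
  starts <- sample.int(max_pos, n, replace = TRUE) - 1L
  tibble::tibble(
    doc_id = sample(docs, n, replace = TRUE),
    start = starts,
    end = starts + sample.int(5L, n, replace = TRUE),
    label = sample(labels, n, replace = TRUE)
  )
}

random_annotation_set <- function(n, docs = c("d1", "d2"),
                                  labels = c("A", "B", "C"), max_pos = 40L) {
  annotation_set(random_spans(n, docs, labels, max_pos), class_inventory = labels)
}

span_id <- function(x) paste(x$doc_id, x$start, x$end, x$label, sep = "|")

# brute-force vote counting: for every candidate row, count the models that
# contain an identical row, by direct field comparison
oracle_votes <- function(predictions) {
  all_rows <- unique(do.call(
    rbind,
    lapply(predictions, function(p) as.data.frame(p)[c("doc_id", "start", "end", "label")])
  ))
  votes <- integer(nrow(all_rows))
  for (i in seq_len(nrow(all_rows))) {
    for (p in predictions) {
      hit <- FALSE
      for (j in seq_len(nrow(p))) {
        if (p$doc_id[j] == all_rows$doc_id[i] && p$start[j] == all_rows$start[i] &&
            p$end[j] == all_rows$end[i] && p$label[j] == all_rows$label[i]) {
          hit <- TRUE
          break
        }
      }
      if (hit) votes[i] <- votes[i] + 1L
    }
  }
  all_rows$votes <- votes
  all_rows
}

# brute-force exact matching per label by pairwise row comparison
oracle_counts <- function(pred, gold, labels) {
  same_row <- function(a, i, b, j) {
    a$doc_id[i] == b$doc_id[j] && a$start[i] == b$start[j] &&
      a$end[i] == b$end[j] && a$label[i] == b$label[j]
  }
  in_other <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      any(vapply(seq_len(nrow(b)), function(j) same_row(a, i, b, j), logical(1)))
    }, logical(1))
  }
  p <- as.data.frame(pred)
  g <- as.data.frame(gold)
  p_hit <- if (nrow(p)) in_other(p, g) else logical(0)
  g_hit <- if (nrow(g)) in_other(g, p) else logical(0)
  do.call(rbind, lapply(labels, function(lb) {
    data.frame(
      label = lb,
      tp = sum(p_hit & p$label == lb),
      fp = sum(!p_hit & p$label == lb),
      fn = sum(!g_hit & g$label == lb)
    )
  }))
}

# direct-formula P/R/F1 in percent with the 0-denominator convention
oracle_prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

# hand-built token-score table: one row per sub-token
make_scores <- function(doc_id, word_start, word_end, subtoken, score_list) {
  base <- tibble::tibble(
    doc_id = doc_id, word_start = word_start, word_end = word_end,
    subtoken = subtoken
  )
  cbind(base, do.call(rbind, score_list))
}

# small corpus + gold pair used across I/O and CLI tests
tiny_corpus <- function() {
  corpus <- ner_corpus(
    c("doc_a", "doc_b"),
    c(
      "Chauffer le produit pendant 1 h. Refroidir à 25 °C.",
      "Ajouter de la triéthylamine au mélange."
    )
  )
  gold <- annotation_set(
    tibble::tibble(
      doc_id = c("doc_a", "doc_a", "doc_b"),
      start = c(28L, 45L, 14L),
      end = c(31L, 50L, 27L),
      label = c("Time", "Temperature", "reagent_catalyst"),
      surface = c("1 h", "25 °C", "triéthylamine")
    ),
    class_inventory = c("Time", "Temperature", "reagent_catalyst")
  )
  list(corpus = corpus, gold = gold)
}
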