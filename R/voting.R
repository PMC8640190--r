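#' Tally span votes across an ensemble of models
#'
#' Each model casts one vote for every distinct `(doc_id, start, end, label)`
#' span it predicts; candidates are pooled by exact identity, so overlapping
#' near-miss spans compete as distinct candidates (their votes are never
#' merged). Every candidate that received at least one vote is kept together
#' with its vote count. The tally is invariant under permutation of the model
#' list.
#'
#' @param predictions A list of K [annotation_set()]s, one per model, sharing
#'   one class inventory and document collection.
#'
#' @return A tibble of class `vote_tally` with columns `doc_id`, `start`,
#'   `end`, `label`, `surface`, `votes`, and attributes `n_models` and
#'   `class_inventory`.
#' @export
tally_votes <- function(predictions) {
  if (!is.list(predictions) || !length(predictions)) {
    abort_config("`predictions` must be a non-empty list of annotation sets.")
  }
  if (!all(vapply(predictions, is_annotation_set, logical(1)))) {
    abort_config("every element of `predictions` must be an annotation_set.")
  }
  inv <- lapply(predictions, function(x) sort(class_inventory(x)))
  if (length(unique(inv)) != 1L) {
    abort_config("all models must share one class inventory.")
  }
  k <- length(predictions)
  all_spans <- bind_rows(lapply(predictions, as_tibble))  # sets are pre-deduplicated
  tally <- summarise(
    group_by(all_spans, .data$doc_id, .data$start, .data$end, .data$label),
    surface = .data$surface[1L],
    votes = dplyr::n(),
    .groups = "drop"
  )
  tally <- arrange(tally, .data$doc_id, .data$start, .data$end, .data$label)
  structure(
    tally,
    n_models = k,
    class_inventory = inv[[1]],
    class = c("vote_tally", class(tibble()))
  )
}

#' Keep the candidates that reach the vote threshold
#'
#' Emits every candidate passage with at least `threshold` votes. Because
#' candidates are keyed by `(doc_id, start, end, label)` and thresholded
#' independently per label, a passage can come out carrying several labels at
#' once and the output may contain nested spans. No overlap suppression is
#' applied (see [suppress_overlaps()] for the optional post-filter).
#'
#' @param tally A [tally_votes()] result.
#' @param threshold Integer vote threshold `t`, with `1 <= t <= K`. The
#'   boundary values give the union (`t = 1`) and the intersection (`t = K`)
#'   of the models' prediction sets.
#'
#' @return An [annotation_set()].
#' @export
apply_threshold <- function(tally, threshold) {
  if (!inherits(tally, "vote_tally")) {
    abort_config("`tally` must come from tally_votes().")
  }
  k <- attr(tally, "n_models")
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold != as.integer(threshold)) {
    abort_config("`threshold` must be a single integer.")
  }
  threshold <- as.integer(threshold)
  if (threshold < 1L || threshold > k) {
    abort_config(sprintf(
      "`threshold` must lie in [1, %d] (got %d).", k, threshold
    ))
  }
  keep <- as_tibble(tally)[tally$votes >= threshold,
                           c("doc_id", "start", "end", "label", "surface")]
  annotation_set(keep, class_inventory = attr(tally, "class_inventory"))
}

#' Majority-voting ensemble of span predictions
#'
#' The composition of [tally_votes()] and [apply_threshold()]: every model
#' votes with its predicted spans, and candidates reaching the threshold are
#' emitted. With a single model and `t = 1` this is the identity.
#'
#' @inheritParams tally_votes
#' @inheritParams apply_threshold
#'
#' @return An [annotation_set()].
#' @export
#' @examples
#' inv <- c("Time", "Temperature")
#' m1 <- annotation_set(data.frame(doc_id = "d", start = 0, end = 3, label = "Time"), inv)
#' m2 <- annotation_set(data.frame(doc_id = "d", start = 0, end = 3, label = "Time"), inv)
#' m3 <- annotation_set(data.frame(doc_id = "d", start = 5, end = 8, label = "Time"), inv)
#' nrow(ensemble(list(m1, m2, m3), threshold = 2))
ensemble <- function(predictions, threshold) {
  apply_threshold(tally_votes(predictions), threshold)
}

#' Ensemble thresholds used for the benchmark domains
#'
#' Named presets for the vote threshold `t`: 3 for the chemical and clinical
#' tasks, 4 for the wet-lab task. The threshold is always an explicit
#' parameter of [ensemble()]; these are lookups, not silent defaults.
#'
#' @param domain One of `"chemical"`, `"clinical"`, `"wet_lab"`.
#' @return An integer threshold.
#' @export
ensemble_threshold <- function(domain = c("chemical", "clinical", "wet_lab")) {
  domain <- match.arg(domain)
  c(chemical = 3L, clinical = 3L, wet_lab = 4L)[[domain]]
}

#' Suppress overlapping same-label candidates (optional post-filter)
#'
#' Off by default in the pipeline: all candidates reaching the threshold are
#' emitted. When invoked, spans of the same document and label that overlap
#' are clustered transitively and one representative per cluster is kept:
#' highest vote count, ties broken by earlier start, then by longer span.
#'
#' @param annotations An [annotation_set()], typically from [apply_threshold()].
#' @param tally The [tally_votes()] result supplying vote counts.
#'
#' @return An [annotation_set()].
#' @export
suppress_overlaps <- function(annotations, tally) {
  spans <- as_tibble(annotations)
  if (!nrow(spans)) return(annotations)
  spans <- left_join(
    spans, as_tibble(tally)[c("doc_id", "start", "end", "label", "votes")],
    by = c("doc_id", "start", "end", "label")
  )
  if (anyNA(spans$votes)) {
    abort_config("every span must appear in the tally.")
  }
  keep <- lapply(split(spans, paste(spans$doc_id, spans$label, sep = "\r")), function(g) {
    g <- arrange(g, .data$start, .data$end)
    # transitive overlap clustering along the sorted spans
    cluster <- cumsum(c(TRUE, g$start[-1] >= cummax(g$end)[-nrow(g)]))
    picked <- lapply(split(g, cluster), function(cl) {
      cl <- cl[order(-cl$votes, cl$start, -(cl$end - cl$start)), ]
      cl[1L, ]
    })
    bind_rows(picked)
  })
  out <- bind_rows(keep)
  out$votes <- NULL
  annotation_set(out, class_inventory = class_inventory(annotations))
}
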