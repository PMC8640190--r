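#' Construct a document collection
#'
#' A corpus is the plain-text half of a BRAT document/annotation pair: one row
#' per document with an identifier and the raw, untokenized text. Character
#' offsets used throughout the package are 0-based, end-exclusive and count
#' characters (not bytes), so accented text is handled correctly.
#'
#' @param doc_id Character vector of unique document identifiers.
#' @param text Character vector of document texts, same length as `doc_id`.
#'
#' @return A tibble with columns `doc_id` and `text`.
#' @export
#' @examples
#' ner_corpus("d1", "Stir for 1 h.")
ner_corpus <- function(doc_id, text) {
  doc_id <- as.character(doc_id)
  text <- enc2utf8(as.character(text))
  if (length(doc_id) != length(text)) {
    abort_config("`doc_id` and `text` must have the same length.")
  }
  if (anyDuplicated(doc_id)) {
    abort_integrity("document identifiers must be unique within a corpus.")
  }
  tibble(doc_id = doc_id, text = text)
}

#' Construct an annotation set
#'
#' An annotation set holds all entity spans for a document collection: one
#' model's predictions, or the gold standard. Spans are labeled character
#' intervals `[start, end)` (0-based, end-exclusive). Overlapping and nested
#' spans are permitted — they arise both in multi-label gold annotation and in
#' sigmoid decoding — but exact duplicates of the `(doc_id, start, end, label)`
#' key are collapsed to a single span. Rows are kept in the canonical order
#' (`doc_id`, `start`, `end`, `label`) so that equal sets compare identical.
#'
#' @param spans A data frame with columns `doc_id`, `start`, `end`, `label`
#'   and optionally `surface` (the covered text; `NA` when unknown). `NULL`
#'   gives an empty set.
#' @param class_inventory Character vector of allowed entity class names. If
#'   `NULL`, the labels observed in `spans` (sorted) are used.
#'
#' @return A tibble of class `annotation_set` with a `class_inventory`
#'   attribute.
#' @export
#' @examples
#' annotation_set(
#'   data.frame(doc_id = "d1", start = 9, end = 12, label = "Time"),
#'   class_inventory = c("Time", "Temperature")
#' )
annotation_set <- function(spans = NULL, class_inventory = NULL) {
  if (is.null(spans)) {
    spans <- tibble(
      doc_id = character(), start = integer(), end = integer(),
      label = character(), surface = character()
    )
  }
  spans <- as_tibble(spans)
  required <- c("doc_id", "start", "end", "label")
  missing_cols <- setdiff(required, names(spans))
  if (length(missing_cols)) {
    abort_config(paste0(
      "annotation spans need columns ",
      paste0("`", missing_cols, "`", collapse = ", "), "."
    ))
  }
  if (!"surface" %in% names(spans)) spans$surface <- NA_character_
  spans <- spans[c("doc_id", "start", "end", "label", "surface")]
  spans$doc_id <- as.character(spans$doc_id)
  spans$start <- as.integer(spans$start)
  spans$end <- as.integer(spans$end)
  spans$label <- as.character(spans$label)
  spans$surface <- as.character(spans$surface)
  if (nrow(spans)) {
    if (anyNA(spans$start) || anyNA(spans$end) || anyNA(spans$doc_id) ||
        anyNA(spans$label)) {
      abort_integrity("span fields doc_id/start/end/label must not be NA.")
    }
    if (any(spans$start < 0L) || any(spans$end <= spans$start)) {
      abort_integrity("spans must satisfy 0 <= start < end.")
    }
  }
  if (is.null(class_inventory)) {
    class_inventory <- sort(unique(spans$label))
  } else {
    class_inventory <- as.character(class_inventory)
    bad <- setdiff(spans$label, class_inventory)
    if (length(bad)) {
      abort_integrity(paste0(
        "span labels outside the class inventory: ",
        paste(unique(bad), collapse = ", ")
      ))
    }
  }
  spans <- distinct(spans, .data$doc_id, .data$start, .data$end, .data$label,
    .keep_all = TRUE
  )
  spans <- arrange(spans, .data$doc_id, .data$start, .data$end, .data$label)
  # rebuild from bare columns so stray attributes of the input never leak in
  spans <- tibble(
    doc_id = spans$doc_id, start = spans$start, end = spans$end,
    label = spans$label, surface = spans$surface
  )
  new_annotation_set(spans, class_inventory)
}

new_annotation_set <- function(spans, class_inventory) {
  structure(
    spans,
    class_inventory = as.character(class_inventory),
    class = c("annotation_set", class(tibble()))
  )
}

#' @rdname annotation_set
#' @param x Object to test or query.
#' @export
is_annotation_set <- function(x) inherits(x, "annotation_set")

#' @rdname annotation_set
#' @export
class_inventory <- function(x) attr(x, "class_inventory")

#' @export
print.annotation_set <- function(x, ...) {
  inv <- class_inventory(x)
  cat(sprintf(
    "<annotation_set: %d spans, %d documents, %d classes>\n",
    nrow(x), length(unique(x$doc_id)), length(inv)
  ))
  NextMethod()
}

# unique identity key of a span candidate; the unit of voting and matching
span_key <- function(x) {
  if (!nrow(x)) return(character())
  paste(x$doc_id, x$start, x$end, x$label, sep = "\r")
}

# verify surfaces against the corpus text; used by standoff I/O and writers
check_surfaces <- function(spans, corpus) {
  if (!nrow(spans)) return(invisible(spans))
  txt <- setNames(corpus$text, corpus$doc_id)
  missing_docs <- setdiff(spans$doc_id, corpus$doc_id)
  if (length(missing_docs)) {
    abort_integrity(paste0(
      "spans reference documents absent from the corpus: ",
      paste(unique(missing_docs), collapse = ", ")
    ))
  }
  doc_text <- txt[spans$doc_id]
  if (any(spans$end > nchar(doc_text))) {
    abort_integrity("span offsets extend beyond the document text.")
  }
  actual <- substr(doc_text, spans$start + 1L, spans$end)
  stated <- spans$surface
  bad <- !is.na(stated) & stated != actual
  if (any(bad)) {
    i <- which(bad)[1L]
    abort_integrity(sprintf(
      "surface mismatch in %s [%d,%d): annotation says %s but text reads %s",
      spans$doc_id[i], spans$start[i], spans$end[i],
      dQuote(stated[i]), dQuote(actual[i])
    ))
  }
  invisible(spans)
}

# fill missing surfaces from the corpus text
fill_surfaces <- function(spans, corpus) {
  if (!nrow(spans)) return(spans)
  txt <- setNames(corpus$text, corpus$doc_id)
  spans$surface <- substr(txt[spans$doc_id], spans$start + 1L, spans$end)
  spans
}
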