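#' Read BRAT standoff annotations for one document
#'
#' Parses the text-bound ("T") lines of a BRAT `.ann` file into an annotation
#' set, cross-checking every stated surface string against the document text.
#' Offsets are interpreted as 0-based, end-exclusive character offsets, the
#' BRAT convention. Non-T lines (relations, events, notes) are skipped.
#' Discontinuous spans (semicolon-separated offset fragments) are rejected:
#' the toolkit handles contiguous spans only.
#'
#' @param ann A character scalar holding the `.ann` file content, or a
#'   character vector of its lines.
#' @param doc A one-row corpus (see [ner_corpus()]) or any list with `doc_id`
#'   and `text` fields, giving the document the annotations refer to.
#' @param class_inventory Optional label inventory for the resulting set.
#'
#' @return An [annotation_set()].
#' @export
#' @examples
#' doc <- ner_corpus("d1", "Stir for 1 h.")
#' read_standoff("T1\tTime 9 12\t1 h", doc)
read_standoff <- function(ann, doc, class_inventory = NULL) {
  doc_id <- doc$doc_id[[1]]
  text <- doc$text[[1]]
  lines <- if (length(ann) == 1L) strsplit(ann, "\n", fixed = TRUE)[[1]] else ann
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  is_t <- startsWith(lines, "T")
  out <- vector("list", sum(is_t))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!is_t[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      abort_parse(sprintf("malformed annotation line %d: %s", lineno[i], dQuote(lines[i])))
    }
    mid <- fields[2]
    if (grepl(";", mid, fixed = TRUE)) {
      abort(sprintf(
        "discontinuous span on line %d is not supported (semicolon offsets): %s",
        lineno[i], dQuote(lines[i])
      ), class = c("nervote_unsupported_error", "nervote_parse_error", "nervote_integrity_error"))
    }
    parts <- strsplit(mid, " ", fixed = TRUE)[[1]]
    if (length(parts) != 3L || !grepl("^[0-9]+$", parts[2]) || !grepl("^[0-9]+$", parts[3])) {
      abort_parse(sprintf("malformed annotation line %d: %s", lineno[i], dQuote(lines[i])))
    }
    j <- j + 1L
    out[[j]] <- tibble(
      doc_id = doc_id,
      start = as.integer(parts[2]),
      end = as.integer(parts[3]),
      label = parts[1],
      surface = if (length(fields) >= 3L) paste(fields[-(1:2)], collapse = "\t") else NA_character_
    )
  }
  spans <- if (j) bind_rows(out[seq_len(j)]) else NULL
  res <- annotation_set(spans, class_inventory = class_inventory)
  check_surfaces(res, tibble(doc_id = doc_id, text = text))
  res
}

#' Write BRAT standoff annotations for one document
#'
#' Serializes the spans of one document to BRAT text-bound lines, in the
#' deterministic order (start, end, label), with surfaces taken from the
#' document text so the output always satisfies the BRAT integrity rule.
#'
#' @param annotations An [annotation_set()]; only spans of `doc$doc_id` are
#'   written and all spans must belong to it.
#' @param doc A one-row corpus or list with `doc_id` and `text`.
#'
#' @return A character scalar: the `.ann` file content ("" for no spans).
#' @export
write_standoff <- function(annotations, doc) {
  doc_id <- doc$doc_id[[1]]
  text <- doc$text[[1]]
  spans <- as_tibble(annotations)
  if (nrow(spans) && !all(spans$doc_id == doc_id)) {
    abort_integrity("all spans must reference the document being written.")
  }
  if (!nrow(spans)) return("")
  spans <- arrange(spans, .data$start, .data$end, .data$label)
  check_surfaces(spans, tibble(doc_id = doc_id, text = text))
  surface <- substring(text, spans$start + 1L, spans$end)
  paste0(
    sprintf(
      "T%d\t%s %d %d\t%s",
      seq_len(nrow(spans)), spans$label, spans$start, spans$end, surface
    ),
    collapse = "\n"
  )
}

#' Read or write a directory of standoff document/annotation pairs
#'
#' The on-disk layout is the usual BRAT one: one `<doc_id>.txt` / `<doc_id>.ann`
#' pair per document; one directory per model's predictions. Files are read
#' and written as UTF-8.
#'
#' @param dir Directory containing (or to receive) the `.txt`/`.ann` pairs.
#' @param class_inventory Optional label inventory for the annotation set.
#'
#' @return `read_standoff_dir()`: a list with `corpus` (tibble) and
#'   `annotations` ([annotation_set()]). `write_standoff_dir()`: `dir`,
#'   invisibly.
#' @export
read_standoff_dir <- function(dir, class_inventory = NULL) {
  txt_files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txt_files)) {
    abort_config(sprintf("no .txt documents found under %s", dir))
  }
  doc_id <- sub("\\.txt$", "", basename(txt_files))
  text <- vapply(txt_files, read_utf8_file, character(1))
  corpus <- ner_corpus(doc_id, text)
  sets <- lapply(seq_along(doc_id), function(i) {
    ann_path <- file.path(dir, paste0(doc_id[i], ".ann"))
    ann <- if (file.exists(ann_path)) read_utf8_file(ann_path) else ""
    as_tibble(read_standoff(ann, corpus[i, ], class_inventory = class_inventory))
  })
  annotations <- annotation_set(bind_rows(sets), class_inventory = class_inventory)
  list(corpus = corpus, annotations = annotations)
}

#' @rdname read_standoff_dir
#' @param annotations An [annotation_set()] covering the corpus.
#' @param corpus A corpus tibble (see [ner_corpus()]).
#' @export
write_standoff_dir <- function(annotations, corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus))) {
    doc <- corpus[i, ]
    spans <- annotation_set(
      as_tibble(annotations)[annotations$doc_id == doc$doc_id, ],
      class_inventory = class_inventory(annotations)
    )
    write_utf8_file(doc$text, file.path(dir, paste0(doc$doc_id, ".txt")))
    write_utf8_file(write_standoff(spans, doc), file.path(dir, paste0(doc$doc_id, ".ann")))
  }
  invisible(dir)
}

read_utf8_file <- function(path) {
  n <- file.info(path)$size
  raw <- readChar(path, n, useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  raw
}

write_utf8_file <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(x)), con)
  invisible(path)
}

#' Split a document into sentence intervals
#'
#' Rule-based sentence splitting: a boundary is whitespace preceded by
#' terminal punctuation (`.`, `?`, `!`) and followed by an uppercase letter or
#' digit. Returned intervals are 0-based, end-exclusive character intervals,
#' disjoint and ordered; each is trimmed to its first/last non-whitespace
#' character, so concatenating the covered substrings reconstructs the
#' document minus inter-sentence whitespace. Text without a recognized
#' boundary yields a single interval; all-whitespace text yields none.
#' Intervals are advisory: entities are never clipped to them.
#'
#' @param doc A one-row corpus or list with a `text` field, or a character
#'   scalar of raw text.
#' @param boundary_regex Perl-compatible regex matching the inter-sentence
#'   whitespace gap.
#'
#' @return A tibble with integer columns `start` and `end`.
#' @export
#' @examples
#' split_sentences("Add NaCl. Stir for 1 h.")
split_sentences <- function(doc,
                            boundary_regex = "(?<=[.?!])\\s+(?=[[:upper:]0-9])") {
  text <- if (is.character(doc)) doc[[1]] else doc$text[[1]]
  nc <- nchar(text)
  if (!nc || !nzchar(trimws(text))) {
    return(tibble(start = integer(), end = integer()))
  }
  m <- gregexpr(boundary_regex, text, perl = TRUE)[[1]]
  piece_start <- 1L
  starts <- integer()
  ends <- integer()
  gap_starts <- if (m[1] == -1L) integer() else as.integer(m)
  gap_lens <- if (m[1] == -1L) integer() else attr(m, "match.length")
  bounds_lo <- c(piece_start, gap_starts + gap_lens)
  bounds_hi <- c(gap_starts - 1L, nc)
  for (k in seq_along(bounds_lo)) {
    lo <- bounds_lo[k]
    hi <- bounds_hi[k]
    if (hi < lo) next
    piece <- substr(text, lo, hi)
    first_nw <- regexpr("\\S", piece, perl = TRUE)
    if (first_nw == -1L) next
    last_nw <- nchar(sub("\\s+$", "", piece, perl = TRUE))
    starts <- c(starts, lo + as.integer(first_nw) - 2L)  # to 0-based
    ends <- c(ends, lo + last_nw - 1L)
  }
  tibble(start = starts, end = ends)
}
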