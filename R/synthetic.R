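#' Configuration for a synthetic annotated corpus
#'
#' The generator produces BRAT-style document/annotation collections with
#' controlled statistical structure: exact per-class span counts, a skewed
#' reuse of surface forms (so entity-frequency profiles have mass in every
#' bin), an adjustable share of surface forms carrying more than one label,
#' and optional nested spans. Text is pseudo-word gibberish (including
#' accented characters, so character-offset handling is exercised on
#' multi-byte text); sentences start with a capitalized filler word and end
#' with a period, so [split_sentences()] recovers the generator's sentence
#' boundaries.
#'
#' @param class_counts Named integer vector: target gold span count per
#'   entity class. Realized counts equal these exactly.
#' @param n_docs Number of documents.
#' @param sentences_per_doc Integer range `c(min, max)`; per-document counts
#'   are drawn uniformly from it.
#' @param length_probs Named numeric vector: probability of each entity
#'   length in words (names are the word counts).
#' @param nesting_rate Target fraction of spans that sit nested inside a span
#'   of a different label (realized approximately; requires >= 2 classes).
#' @param multilabel_rate Target fraction of distinct surface forms assigned
#'   two labels (realized exactly up to pairing feasibility).
#' @param forms_per_occurrence Lexicon size per class as a fraction of its
#'   span count; smaller values mean more form reuse.
#' @param max_entities_per_sentence Capacity bound used for the sizing check.
#' @param seed Integer RNG seed; identical configurations generate
#'   byte-identical corpora.
#' @param doc_prefix Prefix for document identifiers.
#'
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(class_counts,
                          n_docs,
                          sentences_per_doc = c(4, 10),
                          length_probs = c("1" = 0.5, "2" = 0.25, "3" = 0.15, "4" = 0.1),
                          nesting_rate = 0,
                          multilabel_rate = 0,
                          forms_per_occurrence = 0.3,
                          max_entities_per_sentence = 6L,
                          seed = 1L,
                          doc_prefix = "doc") {
  if (is.null(names(class_counts)) || any(!nzchar(names(class_counts)))) {
    abort_config("`class_counts` must be a named vector of span counts.")
  }
  class_counts <- setNames(as.integer(class_counts), names(class_counts))
  if (any(class_counts < 0L) || anyNA(class_counts)) {
    abort_config("class counts must be nonnegative integers.")
  }
  for (r in c(nesting_rate, multilabel_rate)) {
    if (!is.numeric(r) || r < 0 || r > 1) abort_config("rates must lie in [0, 1].")
  }
  if (length(sentences_per_doc) != 2L || sentences_per_doc[1] > sentences_per_doc[2] ||
      sentences_per_doc[1] < 1L) {
    abort_config("`sentences_per_doc` must be an increasing range c(min, max), min >= 1.")
  }
  if (n_docs < 1L) abort_config("`n_docs` must be at least 1.")
  if (abs(sum(length_probs) - 1) > 1e-8 || any(length_probs < 0)) {
    abort_config("`length_probs` must be a probability vector.")
  }
  structure(
    list(
      class_counts = class_counts,
      n_docs = as.integer(n_docs),
      sentences_per_doc = as.integer(sentences_per_doc),
      length_probs = length_probs,
      nesting_rate = nesting_rate,
      multilabel_rate = multilabel_rate,
      forms_per_occurrence = forms_per_occurrence,
      max_entities_per_sentence = as.integer(max_entities_per_sentence),
      seed = as.integer(seed),
      doc_prefix = doc_prefix
    ),
    class = "corpus_config"
  )
}

# seeded pseudo-word generator: 2-4 syllables, lowercase, some accented vowels
make_words <- function(n) {
  if (!n) return(character())
  consonants <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v", "z", "ch", "qu")
  vowels <- c("a", "e", "i", "o", "u", "é", "è", "ai", "ou")
  syl <- function(k) paste0(sample(consonants, k, TRUE), sample(vowels, k, TRUE))
  n_syl <- sample(2:4, n, TRUE)
  w <- paste0(syl(n), syl(n))
  w <- ifelse(n_syl >= 3L, paste0(w, syl(n)), w)
  ifelse(n_syl == 4L, paste0(w, syl(n)), w)
}

# n multi-word surface forms with word counts drawn from length_probs,
# guaranteed pairwise distinct
make_forms <- function(n, length_probs) {
  if (!n) return(character())
  lens <- as.integer(sample(names(length_probs), n, TRUE, prob = length_probs))
  forms <- vapply(lens, function(l) paste(make_words(l), collapse = " "), character(1))
  for (tries in 1:20) {
    dup <- duplicated(forms)
    if (!any(dup)) break
    forms[dup] <- vapply(lens[dup], function(l) paste(make_words(l), collapse = " "), character(1))
  }
  forms
}

#' Generate a synthetic gold-annotated corpus
#'
#' See [corpus_config()] for what is controlled. Per-class gold span counts
#' equal the configured counts exactly; the same configuration (including
#' seed) yields byte-identical text and annotations.
#'
#' @param config A [corpus_config()].
#' @return A list with `corpus` (tibble of documents), `gold`
#'   ([annotation_set()]), `sentences` (tibble `doc_id`, `start`, `end` of
#'   the generated sentence intervals) and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  withr::local_seed(config$seed)
  counts <- config$class_counts[config$class_counts > 0L]
  inventory <- names(config$class_counts)
  total <- sum(counts)

  # --- nested pairs consume one outer slot per pair; inners are ordinary
  #     occurrences placed inside the outer composite
  n_pairs <- round(config$nesting_rate * total)
  if (n_pairs > 0L && length(counts) < 2L) {
    abort_config("nesting requires at least two entity classes with spans.")
  }
  budget <- counts
  pair_inner <- character(0)
  pair_outer <- character(0)
  for (p in seq_len(n_pairs)) {
    avail <- names(budget)[budget > 0L]
    if (length(avail) < 2L) break
    inner <- sample(avail, 1L, prob = budget[avail])
    rest <- setdiff(names(budget)[budget > 0L], inner)
    outer <- if (length(rest) == 1L) rest else sample(rest, 1L, prob = budget[rest])
    budget[inner] <- budget[inner] - 1L
    budget[outer] <- budget[outer] - 1L
    pair_inner <- c(pair_inner, inner)
    pair_outer <- c(pair_outer, outer)
  }
  n_pairs <- length(pair_inner)

  # --- lexicons: n_forms per class, a controlled share of forms shared
  #     between two classes; inner slots need 1-word forms available
  n_occ <- budget + as.integer(table(factor(pair_inner, levels = names(budget))))
  n_forms <- pmax(pmin(n_occ, as.integer(ceiling(counts * config$forms_per_occurrence))), 1L)
  m_shared <- round(config$multilabel_rate * sum(n_forms) / (1 + config$multilabel_rate))
  slots_left <- n_forms
  shared_assign <- list()
  for (s in seq_len(m_shared)) {
    open <- names(slots_left)[slots_left > 0L]
    if (length(open) < 2L) break
    pick <- open[order(-slots_left[open])][1:2]
    slots_left[pick] <- slots_left[pick] - 1L
    shared_assign[[length(shared_assign) + 1L]] <- pick
  }
  n_shared <- length(shared_assign)
  shared_forms <- make_forms(n_shared, config$length_probs)
  lexicon <- lapply(setNames(names(counts), names(counts)), function(lb) {
    own <- make_forms(slots_left[[lb]], config$length_probs)
    shared <- shared_forms[vapply(shared_assign, function(p) lb %in% p, logical(1))]
    c(own, shared)
  })
  # classes that host nested inners must offer a single-word form
  inner_demand <- table(factor(pair_inner, levels = names(counts)))
  for (lb in names(counts)) {
    if (inner_demand[[lb]] > 0L && !any(surface_word_count(lexicon[[lb]]) == 1L)) {
      lexicon[[lb]][1L] <- make_words(1L)
    }
  }

  # --- occurrence surfaces: every form used at least once, remainder drawn
  #     with Zipf-like weights so frequencies are skewed
  draw_surfaces <- function(forms, n) {
    if (n < length(forms)) forms <- forms[seq_len(n)]
    extra <- n - length(forms)
    reuse <- if (extra > 0L) {
      sample(forms, extra, TRUE, prob = 1 / seq_along(forms))
    } else character(0)
    sample(c(forms, reuse))
  }
  occ_regular <- lapply(setNames(names(budget), names(budget)), function(lb) {
    draw_surfaces(lexicon[[lb]], budget[[lb]] + inner_demand[[lb]])
  })

  # split off the inner occurrences (must be 1-word surfaces)
  inner_surface <- character(n_pairs)
  for (lb in unique(pair_inner)) {
    idx_pairs <- which(pair_inner == lb)
    occ <- occ_regular[[lb]]
    one_word <- which(surface_word_count(occ) == 1L)
    need <- length(idx_pairs)
    if (length(one_word) < need) {
      # top up with the class's single-word forms; keeps counts exact
      short <- lexicon[[lb]][surface_word_count(lexicon[[lb]]) == 1L][1L]
      occ[seq_len(need - length(one_word))] <- short
      one_word <- which(surface_word_count(occ) == 1L)
    }
    take <- one_word[seq_len(need)]
    inner_surface[idx_pairs] <- occ[take]
    occ_regular[[lb]] <- occ[-take]
  }

  # --- token table: one row per entity token; nested pairs form a single
  #     composite token "filler inner filler" carrying both spans
  plain <- tibble(
    label = rep(names(occ_regular), lengths(occ_regular)),
    surface = as.character(unlist(occ_regular, use.names = FALSE)),
    inner_label = NA_character_,
    inner_surface = NA_character_,
    inner_off = NA_integer_
  )
  if (n_pairs > 0L) {
    left_w <- make_words(n_pairs)
    right_w <- make_words(n_pairs)
    nested <- tibble(
      label = pair_outer,
      surface = paste(left_w, inner_surface, right_w),
      inner_label = pair_inner,
      inner_surface = inner_surface,
      inner_off = nchar(left_w) + 1L
    )
    tokens <- bind_rows(plain, nested)
  } else {
    tokens <- plain
  }
  n_tok <- nrow(tokens)

  # --- documents, sentences, capacity check
  sent_range <- seq(config$sentences_per_doc[1], config$sentences_per_doc[2])
  sent_counts <- sent_range[sample.int(length(sent_range), config$n_docs, replace = TRUE)]
  n_sent <- sum(sent_counts)
  if (n_tok > n_sent * config$max_entities_per_sentence) {
    abort_config(sprintf(
      "cannot place %d entities in %d sentences (max %d per sentence); increase the document budget.",
      n_tok, n_sent, config$max_entities_per_sentence
    ))
  }
  doc_of_sent <- rep(seq_len(config$n_docs), sent_counts)
  slot_sent <- rep(seq_len(n_sent), config$max_entities_per_sentence)
  tokens$sent <- slot_sent[sample.int(length(slot_sent), n_tok)]
  tokens$pos <- runif(n_tok)

  # filler tokens: one capitalized sentence opener, 1-2 words after each
  # entity, and a few extra words in entity-free sentences
  n_post <- sample(1:2, n_tok, TRUE)
  post <- tibble(
    sent = rep(tokens$sent, n_post),
    pos = rep(tokens$pos, n_post) + sequence(n_post) * 1e-7,
    surface = make_words(sum(n_post)),
    kind = "filler"
  )
  openers <- make_words(n_sent)
  openers <- paste0(toupper(substr(openers, 1, 1)), substr(openers, 2, nchar(openers)))
  lead <- tibble(sent = seq_len(n_sent), pos = -1, surface = openers, kind = "filler")
  empty_sent <- setdiff(seq_len(n_sent), unique(tokens$sent))
  n_extra <- sample(2:6, length(empty_sent), TRUE)
  extra <- tibble(
    sent = rep(empty_sent, n_extra),
    pos = sequence(n_extra),
    surface = make_words(sum(n_extra)),
    kind = "filler"
  )
  ent <- tibble(
    sent = tokens$sent, pos = tokens$pos, surface = tokens$surface, kind = "entity",
    label = tokens$label, inner_label = tokens$inner_label,
    inner_surface = tokens$inner_surface, inner_off = tokens$inner_off
  )
  stream <- bind_rows(lead, ent, post, extra)
  stream$doc <- doc_of_sent[stream$sent]
  stream <- arrange(stream, .data$doc, .data$sent, .data$pos)

  # --- lay out text and compute character offsets (0-based)
  last_of_sent <- c(stream$sent[-1] != stream$sent[-nrow(stream)], TRUE)
  display <- ifelse(last_of_sent, paste0(stream$surface, "."), stream$surface)
  width <- nchar(display)
  step <- width + 1L  # single space between tokens
  offset_in_doc <- stats::ave(step, stream$doc, FUN = function(x) cumsum(c(0L, head(x, -1L))))
  stream$start <- as.integer(offset_in_doc)

  doc_ids <- sprintf("%s_%0*d", config$doc_prefix,
                     max(3L, nchar(as.character(config$n_docs))), seq_len(config$n_docs))
  texts <- vapply(
    split(display, factor(stream$doc, levels = seq_len(config$n_docs))),
    paste, character(1), collapse = " "
  )
  corpus <- ner_corpus(doc_ids, unname(texts))

  is_ent <- stream$kind == "entity"
  ent_rows <- stream[is_ent, ]
  spans <- tibble(
    doc_id = doc_ids[ent_rows$doc],
    start = ent_rows$start,
    end = ent_rows$start + nchar(ent_rows$surface),
    label = ent_rows$label,
    surface = ent_rows$surface
  )
  nested_rows <- ent_rows[!is.na(ent_rows$inner_label), ]
  if (nrow(nested_rows)) {
    spans <- bind_rows(spans, tibble(
      doc_id = doc_ids[nested_rows$doc],
      start = nested_rows$start + nested_rows$inner_off,
      end = nested_rows$start + nested_rows$inner_off + nchar(nested_rows$inner_surface),
      label = nested_rows$inner_label,
      surface = nested_rows$inner_surface
    ))
  }
  gold <- annotation_set(spans, class_inventory = inventory)
  check_surfaces(gold, corpus)

  sent_first <- !duplicated(stream$sent)
  sent_last <- rev(!duplicated(rev(stream$sent)))
  sentences <- tibble(
    doc_id = doc_ids[stream$doc[sent_first]],
    start = stream$start[sent_first],
    end = stream$start[sent_last] + width[sent_last]
  )
  list(corpus = corpus, gold = gold, sentences = sentences, config = config)
}

#' Preset corpus configurations emulating the benchmark datasets
#'
#' Reproduce the per-class gold span counts of the chemical-patent
#' (`chemu_*`), French clinical (`deft_*`) and wet-lab protocol (`wnut_*`)
#' training and test collections. Document counts follow the original
#' collection sizes; the clinical presets include nested spans and a low
#' multi-label surface-form share (~1%), while the chemical and wet-lab
#' presets use ~10% multi-label forms.
#'
#' @param name One of `"chemu_train"`, `"chemu_test"`, `"deft_train"`,
#'   `"deft_test"`, `"wnut_train"`, `"wnut_test"`.
#' @param seed RNG seed passed through to [corpus_config()].
#' @return A [corpus_config()].
#' @export
preset_corpus_config <- function(name = c("chemu_train", "chemu_test",
                                          "deft_train", "deft_test",
                                          "wnut_train", "wnut_test"),
                                 seed = 1L) {
  name <- match.arg(name)
  chemu <- list(
    train = c(example_label = 1104, other_compound = 5720, reaction_product = 2558,
              reagent_catalyst = 1570, Solvent = 1390, starting_material = 2167,
              Temperature = 1861, Time = 1311, yield_other = 1322, yield_percent = 1183),
    test = c(example_label = 349, other_compound = 1931, reaction_product = 855,
             reagent_catalyst = 504, Solvent = 428, starting_material = 711,
             Temperature = 612, Time = 452, yield_other = 440, yield_percent = 389)
  )
  deft <- list(
    train = c(anatomie = 1298, dose = 342, examen = 1081, mode = 238, moment = 440,
              pathologie = 351, sosy = 1647, substance = 968, traitement = 494, valeur = 562),
    test = c(anatomie = 174, dose = 5, examen = 137, mode = 11, moment = 54,
             pathologie = 184, sosy = 33, substance = 22, traitement = 52, valeur = 5)
  )
  wnut <- list(
    train = c(Action = 20504, Amount = 5712, Concentration = 2287, Device = 2836,
              `Generic-Measure` = 759, Location = 6643, `Measure-Type` = 1453,
              Mention = 396, Method = 2716, Modifier = 7736, Numerical = 1322,
              Reagent = 18710, Seal = 366, Size = 498, Speed = 1032,
              Temperature = 2610, Time = 4011, pH = 166),
    test = c(Action = 5346, Amount = 1223, Concentration = 701, Device = 888,
             `Generic-Measure` = 173, Location = 1657, `Measure-Type` = 720,
             Mention = 142, Method = 1059, Modifier = 3416, Numerical = 513,
             Reagent = 5012, Seal = 119, Size = 232, Speed = 238,
             Temperature = 744, Time = 951, pH = 66)
  )
  spec <- switch(name,
    chemu_train = list(counts = chemu$train, n_docs = 1125, sents = c(4, 10),
                       nesting = 0, multilabel = 0.10),
    chemu_test = list(counts = chemu$test, n_docs = 375, sents = c(4, 10),
                      nesting = 0, multilabel = 0.10),
    deft_train = list(counts = deft$train, n_docs = 100, sents = c(25, 45),
                      nesting = 0.05, multilabel = 0.01),
    deft_test = list(counts = deft$test, n_docs = 67, sents = c(4, 8),
                     nesting = 0.05, multilabel = 0.01),
    wnut_train = list(counts = wnut$train, n_docs = 616, sents = c(45, 75),
                      nesting = 0, multilabel = 0.10),
    wnut_test = list(counts = wnut$test, n_docs = 111, sents = c(70, 110),
                     nesting = 0, multilabel = 0.10)
  )
  corpus_config(
    class_counts = spec$counts,
    n_docs = spec$n_docs,
    sentences_per_doc = spec$sents,
    nesting_rate = spec$nesting,
    multilabel_rate = spec$multilabel,
    seed = seed,
    doc_prefix = name
  )
}

#' Per-model annotation-noise model
#'
#' Describes one imperfect model's deviation from gold: dropped spans,
#' label substitutions, one-word boundary shifts, and invented (spurious)
#' spans placed at uniform word positions.
#'
#' @param miss_rate Probability a gold span is dropped.
#' @param spurious_rate Expected number of invented spans per document
#'   (Poisson).
#' @param boundary_jitter_rate Probability a surviving span has one boundary
#'   shifted by one word.
#' @param confusion Named list: for each source label, a named numeric vector
#'   of substitution probabilities into other labels (row sum <= 1; the
#'   remainder keeps the label).
#' @param collision_rate Probability a spurious span is drawn from the
#'   exclusion pool (other models' previous errors) instead of fresh — 0
#'   keeps the models' spurious spans disjoint.
#' @param seed Optional seed; [perturb_predictions()] uses the current RNG
#'   state when `NULL`.
#'
#' @return A list of class `perturbation_model`.
#' @export
perturbation_model <- function(miss_rate = 0, spurious_rate = 0,
                               boundary_jitter_rate = 0, confusion = NULL,
                               collision_rate = 0, seed = NULL) {
  for (r in c(miss_rate, boundary_jitter_rate, collision_rate)) {
    if (!is.numeric(r) || r < 0 || r > 1) abort_config("rates must lie in [0, 1].")
  }
  if (!is.numeric(spurious_rate) || spurious_rate < 0) {
    abort_config("`spurious_rate` must be nonnegative.")
  }
  if (!is.null(confusion)) {
    ok <- vapply(confusion, function(row) {
      is.numeric(row) && !is.null(names(row)) && all(row >= 0) && sum(row) <= 1 + 1e-9
    }, logical(1))
    if (!all(ok)) abort_config("confusion rows must be named, nonnegative, and sum to <= 1.")
  }
  structure(
    list(
      miss_rate = miss_rate, spurious_rate = spurious_rate,
      boundary_jitter_rate = boundary_jitter_rate, confusion = confusion,
      collision_rate = collision_rate,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "perturbation_model"
  )
}

# word intervals (0-based start, end-exclusive) of a text
word_intervals <- function(text) {
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(tibble(start = integer(), end = integer()))
  tibble(start = as.integer(m) - 1L, end = as.integer(m) - 1L + attr(m, "match.length"))
}

#' Simulate one imperfect model's predictions
#'
#' Applies a [perturbation_model()] to the gold standard: each gold span is
#' independently dropped with `miss_rate`, relabeled per the confusion
#' distribution, and boundary-jittered by one word with
#' `boundary_jitter_rate`; per document, `Poisson(spurious_rate)` invented
#' spans are placed at uniform word positions (1–3 words long, uniform
#' label). With all rates zero the output equals the gold exactly.
#'
#' @param gold The gold [annotation_set()].
#' @param model A [perturbation_model()].
#' @param corpus The corpus the spans refer to (needed for word boundaries
#'   and surfaces).
#' @param exclude Optional annotation set (or span tibble) of candidates the
#'   spurious sampler must avoid — used by the ensemble simulation to keep
#'   different models' spurious spans from coinciding.
#'
#' @return An [annotation_set()] of the simulated predictions.
#' @export
perturb_predictions <- function(gold, model, corpus, exclude = NULL) {
  stopifnot(inherits(model, "perturbation_model"))
  if (!is.null(model$seed)) withr::local_seed(model$seed)
  inv <- class_inventory(gold)
  spans <- as_tibble(gold)

  if (nrow(spans)) {
    spans <- spans[runif(nrow(spans)) >= model$miss_rate, , drop = FALSE]
  }

  if (!is.null(model$confusion) && nrow(spans)) {
    for (src in names(model$confusion)) {
      row <- model$confusion[[src]]
      idx <- which(spans$label == src)
      if (!length(idx)) next
      u <- runif(length(idx))
      cum <- cumsum(row)
      pick <- findInterval(u, c(0, cum), left.open = TRUE)
      hit <- pick >= 1L & pick <= length(row)
      spans$label[idx[hit]] <- names(row)[pick[hit]]
    }
  }

  words <- lapply(setNames(corpus$text, corpus$doc_id), word_intervals)

  if (model$boundary_jitter_rate > 0 && nrow(spans)) {
    sel <- which(runif(nrow(spans)) < model$boundary_jitter_rate)
    for (i in sel) {
      w <- words[[spans$doc_id[i]]]
      side <- sample(c("start", "end"), 1L)
      dir <- sample(c(-1L, 1L), 1L)
      if (side == "start") {
        pos <- findInterval(spans$start[i], w$start)
        j <- pos + dir
        if (j >= 1L && j <= nrow(w) && w$start[j] < spans$end[i]) {
          spans$start[i] <- w$start[j]
        }
      } else {
        pos <- findInterval(spans$end[i], w$end)
        j <- pos + dir
        if (j >= 1L && j <= nrow(w) && w$end[j] > spans$start[i]) {
          spans$end[i] <- w$end[j]
        }
      }
    }
  }

  if (model$spurious_rate > 0) {
    gold_keys <- span_key(gold)
    used_keys <- c(gold_keys, span_key(spans))
    pool <- if (!is.null(exclude)) as_tibble(exclude) else tibble()
    pool_keys <- if (nrow(pool)) span_key(pool) else character()
    forbidden <- c(used_keys, pool_keys)
    extra <- list()
    for (d in seq_len(nrow(corpus))) {
      w <- words[[corpus$doc_id[d]]]
      if (!nrow(w)) next
      n_sp <- rpois(1L, model$spurious_rate)
      for (s in seq_len(n_sp)) {
        if (model$collision_rate > 0 && nrow(pool) &&
            runif(1) < model$collision_rate) {
          take <- pool[sample.int(nrow(pool), 1L), c("doc_id", "start", "end", "label")]
          extra[[length(extra) + 1L]] <- take
          next
        }
        for (try in 1:30) {
          i <- sample.int(nrow(w), 1L)
          len <- sample(1:3, 1L, prob = c(0.5, 0.3, 0.2))
          j <- min(i + len - 1L, nrow(w))
          cand <- tibble(
            doc_id = corpus$doc_id[d], start = w$start[i], end = w$end[j],
            label = sample(inv, 1L)
          )
          key <- span_key(cand)
          if (!key %in% forbidden) {
            forbidden <- c(forbidden, key)
            extra[[length(extra) + 1L]] <- cand
            break
          }
        }
      }
    }
    if (length(extra)) {
      spans <- bind_rows(spans[c("doc_id", "start", "end", "label")],
                         bind_rows(extra))
    }
  }

  spans <- fill_surfaces(spans[c("doc_id", "start", "end", "label")], corpus)
  annotation_set(spans, class_inventory = inv)
}

#' Run the full generate / perturb / vote / score pipeline
#'
#' Generates a corpus, simulates K independent imperfect models, combines
#' them by majority voting at threshold `t`, and scores every model and the
#' ensemble against the gold (micro-averaged). Because different models'
#' spurious spans are kept from coinciding (unless a model's
#' `collision_rate` says otherwise), spurious candidates rarely reach the
#' threshold while genuine spans usually do — the mechanism by which voting
#' restricts predictions to the ones more likely true and boosts precision.
#'
#' @param config A [corpus_config()].
#' @param models A list of K [perturbation_model()]s, or a single model used
#'   for all `k` models.
#' @param threshold Vote threshold `t`, `1 <= t <= K`.
#' @param k Number of models when `models` is a single model.
#' @param seed Base seed for the per-model noise draws; defaults to
#'   `config$seed`. Model seeds are derived deterministically from it.
#'
#' @return A list with `report` (tibble: one row per model plus
#'   `mean_individual` and `ensemble`, columns `precision`, `recall`, `f1`),
#'   `gold`, `corpus`, `predictions` (list of K sets), `ensemble`
#'   ([annotation_set()]) and `threshold`.
#' @export
simulate_ensemble_experiment <- function(config, models, threshold, k = NULL,
                                         seed = NULL) {
  if (inherits(models, "perturbation_model")) {
    if (is.null(k)) abort_config("give `k` when passing a single perturbation model.")
    models <- rep(list(models), k)
  }
  n_models <- length(models)
  if (threshold > n_models) {
    abort_config("`threshold` cannot exceed the number of models.")
  }
  base_seed <- as.integer(seed %||% config$seed)
  gen <- generate_corpus(config)
  gold_keys <- span_key(gen$gold)

  predictions <- vector("list", n_models)
  exclude <- tibble()
  for (m in seq_len(n_models)) {
    pm <- models[[m]]
    pm$seed <- pm$seed %||% as.integer((base_seed + 7919L * m) %% .Machine$integer.max)
    predictions[[m]] <- perturb_predictions(gen$gold, pm, gen$corpus,
                                            exclude = exclude)
    errs <- as_tibble(predictions[[m]])
    errs <- errs[!(span_key(errs) %in% gold_keys), , drop = FALSE]
    exclude <- bind_rows(exclude, errs)
  }

  ens <- ensemble(predictions, threshold)
  micro_of <- function(p) aggregate_scores(match_exact(p, gen$gold), "micro")
  indiv <- bind_rows(lapply(predictions, micro_of))
  ens_score <- micro_of(ens)
  report <- bind_rows(
    tibble(model = sprintf("model_%d", seq_len(n_models)),
           precision = indiv$precision, recall = indiv$recall, f1 = indiv$f1),
    tibble(model = "mean_individual", precision = mean(indiv$precision),
           recall = mean(indiv$recall), f1 = mean(indiv$f1)),
    tibble(model = "ensemble", precision = ens_score$precision,
           recall = ens_score$recall, f1 = ens_score$f1)
  )
  list(
    report = report, gold = gen$gold, corpus = gen$corpus,
    predictions = predictions, ensemble = ens, threshold = threshold,
    sentences = gen$sentences
  )
}
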