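test_that("generated corpora hit the configured class counts exactly", {
  cfg <- corpus_config(c(A = 137, B = 41, C = 7), n_docs = 8, seed = 4,
                       multilabel_rate = 0.1)
  g <- generate_corpus(cfg)
  expect_equal(
    as.integer(table(factor(g$gold$label, levels = c("A", "B", "C")))),
    c(137L, 41L, 7L)
  )
  # zero-count classes stay in the inventory but produce no spans
  cfg0 <- corpus_config(c(A = 10, B = 0), n_docs = 2, seed = 4)
  g0 <- generate_corpus(cfg0)
  expect_equal(sum(g0$gold$label == "B"), 0L)
  expect_equal(class_inventory(g0$gold), c("A", "B"))

  all0 <- generate_corpus(corpus_config(c(A = 0, B = 0), n_docs = 3, seed = 1))
  expect_equal(nrow(all0$gold), 0L)
  expect_equal(nrow(all0$corpus), 3L)
  expect_true(all(nchar(all0$corpus$text) > 0))
})

test_that("generation is seed-deterministic and offsets are verifiable", {
  cfg <- corpus_config(c(A = 50, B = 20), n_docs = 4, seed = 99,
                       nesting_rate = 0.1, multilabel_rate = 0.2)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1$corpus$text, g2$corpus$text)
  expect_identical(as.data.frame(g1$gold), as.data.frame(g2$gold))

  cfg2 <- corpus_config(c(A = 50, B = 20), n_docs = 4, seed = 100,
                        nesting_rate = 0.1, multilabel_rate = 0.2)
  g3 <- generate_corpus(cfg2)
  expect_false(identical(g1$corpus$text, g3$corpus$text))
  expect_equal(table(g3$gold$label), table(g1$gold$label))

  # surfaces equal the document substrings (checked independently here)
  txt <- setNames(g1$corpus$text, g1$corpus$doc_id)
  expect_identical(
    substr(txt[g1$gold$doc_id], g1$gold$start + 1, g1$gold$end),
    setNames(g1$gold$surface, g1$gold$doc_id)
  )
})

test_that("nesting places contained spans of a different label", {
  g <- generate_corpus(corpus_config(c(A = 100, B = 100), n_docs = 10,
                                     nesting_rate = 0.1, seed = 8))
  spans <- tibble::as_tibble(g$gold)
  nested <- 0L
  for (i in seq_len(nrow(spans))) {
    host <- spans$doc_id == spans$doc_id[i] & spans$start <= spans$start[i] &
      spans$end >= spans$end[i] & spans$label != spans$label[i] &
      (spans$end - spans$start > spans$end[i] - spans$start[i])
    if (any(host)) nested <- nested + 1L
  }
  expect_gt(nested, 10L)  # ~20 expected at rate 0.1 of 200 spans
  expect_error(
    generate_corpus(corpus_config(c(A = 10), n_docs = 2, nesting_rate = 0.5, seed = 1)),
    class = "nervote_config_error"
  )
})

test_that("an unsatisfiable document budget raises a sizing error", {
  expect_error(
    generate_corpus(corpus_config(c(A = 1000), n_docs = 1,
                                  sentences_per_doc = c(1, 1),
                                  max_entities_per_sentence = 3, seed = 1)),
    class = "nervote_config_error"
  )
})

test_that("perturbation respects its rates", {
  g <- generate_corpus(corpus_config(c(A = 600, B = 400), n_docs = 40, seed = 12))

  clean <- perturb_predictions(g$gold, perturbation_model(seed = 1), g$corpus)
  expect_equal(as.data.frame(clean), as.data.frame(g$gold))

  none <- perturb_predictions(g$gold, perturbation_model(miss_rate = 1, seed = 1), g$corpus)
  expect_equal(nrow(none), 0L)

  # survivors of miss_rate 0.2 on 1,000 spans within 3 sd of Binomial(1000, .8)
  miss <- perturb_predictions(g$gold, perturbation_model(miss_rate = 0.2, seed = 2), g$corpus)
  expect_gt(nrow(miss), 800 - 3 * sqrt(1000 * 0.2 * 0.8))
  expect_lt(nrow(miss), 800 + 3 * sqrt(1000 * 0.2 * 0.8))

  # full confusion swaps every label deterministically
  conf <- perturb_predictions(
    g$gold,
    perturbation_model(confusion = list(A = c(B = 1)), seed = 3),
    g$corpus
  )
  expect_equal(sum(conf$label == "A"), 0L)
  expect_equal(sum(conf$label == "B"), 1000L)

  # jitter keeps the span count but moves boundaries by one word
  jit <- perturb_predictions(
    g$gold, perturbation_model(boundary_jitter_rate = 1, seed = 4), g$corpus
  )
  expect_equal(nrow(jit), nrow(g$gold))
  expect_lt(sum(span_id(jit) %in% span_id(g$gold)), nrow(g$gold) / 2)

  # spurious spans appear at roughly Poisson rate and never duplicate gold
  spur <- perturb_predictions(
    g$gold, perturbation_model(spurious_rate = 2, seed = 5), g$corpus
  )
  n_extra <- nrow(spur) - nrow(g$gold)
  expect_gt(n_extra, 45)  # 40 docs * rate 2, +/- 4 sd
  expect_lt(n_extra, 115)
})

test_that("the end-to-end simulation is deterministic and behaves at the extremes", {
  cfg <- corpus_config(c(A = 120, B = 80), n_docs = 10, seed = 21)
  clean <- simulate_ensemble_experiment(cfg, perturbation_model(), threshold = 3, k = 5)
  expect_true(all(clean$report$precision == 100))
  expect_true(all(clean$report$recall == 100))

  noisy_model <- perturbation_model(miss_rate = 0.1, spurious_rate = 2)
  s1 <- simulate_ensemble_experiment(cfg, noisy_model, threshold = 3, k = 5)
  s2 <- simulate_ensemble_experiment(cfg, noisy_model, threshold = 3, k = 5)
  expect_identical(s1$report, s2$report)

  # recall at t = K (intersection) cannot exceed recall at t = 1 (union)
  r5 <- simulate_ensemble_experiment(cfg, noisy_model, threshold = 5, k = 5)
  r1 <- simulate_ensemble_experiment(cfg, noisy_model, threshold = 1, k = 5)
  rec <- function(s) s$report$recall[s$report$model == "ensemble"]
  expect_lte(rec(r5), rec(r1))

  # different models' spurious spans never coincide when collision_rate is 0
  spur_keys <- lapply(s1$predictions, function(p) {
    setdiff(span_id(p), span_id(s1$gold))
  })
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_length(intersect(spur_keys[[i]], spur_keys[[j]]), 0)
    }
  }
})
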