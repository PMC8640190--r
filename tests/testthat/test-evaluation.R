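inv <- c("A", "B")

aset <- function(df) annotation_set(df, class_inventory = inv)

test_that("exact matching counts TP/FP/FN per label", {
  gold <- aset(tibble::tibble(
    doc_id = "d", start = c(0, 5, 10, 15), end = c(3, 8, 13, 18), label = "A"
  ))
  # 3 predictions, 2 exact matches
  pred <- aset(tibble::tibble(
    doc_id = "d", start = c(0, 5, 20), end = c(3, 8, 23), label = "A"
  ))
  counts <- match_exact(pred, gold)
  a <- counts[counts$label == "A", ]
  expect_equal(c(a$tp, a$fp, a$fn), c(2L, 1L, 2L))

  # invariants: TP + FN = gold size, TP + FP = prediction size
  expect_equal(a$tp + a$fn, 4L)
  expect_equal(a$tp + a$fp, 3L)

  perfect <- match_exact(gold, gold)
  expect_true(all(perfect$fp == 0L) && all(perfect$fn == 0L))

  off <- aset(tibble::tibble(doc_id = "d", start = 1, end = 3, label = "A"))
  one <- aset(tibble::tibble(doc_id = "d", start = 0, end = 3, label = "A"))
  c2 <- match_exact(off, one)
  expect_equal(c(sum(c2$tp), sum(c2$fp), sum(c2$fn)), c(0L, 1L, 1L))
  # off-by-one at the end boundary fails equally
  off_end <- aset(tibble::tibble(doc_id = "d", start = 0, end = 4, label = "A"))
  c3 <- match_exact(off_end, one)
  expect_equal(c(sum(c3$tp), sum(c3$fp), sum(c3$fn)), c(0L, 1L, 1L))
})

test_that("swapping prediction and gold exchanges FP and FN", {
  set.seed(7)
  for (trial in 1:10) {
    p <- random_annotation_set(8)
    g <- random_annotation_set(8)
    ab <- match_exact(p, g)
    ba <- match_exact(g, p)
    expect_equal(ab$tp, ba$tp)
    expect_equal(ab$fp, ba$fn)
    expect_equal(ab$fn, ba$fp)
  }
})

test_that("precision, recall and F1 follow the formulas with 0-denominator convention", {
  s <- ner_score(tibble::tibble(tp = 2L, fp = 1L, fn = 2L))
  expect_equal(round(s$precision, 2), 66.67)
  expect_equal(round(s$recall, 2), 50.00)
  expect_equal(round(s$f1, 2), 57.14)

  z <- ner_score(tibble::tibble(tp = 0L, fp = 0L, fn = 5L))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  z2 <- ner_score(tibble::tibble(tp = 0L, fp = 3L, fn = 0L))
  expect_equal(c(z2$precision, z2$recall, z2$f1), c(0, 0, 0))

  # F1 lies between P and R whenever both are defined
  set.seed(13)
  tp <- sample(0:20, 50, TRUE); fp <- sample(0:20, 50, TRUE); fn <- sample(0:20, 50, TRUE)
  sc <- ner_score(tibble::tibble(tp = tp, fp = fp, fn = fn))
  ok <- sc$precision + sc$recall > 0
  expect_true(all(sc$f1[ok] >= pmin(sc$precision, sc$recall)[ok] - 1e-9))
  expect_true(all(sc$f1[ok] <= pmax(sc$precision, sc$recall)[ok] + 1e-9))
})

test_that("micro and macro aggregation match direct formula arithmetic", {
  counts <- tibble::tibble(
    label = c("x", "y", "z"),
    tp = c(10L, 0L, 5L), fp = c(0L, 10L, 5L), fn = c(0L, 10L, 5L)
  )
  micro <- aggregate_scores(counts, "micro")
  expect_equal(
    unname(unlist(micro[c("precision", "recall", "f1")])),
    unname(oracle_prf(15, 15, 15))
  )
  macro <- aggregate_scores(counts, "macro")
  per <- rbind(oracle_prf(10, 0, 0), oracle_prf(0, 10, 10), oracle_prf(5, 5, 5))
  expect_equal(macro$precision, mean(per[, "precision"]))
  expect_equal(macro$recall, mean(per[, "recall"]))
  expect_equal(macro$f1, mean(per[, "f1"]))

  one <- counts[1, ]
  expect_equal(aggregate_scores(one, "micro")$f1, aggregate_scores(one, "macro")$f1)
  equal_two <- tibble::tibble(label = c("x", "y"), tp = 4L, fp = 2L, fn = 1L)
  expect_equal(
    aggregate_scores(equal_two, "micro")$f1,
    aggregate_scores(equal_two, "macro")$f1
  )
})

test_that("micro aggregation equals scoring the concatenated span sets", {
  set.seed(31)
  for (trial in 1:10) {
    p <- random_annotation_set(10)
    g <- random_annotation_set(10)
    micro <- aggregate_scores(match_exact(p, g), "micro")
    # label-blind recount over the pooled sets
    pk <- span_id(p); gk <- span_id(g)
    tp <- sum(pk %in% gk)
    expect_equal(
      unname(unlist(micro[c("precision", "recall", "f1")])),
      unname(oracle_prf(tp, length(pk) - tp, length(gk) - tp))
    )
  }
})

test_that("the paired t-test matches the closed form and flags degenerate input", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2.5, 2.9, 4.1, 5.3, 5.8)
  p <- compare_systems(a, b)
  d <- a - b
  t_stat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_manual <- 2 * stats::pt(-abs(t_stat), df = length(d) - 1)
  expect_equal(as.numeric(p), p_manual, tolerance = 1e-12)
  expect_equal(attr(p, "statistic"), t_stat, tolerance = 1e-12)

  expect_error(compare_systems(a, a), class = "nervote_config_error")
  expect_error(compare_systems(a, a + 1), class = "nervote_config_error")  # constant diff
  expect_error(compare_systems(1, 2), class = "nervote_config_error")
  expect_error(compare_systems(a, b[1:3]), class = "nervote_config_error")

  set.seed(3)
  x <- stats::rnorm(20, mean = 70, sd = 2)
  y <- x + 10 + stats::rnorm(20, sd = 0.5)
  expect_lt(as.numeric(compare_systems(x, y)), 0.05)
})

test_that("per-document F1 provides paired units over the document union", {
  fx <- tiny_corpus()
  f <- per_document_f1(fx$gold, fx$gold)
  expect_equal(f$doc_id, c("doc_a", "doc_b"))
  expect_equal(f$f1, c(100, 100))
  empty <- annotation_set(NULL, class_inventory(fx$gold))
  f0 <- per_document_f1(empty, fx$gold)
  expect_equal(f0$f1, c(0, 0))
})
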