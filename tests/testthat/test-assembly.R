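test_that("sub-token pooling takes per-label maxima and honors alternatives", {
  s <- make_scores(
    doc_id = "d", word_start = c(0, 0), word_end = c(5, 5), subtoken = 1:2,
    score_list = list(c(A = 0.9, B = 0.1), c(A = 0.2, B = 0.8))
  )
  pooled <- pool_subtokens(s)
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$A, 0.9)
  expect_equal(pooled$B, 0.8)
  expect_equal(names(which.max(c(A = pooled$A, B = pooled$B))), "A")

  expect_equal(pool_subtokens(s, method = "mean")$A, 0.55)
  expect_equal(pool_subtokens(s, method = "first")$B, 0.1)

  one <- make_scores("d", 0, 5, 1, list(c(A = 0.3, B = 0.7)))
  expect_equal(pool_subtokens(one)$B, 0.7)

  two_same <- make_scores("d", c(0, 0), c(5, 5), 1:2,
                          list(c(A = 0.4, B = 0.6), c(A = 0.4, B = 0.6)))
  expect_equal(pool_subtokens(two_same)$A, 0.4)

  empty <- tibble::tibble(
    doc_id = character(), word_start = numeric(), word_end = numeric(),
    subtoken = integer(), A = numeric()
  )
  expect_error(pool_subtokens(empty), class = "nervote_config_error")
  overlapping <- make_scores("d", c(0, 3), c(5, 8), c(1, 1),
                             list(c(A = 1), c(A = 1)))
  expect_error(pool_subtokens(overlapping), class = "nervote_integrity_error")
})

test_that("softmax decoding merges adjacent same-label words into phrases", {
  # three adjacent words all decoded as one class -> a single phrase span,
  # the "sodium hydrogen carbonate" pattern
  s <- make_scores(
    "d", c(0, 7, 16), c(6, 15, 25), c(1, 1, 1),
    list(
      c(reagent_catalyst = 0.8, other_compound = 0.1, O = 0.1),
      c(reagent_catalyst = 0.7, other_compound = 0.2, O = 0.1),
      c(reagent_catalyst = 0.9, other_compound = 0.05, O = 0.05)
    )
  )
  a <- decode_softmax(s)
  expect_equal(nrow(a), 1L)
  expect_equal(a$start, 0L)
  expect_equal(a$end, 25L)
  expect_equal(a$label, "reagent_catalyst")

  # A, no-entity, A -> two single-word spans
  s2 <- make_scores(
    "d", c(0, 4, 8), c(3, 7, 11), c(1, 1, 1),
    list(c(A = 0.9, O = 0.1), c(A = 0.2, O = 0.8), c(A = 0.9, O = 0.1))
  )
  a2 <- decode_softmax(s2)
  expect_equal(nrow(a2), 2L)
  expect_equal(a2$start, c(0L, 8L))
  expect_equal(a2$end, c(3L, 11L))

  # all no-entity -> empty
  s3 <- make_scores("d", c(0, 4), c(3, 7), c(1, 1),
                    list(c(A = 0.1, O = 0.9), c(A = 0.3, O = 0.7)))
  expect_equal(nrow(decode_softmax(s3)), 0L)

  # spans never overlap
  set.seed(5)
  n <- 40
  starts <- seq(0, by = 4, length.out = n)
  raw <- matrix(stats::runif(3 * n), ncol = 3)
  raw <- raw / rowSums(raw)
  colnames(raw) <- c("A", "B", "O")
  s4 <- cbind(
    tibble::tibble(doc_id = "d", word_start = starts, word_end = starts + 3, subtoken = 1),
    tibble::as_tibble(raw)
  )
  a4 <- decode_softmax(s4)
  if (nrow(a4) > 1) {
    same_doc <- a4$doc_id[-1] == a4$doc_id[-nrow(a4)]
    expect_true(all(a4$start[-1][same_doc] >= a4$end[-nrow(a4)][same_doc]))
  }
})

test_that("softmax validation and deterministic tie-breaking", {
  bad <- make_scores("d", 0, 3, 1, list(c(A = 0.5, O = 0.4)))
  expect_error(decode_softmax(bad), class = "nervote_integrity_error")
  # tie between an entity class and no-entity resolves to the entity class
  tie <- make_scores("d", 0, 3, 1, list(c(A = 0.5, O = 0.5)))
  expect_message(a <- decode_softmax(tie), "tie")
  expect_equal(a$label, "A")
  # tie between two entity classes resolves by inventory (column) order
  tie2 <- make_scores("d", 0, 3, 1, list(c(A = 0.4, B = 0.4, O = 0.2)))
  expect_message(a2 <- decode_softmax(tie2), "tie")
  expect_equal(a2$label, "A")
})

test_that("sigmoid decoding is independent per label and supports nesting", {
  s <- make_scores("d", 0, 4, 1, list(c(sosy = 0.9, anatomie = 0.8)))
  a <- decode_sigmoid(s, cutoff = 0.5)
  expect_equal(nrow(a), 2L)
  expect_equal(a$start, c(0L, 0L))
  expect_equal(a$end, c(4L, 4L))
  expect_setequal(a$label, c("sosy", "anatomie"))

  expect_equal(nrow(decode_sigmoid(s, cutoff = 0.95)), 0L)

  # 3-word run of A with the middle word also active for B: nested spans
  s2 <- make_scores(
    "d", c(0, 4, 8), c(3, 7, 11), c(1, 1, 1),
    list(c(A = 0.9, B = 0.1), c(A = 0.8, B = 0.9), c(A = 0.7, B = 0.2))
  )
  a2 <- decode_sigmoid(s2, cutoff = 0.5)
  expect_equal(nrow(a2), 2L)
  a_span <- a2[a2$label == "A", ]
  b_span <- a2[a2$label == "B", ]
  expect_equal(c(a_span$start, a_span$end), c(0L, 11L))
  expect_equal(c(b_span$start, b_span$end), c(4L, 7L))
  expect_true(b_span$start >= a_span$start && b_span$end <= a_span$end)

  expect_error(decode_sigmoid(s2, cutoff = 0), class = "nervote_config_error")
  expect_error(decode_sigmoid(s2, cutoff = 1.2), class = "nervote_config_error")
})

test_that("sigmoid restricted to one label equals binarized softmax decoding", {
  set.seed(21)
  for (trial in 1:10) {
    n <- 12
    starts <- seq(0, by = 5, length.out = n)
    p <- stats::runif(n)
    sig <- cbind(
      tibble::tibble(doc_id = "d", word_start = starts, word_end = starts + 4, subtoken = 1),
      tibble::tibble(A = p)
    )
    soft <- cbind(
      tibble::tibble(doc_id = "d", word_start = starts, word_end = starts + 4, subtoken = 1),
      tibble::tibble(A = p, O = 1 - p)
    )
    from_sig <- decode_sigmoid(sig, cutoff = 0.5)
    from_soft <- suppressMessages(decode_softmax(soft))
    expect_equal(as.data.frame(from_sig), as.data.frame(from_soft))
  }
})

test_that("raising the sigmoid cutoff only shrinks the active-word cover", {
  set.seed(33)
  for (trial in 1:10) {
    n <- 15
    starts <- seq(0, by = 5, length.out = n)
    s <- cbind(
      tibble::tibble(doc_id = "d", word_start = starts, word_end = starts + 4, subtoken = 1),
      tibble::tibble(A = stats::runif(n), B = stats::runif(n))
    )
    lo <- decode_sigmoid(s, cutoff = 0.4)
    hi <- decode_sigmoid(s, cutoff = 0.7)
    # every span at the high cutoff lies inside a same-label span at the low one
    for (i in seq_len(nrow(hi))) {
      covered <- any(lo$label == hi$label[i] & lo$start <= hi$start[i] &
                       lo$end >= hi$end[i])
      expect_true(covered)
    }
  }
})
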