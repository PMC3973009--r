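test_that("STM buffer inserts, rehearses and evicts by recency", {
  b <- stm_buffer(2)
  b <- stm_update(b, "a")$buffer
  b <- stm_update(b, "b")$buffer
  # new word at capacity evicts the least recently rehearsed word
  res <- stm_update(b, "c")
  expect_identical(res$buffer$slots, c("b", "c"))
  expect_identical(res$evicted, "a")
  # rehearsal moves the word to most-recent and evicts nothing
  res <- stm_update(b, "a")
  expect_identical(res$buffer$slots, c("b", "a"))
  expect_null(res$evicted)
  # capacity 0: nothing ever enters
  res <- stm_update(stm_buffer(0), "x")
  expect_identical(res$buffer$slots, character(0))
  expect_null(res$evicted)
})

test_that("decay lowers unprotected activation, floors at rest, spares STM", {
  st <- activation_state(c(x = 2, y = 2), c(x = 1L, y = 2L))
  expect_identical(decay_step(st, character(), 0), st)
  out <- decay_step(st, protected_items = "x", delta = 1)
  expect_equal(out$activation, c(x = 2, y = 1))
  expect_identical(out$first_seen, st$first_seen)
  low <- activation_state(c(x = 0.3), c(x = 1L))
  expect_equal(decay_step(low, character(), 0.5)$activation, c(x = 0))
  expo <- decay_step(st, "x", 1, decay_law = "exponential")
  expect_equal(expo$activation, c(x = 2, y = 2 * exp(-1)))
})

test_that("topics rank by activation, then first activation, then name", {
  st <- activation_state(c(a = 3, b = 1), c(a = 1L, b = 2L))
  r <- rank_topics(st, 10)
  expect_identical(r$item, c("a", "b"))
  # activation tie: earlier first activation wins
  st <- activation_state(c(a = 2, b = 2), c(a = 5L, b = 1L))
  expect_identical(rank_topics(st, 1)$item, "b")
  # full tie: lexicographic
  st <- activation_state(c(b = 2, a = 2), c(a = 3L, b = 3L))
  expect_identical(rank_topics(st)$item, c("a", "b"))
  # zero activation is resting, not a topic
  st <- activation_state(c(a = 0), c(a = 1L))
  expect_identical(nrow(rank_topics(st)), 0L)
})

test_that("three disjoint words trace the documented step convention", {
  lex <- disjoint_backend(3)
  doc <- c("w1", "w2", "w3")
  # delta = 1: each item is activated then decays away (capacity 0 protects
  # nothing, not even the word just read)
  r <- process_document(doc, read_params(0, 1), lex,
                        empty_stopwords(), empty_undesirable())
  expect_identical(nrow(r), 0L)
  # delta = 0.5: only the last item retains activation 1 - 0.5
  r <- process_document(doc, read_params(0, 2), lex,
                        empty_stopwords(), empty_undesirable())
  expect_identical(r$item, "i3")
  expect_equal(r$activation, 0.5)
  # empty document
  r <- process_document(character(), read_params(0, 1), lex,
                        empty_stopwords(), empty_undesirable())
  expect_identical(nrow(r), 0L)
})

test_that("items shared with a word still in STM are protected from decay", {
  lex <- lexicon_backend(list(a = c("s", "x"), b = c("s", "y")))
  r <- process_document(c("a", "b"), read_params(1, 1), lex,
                        empty_stopwords(), empty_undesirable())
  # after reading b: a was evicted, but s is shared with b and stays
  # protected; x decays to rest
  expect_identical(r$item, c("s", "y"))
  expect_equal(r$activation, c(2, 1))
})

test_that("without decay and STM the loop equals the frequency baseline", {
  spec <- synth_spec(n_docs = 20L, seed = 101L)
  corpus <- generate_corpus(spec)
  params <- read_params(0, 0)
  for (doc in corpus$documents) {
    a <- process_document(doc, params, corpus$lexicon,
                          empty_stopwords(), empty_undesirable())
    b <- baseline_frequency(doc, corpus$lexicon,
                            empty_stopwords(), empty_undesirable())
    expect_identical(as.data.frame(a), as.data.frame(b))
  }
})

test_that("saturated STM reproduces the no-decay ranking at any decay rate", {
  spec <- synth_spec(n_docs = 5L, seed = 11L)
  corpus <- generate_corpus(spec)
  for (doc in corpus$documents) {
    ref <- baseline_frequency(doc, corpus$lexicon,
                              empty_stopwords(), empty_undesirable())
    cap <- length(unique(doc))
    for (eta in c(1, 5, 25)) {
      r <- process_document(doc, read_params(cap, eta), corpus$lexicon,
                            empty_stopwords(), empty_undesirable())
      expect_identical(as.data.frame(r), as.data.frame(ref))
    }
  }
})

test_that("slower decay never lowers an item's final activation", {
  spec <- synth_spec(n_docs = 5L, seed = 23L)
  corpus <- generate_corpus(spec)
  items <- unique(unlist(corpus$lexicon$entries, use.names = FALSE))
  for (doc in corpus$documents) {
    prev <- NULL
    for (eta in c(1, 2, 5, 10, 25)) {
      r <- process_document(doc, read_params(0, eta), corpus$lexicon,
                            empty_stopwords(), empty_undesirable())
      av <- activation_of(r, items)
      if (!is.null(prev)) expect_true(all(av >= prev - 1e-12))
      prev <- av
    }
  }
})

test_that("final activation is bounded by the item's retrieval count", {
  spec <- synth_spec(n_docs = 5L, seed = 31L)
  corpus <- generate_corpus(spec)
  items <- unique(unlist(corpus$lexicon$entries, use.names = FALSE))
  for (doc in corpus$documents) {
    counts <- activation_of(
      baseline_frequency(doc, corpus$lexicon,
                         empty_stopwords(), empty_undesirable()),
      items
    )
    r <- process_document(doc, read_params(4, 3), corpus$lexicon,
                          empty_stopwords(), empty_undesirable())
    av <- activation_of(r, items)
    expect_true(all(av >= 0))
    expect_true(all(av <= counts + 1e-12))
  }
})

test_that("identical inputs give bit-identical rankings", {
  spec <- synth_spec(n_docs = 3L, seed = 77L)
  corpus <- generate_corpus(spec)
  params <- read_params(4, 2)
  doc <- corpus$documents[[1]]
  r1 <- process_document(doc, params, corpus$lexicon,
                         empty_stopwords(), empty_undesirable())
  r2 <- process_document(doc, params, corpus$lexicon,
                         empty_stopwords(), empty_undesirable())
  expect_identical(r1, r2)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(read_params(-1, 0), "stm_capacity")
  expect_error(read_params(0, -2), "decay_rate")
  expect_error(read_params(0, 0, top_k = c(10, 5)), "top_k")
  expect_error(read_params(0, 0, activation_increment = 0), "increment")
  expect_equal(decay_delta(read_params(0, 4)), 0.25)
  expect_equal(decay_delta(read_params(0, 0)), 0)
})
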