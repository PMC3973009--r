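test_that("theme words share their theme's planted items", {
  spec <- synth_spec(n_themes = 1L, themes_per_doc = 1L, words_per_theme = 3L,
                     shared_items_per_theme = 1L)
  lex <- generate_lexicon(spec)
  shared <- planted_topics(spec)
  expect_length(shared, 1L)
  for (w in c("t1w1", "t1w2", "t1w3")) {
    expect_true(shared %in% lex$entries[[w]])
  }
})

test_that("distractor items are pairwise disjoint across distractor words", {
  spec <- synth_spec()
  lex <- generate_lexicon(spec)
  dnames <- grep("^dw", names(lex$entries), value = TRUE)
  expect_length(dnames, spec$n_distractor_words)
  for (i in seq_along(dnames)) {
    for (j in seq_along(dnames)) {
      if (i < j) {
        expect_length(
          intersect(lex$entries[[dnames[i]]], lex$entries[[dnames[j]]]), 0L
        )
      }
    }
  }
  # and disjoint from every theme word's items
  tnames <- grep("^t", names(lex$entries), value = TRUE)
  theme_items <- unique(unlist(lex$entries[tnames], use.names = FALSE))
  distractor_items <- unlist(lex$entries[dnames], use.names = FALSE)
  expect_length(intersect(theme_items, distractor_items), 0L)
})

test_that("a fixed seed reproduces the corpus byte for byte", {
  spec <- synth_spec(n_docs = 4L, seed = 99L)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1$documents, c2$documents)
  expect_identical(c1$gold, c2$gold)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_corpus(c1, d1)
  write_corpus(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  # a different seed changes the token stream
  c3 <- generate_corpus(synth_spec(n_docs = 4L, seed = 100L))
  expect_false(identical(c1$documents, c3$documents))
})

test_that("infeasible specifications are rejected", {
  expect_error(synth_spec(shared_items_per_theme = 6L, items_per_word = 5L),
               "cannot exceed")
  expect_error(synth_spec(themes_per_doc = 4L, n_themes = 3L),
               "cannot exceed")
  expect_error(synth_spec(theme_word_probability = 0), "strictly between")
  expect_error(synth_spec(theme_word_probability = 1), "strictly between")
  expect_error(synth_spec(n_docs = 0L), "positive")
})

test_that("theme probability near one fills documents with theme words", {
  spec <- synth_spec(n_docs = 2L, theme_word_probability = 1 - 1e-9,
                     seed = 5L)
  corpus <- generate_corpus(spec)
  theme_vocab <- grep("^t", names(corpus$lexicon$entries), value = TRUE)
  for (doc in corpus$documents) {
    expect_true(all(doc %in% theme_vocab))
  }
})

test_that("gold lists exactly the document's planted shared items", {
  spec <- synth_spec(n_docs = 10L, seed = 303L)
  corpus <- generate_corpus(spec)
  for (id in names(corpus$documents)) {
    themes <- corpus$doc_themes[[id]]
    expect_length(themes, spec$themes_per_doc)
    expected <- unlist(lapply(themes, function(t) {
      sprintf("theme%dcore%d", t, seq_len(spec$shared_items_per_theme))
    }))
    expect_identical(corpus$gold[[id]], expected)
    # every theme word in the document belongs to a planted theme
    tw <- grep("^t", corpus$documents[[id]], value = TRUE)
    expect_true(all(sub("^t(\\d+)w\\d+$", "\\1", tw) %in% themes))
  }
})

test_that("frequency baseline ranks a planted shared item first when theme
           tokens outnumber every distractor's count", {
  spec <- synth_spec(n_docs = 10L, seed = 17L)
  corpus <- generate_corpus(spec)
  for (id in names(corpus$documents)) {
    doc <- corpus$documents[[id]]
    per_theme <- table(sub("w\\d+$", "", grep("^t", doc, value = TRUE)))
    distractor_max <- max(table(grep("^dw", doc, value = TRUE)), 0)
    if (max(per_theme) > distractor_max) {
      top <- baseline_frequency(doc, corpus$lexicon,
                                empty_stopwords(), empty_undesirable(),
                                k = 1)
      expect_true(top$item %in% corpus$gold[[id]])
    }
  }
})
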