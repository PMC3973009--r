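#' Specification for a synthetic lexicon and corpus
#'
#' The generator emulates the one property of real documents the reading
#' model depends on: recurring words whose dictionary items overlap. Each
#' *theme* is a small group of words that all retrieve the same
#' `shared_items_per_theme` planted items (the document's true topics) plus
#' word-specific items; *distractor* words retrieve items no other word
#' shares. Each document is planted with a subset of `themes_per_doc` of the
#' corpus themes (documents discuss some, not all, of the corpus's recurring
#' themes, like multi-topic news items) and draws tokens i.i.d.: with
#' probability `theme_word_probability` a word of one of the document's
#' themes (theme chosen uniformly, then a word uniformly within that theme),
#' otherwise a distractor. The gold standard of a document is the set of
#' shared items planted for *that document's* themes.
#'
#' @param n_themes Number of themes in the corpus (default 3).
#' @param themes_per_doc Themes planted in each document (default 2); must
#'   not exceed `n_themes`.
#' @param words_per_theme Words per theme (default 4).
#' @param n_distractor_words Number of distractor words (default 30).
#' @param items_per_word Items each word retrieves (default 5).
#' @param shared_items_per_theme Planted items common to all words of a theme
#'   (default 2); must not exceed `items_per_word`.
#' @param doc_length Tokens per document (default 200).
#' @param theme_word_probability Probability in (0, 1) that a token is a
#'   theme word (default 0.6).
#' @param n_docs Number of documents (default 30).
#' @param seed Integer seed; a fixed seed reproduces the corpus exactly.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_themes = 3L, themes_per_doc = 2L,
                       words_per_theme = 4L,
                       n_distractor_words = 30L, items_per_word = 5L,
                       shared_items_per_theme = 2L, doc_length = 200L,
                       theme_word_probability = 0.6, n_docs = 30L,
                       seed = 42L) {
  spec <- list(
    n_themes = as.integer(n_themes),
    themes_per_doc = as.integer(themes_per_doc),
    words_per_theme = as.integer(words_per_theme),
    n_distractor_words = as.integer(n_distractor_words),
    items_per_word = as.integer(items_per_word),
    shared_items_per_theme = as.integer(shared_items_per_theme),
    doc_length = as.integer(doc_length),
    theme_word_probability = as.numeric(theme_word_probability),
    n_docs = as.integer(n_docs),
    seed = as.integer(seed)
  )
  counts <- spec[c("n_themes", "themes_per_doc", "words_per_theme",
                   "n_distractor_words", "items_per_word",
                   "shared_items_per_theme", "doc_length", "n_docs")]
  if (any(vapply(counts, function(x) is.na(x) || x <= 0L, logical(1)))) {
    stop("all synthetic counts must be positive integers")
  }
  if (spec$themes_per_doc > spec$n_themes) {
    stop("'themes_per_doc' cannot exceed 'n_themes'")
  }
  p <- spec$theme_word_probability
  if (is.na(p) || p <= 0 || p >= 1) {
    stop("'theme_word_probability' must lie strictly between 0 and 1")
  }
  if (spec$shared_items_per_theme > spec$items_per_word) {
    stop("'shared_items_per_theme' cannot exceed 'items_per_word'")
  }
  if (is.na(spec$seed)) stop("'seed' must be an integer")
  structure(spec, class = "synth_spec")
}

theme_word_names <- function(spec) {
  unlist(lapply(seq_len(spec$n_themes), function(t) {
    sprintf("t%dw%d", t, seq_len(spec$words_per_theme))
  }), use.names = FALSE)
}

distractor_word_names <- function(spec) {
  sprintf("dw%02d", seq_len(spec$n_distractor_words))
}

#' Planted topics of a synthetic specification
#'
#' @param spec A [synth_spec()].
#' @return Character vector of the shared items of all themes, in theme order.
#' @export
planted_topics <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  unlist(lapply(seq_len(spec$n_themes), function(t) {
    sprintf("theme%dcore%d", t, seq_len(spec$shared_items_per_theme))
  }), use.names = FALSE)
}

#' Generate a synthetic lexicon with planted item overlap
#'
#' Theme words of theme `t` all retrieve that theme's shared items plus
#' word-specific filler items; distractor words retrieve pairwise disjoint
#' items. The construction is deterministic, so a fixed spec always yields
#' the identical lexicon.
#'
#' @param spec A [synth_spec()].
#' @return A [lexicon_backend()].
#' @export
generate_lexicon <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  entries <- list()
  n_fill <- spec$items_per_word - spec$shared_items_per_theme
  for (t in seq_len(spec$n_themes)) {
    shared <- sprintf("theme%dcore%d", t, seq_len(spec$shared_items_per_theme))
    for (j in seq_len(spec$words_per_theme)) {
      w <- sprintf("t%dw%d", t, j)
      fill <- if (n_fill > 0) sprintf("%sx%d", w, seq_len(n_fill)) else character()
      entries[[w]] <- c(shared, fill)
    }
  }
  for (d in seq_len(spec$n_distractor_words)) {
    w <- sprintf("dw%02d", d)
    entries[[w]] <- sprintf("%sx%d", w, seq_len(spec$items_per_word))
  }
  lexicon_backend(entries)
}

#' Generate a synthetic corpus with its gold standard
#'
#' Samples `n_docs` documents of `doc_length` i.i.d. tokens each (see
#' [synth_spec()] for the sampling scheme). Each document is planted with
#' `themes_per_doc` themes drawn uniformly from the corpus themes; its gold
#' standard is the set of shared items of exactly those themes.
#'
#' @param spec A [synth_spec()].
#' @return An object of class `synth_corpus`: list with `spec`, `lexicon`
#'   (a [lexicon_backend()]), `documents` (named list of token vectors),
#'   `gold` (named list of topic vectors, ids matching `documents`) and
#'   `doc_themes` (named list of the theme indices planted in each document).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  lexicon <- generate_lexicon(spec)
  dw <- distractor_word_names(spec)
  set.seed(spec$seed)
  documents <- vector("list", spec$n_docs)
  doc_themes <- vector("list", spec$n_docs)
  gold <- vector("list", spec$n_docs)
  ids <- sprintf("doc%03d", seq_len(spec$n_docs))
  for (i in seq_len(spec$n_docs)) {
    themes <- sort(sample.int(spec$n_themes, spec$themes_per_doc))
    tw <- unlist(lapply(themes, function(t) {
      sprintf("t%dw%d", t, seq_len(spec$words_per_theme))
    }), use.names = FALSE)
    is_theme <- stats::runif(spec$doc_length) < spec$theme_word_probability
    toks <- character(spec$doc_length)
    if (any(is_theme)) {
      # equal theme sizes: uniform over the doc's theme words is the same as
      # theme-uniform then word-uniform within the theme
      toks[is_theme] <- sample(tw, sum(is_theme), replace = TRUE)
    }
    if (any(!is_theme)) {
      toks[!is_theme] <- sample(dw, sum(!is_theme), replace = TRUE)
    }
    documents[[i]] <- toks
    doc_themes[[i]] <- themes
    gold[[i]] <- unlist(lapply(themes, function(t) {
      sprintf("theme%dcore%d", t, seq_len(spec$shared_items_per_theme))
    }), use.names = FALSE)
  }
  names(documents) <- ids
  names(doc_themes) <- ids
  names(gold) <- ids
  structure(
    list(spec = spec, lexicon = lexicon, documents = documents, gold = gold,
         doc_themes = doc_themes),
    class = "synth_corpus"
  )
}

#' Write a lexicon backend to JSON
#'
#' Inverse of [lexicon_json()] for flat (pre-extracted) entries.
#'
#' @param backend A [lexicon_backend()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon_json <- function(backend, path) {
  stopifnot(inherits(backend, "lexicon_backend"))
  jsonlite::write_json(
    list(
      entries = backend$entries,
      morphology = as.list(backend$morphology)
    ),
    path
  )
  invisible(path)
}

#' Write a synthetic corpus to disk
#'
#' Creates `dir/` containing one `<doc id>.txt` file per document (tokens
#' separated by spaces), `gold.json` and `lexicon.json`.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synth_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(corpus$documents)) {
    writeLines(paste(corpus$documents[[id]], collapse = " "),
               file.path(dir, paste0(id, ".txt")))
  }
  write_gold_json(corpus$gold, file.path(dir, "gold.json"))
  write_lexicon_json(corpus$lexicon, file.path(dir, "lexicon.json"))
  invisible(dir)
}

#' Read a corpus directory into normalized token lists
#'
#' Reads every `*.txt` file in `dir` and normalizes it with
#' [normalize_document()]. Document ids are the file names without extension.
#'
#' @param dir Directory of plain-text documents.
#' @param backend A [lexicon_backend()] (for morphology), or `NULL`.
#' @param stopwords A [word_list()].
#' @return Named list of token vectors.
#' @export
read_corpus_dir <- function(dir, backend = NULL,
                            stopwords = default_stopwords()) {
  if (!dir.exists(dir)) stop("corpus directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) stop("no .txt documents in ", dir)
  docs <- lapply(files, function(f) {
    normalize_document(readLines(f, encoding = "UTF-8", warn = FALSE),
                       backend, stopwords)
  })
  names(docs) <- sub("\\.txt$", "", basename(files))
  docs
}
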