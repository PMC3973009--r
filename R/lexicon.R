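#' Tokenize text
#'
#' Lowercases and splits on runs of non-alphanumeric characters. This is the
#' single tokenizer used for documents, sense definitions, glosses and
#' multi-word synset members, so items and document words always live in the
#' same token space.
#'
#' @param text Character vector; elements are concatenated.
#' @return Character vector of lowercase tokens (possibly empty).
#' @export
tokenize_text <- function(text) {
  text <- tolower(paste(as.character(text), collapse = "\n"))
  toks <- unlist(strsplit(text, "[^a-z0-9]+"), use.names = FALSE)
  toks[nzchar(toks)]
}

#' Construct a lexicon backend
#'
#' The lexicon stands in for long-term memory: a word maps to the
#' unstructured stream of words ("items") found in its dictionary sense
#' records. An entry is either
#' \itemize{
#'   \item a character vector -- a pre-extracted raw item stream, or
#'   \item a list of *senses*, each a list with fields `synset` (character
#'     vector of member terms; multi-word members are split into single
#'     tokens), `definition` (string), `glosses` (character vector of example
#'     sentences) and `hypernyms` (list of parent records with the same
#'     `synset`/`definition`/`glosses` fields).
#' }
#' Item order within an entry follows first occurrence in the concatenated
#' sense text: per sense, synset members, then definition, then glosses, then
#' each hypernym's synset members, definition and glosses.
#'
#' @param entries Named list of entries (names are headwords, lowercased).
#' @param morphology Named character vector mapping surface forms to
#'   dictionary base forms (e.g. `c(cats = "cat")`); used only when
#'   normalizing documents, never applied to items.
#' @param source Optional provenance string (e.g. a file path).
#' @return An object of class `lexicon_backend`.
#' @seealso [lexicon_json()], [lookup_items()]
#' @export
lexicon_backend <- function(entries = list(), morphology = character(),
                            source = NULL) {
  stopifnot(is.list(entries))
  if (length(entries) && is.null(names(entries))) {
    stop("lexicon entries must be named by headword")
  }
  names(entries) <- tolower(names(entries))
  morphology <- unlist(morphology)
  if (length(morphology)) {
    if (is.null(names(morphology))) {
      stop("morphology must map surface forms (names) to base forms (values)")
    }
    morphology <- stats::setNames(
      tolower(as.character(morphology)),
      tolower(names(morphology))
    )
  } else {
    morphology <- character()
  }
  structure(
    list(
      kind = "toy-json",
      source = source,
      entries = entries,
      morphology = morphology,
      cache = new.env(parent = emptyenv())
    ),
    class = "lexicon_backend"
  )
}

#' @export
print.lexicon_backend <- function(x, ...) {
  cat(sprintf(
    "<lexicon_backend: %d entries, %d morphology rules%s>\n",
    length(x$entries), length(x$morphology),
    if (is.null(x$source)) "" else paste0(", source=", x$source)
  ))
  invisible(x)
}

#' Load a lexicon backend from a JSON file
#'
#' Expected schema:
#' ```
#' {"entries":    {"word": [items or sense records, ...], ...},
#'  "morphology": {"surface": "base", ...}}
#' ```
#' See [lexicon_backend()] for the two entry forms.
#'
#' @param path Path to the JSON file.
#' @return A `lexicon_backend`.
#' @export
lexicon_json <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("lexicon file not found: ", path)
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$entries)) stop("lexicon JSON must have an 'entries' field")
  lexicon_backend(
    entries = obj$entries,
    morphology = obj$morphology,
    source = path
  )
}

# Flatten one entry (either raw item vector or list of senses) into the
# ordered raw token stream, before any filtering.
entry_token_stream <- function(entry) {
  if (is.character(entry)) {
    return(tokenize_text(entry))
  }
  if (is.list(entry) && length(entry) &&
      all(vapply(entry, function(e) is.character(e) && length(e) == 1L,
                 logical(1)))) {
    # JSON array of strings parsed with simplifyVector = FALSE
    return(tokenize_text(unlist(entry, use.names = FALSE)))
  }
  if (!is.list(entry)) return(character())
  unlist(lapply(entry, sense_token_stream), use.names = FALSE)
}

sense_token_stream <- function(sense) {
  if (is.character(sense)) return(tokenize_text(sense))
  own <- c(
    tokenize_text(unlist(sense$synset, use.names = FALSE)),
    tokenize_text(unlist(sense$definition, use.names = FALSE)),
    tokenize_text(unlist(sense$glosses, use.names = FALSE))
  )
  hyp <- unlist(
    lapply(sense$hypernyms, function(h) {
      c(
        tokenize_text(unlist(h$synset, use.names = FALSE)),
        tokenize_text(unlist(h$definition, use.names = FALSE)),
        tokenize_text(unlist(h$glosses, use.names = FALSE))
      )
    }),
    use.names = FALSE
  )
  c(own, hyp)
}

#' Look up the items retrieved by a word
#'
#' Returns every unique word found across *all* noun senses of `word`
#' (exhaustive access: no sense disambiguation), in order of first occurrence,
#' with stop words and undesirable words removed. Items are deliberately not
#' stemmed or otherwise normalized. A word absent from the lexicon yields an
#' empty item list; that is not an error (the word was still read).
#'
#' @param word A single token; lowercased before lookup.
#' @param backend A [lexicon_backend()].
#' @param stopwords,undesirable [word_list()] objects.
#' @return An object of class `lexicon_entry`: a list with `word` and `items`
#'   (character vector, unique, no stop or undesirable words, no whitespace).
#' @examples
#' lex <- lexicon_backend(list(cat = c("feline", "animal", "pet")))
#' lookup_items("cat", lex,
#'   stopwords = word_list(character(), "stopwords"),
#'   undesirable = word_list("animal", "undesirable")
#' )$items
#' @export
lookup_items <- function(word, backend,
                         stopwords = default_stopwords(),
                         undesirable = default_undesirable()) {
  stopifnot(inherits(backend, "lexicon_backend"))
  if (!is.character(word) || length(word) != 1L) {
    stop("'word' must be a single string")
  }
  word <- tolower(word)
  entry <- backend$entries[[word]]
  raw <- if (is.null(entry)) character() else entry_token_stream(entry)
  items <- raw[!(raw %in% stopwords$words) & !(raw %in% undesirable$words)]
  items <- items[!duplicated(items)]
  structure(list(word = word, items = items), class = "lexicon_entry")
}

#' @export
print.lexicon_entry <- function(x, ...) {
  cat(sprintf("<lexicon_entry '%s': %d items>\n", x$word, length(x$items)))
  if (length(x$items)) cat(" ", paste(x$items, collapse = ", "), "\n")
  invisible(x)
}

# Memoized filtered-item lookup. The cache lives on the backend and is keyed
# by word; it is invalidated whenever the word lists change (fingerprint
# comparison), so the same backend can be reused across configurations.
items_for_word <- function(word, backend, stopwords, undesirable) {
  cache <- backend$cache
  fp <- paste(stopwords$fingerprint, undesirable$fingerprint, sep = "\f")
  if (!identical(cache$fingerprint, fp)) {
    cache$fingerprint <- fp
    cache$items <- new.env(parent = emptyenv())
  }
  got <- cache$items[[word]]
  if (is.null(got)) {
    got <- lookup_items(word, backend, stopwords, undesirable)$items
    assign(word, got, envir = cache$items)
  }
  got
}

#' Normalize a document into its reading-order token sequence
#'
#' Lowercases, strips punctuation, removes stop words, and maps each
#' remaining token to its dictionary base form through the backend's
#' morphology table when one exists. Document words *are* normalized in this
#' way; items never are. Reading order is preserved, including repeats.
#'
#' @param text Character vector holding the document text.
#' @param backend A [lexicon_backend()], or `NULL` to skip morphology.
#' @param stopwords A [word_list()].
#' @return Character vector of tokens in reading order.
#' @export
normalize_document <- function(text, backend = NULL,
                               stopwords = default_stopwords()) {
  toks <- tokenize_text(text)
  toks <- toks[!(toks %in% stopwords$words)]
  if (!is.null(backend) && length(backend$morphology) && length(toks)) {
    base <- backend$morphology[toks]
    hit <- !is.na(base)
    toks[hit] <- unname(base[hit])
  }
  toks
}
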