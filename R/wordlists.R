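#' Construct a word list
#'
#' A word list is a set of lowercase single-token words with a role: either
#' `"stopwords"` (function words removed from documents and from item
#' streams) or `"undesirable"` (dictionary items too general to be useful
#' topics, removed from item lists only).
#'
#' @param words Character vector; entries are trimmed, lowercased and
#'   deduplicated. Entries containing whitespace are an error.
#' @param role `"stopwords"` or `"undesirable"`.
#' @return An object of class `word_list` with elements `words` and `role`.
#' @examples
#' word_list(c("The", "a", "of", "the"), "stopwords")
#' @export
word_list <- function(words, role = c("stopwords", "undesirable")) {
  role <- match.arg(role)
  words <- tolower(trimws(as.character(words)))
  words <- words[nzchar(words)]
  if (any(grepl("[[:space:]]", words))) {
    stop("word list entries must be single tokens without whitespace")
  }
  words <- unique(words)
  structure(
    list(
      words = words,
      role = role,
      # content fingerprint so item caches can detect a changed list cheaply
      fingerprint = paste(role, paste(words, collapse = "\r"), sep = "\n")
    ),
    class = "word_list"
  )
}

#' @export
print.word_list <- function(x, ...) {
  cat(sprintf("<word_list role=%s, %d words>\n", x$role, length(x$words)))
  invisible(x)
}

#' Load a word list from a plain-text file
#'
#' One word per line; `#` starts a comment; blank lines are ignored.
#'
#' @param path Path to the file.
#' @inheritParams word_list
#' @return A [word_list()].
#' @export
load_wordlist <- function(path, role = c("stopwords", "undesirable")) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("word list file not found: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  word_list(lines[nzchar(lines)], role)
}

#' Bundled English stop-word list
#' @return A [word_list()] with role `"stopwords"`.
#' @export
default_stopwords <- function() {
  load_wordlist(
    system.file("extdata", "stopwords_en.txt", package = "readtopics"),
    "stopwords"
  )
}

#' Bundled undesirable-word list
#'
#' Dictionary items that are too general or appear in too many sense
#' definitions to make useful topics (e.g. "thing", "person", "time").
#' @return A [word_list()] with role `"undesirable"`.
#' @export
default_undesirable <- function() {
  load_wordlist(
    system.file("extdata", "undesirable_words.txt", package = "readtopics"),
    "undesirable"
  )
}
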