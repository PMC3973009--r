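#' Count exact string matches between a ranking and a gold standard
#'
#' Quality is a direct count of case-insensitive full-string matches between
#' ranked topics and the gold-standard set, counted separately for ranks 1--5
#' (`top5`) and ranks 6--10 (`next5`). Topics beyond rank 10 are ignored: a
#' topic that far down the list is not considered identified. No stemming,
#' substring or synonym matching is performed, so a multi-word gold topic can
#' never match a single-token item.
#'
#' @param ranking A `topic_ranking` (from [rank_topics()],
#'   [process_document()] or [baseline_frequency()]) or a character vector of
#'   topics in rank order.
#' @param gold Character vector of gold-standard topic strings (unordered).
#' @return An object of class `match_counts`: list with integer fields
#'   `top5`, `next5` and `top10 = top5 + next5`.
#' @examples
#' count_matches(
#'   c("bank", "company", "rates", "dollar", "Canada",
#'     "oil", "sand", "Alberta", "exploitation", "financing"),
#'   c("dollar", "price", "corporation", "oil", "business", "bank")
#' )
#' @export
count_matches <- function(ranking, gold) {
  items <- if (inherits(ranking, "data.frame")) {
    as.character(ranking$item)
  } else {
    as.character(ranking)
  }
  items <- tolower(items)
  gold <- unique(tolower(as.character(gold)))
  gold <- gold[nzchar(gold)]
  head5 <- items[seq_len(min(5L, length(items)))]
  tail5 <- if (length(items) > 5L) items[6L:min(10L, length(items))] else character()
  top5 <- sum(head5 %in% gold)
  next5 <- sum(tail5 %in% gold)
  structure(
    list(
      top5 = as.integer(top5),
      next5 = as.integer(next5),
      top10 = as.integer(top5 + next5)
    ),
    class = "match_counts"
  )
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("<match_counts top5=%d next5=%d top10=%d>\n",
              x$top5, x$next5, x$top10))
  invisible(x)
}

#' Aggregate match counts over a corpus
#'
#' Reported quality for a parameter setting is the total number of matches
#' over all documents, kept separate for ranks 1--5 and ranks 6--10.
#'
#' @param counts A list of [count_matches()] results (one per document).
#' @return Named integer vector `c(total_top5, total_next5)`.
#' @export
aggregate_matches <- function(counts) {
  if (!length(counts)) {
    return(c(total_top5 = 0L, total_next5 = 0L))
  }
  stopifnot(all(vapply(counts, inherits, logical(1), "match_counts")))
  c(
    total_top5 = sum(vapply(counts, `[[`, integer(1), "top5")),
    total_next5 = sum(vapply(counts, `[[`, integer(1), "next5"))
  )
}

#' Read a gold standard from JSON
#'
#' Schema: `{"doc_id": ["topic", ...], ...}`. Topic strings are lowercased
#' and deduplicated.
#'
#' @param path Path to the JSON file.
#' @return Named list mapping document id to a character vector of topics.
#' @export
read_gold_json <- function(path) {
  if (!file.exists(path)) stop("gold standard file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(obj)) stop("gold standard JSON must be an object of arrays")
  lapply(obj, function(x) unique(tolower(as.character(x))))
}

#' Read a gold standard from TSV
#'
#' Two tab-separated columns, no header: document id and one topic per line
#' (Reuters-style expert topic lists). Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping document id to a character vector of topics.
#' @export
read_gold_tsv <- function(path) {
  if (!file.exists(path)) stop("gold standard file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("doc_id", "topic"),
                          colClasses = "character")
  lapply(split(tolower(df$topic), df$doc_id), unique)
}

#' Write a gold standard to JSON
#'
#' @param gold Named list mapping document id to a character vector of topics.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold_json <- function(gold, path) {
  stopifnot(is.list(gold), !is.null(names(gold)))
  jsonlite::write_json(lapply(gold, as.character), path)
  invisible(path)
}
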