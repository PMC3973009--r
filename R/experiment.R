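#' Define a sweep grid over STM capacity and decay rate
#'
#' Defaults mirror the experimental ranges that matter for the model: STM
#' capacities 0--10 in steps of two and decay rates 0 (no decay) through 25;
#' beyond those values quality changes little.
#'
#' @param stm_values Non-negative integers.
#' @param decay_values Non-negative numbers; `0` is the no-decay setting.
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(stm_values = c(0L, 2L, 4L, 6L, 8L, 10L),
                       decay_values = c(0, seq_len(25))) {
  stm_values <- as.integer(stm_values)
  decay_values <- as.numeric(decay_values)
  if (!length(stm_values) || any(is.na(stm_values)) || any(stm_values < 0L)) {
    stop("'stm_values' must be non-negative integers")
  }
  if (!length(decay_values) || any(is.na(decay_values)) ||
      any(decay_values < 0)) {
    stop("'decay_values' must be non-negative numbers")
  }
  structure(
    list(stm_values = unique(stm_values), decay_values = unique(decay_values)),
    class = "sweep_grid"
  )
}

#' Run the STM-capacity x decay-rate sweep over a corpus
#'
#' For every (STM capacity, decay rate) pair in the grid, processes every
#' document with [process_document()], keeps the top 10 topics, counts gold
#' matches with [count_matches()], and sums the counts over the corpus. The
#' upper-quality control baseline (no decay, no STM) is computed once with
#' [baseline_frequency()] and attached to the result. Documents with no gold
#' entry are skipped with a warning.
#'
#' @param documents Named list of normalized token vectors, or a directory
#'   path accepted by [read_corpus_dir()].
#' @param gold Named list of gold topic vectors (ids matching `documents`),
#'   or a path to a gold-standard JSON file.
#' @param grid A [sweep_grid()].
#' @param backend A [lexicon_backend()].
#' @param stopwords,undesirable [word_list()] objects.
#' @param decay_law Passed to [read_params()].
#' @param quiet If `FALSE`, log per-pair progress to stderr.
#' @return An object of classes `sweep_result` and `data.frame` with columns
#'   `stm`, `decay`, `total_top5`, `total_next5` (one row per grid pair) and
#'   attributes `baseline_top5`, `baseline_next5` and `n_docs`.
#' @export
run_sweep <- function(documents, gold, grid = sweep_grid(), backend,
                      stopwords = default_stopwords(),
                      undesirable = default_undesirable(),
                      decay_law = "linear", quiet = TRUE) {
  stopifnot(inherits(grid, "sweep_grid"), inherits(backend, "lexicon_backend"))
  if (is.character(documents) && length(documents) == 1L) {
    documents <- read_corpus_dir(documents, backend, stopwords)
  }
  if (is.character(gold) && length(gold) == 1L) {
    gold <- read_gold_json(gold)
  }
  stopifnot(is.list(documents), !is.null(names(documents)), is.list(gold))
  missing_gold <- setdiff(names(documents), names(gold))
  if (length(missing_gold)) {
    warning("skipping documents with no gold entry: ",
            paste(missing_gold, collapse = ", "))
    documents <- documents[setdiff(names(documents), missing_gold)]
  }
  ids <- names(documents)

  base_counts <- lapply(ids, function(id) {
    count_matches(
      baseline_frequency(documents[[id]], backend, stopwords, undesirable,
                         k = 10),
      gold[[id]]
    )
  })
  baseline <- aggregate_matches(base_counts)

  cells <- expand.grid(
    decay = grid$decay_values, stm = grid$stm_values,
    KEEP.OUT.ATTRS = FALSE
  )[, c("stm", "decay")]
  totals <- t(vapply(seq_len(nrow(cells)), function(r) {
    params <- read_params(
      stm_capacity = cells$stm[r], decay_rate = cells$decay[r],
      decay_law = decay_law
    )
    if (!quiet) {
      message(sprintf("sweep: stm=%d decay=%g", cells$stm[r], cells$decay[r]))
    }
    counts <- lapply(ids, function(id) {
      count_matches(
        process_document(documents[[id]], params, backend,
                         stopwords, undesirable),
        gold[[id]]
      )
    })
    aggregate_matches(counts)
  }, c(total_top5 = 0L, total_next5 = 0L)))

  out <- data.frame(
    stm = cells$stm,
    decay = cells$decay,
    total_top5 = as.integer(totals[, "total_top5"]),
    total_next5 = as.integer(totals[, "total_next5"]),
    stringsAsFactors = FALSE
  )
  attr(out, "baseline_top5") <- unname(baseline["total_top5"])
  attr(out, "baseline_next5") <- unname(baseline["total_next5"])
  attr(out, "n_docs") <- length(ids)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Write sweep results to CSV
#'
#' Columns `stm`, `decay`, `total_top5`, `total_next5`, `baseline`; the
#' control baseline (no decay, no STM) is appended as an extra flagged row if
#' the grid itself did not contain it. Round-trips through [read_results()].
#'
#' @param result A [run_sweep()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  df <- as.data.frame(result)
  df$baseline <- df$stm == 0L & df$decay == 0
  if (!any(df$baseline)) {
    df <- rbind(df, data.frame(
      stm = 0L, decay = 0,
      total_top5 = as.integer(attr(result, "baseline_top5")),
      total_next5 = as.integer(attr(result, "baseline_next5")),
      baseline = TRUE
    ))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sweep results written by [write_results()]
#'
#' @param path CSV path.
#' @return A `sweep_result` data frame (baseline attributes restored from the
#'   flagged row).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stm", "decay", "total_top5", "total_next5", "baseline")
  if (!all(need %in% names(df))) {
    stop("results file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  base_row <- df[df$baseline, , drop = FALSE][1L, ]
  attr(df, "baseline_top5") <- as.integer(base_row$total_top5)
  attr(df, "baseline_next5") <- as.integer(base_row$total_next5)
  class(df) <- c("sweep_result", "data.frame")
  df
}
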