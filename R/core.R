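#' Model parameters for the activation--decay reading loop
#'
#' @param stm_capacity Non-negative integer: number of words the short-term
#'   memory (STM) buffer holds. `0` disables STM entirely (no word is ever
#'   protected, not even the word just read).
#' @param decay_rate Non-negative number, the decay rate eta. `0` means no
#'   decay (the frequency baseline). For `eta > 0` the per-step decay
#'   magnitude is `delta = 1/eta` activation units, so a *low* eta means
#'   *rapid* decay.
#' @param top_k Strictly increasing positive integers: report cutoffs
#'   (default ranks 5 and 10).
#' @param decay_law `"linear"` (subtract `delta`, floor at 0; default) or
#'   `"exponential"` (multiply unprotected activations by `exp(-delta)`).
#' @param activation_increment Positive number added to each retrieved item's
#'   activation per word occurrence. With the default `1`, the no-decay case
#'   equals raw item frequency.
#' @return An object of class `read_params`.
#' @export
read_params <- function(stm_capacity = 0L, decay_rate = 0,
                        top_k = c(5L, 10L),
                        decay_law = c("linear", "exponential"),
                        activation_increment = 1) {
  decay_law <- match.arg(decay_law)
  stm_capacity <- as.integer(stm_capacity)
  if (length(stm_capacity) != 1L || is.na(stm_capacity) || stm_capacity < 0L) {
    stop("'stm_capacity' must be a single non-negative integer")
  }
  if (!is.numeric(decay_rate) || length(decay_rate) != 1L ||
      is.na(decay_rate) || decay_rate < 0) {
    stop("'decay_rate' must be a single non-negative number")
  }
  top_k <- as.integer(top_k)
  if (!length(top_k) || any(is.na(top_k)) || any(top_k <= 0L) ||
      is.unsorted(top_k, strictly = TRUE)) {
    stop("'top_k' must be strictly increasing positive integers")
  }
  if (!is.numeric(activation_increment) || length(activation_increment) != 1L ||
      activation_increment <= 0) {
    stop("'activation_increment' must be a single positive number")
  }
  structure(
    list(
      stm_capacity = stm_capacity,
      decay_rate = as.numeric(decay_rate),
      top_k = top_k,
      decay_law = decay_law,
      activation_increment = as.numeric(activation_increment)
    ),
    class = "read_params"
  )
}

#' Per-step decay magnitude implied by the decay rate
#'
#' `delta = 1/eta` for `eta > 0`, `0` for `eta = 0`: a small eta decays
#' activation quickly, a large eta slowly, and `eta = 0` not at all.
#'
#' @param params A [read_params()] object (or a bare non-negative number,
#'   taken as eta).
#' @return A single non-negative number.
#' @export
decay_delta <- function(params) {
  eta <- if (inherits(params, "read_params")) params$decay_rate else params
  stopifnot(is.numeric(eta), length(eta) == 1L, eta >= 0)
  if (eta > 0) 1 / eta else 0
}

#' Create an empty short-term-memory buffer
#'
#' The buffer stores at most `capacity` distinct words, ordered by recency of
#' rehearsal (least recently rehearsed first).
#'
#' @param capacity Non-negative integer.
#' @return An object of class `stm_buffer` with fields `capacity` and `slots`.
#' @export
stm_buffer <- function(capacity) {
  capacity <- as.integer(capacity)
  stopifnot(length(capacity) == 1L, !is.na(capacity), capacity >= 0L)
  structure(
    list(capacity = capacity, slots = character(0)),
    class = "stm_buffer"
  )
}

#' Read one word into the short-term-memory buffer
#'
#' With capacity 0 the buffer never holds anything. A word already present is
#' *rehearsed*: it moves to the most-recent position and nothing is evicted.
#' A new word is appended; if the buffer then exceeds capacity, the word that
#' has gone longest without rehearsal is evicted and returned.
#'
#' @param buffer An [stm_buffer()].
#' @param word A single token.
#' @return A list with elements `buffer` (the updated buffer) and `evicted`
#'   (the evicted word, or `NULL`).
#' @examples
#' b <- stm_buffer(2)
#' b <- stm_update(b, "a")$buffer
#' b <- stm_update(b, "b")$buffer
#' stm_update(b, "c") # evicts "a"
#' @export
stm_update <- function(buffer, word) {
  stopifnot(inherits(buffer, "stm_buffer"))
  if (!is.character(word) || length(word) != 1L) {
    stop("'word' must be a single string")
  }
  if (buffer$capacity == 0L) {
    return(list(buffer = buffer, evicted = NULL))
  }
  evicted <- NULL
  pos <- match(word, buffer$slots)
  if (!is.na(pos)) {
    buffer$slots <- c(buffer$slots[-pos], word) # rehearsal
  } else {
    buffer$slots <- c(buffer$slots, word)
    if (length(buffer$slots) > buffer$capacity) {
      evicted <- buffer$slots[1L]
      buffer$slots <- buffer$slots[-1L]
    }
  }
  list(buffer = buffer, evicted = evicted)
}

#' Construct an activation state
#'
#' Holds each item's current activation (non-negative; resting level 0) and
#' the reading step at which it was first activated (used to break ranking
#' ties deterministically).
#'
#' @param activation Named non-negative numeric vector.
#' @param first_seen Named integer vector over the same items.
#' @return An object of class `activation_state`.
#' @export
activation_state <- function(activation = numeric(), first_seen = integer()) {
  if (length(activation) && is.null(names(activation))) {
    stop("'activation' must be named by item")
  }
  if (any(activation < 0)) stop("activations must be non-negative")
  if (!setequal(names(activation), names(first_seen))) {
    stop("'first_seen' must cover exactly the items of 'activation'")
  }
  first_seen <- first_seen[names(activation)]
  if (length(activation)) storage.mode(activation) <- "double"
  if (length(first_seen)) storage.mode(first_seen) <- "integer"
  structure(
    list(activation = activation, first_seen = first_seen),
    class = "activation_state"
  )
}

#' @export
print.activation_state <- function(x, ...) {
  cat(sprintf(
    "<activation_state: %d items, %d active>\n",
    length(x$activation), sum(x$activation > 0)
  ))
  invisible(x)
}

#' Apply one decay step
#'
#' Every item *not* in `protected_items` loses activation: under the linear
#' law it is reduced by `delta` and floored at the resting level 0; under the
#' exponential law it is multiplied by `exp(-delta)`. Protected items and
#' first-activation records are untouched.
#'
#' @param state An [activation_state()].
#' @param protected_items Character vector of items shielded from decay
#'   (typically the union of the item lists of all words currently in STM).
#' @param delta Non-negative decay magnitude for this step (see
#'   [decay_delta()]).
#' @param decay_law `"linear"` or `"exponential"`.
#' @return The decayed `activation_state`.
#' @export
decay_step <- function(state, protected_items, delta,
                       decay_law = c("linear", "exponential")) {
  decay_law <- match.arg(decay_law)
  stopifnot(inherits(state, "activation_state"),
            is.numeric(delta), length(delta) == 1L, delta >= 0)
  if (delta == 0 || !length(state$activation)) return(state)
  unprot <- !(names(state$activation) %in% protected_items)
  if (any(unprot)) {
    if (decay_law == "linear") {
      state$activation[unprot] <- pmax(state$activation[unprot] - delta, 0)
    } else {
      state$activation[unprot] <- state$activation[unprot] * exp(-delta)
    }
  }
  state
}

#' Rank activated items as topics
#'
#' Items with positive activation, ordered by decreasing activation; ties are
#' broken by earlier first activation, then lexicographically (C locale), so
#' rankings are fully deterministic.
#'
#' @param state An [activation_state()].
#' @param k Maximum number of topics to return (default: all positive).
#' @return An object of classes `topic_ranking` and `data.frame` with columns
#'   `rank`, `item`, `activation`.
#' @export
rank_topics <- function(state, k = Inf) {
  stopifnot(inherits(state, "activation_state"), k >= 1 || k == Inf)
  av <- state$activation
  keep <- av > 0
  av <- av[keep]
  if (!length(av)) {
    out <- data.frame(
      rank = integer(), item = character(), activation = numeric(),
      stringsAsFactors = FALSE
    )
    class(out) <- c("topic_ranking", "data.frame")
    return(out)
  }
  fs <- state$first_seen[names(av)]
  ord <- order(-av, fs, names(av), method = "radix")
  n <- min(length(ord), k)
  sel <- ord[seq_len(n)]
  out <- data.frame(
    rank = seq_len(n),
    item = names(av)[sel],
    activation = unname(av[sel]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("topic_ranking", "data.frame")
  out
}

#' Process a document with the activation--decay reading loop
#'
#' For each token in reading order: (1) retrieve the token's items and add
#' `activation_increment` to each (recording the step of first activation);
#' (2) update the STM buffer with the token (insert, rehearse, or evict);
#' (3) apply one decay step of magnitude `1/eta` to every item not protected
#' by STM, where the protected set is the union of the item lists of all
#' words currently in the buffer. With `stm_capacity = 0` nothing is ever
#' protected -- the current word's items decay on the very step that
#' activated them. With `decay_rate = 0` the result equals
#' [baseline_frequency()] exactly.
#'
#' @param tokens Character vector of document tokens in reading order,
#'   already normalized by [normalize_document()].
#' @param params A [read_params()] object.
#' @param backend A [lexicon_backend()].
#' @param stopwords,undesirable [word_list()] objects used to filter items.
#' @return A [rank_topics()] ranking over all items with positive final
#'   activation.
#' @examples
#' lex <- lexicon_backend(list(w1 = "i1", w2 = "i2", w3 = "i3"))
#' none <- word_list(character(), "stopwords")
#' und <- word_list(character(), "undesirable")
#' process_document(c("w1", "w2", "w3"), read_params(0, 2), lex, none, und)
#' @export
process_document <- function(tokens, params = read_params(), backend,
                             stopwords = default_stopwords(),
                             undesirable = default_undesirable()) {
  stopifnot(inherits(params, "read_params"),
            inherits(backend, "lexicon_backend"))
  tokens <- as.character(tokens)
  act <- numeric(0)
  fs <- integer(0)
  buf <- stm_buffer(params$stm_capacity)
  delta <- decay_delta(params)
  inc <- params$activation_increment
  law <- params$decay_law

  for (step in seq_along(tokens)) {
    w <- tokens[[step]]
    items <- items_for_word(w, backend, stopwords, undesirable)
    if (length(items)) {
      new <- items[!(items %in% names(act))]
      if (length(new)) {
        act[new] <- 0
        fs[new] <- step
      }
      act[items] <- act[items] + inc
    }
    buf <- stm_update(buf, w)$buffer
    if (delta > 0 && length(act)) {
      protected <- if (length(buf$slots)) {
        unique(unlist(
          lapply(buf$slots, items_for_word,
                 backend = backend, stopwords = stopwords,
                 undesirable = undesirable),
          use.names = FALSE
        ))
      } else {
        character(0)
      }
      unprot <- !(names(act) %in% protected)
      if (any(unprot)) {
        if (law == "linear") {
          act[unprot] <- pmax(act[unprot] - delta, 0)
        } else {
          act[unprot] <- act[unprot] * exp(-delta)
        }
      }
    }
  }
  state <- structure(list(activation = act, first_seen = fs),
                     class = "activation_state")
  rank_topics(state)
}

#' Frequency baseline: topics without decay and without STM
#'
#' Counts, over the whole document, how many word occurrences retrieve each
#' item, and ranks items by that count with the same tie-breaking as
#' [rank_topics()]. This is the control condition: the reading loop with
#' `stm_capacity = 0` and `decay_rate = 0` must reproduce it exactly.
#'
#' @inheritParams process_document
#' @param k Maximum number of topics to return.
#' @return A `topic_ranking`.
#' @export
baseline_frequency <- function(tokens, backend,
                               stopwords = default_stopwords(),
                               undesirable = default_undesirable(),
                               k = Inf) {
  stopifnot(inherits(backend, "lexicon_backend"))
  tokens <- as.character(tokens)
  per_tok <- lapply(tokens, items_for_word,
                    backend = backend, stopwords = stopwords,
                    undesirable = undesirable)
  all_items <- unlist(per_tok, use.names = FALSE)
  if (!length(all_items)) {
    return(rank_topics(activation_state()))
  }
  steps <- rep(seq_along(per_tok), lengths(per_tok))
  counts <- table(all_items)
  first <- tapply(steps, all_items, min)
  items <- names(counts)
  state <- activation_state(
    activation = stats::setNames(as.numeric(counts), items),
    first_seen = stats::setNames(as.integer(first[items]), items)
  )
  rank_topics(state, k)
}
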