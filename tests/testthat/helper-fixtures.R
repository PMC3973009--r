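# Shared fixtures: tiny lexicons and word lists built in code.

empty_stopwords <- function() word_list(character(), "stopwords")
empty_undesirable <- function() word_list(character(), "undesirable")

# Lexicon with disjoint single-item entries: wN -> iN
disjoint_backend <- function(n = 3) {
  entries <- stats::setNames(
    as.list(sprintf("i%d", seq_len(n))),
    sprintf("w%d", seq_len(n))
  )
  lexicon_backend(entries)
}

gold_fixture_backend <- function() {
  lexicon_json(
    system.file("extdata", "gold_senses.json", package = "readtopics")
  )
}

# The printed item list for "gold" (the duplicated "amber" deduplicated).
gold_expected_items <- c(
  "gold", "coins", "precious", "metal", "common", "valuable", "metals",
  "jewelry", "amber", "deep", "yellow", "color", "light", "illuminated",
  "room", "yellowness", "pigment"
)

# The worked evaluation example: a ranked top-10 list and its gold set.
worked_ranking <- c(
  "bank", "company", "rates", "dollar", "Canada",
  "oil", "sand", "Alberta", "exploitation", "financing"
)
worked_gold <- c("dollar", "price", "corporation", "oil", "business", "bank")

# Activation per item recovered from a ranking, as a named vector
# (items absent from the ranking sit at the resting level 0).
activation_of <- function(ranking, items) {
  av <- stats::setNames(rep(0, length(items)), items)
  av[ranking$item] <- ranking$activation
  av
}
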