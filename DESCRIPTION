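Package: readtopics
Title: Topic Identification by Activation and Decay of Lexical Long-Term Memory
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates how a reader identifies the topics of a single document
    from existing lexical knowledge, with no corpus training. Each word read
    retrieves unstructured "items" (single words drawn from dictionary sense
    records) that act as surrogates for loosely organized long-term-memory
    ideas; item activation accumulates with recurrence, decays when a word
    leaves a limited-capacity short-term-memory buffer, and the most activated
    items are reported as topics. Includes exact string-match evaluation
    against gold-standard topic lists, a synthetic corpus generator with
    planted themes, a reproducible sweep over short-term-memory capacity and
    decay rate, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
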