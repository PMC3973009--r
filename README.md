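# readtopics

Topic identification by activation and decay of lexical long-term memory.

## The problem

The topics of a text are its main themes. Most computational approaches learn
them from the statistics of large corpora. `readtopics` instead simulates how
a *single reader with existing knowledge* might identify the topics of a
*single document*: as a frequency computation over loosely organized ideas in
long-term memory (LTM), carried out by neural activation that inevitably
decays, with a small short-term-memory (STM) buffer keeping the focus of
attention on recent words. The package is aimed at computational cognitive
modellers who want to study how activation dynamics, decay speed and STM
capacity interact in deriving basic document meaning — not at beating modern
topic-modelling systems.

## The model

Reading proceeds word by word. For the *t*-th word read:

1. **Retrieval.** The word's *items* are retrieved from the lexicon — every
   single word occurring in any of its dictionary sense records (synset
   members, definitions, direct hypernyms, example glosses), with stop words
   and overly general "undesirable" words removed, and no stemming. Items are
   surrogates for unstructured LTM ideas; all senses contribute (exhaustive
   access, no disambiguation).
2. **Activation.** Each retrieved item *i* gains one unit of activation:
   *a(i) ← a(i) + 1*.
3. **STM update.** The word enters a bounded buffer of capacity *C*. A word
   already present is *rehearsed* (moved to most recent); otherwise the word
   that has gone longest without rehearsal is evicted.
4. **Decay.** Every item not retrieved by any word currently in STM loses
   *δ = 1/η* activation, floored at the resting level 0. The decay rate
   *η ≥ 0* is oriented so that a *small* η means *rapid* decay, and *η = 0*
   means no decay at all.

After the last word, items are ranked by decreasing activation (ties: earlier
first activation, then alphabetical). The top ranks are the topics. With
*C = 0* and *η = 0* the procedure reduces exactly to ranking items by raw
retrieval frequency — the control baseline.

Quality is measured as a direct count of exact string matches between ranked
topics and a human gold standard, counted separately for ranks 1–5 and 6–10
and summed over a corpus.

## Worked example

A miniature lexicon in which several words share the idea "love":

```r
library(readtopics)

lex <- lexicon_backend(list(
  red   = c("blood", "love", "color", "stop", "danger"),
  rose  = c("flower", "love", "red"),
  heart = c("organ", "love", "blood"),
  bank  = c("money", "river")
))
none <- word_list(character(), "stopwords")
nou  <- word_list(character(), "undesirable")

doc <- c("red", "rose", "bank", "heart", "rose")
process_document(doc, read_params(stm_capacity = 2, decay_rate = 2),
                 lex, none, nou)
#>   rank   item activation
#> 1    1   love        4.0
#> 2    2  blood        1.5
#> 3    3 flower        1.5
#> 4    4    red        1.5
#> 5    5  organ        1.0
#> 6    6  money        0.5
#> 7    7  river        0.5
```

Although no single word "means" love, the recurring retrieval of that shared
item accumulates the most activation (4 units), so it surfaces as the topic.
Items retrieved only once ("money", "river") have mostly decayed back toward
rest; items still protected by the 2-word STM buffer kept more.

Dictionary-style sense records work the same way. The bundled fixture holds
the two noun senses of "gold" (synsets, definitions, a gloss, and hypernyms):

```r
g <- lexicon_json(system.file("extdata", "gold_senses.json",
                              package = "readtopics"))
lookup_items("gold", g)$items
#>  [1] "gold"        "coins"       "precious"    "metal"       "common"
#>  [6] "valuable"    "metals"      "jewelry"     "amber"       "deep"
#> [11] "yellow"      "color"       "light"       "illuminated" "room"
#> [16] "yellowness"  "pigment"
```

Evaluation is an exact string-match count, split by rank band:

```r
count_matches(
  c("bank", "company", "rates", "dollar", "canada",
    "oil", "sand", "alberta", "exploitation", "financing"),
  c("dollar", "price", "corporation", "oil", "business", "bank")
)
#> <match_counts top5=2 next5=1 top10=3>
```

Larger experiments run through `synth_spec()` / `generate_corpus()` (a
seeded corpus with planted themes and its gold standard) and `run_sweep()`
(the STM capacity × decay rate grid with the no-decay baseline attached), or
through the CLI:

```sh
read-topics synth --out corpus/ --seed 42
read-topics sweep --corpus corpus/ --gold corpus/gold.json \
  --lexicon corpus/lexicon.json --stm 0,2,4,6,8,10 --decay 0,1,5,25 \
  --out results.csv
```

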