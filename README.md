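# tprmetrics

Word-level translation product metrics and reading measures for
translation process research.

Researchers who study how translators work relate properties of a source
text and its translation ("product" features) to eye-tracking and
keystroke records of the translation session ("process" measures). This
package computes the product side at the level of the individual source
word — how far its translation moved, how tangled its alignments are, how
much translators disagree about it, and whether its syntactic role
survived translation — and the standard reading-time variables those
metrics are regressed against, emitting per-token tables ready for any
mixed-model backend.

## What it computes

Given a tokenized, word-aligned sentence pair (Pharaoh `"i-j"` links,
0-based):

* **Cross** — signed relative reordering: the position of a word's
  (leftmost) translation minus the position of the previous word's
  translation. A monotone one-to-one ("absolutely literal") translation
  has Cross = 1 everywhere; `abs_cross` is its absolute value.
* **word_cross** — the number of times the word's alignment links cross
  any other link: links (i, j) and (i′, j′) cross iff
  (i − i′)(j − j′) < 0; counts are summed over a word's links.
* **seq_cross** — the same crossing count computed between *word groups*.
  Groups are maximal consistent aligned blocks, internally monotone
  one-to-one or — for multi-word groups (MWGs) — fully bipartite
  (every source word aligned with every target word); each group carries
  one group-level link and passes its value to all member words.
* **astred_change** — after relabeling both Universal Dependencies trees
  so that only aligned words can match (via alignment-graph components),
  an ordered tree edit distance (match 0, rename/delete/insert 1) decides
  per source word whether its node matched (`FALSE`) or required an edit
  (`TRUE`).

Given several translations of the same source sentence, the entropy
family, in bits, H(X) = −Σ P(e) log₂ P(e) over per-version events:

* **HTra** — events are the normalized target renderings of the word
  (lexical disagreement);
* **HCross** — events are the word's Cross values (reordering
  disagreement);
* **HSTC** — events are (source group, target group, group Cross)
  triplets of the word's alignment component (joint disagreement).

Given token-attributed fixation and keystroke logs: first fixation
duration (FFDur), total reading time (TrtS), eye-key span (EKS),
first-pass and regression-path duration (FPD/RPD), per-participant
±2.5 SD outlier exclusion, and the log transform.

A deterministic synthetic generator (`simConfig()`, `genPair()`,
`genEnsemble()`, `genEventLog()`) produces aligned pairs with known group
structure, ensembles with known entropy, and event logs with known gold
measures, so every contract is testable without any external data.

## Worked example

The package ships the canonical MWG configuration: English
"they are called marine sentinels" aligned to Dutch
"ze worden wachters van de zee genoemd", where "marine sentinels" ↔
"wachters van de zee" is a full bipartite 2 × 4 block and "called" ↔
"genoemd" crosses it.

```r
library(tprmetrics)
ex <- mwgExamplePair()
reorderingProfile(ex)
#>   token_index     token cross abs_cross word_cross seq_cross
#> 1           0      they     1         1          0         0
#> 2           1       are     1         1          0         0
#> 3           2    called     5         5          8         1
#> 4           3    marine    -4         4         10         1
#> 5           4 sentinels     0         0         10         1
```

Reading the "called" row: its single link crosses all eight word
alignments of the idiom block (`word_cross` = 8), but after group
construction the block is one unit with one link, so at group level
"called" crosses once (`seq_cross` = 1). Its translation sits five
positions right of the previous word's translation (`cross` = 5). The MWG
members inherit their group's value 1.

Augmenting a per-token table attaches all metric columns in one call:

```r
tab <- augmentTable(readTokenTable("tokens.tsv"),
                    readBundles("sentences.jsonl"))
```

A thin command-line front-end (`inst/cli/tprmetrics`, or `runCli()`
in-process) exposes the same operations as subcommands: `metrics`,
`entropy`, `astred`, `measures`, `augment`, `simulate`.

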