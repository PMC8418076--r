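---
title: "Word-level translation product metrics: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word-level translation product metrics: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tprmetrics)
```

# The problem

Translation process research asks how properties of a source text and its
translation relate to the cognitive effort a translator spends, as proxied
by eye-tracking and keystroke measures. A recurring operationalisation of
"literal translation" is word-order correspondence: in an absolutely
literal translation every source word has exactly one translation and the
word order is preserved. tprmetrics implements a family of word-level
metrics that quantify departures from that ideal — reordering of single
words and of word groups, structural divergence of dependency trees, and
the disagreement among multiple translators — together with the reading
measures they are typically regressed against.

All metrics operate on a `SentencePair`: a tokenized source sentence, a
tokenized target sentence, and a set of word-alignment links in the Pharaoh
`"i-j"` dialect (0-based on both sides). Tokens may be unaligned or
multiply aligned; links form a set. Tokenization and alignment are inputs —
the package never aligns or tokenizes.

# Reordering metrics

## Cross

`crossValues()` walks the source tokens left to right. Each aligned token
points at the 1-based position of its *leftmost* aligned target token; its
Cross value is that position minus the position pointed at by the previous
aligned source token, with 0 as the starting reference. A monotone
one-to-one pair therefore has Cross = 1 everywhere; positive values mean
the translation moved rightward relative to the previous word's
translation, negative values leftward.

Two conventions are deliberate and form the single source of truth for
this implementation:

* a multiply aligned token is represented by its leftmost target (the
  head of its translation span for reading order purposes);
* unaligned tokens yield `NA`, not 0 — a word without a translation has no
  reordering value, and the pointer simply skips it.

## word_cross

Two links $(i, j)$ and $(i', j')$ cross iff $(i - i')(j - j') < 0$: the
source order is inverted on the target side. A token's `wordCross()` value
is the sum over its incident links of each link's crossing count. Summing
(rather than averaging) over a token's links means a token aligned into a
large inverted block accumulates every one of those inversions; the same
convention is applied to target-side queries. The count is computed by the
direct $O(L^2)$ pairwise definition — link sets per sentence are small and
the quadratic form is trivially auditable; the test suite compares it
against an independently coded enumerator on hundreds of random pairs.

## Sequence groups and seq_cross

Translators do not work word by word; idioms and free renderings align as
blocks. `buildSequenceGroups()` partitions the aligned tokens into maximal
groups: a contiguous source span and a contiguous target span such that

1. no member aligns outside the group (phrase consistency),
2. every member token is aligned, and
3. internally the alignment is monotone one-to-one, **or** the multi-word
   group (MWG) alternative holds: every source member is aligned with
   every target member (a full bipartite $m \times n$ block).

Groups are grown greedily left to right, always preferring the larger
source span, which makes the output deterministic and maximal. An aligned
token that fits no group becomes a singleton carrying its original word
links. A contiguous or MWG group contributes a *single* group-level link;
this is the point of the construction: a full bipartite $2 \times 4$ block
contains eight mutually crossing word links, but as a group it is one unit
and one link. `seqCross()` then counts crossings among group-level links
exactly as `wordCross()` does among word links, and every member word
inherits its group's value.

The canonical illustration ships as `mwgExamplePair()`: "marine sentinels"
translated as "wachters van de zee" (full bipartite 2 × 4) with "called"
rendered clause-finally as "genoemd". The single link of "called" crosses
all eight word alignments of the block — `wordCross()` = 8 — but only one
group link, so `seqCross()` = 1:

```{r example}
ex <- mwgExamplePair()
reorderingProfile(ex)
```

The group requirements are stated here operationally (consistency, full
alignment, monotone-1-1 or full-bipartite, maximality) because they pin
down both published worked values; treating the internal-structure clause
as monotone one-to-one is this package's documented reading of the
requirement that MWGs are exempt from.

# Entropy metrics over translation ensembles

With $N \ge 2$ translations of the same source sentence
(`TranslationEnsemble`), disagreement among translators becomes
measurable. All three metrics instantiate
$H(X) = -\sum_{e} P(e) \log_2 P(e)$ (`entropyBits()`), with probabilities
estimated as relative frequencies over the available versions — no
smoothing, matching the conditional "in this context" reading of the
probabilities. Results are in bits and bounded by $\log_2 N$.

* **HTra** — lexical choice. The event is the normalized rendering of the
  target tokens aligned to the source token: lowercased, outer whitespace
  stripped, multi-token renderings joined with single spaces in target
  order. Normalization matters: entropy must not split on trivial
  casing/whitespace variants, and the exact rule is fixed so results are
  reproducible bit-for-bit. Surface forms, not lemmas, are used.
* **HCross** — reordering choice. The event is the token's signed Cross
  value in each version.
* **HSTC** — joint lexical/reordering choice. Per version the event is the
  triplet $(s, t, c)$ of the token's *alignment group*: the connected
  component of the bipartite alignment graph containing it
  (`alignmentComponents()`), rendered as lowercased space-joined source
  and target member strings plus the component's group-level Cross value.
  Components are ordered by leftmost source index and their target
  position is the rank of their leftmost target index; applying the Cross
  pointer convention to that component sequence yields one $c$ per
  component, so all source words of a group share it by construction.

A version in which the token is unaligned contributes no event by default;
`dropUnaligned = FALSE` turns "untranslated" into a distinct event instead.
The default mirrors the view that an untranslated occurrence carries no
evidence about the choice distribution; the switch exists because the
opposite position is defensible.

# Aligned syntactic tree edit distance

`astredChange()` compares the dependency structures of source and target
sentence while respecting the word alignment. Both sentences must parse to
single rooted Universal Dependencies trees (`readConllu()`; multiword
ranges and empty nodes are skipped, and sentences that do not form exactly
one rooted tree are rejected — mirroring a pipeline in which only 1-to-1
sentence translations are analysed).

Naive tree edit distance over relation labels would happily match
unrelated words that coincidentally share a label. The aligned variant
first merges labels (`mergeLabels()`): every node of an aligned word gets
its alignment component's identifier as label, so aligned words share
labels across trees and unaligned nodes get side-prefixed labels that can
match nothing. The published description of the full merging procedure is
a guarantee ("aligned words end up with the same label; only aligned words
can match") rather than an algorithm; component identifiers are this
package's realization of that guarantee, and one-to-many alignments
spanning different subtrees are handled by the component construction.

`treeEditDistance()` then computes ordered tree edit distance under unit
costs (match 0, rename/delete/insert 1). The implementation evaluates the
classical rightmost-root recurrence of ordered-forest edit distance
top-down with memoisation, which keeps the deterministic tie-break
explicit — at equal cost, substitution (match/rename) is preferred over
deletion, deletion over insertion — and makes the backtrace that recovers
per-node operations straightforward. Link and sentence sizes in this
domain are tens of tokens, so the asymptotic refinements of keyroot-based
evaluation are unnecessary; the test suite proves the implementation equal
to an exhaustive search over all ancestry- and order-preserving edit
mappings on hundreds of random small trees.

A source word's `astred_change` is `FALSE` iff its node is a match in the
optimal script; the operation itself (match/rename/delete) is reported
alongside, because collapsing rename and delete loses information some
analyses may want.

# Process measures and filtering

Event logs are consumed with token attribution already present (the
standard translation-process pipelines attribute fixations and keystrokes
to source tokens during export); re-deriving attribution is out of scope.
From a fixation log (participant, token, onset, duration) and a keystroke
log (participant, time, contributing token):

* `firstFixationDuration()` — duration of the earliest fixation on the
  token; two fixations tied for earliest are an ambiguous log and an
  error.
* `totalReadingTime()` — sum of all fixations on the token.
* `eyeKeySpan()` — first contributing keystroke time minus first fixation
  *onset*. The defining phrase "time between the first fixation and the
  first keystroke" does not say onset or offset; onset is chosen and
  fixed. A keystroke preceding the first fixation yields `NA` with a
  diagnostic rather than a negative span.
* `firstPassDuration()` / `regressionPathDuration()` — the standard
  early/late window measures: consecutive-prefix sum, and sum of all
  fixations on the token and earlier tokens until the first fixation to
  its right.

`excludeOutliers()` implements per-participant filtering: drop
observations more than $k = 2.5$ sample standard deviations from the
participant's mean. It is single-pass — statistics come from the full
data, deliberately not iterated — and a zero-variance group keeps all its
points. On standard-normal data the expected loss is the two-sided tail
mass beyond 2.5 sd, about 1.24%. The same function applied to a residual
column reproduces residual-outlier exclusion; model fitting itself is out
of scope, the emitted tables are model-ready for any stats backend.
`logTransform()` is the natural log (the base is a scale choice only, and
is recorded in the output's `base` attribute).

# Table augmentation

`augmentTable()` adds `cross`, `abs_cross`, `word_cross`, `seq_cross`,
`astred_change`, `htra`, `hcross`, `hstc` to a per-token TSV table keyed
by (participant, sent_id, word_id). Single-translation metrics use the
row's own participant's version from the sentence bundle; entropy metrics
use all versions of the sentence at once. Tables are read wholesale as
character columns so that an untouched table rewrites byte-identically;
sentence segmentation is carried by explicit id columns, never re-derived
from punctuation. Existing metric columns are never silently overwritten
(`force = TRUE` replaces them). The TSV dialect is header row, tab
separator, UTF-8, `NA` for missing.

# The synthetic generator

`simConfig()` fixes the study conditions the generators emulate:
ensembles of about ten translations per source text (the scale at which
translation entropies are usually computed), news-like sentence lengths
(15 tokens), modest reordering (`reorderRate = 0.15` expected inversion
density), occasional idiomatic blocks (`mwgProb = 0.1`, source width 2,
target width 2–4), fixation durations around 220 ± 50 ms, a 30%
refixation rate, 20% regressions, and typing latencies around 800 ± 300
ms. Where a published value exists (ensemble size ~10) the default is that
value; the remaining timing and rate defaults are fixed once at values a
reading researcher would call unremarkable, and are not tuned thereafter.

`genPair()` builds pairs group-wise and returns the generating structure
as gold labels, so group recovery is testable against construction truth.
`genEnsemble()` samples renderings from per-token distributions whose
exact entropy is known (`stratified = TRUE` forces counts, making
small-sample entropies exact). `genEventLog()` simulates a left-to-right
reading pass with parameterized refixations, regressions and typing
bursts, and records every measure's gold value *during generation*, so
measure implementations are tested against the construction rather than
against themselves. One master seed fans out to per-generator substreams:
adding a generator never perturbs existing fixtures, and identical seeds
give byte-identical output.

What the generator does *not* emulate: saccade landing-position noise,
fixation detection error, parafoveal preview, revision passes over the
target text, or any cognitive coupling between metric values and reading
times. Passing tests therefore demonstrate contract correctness of the
measures and metrics, not ecological validity on real gaze data.

# Numerical and degenerate-input choices

* Entropy uses $\log_2$ throughout; $0 \log 0 = 0$; empty distributions
  are a domain error, single-event distributions are exactly 0 bits.
* Crossing counts and Cross values are integers; no floating point is
  involved anywhere in the reordering metrics.
* Group construction ties are broken by the left-to-right greedy order and
  the larger-source-span preference; component and group orderings are by
  leftmost member, so all outputs are deterministic.
* The TED tie-break (substitution > delete > insert, resolved in
  rightmost-first order) makes `astred_change` deterministic; equal-cost
  scripts exist and the reported one is the canonical choice.
* Empty alignments are legal everywhere: all per-token metrics are `NA`,
  group lists are empty, entropies undefined (`NA`).
* Problem sizes in the shipped tests are chosen for exhaustive
  verifiability: oracle equivalence uses pairs up to 15 × 15 tokens and
  trees up to 6 nodes (where full mapping enumeration is feasible), and
  entropy recovery uses 5 000-version ensembles over a 3-way lexical
  distribution.

# Known limitations

* The group requirements beyond the two published worked values are this
  package's operational reading; corpora with pathological alignment
  patterns (interleaved many-to-many blocks that are neither monotone nor
  full-bipartite) fall back to singletons, which is conservative for
  seq_cross.
* The label-merging procedure realizes the published guarantee via
  alignment components; other realizations consistent with the same
  guarantee could produce different (equally defensible) rename/delete
  splits on heavily divergent trees, though the match/no-match partition
  for aligned nodes is stable.
* Entropy estimates at small ensemble sizes are biased low (plug-in
  estimator); the package reports the plug-in value by design, matching
  field practice, and makes no small-sample correction.
* `excludeOutliers()` with very small groups rarely excludes anything —
  the sample sd is inflated by the very point under test; this is a
  property of the published rule, not of the implementation.
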