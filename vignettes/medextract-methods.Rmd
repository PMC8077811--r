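---
title: "Methods: hybrid rule/neural medication extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid rule/neural medication extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own method: the model, the
choices that were genuinely open, the numerical conventions, and what the
synthetic test bed does and does not show about real clinical text.

## Task and data model

The task is token-level extraction of seven entity categories from French
clinical text: two drug categories (`medication_name`, `medication_class`)
and five attributes of a drug mention (`dosage`, `frequency`, `duration`,
`route`, `condition` of intake). All layers communicate through two
representations:

* **Entity spans** — 0-based, half-open character offsets into the
  *normalized* text, with a `source` layer (`gold`, `rule`, `model`). A
  per-character offset map links normalized positions back to the raw
  document for display.
* **IOB sequences** — per sentence, one tag per token over the 15-tag set
  `{O} ∪ {B-,I-} × 7`; the first token of an entity is `B-c`, subsequent
  tokens `I-c`.

## Preprocessing

Normalization applies, in order: removal of acronym-internal periods
("I.V." → "IV") and replacement of decimal points between digits by
commas; removal of line breaks that are document-conversion artifacts;
accent stripping; apostrophes → spaces. Case is preserved; matching
layers fold case themselves. Sentence boundaries are the remaining
periods and line breaks, except where the adjacent word is in a
configurable continuation list; tokens are maximal alphanumeric runs or
maximal runs of one repeated non-alphanumeric character.

Decisions that the preprocessing contract left open, and how this package
resolves them:

* *Acronym periods.* A period is removed when it sits between single
  uppercase letters, and a trailing period chained to such a pattern is
  removed too ("I.V." → "IV", not "IV."). The cost is that an acronym
  ending a sentence silently merges with the next one; prescriptions
  rarely end sentences with acronyms, and the alternative (keeping the
  trailing period) misparses the far more frequent mid-sentence "en I.V.
  2 fois" case.
* *Wrap artifacts.* A line break is replaced by a space when its line
  does not end with a period and the next line starts lowercase;
  otherwise it is a sentence-boundary candidate. This is a heuristic: a
  hard-wrapped line starting with an uppercase proper noun will still
  split.
* *Continuation words.* The shipped list (`inst/extdata/continuation_fr.txt`,
  ~35 entries) holds prepositions and conjunctions, checked on *both*
  sides of a candidate boundary. Verb-based boundary blocking would need
  a lexicon or tagger we deliberately do not depend on; this divergence
  is accepted and documented here.
* *Span/token reconciliation.* A character span labels every token it
  overlaps by at least one character (any-overlap). This matches the
  granularity of token-level evaluation; the alternative
  (majority-overlap) only differs for spans that split tokens, which the
  generator never produces and real annotation guidelines discourage.

Normalization is idempotent and total; both properties are tested on
fuzzed inputs.

## Rule layer

The dictionary is built from drug tables (surface, ATC code, entry type),
normalized with the package tokenizer, case-folded and deduplicated.
Matching is exact at the token-sequence level, longest-leftmost — chosen
for precision, which is the design goal of a pre-annotation layer. A
surface listed as both name and class resolves to `medication_name`
(names dominate prescription text) and is logged.

Attributes are extracted only around anchors. Defaults: same sentence,
both directions, ≤ 10 tokens from the anchor (configurable per rule);
attribute spans attach to their nearest anchor; overlaps resolve by
attribute priority `dosage > frequency > duration > route > condition`
(mirroring corpus frequency), then match length. The shipped French rule
inventory (16 patterns across the five attributes: numeric doses with
units or galenic forms, "X fois par jour" / "toutes les X heures"
frequencies, "pendant X jours" durations, administration routes, "si …" /
"en cas de …" conditions) is an original artifact: the mechanism is
fixed, the inventory is expected to be adapted per corpus and can be
supplied as a YAML file.

## Embedding providers

Providers implement one contract — token sequence in, fixed-dimension
vector sequence out — and are frozen once trained:

* **Static** skip-gram with negative sampling, trained on the (training)
  corpus only. Default dimension 100, window 5, 5 negatives, 3 epochs:
  standard small-corpus settings; the tagger, not the embedding, carries
  most of the capacity. Out-of-vocabulary tokens map to one seed-fixed
  unknown vector.
* **Subword**: the same objective, but a word's input vector is the mean
  of its character n-gram vectors (n = 3–6, plus the whole word), so
  unseen words compose vectors from known n-grams.
* **Contextual**: a small character-aware recurrent language model (one
  forward and one backward character LSTM); a token's vector concatenates
  the forward state at its last character with the backward state at its
  first. This implements the contextual-provider contract at package
  scale; reproducing large pretrained clinical language models is out of
  scope by design.

The rule layer enters the tagger as a 15-dimensional one-hot encoding of
its IOB tag, concatenated after the embedding block. The tag order is
fixed (`O`, then `B-c`/`I-c` per category), so ablating the rule features
is exactly "drop the last 15 columns".

## Tagger and training schedule

The tagger is a bidirectional LSTM: forward and backward encoders over
the per-token inputs, hidden states concatenated, then either a dense
softmax over the 15 tags or a linear-chain CRF (emissions plus a 15 × 15
transition table). Sentences are batched with end-padding and loss
masking; because pads trail, recurrent state never leaks from padding
into a real token's loss.

CRF training minimizes the sequence-level categorical cross-entropy (the
CRF negative log-likelihood). Its gradient is precisely the
forward–backward marginals minus the gold indicators — marginal-based
optimization — and decoding uses per-token marginal argmax by default
with joint Viterbi behind a flag, so the marginal and joint readings can
be compared. All gradients (LSTM backpropagation through time, CRF
emission and transition gradients) are verified against numerical
differentiation in the test suite.

Schedule: Adam at 0.001, at most 50 epochs, early stopping after 8 epochs
without a development-loss improvement, learning rate × 0.1 after 3
epochs without an improvement larger than 1e-4 (the trigger threshold and
window are this package's choice; only the factor and trigger kind were
fixed upstream). The checkpoint returned is the best development *loss*;
development F is logged alongside so the alternative selection rule can
be audited. Hyperparameter search is uniform random sampling of 15
configurations from the grids (hidden 128/256/512, batch 64/128, dropout
{0, .1, .2, .3, .5, .6, .7} at input, output and recurrence), scored by
development micro-F.

## Evaluation

Token scoring compares classes and ignores the B/I prefix (a gold
`B-dosage` predicted `I-dosage` is a true positive); a wrong-class
prediction is simultaneously a false positive of the predicted class and
a false negative of the gold class. Micro-averaging pools counts over
classes. Zero denominators yield 0 with an explicit flag rather than NaN.

Slot-level scoring aligns gold and predicted slots — per sentence — with
an **exact optimal matching** rather than a greedy one: slots from IOB
tags are ordered and disjoint, so any matching with positive overlaps is
non-crossing and a quadratic dynamic program enumerates the optimum
exactly. The objective is lexicographic: maximize total token overlap
(weight 4) plus bonuses for matching class (2) and exact boundaries (1);
ties broken by more matched pairs, then the lexicographically earliest
pair list, making the optimum unique and independently checkable by brute
force (the suite verifies equality on a thousand random pairs). Matched
pairs classify as correct, type error (same boundaries, other class),
frontier error (same class, other boundaries), or both (one type plus one
frontier); unmatched gold slots are deletions, unmatched predictions
insertions, and

SER = (D + I + 0.5 · (T + Fr)) / R.

The half-weighting of substitution-like errors is the convention under
which the published component/aggregate pairs for this metric are
internally consistent, and `ser_from_rates()` reproduces them exactly.
Reports are on the percent scale, rounded to two decimals at print time
only.

## Synthetic corpus

The generator emulates prescription-style sentences with a slot grammar
`<prefix> <drug> [<dosage>] [<frequency>] [<duration|route|condition>]`,
French surface inventories, and exact gold spans recorded during
assembly. Defaults are the package's standard study conditions, chosen
once: 320 documents of 3–6 sentences (split 216/24/80), attribute
presence probabilities that reproduce a prescription-corpus frequency
profile (names most frequent, dosage ≈ frequency next, class moderate,
condition > duration > route rare), 30% alias noise, 30% paraphrase
noise, 2% typo noise, 25% entity-free distractor sentences. Each noise
kind targets one rule-layer failure mode: aliases remove the anchor
(deletion errors), paraphrases escape the rule inventory (attribute
deletions), typos corrupt surfaces. Generated text is emitted already in
normalized form, and attribute blocks are kept within the default rule
window, so that at zero noise the rule layer is exact by construction —
the anchor for the clean-corpus acceptance check.

What passing on this corpus does **not** show: robustness to real
clinical spelling variation, section headers, tables, negation or
hedging, coordination ("doliprane et kardegic 1 cp chacun"), or
discontinuous/nested mentions — none of which the generator produces.
The synthetic results demonstrate that the machinery (rules, fusion,
tagger, metrics) is correct and that the qualitative precision/recall
asymmetry and the rule/neural synergy reproduce at desk scale; absolute
F-measures on real corpora are a different question.

## Problem sizes

The shipped tests run the full hybrid comparison at reduced scale — 320
synthetic documents, static embeddings of dimension 100 (3 epochs),
hidden size 128, batch 64, 15 training epochs — sizes chosen so the whole
suite completes in a few minutes on one core while still separating the
three systems (hybrid > neural-only > rules-only on test micro-F).
Oracle-equivalence and round-trip properties run on 1000 random pairs and
500 generated documents respectively.

## Known limitations

* Relation extraction (linking attributes to *their* drug in
  multi-drug sentences beyond nearest-anchor attachment), event markers
  and meta-attributes (negation, experiencer, temporality) are out of
  scope.
* The rule inventory is a functional stand-in sized for the synthetic
  corpus; production use on hospital text requires extending it.
* The contextual provider is a package-scale reference implementation of
  the contract, not a substitute for a large pretrained clinical language
  model.
* Training is pure R on CPU; it is sized for corpora of hundreds of
  documents, not hundreds of thousands.
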