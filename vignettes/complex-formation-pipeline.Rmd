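---
title: "Extracting protein complex-formation relations and their trigger words"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting protein complex-formation relations and their trigger words}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(retrigger)
```

## The task

Biomedical abstracts state physical protein–protein associations
("X binds Y", "the X–Y complex") alongside many other relations
(regulation, phosphorylation) that are *not* complex formation. Given a
document annotated with protein mentions, the pipeline answers two
questions for every unordered mention pair:

1. **Is a complex-formation relation stated for this pair?** — binary
   classification over a token window containing both mentions.
2. **Which word(s) state it?** — unsupervised *trigger detection*:
   per-token attribution of the classifier's positive decision, with the
   top-scoring token emitted as the trigger span.

Documents travel in BRAT standoff format: a `.txt` file with the raw text
and an `.ann` file with `T` (entity), `R` (relation), `A` (attribute) and
`*	Equiv` (alias-group) lines over 0-based half-open character offsets.
The corpus conventions matter for modelling:

* relations are **undirected** and binary (`Complex_formation`);
* an `Equiv` group marks alternative names of the same entity — a
  relation to any member holds for all members, which the pair
  enumerator expands;
* `Blocklisted` entities are excluded from the prediction regime, as are
  all non-protein types (`filter_for_prediction()`).

## From pair to example

For a candidate pair the document text is transformed and windowed
(`transform_text()`, `build_example()`):

* **mark** scheme: the two mentions are wrapped in reserved boundary
  tokens `[E1] … [/E1]`, `[E2] … [/E2]`;
* **mask** scheme: each mention's surface is replaced by a reserved
  placeholder (`[P1]`, `[P2]`), hiding lexical identity;
* a `[CLS]` token is prepended (snippet start) and `[SEP]` appended
  (snippet end).

The reserved tokens play the role of a pretrained vocabulary's "unused"
entries. Tokenization is WordPiece-style with exact offsets, so every
sub-token maps back to original document characters.

An example is generated only if both (transformed) mentions fit inside a
window of at most `msl` sub-tokens. There is **no sentence splitting**:
cross-sentence pairs produce examples whenever they fit, which is what
lets the classifier handle the small cross-sentence fraction of
relations. Window placement is our choice (the contract only fixes the
fit test): the minimal entity-enclosing token span is extended
symmetrically left and right until the budget is exhausted, leftover
budget flowing to the other side.

## The classifier

`train_relation_model()` fine-tunes a transformer encoder with a two-way
softmax decision layer read off the `[CLS]` position. In the original
system the encoder is a pretrained 24-layer RoBERTa; this package ships a
small **trainable-from-scratch** encoder with hand-written forward and
backward passes (no deep-learning framework is required), because the
desk-scale tests train on synthetic corpora where a pretrained model
is neither available nor needed. Architectural choices:

* **pre-layer-norm** residual blocks with a final layer norm. We first
  implemented the BERT-style post-norm arrangement and found it
  untrainable from random initialization at this scale (the classifier
  collapsed to the majority class); pre-norm converges reliably. This is
  the package's own design decision, consistent with common practice for
  small-scale training.
* AdamW (decoupled weight decay, no decay on biases/layer-norm gains),
  linear warmup over the first 10% of steps, linear decay to zero.
* No early stopping: the model trains for the configured number of
  epochs, and the weights of the epoch with the **highest dev F1** are
  returned (ties → earliest epoch, for determinism).
* Gradients of every block are verified against central finite
  differences in the test suite.

Reference hyper-parameters from the original study are shipped as
presets (`model_config(preset = "reference")`: MSL 128, lr 3e-6,
11 epochs, batch 5; `preset = "baseline"`: lr 5e-6, 12 epochs). They
document the published configuration; the synthetic experiments use the
desk-scale defaults of `end_to_end_recovery()` (MSL 24, d_model 48,
2 layers, 4 heads, lr 2e-3, 12 epochs), chosen once for trainability
and a one-CPU runtime budget.

`grid_search()` repeats each configuration with distinct seeds and ranks
configurations by mean best-epoch dev F1 (standard deviation reported),
mirroring the repeat-four-times protocol. It operates on pre-built
example sets, so its grid covers training hyper-parameters; changing MSL
or the transform scheme means rebuilding examples one level up (the
pipeline driver does this per stage).

## Trigger detection

Only pairs the model predicts **positive** are explained — explaining
negative or false-negative predictions produces junk spans, so
`detect_triggers()` gates on the predicted label.

Two attribution methods assign a score per token:

* **Layer integrated gradients** (`layer_integrated_gradients()`): the
  straight-line path integral of gradients of the positive-class
  probability with respect to a chosen layer's outputs (0 = embedding
  output), approximated with a trapezoidal rule; per-token scores are
  sums over the hidden dimension. The baseline is the activation of a
  copy of the input whose non-reserved tokens are replaced by `[PAD]` —
  a content-free reference. The completeness identity
  `sum(attr) = f(input) − f(baseline)` is asserted to within 1% at 256
  steps in the tests; pipeline runs use 32 steps.
* **Sampled Shapley values** (`shapley_values()`): permutation sampling
  of the per-token Shapley value under a masking value function (absent
  tokens → `[PAD]`). The boundary tokens optionally join the player set,
  giving the with/without-boundary variants. Exactness is checked
  against full coalition enumeration on ≤8-player examples.

A layer sweep plus the two Shapley variants yields `n_layers + 3`
prediction sets (`trigger_prediction_sets()`), the generalization of the
27 sets a 24-layer encoder produces.

**Post-processing heuristics** (`apply_heuristics()`) remove tokens that
cannot be triggers before the argmax: boundary/reserved tokens, tokens
inside either focus mention, tokens inside other annotated mentions,
purely numeric tokens, closed-class function words, and
sentence-delimiting punctuation. Linking punctuation (`-`, `/`) is kept
deliberately — in fusions like "the CD40-TRAF2 complex" the hyphen *is*
a valid trigger. The exact rules of the original system are not public;
this list was developed on synthetic trigger-dev data the same way the
original rules were developed on theirs, and is configurable and recorded
in the attribution config. The function-word and punctuation rules earn
their place: without them the argmax frequently lands on context
carriers ("in", ".") that the saturated classifier also uses as signal.

`select_trigger()` takes the highest-scoring surviving token (ties →
leftmost), extends it to its full word-piece group and maps it back to
document offsets. For the small encoders used here the embedding-layer
vectors (layer 0) give the cleanest token-level attribution, so the
end-to-end default is layer 0; deeper layers mix information into the
`[CLS]` stream and lose token resolution. For the original 24-layer
encoder, a middle hidden layer was best — the layer is a tunable to be
selected on a trigger development set, which is why it is exposed in
`attrib_config()`.

The **baseline matcher** (`baseline_trigger_match()`) reproduces the
regex/window comparison method: lexicon items harvested from a trigger
dev set are matched, longest first and case-insensitively at token
boundaries, within a sub-token window around each mention.

## Evaluating trigger spans

Gold annotations may contain several *alternative* spans that are equally
valid for one pair ("the CD40-TRAF2 *interaction*" — both the hyphen and
"interaction" are correct). `evaluate_triggers()` scores predictions in
four matching modes — exact, left-bound, right-bound, overlap — and
averages them; mode monotonicity (exact ≤ left/right ≤ overlap) is a
tested invariant.

Two accounting modes are exposed because the original counting is not
printed in full:

* **penalizing** (used for method development): every gold alternative is
  a recall target, so a pair with k alternatives contributes k
  opportunities; a matched prediction earns one TP per matched span, an
  unmatched one costs one FP, and spans not matched are FNs;
* **non-penalizing** (used for final manual evaluation there): one TP if
  the prediction matches *any* alternative.

Non-penalizing recall ≥ penalizing recall on every input (tested by a
brute-force recount on random instances). Spans are compared exactly as
annotated; no whitespace trimming.

## The synthetic world

`generate_corpus()` produces standoff corpora in which every stage of the
pipeline has a known ground truth. What it emulates, and the defaults:

| property | default | rationale |
|---|---|---|
| documents | 200 (acceptance run) | desk-scale, one CPU |
| sentences/doc | 3–6 | short abstract-like documents |
| mentions/doc | within 2–40 | the corpus's document-selection rule |
| positive-pair rate | 0.40 per sentence slot | rich in relations, like the hand-picked corpus |
| cross-sentence fraction | 0.04 | >96% of corpus relations are intra-sentence |
| Blocklisted rate | 0.05 | exercises the filtering path |
| Equiv alias rate | 0.10 | exercises label expansion |

Positive pairs are always signalled by a planted cue: a verbal cue
between the mentions ("binds", "forms a complex with", …), a hyphenated
fusion ("the X-Y complex", whose hyphen and "complex" form an
alternative-span group), or a two-sentence complex statement for the
cross-sentence fraction. Negatives carry distractor verbs ("regulates",
"phosphorylates") or no cue. Protein names are synthetic alphanumerics
(three letters + digit), so no real gene symbol appears in tests.

What a green test does **not** establish: the generator's templated
pseudo-English has none of the lexical ambiguity, negation, coreference
or discourse structure of real abstracts, so synthetic F1 says nothing
about performance on real literature — it establishes that the pipeline
machinery (windowing, training, gating, attribution, span accounting) is
correct and that the planted signal is recoverable. The published
headline numbers (85.5% dev / 82.8% test F1; 77.3% average trigger F1)
require the full annotated corpus and GPU-scale fine-tuning of a
pretrained 24-layer encoder, which is out of desk-scale scope; the
corpus-statistics acceptance criterion runs only when a downloaded copy
of the released corpus is supplied via
`options(retrigger.complextome_dir = ...)`.

## Numerical choices and degenerate inputs

* Character offsets are 0-based half-open everywhere; adjacent spans do
  not overlap.
* Discontinuous entity spans keep their fragment list; the enclosing
  span is the working anchor (the windowing needs one contiguous span).
* Duplicate relations on one unordered pair collapse with a warning.
* Split sizes follow the largest-remainder rule; the trigger-set halving
  assigns the odd document to the dev half.
* Trapezoidal integration for LIG (endpoint weights ½); `steps ≥ 8`
  enforced.
* Shapley estimation satisfies the efficiency identity exactly (each
  permutation's contributions telescope).
* All tie-breaks (best epoch, argmax token) resolve to the earliest /
  leftmost candidate.
* A heuristics pass that removes every token raises an error rather than
  emitting an arbitrary span; `detect_triggers()` then emits nothing for
  that pair.
* Seeds: corpus generation, splits, weight init, batch order and Shapley
  permutations are all separately seeded; fixed seeds give byte-identical
  corpora and bit-identical training histories.

## Known limitations

* The encoder is intentionally tiny; it cannot represent the lexical
  breadth of real biomedical text and is not a substitute for a
  pretrained model. The architecture is pluggable at the config level
  (`d_model`, `n_layers`, `n_heads`, `d_ff`, `msl`).
* `grid_search()` does not rebuild examples, so MSL/scheme belong to the
  outer pipeline loop.
* The penalizing-mode denominator is our declared reading of the
  published description; both modes are reported so either convention
  can be used.
* SHAP runtime grows quadratically in window length times samples; the
  defaults are sized for ≤24-token windows.
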