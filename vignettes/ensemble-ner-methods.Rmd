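---
title: "Span-level majority voting for named entity recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Span-level majority voting for named entity recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervote)
```

## The problem

Named entity recognition (NER) in health and life-science text — chemical
patents, clinical notes, wet-lab protocols — is the task of locating text
spans that denote entities and assigning each a class label
(`reaction_product`, `sosy`, `Action`, ...). Modern token classifiers differ
in pretraining corpus, tokenizer and architecture, and their errors are
partly uncorrelated. `nervote` implements the post-processing side of an
ensemble NER system: it takes the span predictions of several independently
trained models and combines them by per-entity majority voting, together
with everything needed to run and audit such a pipeline end to end —
standoff annotation I/O, span assembly from token scores, exact-match
scoring, entity-property profiling, and a synthetic corpus generator that
makes the whole pipeline testable without any external data.

## The voting model

Every model casts one vote for each distinct candidate passage it predicts,
where a candidate is the exact tuple

$$(\text{document}, \text{start}, \text{end}, \text{label}),$$

with 0-based, end-exclusive character offsets. Given $K$ models and a vote
threshold $t$, the ensemble emits every candidate with at least $t$ votes.
Three algebraic identities pin the behaviour down and are enforced by the
test suite:

* $t = 1$ yields the union of the models' prediction sets;
* $t = K$ yields their intersection;
* the output shrinks monotonically as $t$ grows.

Voting is independent per label: a passage supported for two labels at once
is emitted twice, so multi-label passages and nested entities survive the
ensemble. Candidates are pooled by **exact identity** — two near-miss spans
that overlap but differ in one offset compete as distinct candidates and
their votes are never merged. This is a deliberate design choice: any
overlap-clustered pooling requires an arbitrary notion of "the same
passage", and the exact rule keeps the ensemble a pure set operation whose
properties can be verified by brute force. An optional post-filter
(`suppress_overlaps()`) that keeps the best-supported span among
same-label overlapping outputs is provided but off by default, since the
voting rule itself never suppresses anything.

Why voting helps precision: model errors of commission (spurious spans) are
mostly idiosyncratic, so a spurious candidate rarely collects $t$ votes,
while genuine entities missed by one model are usually carried by the other
$K-1$. With independent per-model miss probability $m$, a gold span survives
the ensemble with probability $P(\mathrm{Bin}(K, 1-m) \ge t)$ — for $K=5$,
$m=0.1$, $t=3$ that is $\approx 0.991$, i.e. the ensemble typically *gains*
recall over the average individual model while its precision approaches
100%. The package demonstrates this mechanism quantitatively with
`simulate_ensemble_experiment()`; the domain presets for the threshold are
$t=3$ (chemical, clinical) and $t=4$ (wet lab), exposed via
`ensemble_threshold()` and always passed explicitly.

## Span assembly from token scores

Transformer-style taggers classify sub-word tokens, not words, so spans
must be reconstituted. `nervote` consumes a deliberately plain tabular
format (document, word interval, sub-token index, one numeric column per
class) that any external model can export, and applies two steps:

1. **Sub-token pooling** (`pool_subtokens()`): the word-level score for a
   label is the maximum over the word's sub-tokens. The pooling statistic is
   genuinely underdetermined — first-sub-token and mean pooling are equally
   defensible and are offered as options — but max-pooling is the default
   because it is the only rule under which "the label with the highest
   probability anywhere in the word" always wins, which matches how
   label-per-token decoding is usually described.
2. **Run merging**: in single-label (softmax) mode each word takes its
   argmax label and maximal runs of adjacent words with the same entity
   label become one span; in multi-label (sigmoid) mode each label is
   thresholded independently (default cutoff 0.5, a neutral choice on a
   probability scale) and runs are merged per label, so spans of different
   labels may nest — the decoding used for corpora with nested entities.

Numerical conventions: softmax vectors must sum to 1 within $10^{-6}$;
exact argmax ties are resolved by class-inventory order with the no-entity
class last (a deterministic rule, reported via a message, chosen over
random tie-breaking to keep decoding reproducible); "adjacent" means
consecutive in the word sequence regardless of intervening characters,
since adjacency is a property of the tokenization, not of whitespace. No
gap-bridging across no-entity words is attempted.

## Scoring

Evaluation is exact span matching: a prediction is correct only if
document, start, end and label all match a gold annotation. Per label,
$P = TP/(TP+FP)$, $R = TP/(TP+FN)$, $F_1 = 2PR/(P+R)$, reported in percent.
Conventions that the underlying challenge tooling leaves unstated are fixed
as: a zero denominator yields 0 (and $F_1 = 0$ when $P + R = 0$); duplicate
identical gold spans count once (they are collapsed by the annotation-set
invariant); micro aggregation pools counts before computing metrics; macro
aggregation averages per-label metrics over the labels that occur at all
(TP+FP+FN > 0) — inventory labels untouched by both sets carry no signal
and would otherwise silently drag per-document macro scores to zero.
Rounding to two decimals happens only at presentation; all comparisons use
unrounded values.

Significance between two systems uses the paired two-sided Student's t-test
(`stats::t.test` under the hood). The pairing unit is configurable because
the choice is genuinely open; per-document macro-$F_1$ vectors
(`per_document_f1()`) are the default unit since documents are the natural
independent sampling unit of a corpus. Degenerate inputs (fewer than two
pairs, zero-variance differences) raise an error instead of fabricating a
p-value.

## Profiling

Three entity-property analyses explain *where* an ensemble helps:

* **class distribution** — counts and percentage shares per label;
* **performance by entity length** (words by default, characters as an
  option) and **by training-corpus frequency** of the normalized surface
  form, with scoring stratified within bins. Matched predictions inherit
  the bin of the gold span they match; unmatched predictions are binned by
  their own length/frequency. Default frequency bins are 0, 1, 2–5, 6–20,
  21+ (the published analyses do not print their binning, so the bins are
  configurable everywhere);
* **label consistency** — the share of distinct normalized surface forms
  (case-folded, whitespace-collapsed) that carry two or more different
  labels across the corpus, the "same passage, different label" ambiguity
  measure.

## The synthetic corpus generator

The generator exists so that every pipeline stage is exercisable, at full
statistical fidelity of the *structure* of the benchmark corpora, without
distributing any third-party data. It emits pseudo-word gibberish documents
(seeded, including accented characters so character-offset handling is
exercised on multi-byte text) with entities embedded at recorded offsets.
What is controlled:

* **exact per-class span counts** — the `chemu_*`, `deft_*` and `wnut_*`
  presets reproduce the published per-class counts of the three benchmark
  training/test collections exactly (26,857 / 8,098 / 102,957 spans in
  total), with document counts following the original collection sizes;
* **surface-form reuse** — each class draws its mentions from a lexicon of
  about one form per three occurrences, reused with Zipf-like weights, so
  the frequency profile has mass in every bin; every lexicon form is used
  at least once, which makes the realized multi-label share exact;
* **multi-label forms** — a configurable fraction of distinct forms is
  assigned to two classes (10% in the chemical/wet-lab presets, 1% in the
  clinical presets, following the reported annotation-consistency
  analysis);
* **nesting** — a configurable fraction of spans is placed inside a
  longer span of a different class (5% in the clinical presets; the true
  rate is not published, and 5% makes nested decoding visible without
  dominating the corpus). Nested pairs are built as composite mentions, so
  the realized rate is approximate; tests assert it within a tolerance;
* **sentences** — every sentence opens with a capitalized filler word and
  ends with a period, so the rule-based sentence splitter recovers the
  generator's sentence boundaries exactly and every entity is
  sentence-internal.

The noise model (`perturbation_model()`) simulates an imperfect model per
the four error modes that matter for voting: misses (per-span Bernoulli),
label confusions (per-source-label substitution distribution), one-word
boundary jitter, and spurious spans (per-document Poisson, uniform word
positions, 1–3 words). In the multi-model simulation different models'
spurious spans are kept from coinciding by construction (an exclusion set
with rejection redraws), because accidental collisions — vanishingly rare
in real corpora with large position spaces, but non-negligible in small
synthetic documents — would blur the precision mechanism the simulation is
meant to isolate; a `collision_rate` parameter reintroduces them
deliberately.

What the generator does **not** emulate: linguistic realism (no grammar, no
real vocabulary), tokenizer idiosyncrasies, document-level topical
correlation between entities, and realistic confusion structure between
specific class pairs. Passing tests on synthetic corpora therefore
demonstrate the correctness of the *mechanics* — parsing, offsets, voting
algebra, scoring arithmetic, profiling bookkeeping — not the linguistic
performance of any particular model ensemble.

## Problem sizes and determinism

The test suite and the acceptance script regenerate everything from code:
the three preset corpus pairs (up to ~103k spans, a few seconds each), a
1,000-trial randomized comparison of the voting engine against a
brute-force candidate enumerator, randomized scorer-versus-oracle checks,
and a 1,000-gold-span, 60-document, 5-model precision-mechanism simulation.
All randomness flows through explicit integer seeds; identical
configurations produce byte-identical corpora, standoff files and reports.

## Known limitations

* Discontinuous standoff spans (semicolon offsets) are rejected, not split.
* Vote pooling by exact span identity means systematically offset-shifted
  but correct predictions get no partial credit in the ensemble — by
  design, and consistent with exact-match evaluation.
* Relaxed/overlap matching and weighted or probability-averaging ensembles
  are out of scope.
* The sentence splitter is a terminal-punctuation heuristic (configurable
  regex); sentence intervals are advisory and never clip entities.
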