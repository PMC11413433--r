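---
title: "Silver-standard augmentation for low-resource ICD-10 coding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silver-standard augmentation for low-resource ICD-10 coding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdaug)
```

## The problem

Automated ICD-10 coding assigns a set of diagnosis codes to a free-text
discharge summary. The label space is huge and hierarchically organised:
codes sharing a 3-character head (e.g. `S02.*`) form a *family*. Real coded
corpora have a big-head long-tail label distribution — a handful of common
conditions and thousands of codes with single-digit or zero training
occurrences. Data-driven coders fail on that tail.

`icdaug` implements, end to end and on fully synthetic data, a study design
for attacking the tail by *generation*: pick low-resource code families,
build *silver-standard* label sets from real label combinations, have a
document generator write a coded discharge summary for each label set,
merge the generated documents into the training set, and measure whether
the augmented coder improves on the low-resource codes — and whether its
remaining errors move *into* the right family.

## Pipeline stages and their parameters

**Label selection** (`select_generation_targets`). Few-shot candidates are
codes with training population in 1..`few_shot_max` (default 5) present in
all three splits. A candidate's family is *retained* when it contains at
least one frequent member (training population strictly above
`frequent_threshold`, default 100) and at least one zero-shot member
(absent from training, present in test). `n_families` (default 10) retained
families are sampled uniformly; every member with training population
strictly below `generation_pop_cap` (default 100) becomes a *generation
code*. The codesets reported downstream are `f(gen)` (the generation codes)
and `f` (all codes in the chosen families). Populations count documents
carrying a code, since each document holds one label set.

**Silver standard** (`build_silver_set`). Each few-shot generation code's
source documents are cloned round-robin up to `target_pop = 100` records.
Clones drop `k ~ Uniform{0..min(5, available)}` of their non-relevant
labels — relevant (generation) codes are never dropped, and `k = 0` is
allowed so exact clones occur, which the duplicate rule below then handles.
For each zero-shot code, every training document containing a sibling
yields one record with a uniformly chosen sibling replaced by the zero-shot
code. A record whose final label set equals an earlier record's is a
*duplicate*: duplicates generate at temperature 0.1 (output varies with
seed), unique sets at temperature 0 (deterministic). Original (non-clone)
records keep their label sets unmodified; only clones pass the label
dropper.

**Generation** (`generate_document`). The generator interface takes a
silver record, a code-description table, a temperature, and a seed, and
returns a document whose trailing discharge-diagnoses section lists the
requested codes in square brackets. The built-in `mock_llm_generate` is a
deterministic template generator standing in for a hosted language model:
it renders sectioned prose (history of present illness, hospital course,
social history, family history) in which each label's description is
paraphrased — the keyword "unspecified" is dropped, the umbrella qualifier
"Other" is replaced by a concrete one, and numeric placeholders become
concrete values — and no code token appears outside the trailing brackets.
`extract_assigned_codes` recovers the label set from the brackets;
`scrub_codes` then removes every remaining code-pattern match from the
body before the document joins the training set.

One emulation choice matters more than any other: the mock generator's
background "supporting findings" are drawn from the *same* working
vocabulary as the corpus simulator's noise lexicon. A generator writing in
a vocabulary disjoint from the real documents would let the coder separate
synthetic from real text wholesale — the augmentation signal would be
swamped by a domain-shift shortcut (in early testing this inverted the
few-shot rankings entirely). Real language models write in the same
language as real notes; the shared lexicon is the faithful emulation. The
template scaffolding still gives generated documents a recognisably
distinct style, mirroring the style gap observed between real and
machine-generated summaries.

**Coding-response parsing** (`parse_coding_response`). Responses to a
coding request are parsed structured-first: a well-formed JSON array of
`{"diagnosis": ..., "icd_code": ...}` objects is read directly; anything
else falls back to a tolerant regular expression over the raw text;
garbage yields an empty pair list with a `none` flag. The code surface
pattern used for extraction and scrubbing requires a digit in the second
position (the ICD-10-CM shape, e.g. `S02.63XA`); a looser
letter-plus-alphanumerics pattern would scrub ordinary capitalized words.

## The reference coder

`train_coder` fits a CAML-style network: word embeddings (width
`emb_dim = 16`), one 1-d convolution with tanh activation (width
`conv_dim = 16`, kernel `kernel = 1`), per-label attention over positions,
and a per-label sigmoid output. Training is per-document Adagrad
(`lr = 0.15`) on binary cross-entropy for exactly `epochs = 20` epochs;
after each epoch the dev-set mean average precision (mAP) is recorded and
the best epoch's parameters are kept (earliest epoch wins ties). A
probability threshold (default 0.5) turns scores into label sets. Labels
absent from training are excluded from the output space — which is exactly
why zero-shot codes need augmentation. The training loop is compiled
(RcppArmadillo) and bit-reproducible from its seed.

Two robustness choices:

* *Attention smoothing.* The per-label attention softmax is mixed with a
  10% uniform component. With a pure softmax, a small fraction of labels
  collapsed their attention onto an uninformative position early in
  training and never recovered (Adagrad's decaying steps cannot undo an
  early collapse); the uniform component keeps gradient flowing to every
  position.
* *Kernel width 1 by default.* The simulator emits documents whose token
  order carries no signal, so wider windows only mix a token's embedding
  with random neighbours; width 1 learned markedly better here. For
  natural text a wider kernel is appropriate, and the width is a config
  field.

The mAP variant is macro: for each label with at least one gold-positive
document, documents are ranked by decreasing score (ties keep document
order) and average precision is computed over the positives; labels are
averaged with equal weight.

## Evaluation machinery

Flat micro/macro precision, recall and F1 are computed over an arbitrary
codeset; a label with zero precision and recall contributes F1 = 0, and
codeset labels with neither gold nor predicted instances stay in the macro
denominator by default (`drop_absent` flips this).

Hierarchical metrics extend each document's gold and predicted sets with
ancestor nodes. In *set-based* mode an ancestor is present if any
descendant is; in *count-preserving* mode (CoPHE) an ancestor carries the
number of its present descendant leaves. Per (document, node),
`TP = min(gold, pred)`, `FP = max(pred − gold, 0)`,
`FN = max(gold − pred, 0)`, pooled micro. Sibling confusion (a gold leaf
predicted as its sibling) keeps the family count intact, so CoPHE stays
above set-based; over- or under-prediction inside a family breaks the
count, pulling CoPHE below set-based. Comparing the two therefore reads
out *which kind* of within-family error dominates. The default hierarchy
is family-only (one ancestor, the 3-character head); a multi-level
hierarchy file (`node_id,parent_id,level`) is supported since the
count-preserving construction is depth-general, but no claim is made about
which depth matches any particular published analysis.

The weak hierarchical confusion matrix (`whcm_rates`) classifies every
gold instance of a codeset label as a true positive, a *within-family*
(IF) error — missed, but some false positive from the same family exists
in that document's predictions — or an *out-of-family* (OOF) error.
Matching is deliberately weak: one false positive can license any number
of IF errors in its family; no one-to-one assignment is attempted.
Per-label percentages (over gold instances) conserve to 100 and are
macro-averaged over labels with at least one gold instance; gold-free
labels are excluded with a note.

Rater agreement (`fleiss_kappa`, `agreement_report`) treats the five
ordinal score levels as nominal categories, the classical formulation;
a linear-weighted variant is available behind `weighted = TRUE` but is not
claimed as any study's method. Reports are stratified by real versus
synthetic items, per metric; degenerate strata (all raters always in one
category) are flagged rather than aborting the other metrics.

## The synthetic data generator

`make_code_space` builds designated families of 6 leaves — one frequent,
one mid-population, three few-shot, one zero-shot — plus background codes
in their own families. Each leaf's description pairs a qualifier and a
family noun with a globally unique pseudo-medical word, so every label has
unique trigger vocabulary; some descriptions carry "unspecified" and some
the "Other" prefix to exercise the generation constraints.

`sample_corpus` plants the strata deterministically *before* popularity
sampling — guaranteeing the study's preconditions rather than hoping
rejection sampling meets them: frequent codes get 110–160 training
documents, few-shot codes 1–5 (plus dev and test presence), zero-shot
codes 3–8 test documents and none elsewhere. Remaining label slots are
filled from the background codes with power-law weights (exponent 1.5, the
big-head long-tail shape). Label counts per document are
1 + Poisson(mean − 1), capped, with the same distribution in every split.
Document text is each carried label's trigger tokens (each emitted with
probability 0.9) shuffled among background noise tokens.

Desk-scale defaults: 3000/300/600 train/dev/test documents, mean 5 labels
per document, mean 30 tokens per document, 500 background noise words.
Real inpatient corpora run an order of magnitude larger in every direction
(documents, labels per document around 16, vocabulary); these sizes were
chosen so a full baseline-versus-augmented comparison trains in about a
minute while preserving the structural features the method depends on —
family structure, the long tail, planted few-/zero-shot strata, and
label-conditioned text.

A `balanced = TRUE` profile replaces the few-shot stratum with 20–40
training examples; combined with `trigger_prob = 1` and a small noise
vocabulary this is the *separable configuration* used to verify that
label-conditioned text is learnable (dev mAP ≥ 0.95). With 1–5 examples
per label no desk-scale coder reaches that bar — such scarcity is the very
problem the augmentation study addresses — so the separability check and
the study run on different profiles of the same generator.

What passing tests on this simulator do **not** show: anything about
clinical prose (the text has no grammar, negation, or section semantics),
about real label correlations beyond co-occurrence in sampled sets, or
about absolute metric levels on real corpora. They do show that the
selection rules, silver construction, generation round trip, training
protocol, and every metric behave exactly as specified, and that the
augmentation mechanism — more (synthetic) examples for low-resource codes
improving their recognition and shifting errors into the family — operates
when the generator is label-faithful.

## Numerical and degenerate-input choices

* All randomness flows from one seed through named substreams
  (`substream(seed, stage)`), so stages are independently reproducible and
  a study re-run is byte-identical.
* Temperature-0 generation ignores the seed entirely (a pure function of
  the record); temperature-0.1 generation varies with the seed but keeps
  the trailing code list fixed.
* Empty documents score through the output bias alone; empty label sets,
  empty codesets and gold-free labels are handled per the conventions
  above rather than erroring mid-pipeline.
* Ties in dev mAP keep the earliest epoch; ties in rankings keep document
  order (stable sorts on both the R and C++ paths).
* The divergence guard aborts training on non-finite model output.

## Known limitations

* The built-in generator is a template engine: it validates the pipeline
  and the augmentation mechanism, not generation quality. A hosted-model
  adapter can be plugged in with the same `(record, code_table,
  temperature, seed)` signature.
* The coder is desk-scale; no pretrained encoders, no GPU, no
  hyperparameter search.
* Fleiss' kappa on ordinal scores discards orderedness; the weighted
  variant is provided but unweighted is the default and the reported one.
* Family-only hierarchy depth is the default everywhere; deeper ICD
  structure (blocks, chapters) must be supplied explicitly.
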