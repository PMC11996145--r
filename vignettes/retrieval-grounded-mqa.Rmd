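---
title: "Retrieval-grounded question answering for thyroid pathology reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval-grounded question answering for thyroid pathology reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyromqa)
```

## The problem

Surgical pathology reports carry the staging and recurrence-risk facts —
tumor size, extrathyroidal extension, nodal involvement, histologic type,
aggressive variants — that cancer registries and clinicians need, but they
carry them as free narrative. Medical question answering (MQA) poses a
fixed set of natural-language questions against each report and extracts
typed answers. Because patient narratives cannot leave the institution,
the pipeline is built around components that run locally and
deterministically: a small language model (or, here, a rule-based
reference extractor) answers each question from a compact *context*
assembled out of the report.

`thyromqa` implements that pipeline end to end for thyroid cancer
surgical pathology reports, together with a synthetic report generator
that replaces protected patient data, and a concordance harness that
scores any two answer sources against each other the way human reviewers
and a model are compared in practice.

## The retrieval procedure

A small locally deployable model has a hard context budget; the default
assumed here is 2048 tokens, counted by a pluggable `token_counter`
(default: whitespace tokens — the real tokenizer belongs to whichever
backend is attached). Reports within the budget are used whole. Longer
reports are handled as follows:

1. **Segmentation.** The text is cut into fixed 1200-character segments
   at raw character offsets (`segment_text()`). Segments tile the text —
   no gap, no overlap — so concatenating them reconstructs the report
   exactly. Cutting at character boundaries may split words; step 4
   compensates.
2. **Embedding.** Each segment and the bare question text are embedded
   (`hashed_tf_embedder()`): lowercased word tokens are hashed into a
   512-bucket term-frequency vector with sublinear `1 + log(tf)`
   weighting, unit-normalized. The embedder is deterministic and needs no
   model download; any object implementing the same `embed`/`dimension`
   contract (e.g. a sentence-transformer adapter) can replace it.
3. **Scoring and selection.** Each segment is scored by cosine
   similarity against the question embedding and the top `k = 3`
   segments are kept. Ties break toward the lower segment index. Fewer
   than `k` segments means all are kept.
4. **Assembly.** Selected segments are ordered by document position.
   *Adjacent* segments are concatenated seamlessly — they tile the
   original text, so this restores the exact substring and repairs any
   sentence the 1200-character boundary cut in half; a single newline
   marks each gap between non-adjacent runs. This is the one place the
   package deviates from the simplest "join with newlines" rule, chosen
   because a newline inserted mid-sentence corrupts exactly the
   answer-bearing sentences retrieval is supposed to preserve. The
   best-first score order is retained in the `score_order` metadata.

The bare question text, not the full prompt, is what gets embedded for
scoring: the prompt's fixed instruction wording is shared by all
questions and would only dilute the signal. Prompt construction itself
(`build_prompt()`) is pure two-placeholder substitution and treated as
configuration.

## The 12-question schema

`load_questions()` ships the default schema: tumor size (cm), extension
beyond the thyroid capsule, location (right lobe / left lobe / isthmus),
presence of cervical lymph nodes, count of positive nodes, final
pathologic TNM stage, vascular invasion, lymphatic invasion, primary
histology, aggressive variant (tall cell, hobnail, columnar cell),
second cancer, and second-cancer histology. Two items are conditional:
the node count applies only when nodes are present, and the
second-cancer histology only when a second cancer exists; when the
trigger is negative their canonical answer is `not_applicable`, and
`not_applicable` agrees only with `not_applicable`.

Answers are normalized (`normalize_answer()`) to typed canonical values
before comparison: sizes to cm (mm inputs divided by 10), booleans via
leading yes/no and negation cues, counts from digits or number words,
TNM to the bare T token (`pT3a` → `T3a`), histology and variant through
controlled vocabularies. Normalization is total and idempotent;
unparseable text becomes `not_stated`.

## The reference backend

The deterministic rule-based backend (`reference_backend()`) answers the
schema from a context with per-question pattern logic. Two rules encode
failure modes that motivate the design. First, a dimension is accepted
as the tumor size only from a sentence that names the tumor and is not a
specimen measurement — the classic error being to report the overall
lobe dimension instead of the tumor's. Second, node sections are read by
the phrase "lymph node" and "x of y" count patterns rather than the word
"cervical", which most reports never use, labeling nodes instead by neck
level or compartment. The backend exists so that segmentation,
retrieval, normalization and evaluation can be tested end to end,
deterministically, without any model weights; a real LLM attaches
through the same one-function contract.

## The synthetic generator

`generate_corpus()` produces seeded reports with complete ground truth.
Default composition is the study-scale corpus: 102 reports of which 84
are malignant thyroid cases and the remainder other-organ (10), benign
(2), cytopathology (5) and outside-review (1) cases removed by
`filter_corpus()`. Malignant truth fields are drawn once per report:
size uniform on 0.4–6.0 cm (one decimal), histology 80% papillary / 12%
follicular / 8% medullary, aggressive variants only under papillary
histology (20% of papillary cases), gross extrathyroidal extension 15%,
nodes examined absent in 35% of cases and otherwise 1–12 with positives
binomial(p = 0.3), vascular invasion 20%, lymphatic invasion 25%, second
cancers 15%. These rates are chosen to be clinically plausible for a
thyroid cancer surgical series and to exercise every branch of the
schema; they are fixed defaults, not fitted to any dataset.

The renderer (`render_report()`) writes prose, synoptic (field/value
lines) or mixed styles from small template pools with synonym variation,
and deliberately reproduces the pitfalls that make extraction
nontrivial: specimen-dimension distractors ("The right lobe measures 4.2
x 3.0 x 2.1 cm"), node sections labeled by level or compartment
("level VI lymph nodes") with "cervical" appearing only with probability
0.15, a 20% share of sizes rendered in mm, and number words as well as
digits in node counts. Every ground-truth fact appears as a literal
sentence, recorded per question in the `key_sentences` attribute — which
is what makes the retrieval hit rate measurable. A configurable fraction
of reports (default 30%) is padded with administrative boilerplate until
it exceeds the token budget, forcing the retrieval path; the boilerplate
vocabulary is disjoint from the clinical content so that retrieval is
tested against realistic off-topic bulk.

What the generator does **not** emulate: institutional dialects,
typographical noise, abbreviation variants, contradictory amendments,
multifocal disease beyond a single second focus, and T4/N1a-N1b/M
staging detail. Tests passing on this corpus therefore demonstrate that
the pipeline machinery is correct and robust to the modeled pitfalls —
not that any particular accuracy carries over to real reports.

## Staging rules

`derive_t_category()` implements the simplified AJCC-TNM 8th-edition T
classification (size cut points 1, 2, 4 cm, upper bounds inclusive;
gross extrathyroidal extension into strap muscles overrides to T3b),
`derive_n_category()` the N0/N1 split, and `recurrence_risk_tier()` a
simplified low/intermediate/high stratification (gross ETE high;
vascular invasion, aggressive variant or any positive node
intermediate). The thresholds live in a versioned YAML file
(`staging_thresholds()`). The subset is exactly what the 12-question
schema needs; full-guideline fidelity (T4, nodal compartments,
metastasis, microscopic-ETE nuance, age-dependent stage groups) is
explicitly not claimed, and the generator never emits cases outside the
subset.

## Concordance evaluation

`per_question_rates()` compares two complete answer sets over the same
report-by-question grid: per question, concordant answers over total
answers (percent); overall, both the mean ± SD of the 12 per-question
rates and the pooled ratio of concordant cells. The two framings differ
in general and are both reported, labeled, because published summaries
use them interchangeably. The SD headline uses the sample (n−1)
convention with the population value alongside. Cell-level agreement
(`is_concordant()`) is type-aware: sizes agree after rounding to 0.1 cm,
TNM compares the T token case-insensitively, and for booleans the
default policy equates `not_stated` with "no" — an unmentioned finding
is read as absent, which is how reviewers record absent findings; a
strict policy flag disables this. `compare_pairings()` runs a two-sided
t test between two pairings' per-question rate vectors, paired by
question by default (the 12 questions are shared units) with Welch's
test by flag; identical vectors return t = 0, p = 1 rather than erroring
on zero variance.

## Numerical and design choices

- **Determinism.** Every stochastic step is seed-driven
  (`generate_corpus(n, seed)`), and seeds are consumed through an
  RNG-state-preserving helper so library calls never perturb a caller's
  random stream. Identical seeds give byte-identical corpora.
- **Tie-breaks.** Equal retrieval scores resolve to the lower segment
  index; this makes selection a total, reproducible function.
- **Degenerate inputs.** Empty text embeds to a flagged zero vector with
  similarity defined as 0; empty text segments to zero segments;
  `needs_splitting` is false for empty text; a failing backend yields
  `not_stated` and the run continues.
- **Problem sizes.** The test suite exercises the study-scale corpus
  (102 reports, 30% long) for end-to-end checks, 1000-instance random
  suites for the retrieval-selection oracle and segmentation invariants,
  and 40–200-report all-long corpora for retrieval hit rates. These
  sizes keep the full suite under a minute while leaving every branch
  covered.
- **Regression bars.** On the seeded default corpus the reference
  backend over full text recovers ground truth exactly (100%); through
  retrieval it stays ≥ 95% pooled concordance with a ≥ 90% retrieval hit
  rate (the assembled context contains the answer-bearing sentence).
  These are package regression bars on synthetic data, not claims about
  real-report accuracy.

## Known limitations

The reference backend is intentionally brittle outside the generator's
dialect — it is a test instrument, not a clinical extractor. The hashed
term-frequency embedder captures lexical overlap only; questions whose
wording shares little vocabulary with report phrasing (e.g. asking for
"histology" when reports say "carcinoma" subtype) retrieve worse than
keyword-rich ones, which is visible in the per-question hit rates and
mirrors why more expressive embeddings are attractive. Concordance is
raw agreement; chance-corrected statistics (kappa) and bootstrap
intervals are out of scope. The k = 3 segment count and all budgets are
exposed as configuration but no calibration beyond the defaults is
attempted.
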