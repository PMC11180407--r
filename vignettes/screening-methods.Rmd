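---
title: "Likert-prompt screening: model, evaluation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likert-prompt screening: model, evaluation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening model

Title-and-abstract screening is the systematic-review stage where each
search hit is judged relevant or irrelevant from its title and abstract
alone. `tiabscreen` automates this with a scoring prompt: for every
record the package assembles

```
[Instruction] + "Title:" <title> + ", Abstract:" <abstract> + [Relevant Criteria]
```

and asks a text-generation backend to rate the record's relevance on an
ordinal 1..X Likert scale (default X = 5). The instruction string is
fixed; the relevant-criteria block is written once per review and reused
verbatim for every record, so the only part that varies across a run is
the title/abstract payload. A screening classifier is then a threshold:
the *k+* classifier includes a record iff its score is at least *k*
(default: the 3+ classifier on a 1–5 scale). The ordinal scale, rather
than a direct yes/no question, is what lets one screening run support a
whole family of classifiers — sweeping *k* trades sensitivity against
specificity and traces the run's ROC curve.

Backends are pluggable: any model reachable as an executable
(`backend_command()`) or HTTP completion endpoint (`backend_http()`) can
answer the prompts. Reproducible runs require deterministic generation,
so `generation_settings()` rejects a positive sampling temperature
unless the run is explicitly flagged non-reproducible.

### Score extraction

Backends answer in free text, usually a bare digit. `parse_score()`
extracts positive integer tokens at word boundaries and accepts the
answer only when it maps *unambiguously* to one in-range score:

* exactly one distinct in-range integer occurs, and no out-of-range
  positive integer precedes it (an earlier stray number could itself be
  the intended rating);
* as a documented, toggleable convenience, "x out of y" is accepted as
  score x when y equals the scale maximum — unambiguous to a human
  reader — while slash forms like "3/5" and "out of" phrases naming a
  different scale stay invalid;
* digits embedded in words (model names like "Mistral7B") are never
  score candidates.

Everything else is invalid, with a reason (`no_integer`,
`out_of_range`, `ambiguous`, `response_missing`). Invalid answers are
excluded from metric computation but never silently: every report
carries the invalid count, the reasons, and — when gold labels exist —
how many of the invalid-response records would have been relevant.
`parse_score()` is total and pure; fuzz tests assert it classifies
arbitrary text without raising.

One presentation subtlety: validity percentages of large runs are
reported as `100 − signif(invalid_pct, 1)`, so 3 invalid answers out of
44,055 print as 99.993% while 29 print as 99.93%. A fixed decimal count
either collapses near-complete validity to 100.00 or over-reports
digits; rounding the *invalid* share to one significant figure keeps
exactly the informative digits. The unrounded value is always returned
alongside.

### Evaluation

With gold labels, `evaluate_run()` computes the 2×2 confusion of the
*k+* classifier ("relevant" is the positive class, fixed — there is no
option to invert it, which prevents silent metric swaps) and the five
standard measures: sensitivity (= recall), specificity, accuracy,
precision and F1. A measure with a zero denominator is reported as `NA`
and flagged `undefined`, never as 0. Printed percentages round half-up
to 2 decimals. `roc_curve()` sweeps *k* from `scale_max + 1` (nothing
included) down to 1 (everything included) and reports the trapezoid
area under (1 − specificity, sensitivity); the AUC is an addition
beyond the basic curve, useful as a threshold-free summary. Tests
cross-check it against an independent ROC implementation (pROC) and
assert the curve's monotonicity invariants on random instances.

Pooling across datasets can be done two ways — one confusion over all
records (micro) or averaging per-dataset metrics (macro). The package
computes metrics per scores-table and leaves pooling to the caller, so
either convention is explicit in user code rather than baked in.

## The mock backend and the synthetic generator

The deterministic mock backend makes the full pipeline testable with no
language model. Its published rule: the answer is
`1 + min(scale_max − 1, s)` where `s` is the number of distinct
case-folded content words (non-stopword tokens, against the bundled
stopword list) shared between the criteria block and the
title-plus-abstract — recovered from the prompt text itself, so the
mock also exercises the prompt splitter round trip.

`generate_corpus()` produces labeled corpora that this rule can
separate by a controllable margin. Each abstract is `abstract_len`
background tokens plus each criteria keyword included independently
with probability `q_rel` (relevant records) or `q_irr` (irrelevant
ones); titles carry the same signal at half strength
(`title_signal = 0.5`), reflecting that titles are shorter and noisier
carriers of topical signal than abstracts. The relevant count is exact
(`round(n · prevalence)`), not Bernoulli per record, so class sizes are
deterministic in tests. Background text is drawn from a fixed
deterministic pseudo-word vocabulary (a consonant–vowel syllable
product, built in code); pseudo-words cannot collide with real criteria
keywords or stopwords, which keeps the planted signal exact and avoids
shipping or downloading any real abstracts.

Defaults were chosen once to emulate a mid-sized biomedical screening
dataset: n = 1000 records at 5% prevalence (published screening corpora
range from under 0.2% to about 11% relevant; 5% sits in that band),
abstracts of 30 content tokens over a 500-word vocabulary, q_rel = 0.9
and q_irr = 0.1 for a strong but imperfect signal.

Because keyword inclusions are independent, the mock score of a record
is `1 + min(scale_max − 1, S)` with `S ~ Binomial(m, p)` over the `m`
criteria keywords and per-keyword presence probability
`p = 1 − (1 − q)(1 − title_signal · q)`. `expected_mock_metrics()`
evaluates the resulting classifier metrics in closed form, and the
repository's core end-to-end test checks that
generate → screen → parse → evaluate recovers these expectations within
three Monte-Carlo standard errors at n = 10⁴ (a size that keeps the
whole suite in tens of seconds while leaving binomial noise well below
the effects being checked).

What passing these tests shows — and what it does not: they verify the
pipeline's plumbing, bookkeeping and arithmetic exactly, under a
backend whose behaviour is known by construction. Synthetic corpora do
not model real scientific language, criteria ambiguity, or the
idiosyncratic score distributions of actual language models, so they
say nothing about how well any particular model screens real
literature; that question needs real corpora and real backends.

## The keyword baseline

For comparison against keyword-driven unsupervised screening,
`derive_keywords()` turns a search query into keywords by splitting
into words and removing stop words, duplicates and punctuation; Boolean
operators (AND, OR, NOT) are always stripped, even if a custom
stopword list omits them. The bundled English stopword list is frozen
in the package so derivations are reproducible.

`baseline_screen()` is a deliberately simple unsupervised topic-model
screener: documents are embedded as TF-IDF vectors, clustered with
k-means into `n_topics` groups (default 2: on-topic vs off-topic,
seeded and deterministic), and a cluster counts as keyword-associated
when at least a fraction `min_overlap = 0.1` of its `n_top_terms = 10`
highest-weight terms are keywords; records in keyword-associated
clusters are predicted relevant. The rule guarantees a corpus sharing
no token with the keyword set can never produce an inclusion. All
knobs are exposed and documented as this package's defaults — the
baseline is a stand-in for the genre of LDA-based screeners, not a
reproduction of any particular published pipeline.

## Numerical and interface choices

* **Rounding.** All printed percentages round half-up at the stated
  decimals (`round_half_up()`), matching the convention of published
  screening tables; R's default half-to-even would print 10.885 as
  10.88 or 10.89 depending on binary representation.
* **Prompt layout.** Blocks are joined with single spaces and the
  criteria block is introduced by `", Relevant criteria:"`. The prefix
  is configurable; the layout is a documented choice of this package.
  No truncation is applied to overlong prompts — length limits are a
  backend property and surface as backend errors.
* **Checkpointing.** `screen_corpus()` can persist partial responses
  and resume without re-querying, since real backend runs are long; the
  resume path is covered by tests with a call-counting fake backend.
  Transient backend failures are retried 3 times with exponential
  backoff; a record that still fails is marked `response_missing`
  (distinct from an invalid parse) and the run continues.
* **Degenerate inputs.** Empty abstracts are kept and screened on
  title alone (the block structure is preserved with an empty payload).
  ROC computation refuses single-class inputs. k-means refuses corpora
  smaller than `n_topics`.
* **Exit codes.** The CLI (`inst/cli/tiabscreen.R`) exits 0 on
  success, 2 on validation errors, 3 on backend failures, and screening
  writes scores atomically so a failed run leaves no partial file.

## Known limitations

The mock backend is a lexical-overlap caricature of a language model;
it cannot exhibit hedged answers, instruction sensitivity or scale-use
quirks, so parser robustness beyond its output is covered only by the
fuzz tests. The RIS reader handles the common TI/AB/ID/AN tags and
continuation lines, not the full RIS zoo. The baseline screener is
intentionally minimal; with more topics than 2 its
cluster-to-prediction rule can be coarse on heterogeneous corpora. The
HTTP backend shells out to `curl` and is exercised only structurally in
tests.
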