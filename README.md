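# tiabscreen

Automated title-and-abstract screening for systematic literature
reviews, driven by Likert-scored relevance prompts.

Title/abstract screening is the review stage where thousands of search
hits must each be judged relevant or irrelevant from title and abstract
alone. `tiabscreen` automates it: for every citation record it builds a
structured prompt —

```
[Instruction] + "Title:" <title> + ", Abstract:" <abstract> + [Relevant Criteria]
```

— asks a text-generation backend to rate the record's relevance on an
ordinal 1..X Likert scale, extracts the score from the free-text answer,
and turns scores into include/exclude decisions with a threshold: the
*k+* classifier includes a record iff score ≥ *k* (default: 3+ on a 1–5
scale). Sweeping *k* over the scale trades sensitivity against
specificity and yields the run's ROC curve.

The package ships the complete surrounding machinery:

* **Corpus I/O** — CSV (configurable column mapping) and RIS readers,
  validation (unique ids, non-empty titles), prevalence summaries.
* **Prompting** — the standard and adapted instruction variants, any
  scale maximum ≥ 2, verbatim payload embedding, YAML run configs.
* **Backends** — a generic completion interface (`command` for local
  executables, `http` for endpoints) plus a deterministic **mock
  backend** that scores by criteria/text word overlap, so the whole
  pipeline runs and tests offline. Resumable, checkpointed corpus
  screening with retries and an audit log.
* **Parsing** — total, pure Likert-score extraction with explicit
  invalid reasons (`no_integer`, `out_of_range`, `ambiguous`,
  `response_missing`) and invalid-response accounting.
* **Evaluation** — confusion counts, sensitivity/specificity/accuracy/
  precision/F1 (zero-denominator cases flagged, never zeroed),
  threshold-swept ROC with trapezoid AUC, per-class score
  distributions.
* **Keyword baseline** — search-query keyword derivation (split, strip
  stop words/operators/punctuation, deduplicate) feeding a simple
  unsupervised TF-IDF + k-means topic screener.
* **Synthetic data** — labeled corpora with exact prevalence and a
  plantable lexical signal, plus closed-form expected metrics under the
  mock rule for end-to-end verification.

## Worked example

Screen a synthetic 500-record corpus (7% relevant) with the mock
backend and evaluate the 3+ classifier:

```r
library(tiabscreen)

crit <- paste("Only original articles about software-based clinical decision",
              "support systems used by clinicians in radiation oncology")

spec   <- synthetic_spec(n = 500, prevalence = 0.07,
                         q_rel = 0.9, q_irr = 0.1, seed = 2026)
corpus <- generate_corpus(spec, crit)
summarize_dataset(corpus)
#> 500 records, 35 relevant (7.00%)

cfg       <- prompt_config(crit, scale_max = 5)
responses <- screen_corpus(corpus, cfg, backend_mock(scale_max = 5))
scores    <- parse_scores(responses, scale_max = 5)
evaluate_run(scores, corpus, k = 3, scale_max = 5)
#> 3+ classifier on a 1-5 scale
#> valid responses: 500/500 (100%), invalid relevant: 0
#> sensitivity  100.00%
#> specificity  44.73%
#> accuracy     48.60%
#> precision    11.99%
#> f1           21.41%
#> AUC 0.960; mean score relevant 5.00 vs overall 2.89
```

Every truly relevant record is included (sensitivity 100%) while 44.73%
of the irrelevant ones are excluded — the asymmetry a screening
pre-filter aims for, since a missed relevant publication is costly
while a surviving irrelevant one only means manual work. The closed-form
prediction for these generator settings,
`expected_mock_metrics(spec, crit, scale_max = 5, k = 3)`, gives
100.00% / 46.32%, matching within sampling noise.

A command-line interface wraps the same workflow
(`inst/cli/tiabscreen.R`; exit codes 0 success / 2 validation error / 3
backend failure):

```sh
Rscript inst/cli/tiabscreen.R simulate  --out corpus.csv --criteria "..." --n 500 --prevalence 0.07 --seed 1
Rscript inst/cli/tiabscreen.R screen    --corpus corpus.csv --config config.yaml --out scores.csv
Rscript inst/cli/tiabscreen.R evaluate  --scores scores.csv --corpus corpus.csv --k 3
Rscript inst/cli/tiabscreen.R roc       --scores scores.csv --corpus corpus.csv --out roc.csv
Rscript inst/cli/tiabscreen.R baseline  --corpus corpus.csv --query "(clinical decision support system) AND (radiotherapy OR radiation therapy)"
```

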