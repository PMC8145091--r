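# knowdiag

Multilabel diagnosis from clinical documents, with external medical
knowledge fused in through attention.

A clinical record rarely maps to a single diagnosis: a delivery record may
simultaneously carry a normal finding, a pathology and complications.
`knowdiag` treats diagnosis as multilabel text classification and
implements a knowledge-aware hierarchical model for it:

* a **hierarchical attention encoder** — word-level Bi-GRU + attention
  builds sentence vectors, sentence-level Bi-GRU + attention builds the
  document vector *e*, with every attention weight retained for
  inspection;
* **numeric clinical indicators** (age, menopause months, uterine height,
  ...) parsed from structured fields, unit-normalised (4 weeks ≈ 1 month),
  validated against plausibility ranges (a uterine height of "29 m" is
  deleted, not clamped), z-scored and appended to *e* as *e′*;
* a **knowledge attention module**: one prose document per candidate
  diagnosis is (1) filtered per record by TF-IDF cosine similarity with a
  smoothed IDF, log((1+D)/(1+D(x))) + 1, keeping documents with cosine
  ≥ 0.5, and (2) aggregated — survivors are encoded by the *same* document
  encoder, attention-scored against *e′*, and the top-*k* fused into a
  knowledge embedding *k′* (*k* = ceiling of the mean labels-per-record,
  e.g. 2.688 → 3), zero-padded when fewer survive;
* a **sigmoid head** on [*e′*; *k′*] (two fully connected layers) trained
  with summed binary cross-entropy and Adam (lr 0.001, batch 32); a label
  is predicted when its probability strictly exceeds τ = 0.5;
* the five **example-based multilabel metrics** — average precision,
  one-error, Hamming loss, ranking loss, coverage — each verified against
  brute-force oracles;
* a **synthetic corpus generator** (planted label signatures, distractor
  symptoms, atypical presentations, corrupted numeric fields) so every
  claim is testable without any private data;
* **HTML attention heatmaps** (sentence/word shading, knowledge-attention
  rows with a 10⁻³ display cutoff) for interpretability;
* `full`, `no_knowledge` and `no_attention` **ablations** behind one
  config flag.

Training runs on a small reverse-mode autodiff tape written in base R and
checked against finite differences; no deep-learning runtime is required.

## Worked example

```r
library(knowdiag)

spec <- synthetic_spec(n_records = 120, n_labels = 4, seed = 42)
corp <- generate_corpus(spec)

cfg <- knowdiag_config(embed_dim = 16, hidden = 16, fc_hidden = 32,
                       epochs = 10, seed = 1)
fit <- knowdiag(corp$records[1:100], corp$knowledge,
                corp$label_vocab, corp$schema, cfg)
fit
#> Knowledge-aware hierarchical diagnosis model
#>   labels: 4  vocabulary: 169 tokens
#>   hidden: 16  embed: 16  ablation: full
#>   knowledge documents: 4  k budget: 3
#>   training loss: 2.7297 -> 2.2171 over 10 epochs
```

The model found `k budget: 3` by the ceiling rule from the training
label cardinality, and the training loss fell from 2.73 to 2.22 over ten
epochs. Scoring held-out records gives one probability per (record,
label); the predicted label set keeps the labels strictly above τ:

```r
pred <- predict(fit, corp$records[101:103], type = "both")
round(pred$scores, 3)
#>          D01   D02   D03   D04
#> R00101 0.830 0.742 0.357 0.591
#> R00102 0.652 0.695 0.612 0.527
#> R00103 0.838 0.836 0.570 0.597
pred$labels[[1]]
#> [1] "D01" "D02" "D04"

evaluate(fit, corp$records[101:120])
#>   average_precision one_error hamming_loss ranking_loss coverage
#> 1         0.9138889      0.15          0.3       0.1875     1.85
```

After only ten epochs at toy size, average precision on the 20 held-out
records is already 0.91: on average a record's true diagnoses sit near the
top of its ranked label list. The thresholded metrics (Hamming loss 0.30)
lag the ranking metrics early in training because probabilities still
hover around τ. `pred$alpha` holds each record's attention over the
knowledge collection; `render_document_attention()` and
`render_knowledge_attention()` export the heatmaps.

A thin command-line interface over these functions (synth / train /
predict / evaluate / explain) ships at `inst/cli/knowdiag.R`.

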