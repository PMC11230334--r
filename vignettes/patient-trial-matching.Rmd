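---
title: "Dual-encoder patient–trial matching: model, training, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-encoder patient-trial matching: model, training, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialmatch)
```

## The problem

Screening patients for clinical-trial enrollment means deciding, for a
patient's health record and a trial's eligibility criteria, whether the
patient satisfies the inclusion statements and none of the exclusion
statements. `trialmatch` treats this as pairwise binary classification:
given an `<EHR, criteria>` pair, predict *success* (eligible, label 1) or
*fail* (label 0). Cohorts in this setting are small and imbalanced — the
package's defaults mirror a screening study of 180 patient–trial pairs
with 50 successes and 130 failures — so the architecture and the loss are
chosen for data efficiency.

## The model

Both inputs are first mapped to pretrained-language-model style
embeddings, at one of two granularities:

* **coarse**: one D-vector per document. The EHR is embedded as a single
  text; each criterion statement is embedded independently and the
  statement vectors are mean-pooled.
* **fine**: one embedding row per token, giving a `d x D` matrix for the
  EHR and an `n x D` matrix for the criteria (statements concatenated in
  listed order).

The core model is a **Siamese (weight-sharing) dual encoder**: a single
encoder — one parameter set, applied to both inputs — produces
representations `u = enc(EHR)` and `v = enc(criteria)`, which are fused
(concatenation by default; element-wise addition, multiplication and mean
are also available) and passed through a one-unit linear + sigmoid output
head. Weight sharing is structural: there is one parameter storage, so
the two branches cannot drift apart during training. The **single-encoder
counterpart** implements early fusion — the two inputs are concatenated
first (vectors end-to-end, or token sequences EHR-then-criteria) and one
encoder consumes the fused input. Comparing the two isolates the value of
fusing *learned* representations rather than raw inputs.

Eleven encoder families are provided: an MLP for coarse input (per hidden
layer: affine, batch normalization, ReLU, dropout; then a linear
projection), and for token sequences LSTM, GRU, their bidirectional
variants, self-attention variants of all four, a 1-d CNN over the token
axis with mean-pooling, and a CNN-LSTM hybrid.

## Objectives

Three objectives are supported; probabilities are clamped to
`[1e-7, 1 - 1e-7]` before logs.

* **BCE** `-sum_i [ y_i log p_i + (1 - y_i) log(1 - p_i) ]`.
* **WBCE** multiplies the positive-class terms by a weight `beta > 0`,
  penalizing missed eligible patients more under class imbalance. The
  default `beta` is the fail/success count ratio of the training split
  (about 2.6 at a 50:130 imbalance), computed per fold from training data
  only.
* **Contrastive** `sum_i [ (1 - y_i) d_i^2 + y_i max(0, margin - d_i)^2 ]`
  over the cosine similarity `d_i` of the two encoded representations;
  the output head is unused. The default margin is 1, the largest
  attainable cosine similarity. As printed, the first term drives *fail*
  pairs toward zero similarity, which also penalizes negative
  similarities; the loss is implemented exactly in that form.

The objectives are exposed with both the cohort-sum form and a
per-example mean; the mean is the training default because a summed loss
makes the effective step size depend on fold size at a fixed learning
rate.

## Training and evaluation protocol

Training uses Adam at learning rate 0.005 for 50 epochs (full-batch for
coarse input, minibatches of 16 for token input). Evaluation is
stratified 5-fold cross-validation: a fresh model per fold, `beta` from
that fold's training split, and 10% of the training split held out for
loss monitoring only — the final model is always the last-epoch model.
The headline metric is macro-F1 (the mean of the positive-class and
negative-class F1), with both class F1s always reported, since the
positive-class F1 answers the operationally distinct question of how well
eligible patients are found. F1 is defined as 0 when its denominator is
0. Two cross-validated models sharing a fold seed are compared by
per-fold F1 differences with a two-sided paired t-test; the test is a
documented choice — with five folds its power is limited, and a
zero-variance difference vector returns p = 1 with a warning rather than
NaN.

### Decision rules

BCE/WBCE models predict success when the predicted probability reaches
the threshold (default 0.5; a tie resolves to positive, documented
behaviour rather than an accident of floating point). Contrastive models
have no calibrated probability, so eligibility is thresholded on the
cosine similarity at margin/2 by default — halfway between the two
targets the loss trains toward (0 for fail, margin for success).

## The synthetic cohort generator

Real screening data cannot ship with the package, so the generator
produces cohorts with the statistical structure the method assumes, and
the tests quantify behaviour on them. Each dataset draws a unit latent
*trial direction* `t`. Criteria representations sit near `t` for every
pair. For eligible pairs the EHR representation is
`s*t + (1 - s)*g + noise` with `g` a random per-patient unit direction;
for ineligible pairs it is `g + noise`. The separation `s` in `[0, 1]` is
the strength of the semantic coupling between record and criteria: at
`s = 0` the labels are independent of the data (a leakage control), at
`s = 1` eligible records align fully with the trial direction.
Eligibility is therefore a latent relation between the two inputs, not
surface equality of the vectors. Noise is spherical Gaussian with
`sigma = 0.1`, the simplest controllable noise model. Fine-grained mode
emits per-document token matrices whose rows are the document centroid
plus token-level noise, with lengths drawn uniformly from 5–30 tokens —
long enough for order-sensitive encoders to matter, short enough for
desk-scale runs. Class counts are exact: `round(n * pos_fraction)`
successes (default 50 of 180).

For the rule-based baseline, the generator samples structured patient
records (events, age, gender) whose noiseless label is exactly *all
inclusion rules satisfied and no exclusion rule satisfied* under a
compact cognitive-trial flavoured rule set (age window, qualifying
diagnosis, minimum cognitive score, two exclusions); labels can then be
flipped with a configurable noise rate. At noise 0 the baseline's
features determine the labels, so a random forest should be a perfect
oracle — a plumbing check, not a scientific claim; at noise 0.5 the
labels are coin flips and any F1 above chance would indicate leakage.

What the generator does **not** emulate: clinical language, token-order
semantics within documents (rows are exchangeable around their centroid),
correlated or missing EHR fields, multi-trial heterogeneity, or
distribution shift between sites. Passing tests therefore demonstrate
that the architecture, objectives and harness behave correctly under the
assumed structure — not that any accuracy level transfers to real EHR
text.

## Numerical and design choices

* **Autodiff**: the neural components run on a small reverse-mode tape
  over dense matrices, written for this package and verified against
  central finite differences in the test suite (agreement ~1e-11).
  Recurrent cells are fused nodes with analytic backward passes.
* **Variable-length batches** are padded and masked; masked positions are
  excluded from attention softmax, CNN mean-pooling, and state carrying
  (the last *valid* state is read out).
* **Recurrent readout** is the final hidden state (concatenated final
  forward/backward states when bidirectional); attention variants replace
  it with an additive single-head attention-weighted sum over positions.
  The backward direction processes each sequence reversed within its own
  length, and for bidirectional attention the backward states are
  re-aligned to forward time before concatenation.
* **CNN defaults**: 64 filters, kernel width 3, unit stride, no padding;
  an input shorter than the kernel is an error naming the minimum length.
* **Batch normalization** uses batch statistics in training and running
  statistics in evaluation, so evaluation is deterministic.
* **Zero-vector cosine** raises an error rather than returning 0: a zero
  encoded representation signals encoder collapse and should surface.
* **Dropout grid note**: hidden-layer dropout defaults are 0.1 (MLP) and
  0.5 (recurrent); typical sweeps use {0.1, 0.3, 0.5, 0.8, 0.9}.
* **Criteria concatenation (fine mode)** joins statements in listed order
  without separator tokens — the simplest faithful construction; a
  separator-token variant would need provider support.
* **Embedding provider**: the default synthetic provider derives each
  vector from a seeded RNG keyed by a hash of the input text, so the
  pipeline is deterministic and runs offline; a real LLM backend plugs in
  behind the same interface (`embed_fn`), with document embeddings
  conventionally taken as the mean of final-layer token states.
* **t-SNE** is implemented in the package (exact affinities with
  per-point perplexity calibration, KL gradient descent, early
  exaggeration), with perplexity 30 capped at `(n - 1)/3`; `reduce_2d`
  chains PCA to at most 50 dimensions before t-SNE. PCA resolves its sign
  ambiguity by making each component's largest-magnitude loading
  positive.
* **Seed policy**: one seed fans out to data generation, fold assignment,
  initialization and batch shuffling; every report records it, and a
  fixed seed makes the full pipeline bit-reproducible on one machine.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
cohorts of 180 pairs (embedding dimension 64, token lengths 5–30), with
5-fold cross-validation, 50 epochs, and multi-seed repetitions of 5–20
runs for the monotonicity and no-signal controls — sizes chosen to match
the study-shaped cohort the defaults emulate while keeping a full run on
one CPU in minutes.

## Limitations

The package does not fine-tune or serve a language model; the provider
interface accepts one but the shipped provider is synthetic. The
contrastive decision rule (threshold at margin/2) is a convention, not a
calibrated choice. The paired t-test on five folds has low power and its
independence assumptions are approximate under cross-validation. The
rule DSL covers code presence, numeric thresholds, age ranges and gender
only — it is a portable stand-in for institution-specific cohort SQL, not
a criteria-parsing system.
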