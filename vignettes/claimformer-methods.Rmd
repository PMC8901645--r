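---
title: "Pre-training and fine-tuning transformers on longitudinal claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-training and fine-tuning transformers on longitudinal claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Administrative claims databases hold millions of patient histories, but the
cohorts that define concrete predictive tasks — children at risk of a suicide
attempt, asthma patients headed for an exacerbation — are tiny after
inclusion/exclusion criteria, often a few hundred patients. Deep sequence
models cannot be trained adequately on cohorts of that size. claimformer
implements the two-stage remedy: learn a general representation of claims
sequences from the *whole* unlabelled database with unsupervised objectives,
then adapt that representation to each small labelled cohort with minimal new
parameters.

## Data model

A patient is a date-ordered sequence of visits; each visit has a service
date, a type (inpatient `IP`, outpatient `OP`, pharmacy `RX`) and sets of
codes in three channels: diagnoses, procedures, medications. A grouper table
maps every code to a coarse clinical category (a CCS-style grouping for
diagnoses and procedures, a drug-class grouping for medications); the
package treats the grouper as data, so any 3-column TSV works. Codes below a
corpus frequency of `min_count` (default 5) share a reserved OOV index per
channel rather than being dropped, so no visit ever becomes empty.

## The encoder

Each visit is embedded by stacking, as rows, the embeddings of its codes
(all channels), its visit-type embedding, and a date embedding, and taking
the element-wise maximum — a pooling that yields one vector per visit and is
exactly invariant to code order. The date embedding buckets the gap since
the previous visit (0, 1–7, 8–30, 31–90, 91–365, >365 days); inter-visit
spacing is the irregular quantity that distinguishes claims from text, and
the bucket boundaries follow the natural clinical rhythms (week, month,
quarter, year). A demographic token — one-hot gender (3) and annual age
buckets 0–18 plus 19+ (the encoder targets pediatric populations), projected
to the hidden width — is prepended to every sequence. A post-norm
transformer layer (multi-head self-attention, residual, layer norm,
position-wise feed-forward, residual, layer norm) maps the sequence to
hidden states; the output at the demographic token is the aggregate patient
vector `pe`, the outputs at visit positions are the visit states. Defaults:
hidden width 100 everywhere, 1 layer, 4 heads.

Two masks share one set of weights. The next-visit objective is
autoregressive and uses a causal mask (position *i* attends to positions ≤
*i*); category prediction, fine-tuning and the probes use the all-to-all
mask, because `pe` sits at the first position and must see the whole
sequence there. No positional encoding beyond the date buckets is used:
order information enters through the causal mask and the gap embedding.
Sequences are truncated to the most recent 128 visits.

## Pre-training objectives

**Next-visit prediction (NVP).** From the causally-encoded state of visit
*i*, a softmax over the full cross-channel code vocabulary scores the codes
of visit *i + 1*. Visits hold several codes, so the target is uniform over
the next visit's codes and the per-position loss is the mean of their
negative log-probabilities; the batch loss averages over all contributing
positions. This keeps the likelihood reading of a softmax language-model
objective while accommodating code sets.

**Categorial prediction (CP).** From the bidirectionally-encoded state of
visit *i*, an independent sigmoid per category scores which grouper
categories appear among that visit's codes; the loss is mean binary
cross-entropy over visits and categories. CP injects the grouper ontology
so that rare codes share statistical strength through their category.

The total loss is `NVP + lambda_cp * CP` with `lambda_cp = 1` by default.
Training is RMSprop (lr 0.001, decay 0.9, eps 1e-8) on minibatches of 100
patients, an 80/20 patient split, up to 1000 epochs with early stopping
(patience 10 epochs on the validation total loss; the best-validation
parameters are returned).

**Regularisation.** Dropout sits on the two residual branches (rate 0.1)
and an L2 penalty on all weight matrices. We set the L2 coefficient to
1e-3: the next-visit head (hidden width x full vocabulary) is the largest
parameter block and is the first to overfit on corpora of a few thousand
patients — visible as the validation NVP loss turning upward after a few
epochs while CP still improves. The stronger weight decay holds the NVP
validation loss near its minimum without measurably slowing CP. Both knobs
exist precisely to control this failure mode and are configurable.

## Fine-tuning and probes

A linear head `softmax(pe %*% W + b)` (d x 2 + 2 parameters) is the only
new component. Four modes:

* `FULL_FINETUNE` — update the pre-trained body and the head (body lr 1e-4,
  head lr 1e-3);
* `PROBE_START` — freeze the body, train the head on `pe` (zero-shot
  "start");
* `PROBE_POOL` — freeze the body, train the head on the element-wise max of
  the visit states (zero-shot "pool"; mean-pooling available);
* `FROM_SCRATCH` — re-initialise the body and train end-to-end, the
  no-pre-training control. It uses exactly the same optimisation protocol
  (learning rates, epochs, batches, splits) as `FULL_FINETUNE`, so the
  comparison between the two isolates the initialisation: pre-trained
  versus random.

Fine-tuning minibatches default to 20 patients: cohorts hold a few hundred
patients, and the 20-epoch budget only accumulates enough optimizer steps
to adapt the body when batches are small. Each of the default 5 repeats
re-splits the cohort 70/30 with a repeat-specific derived seed. Splits are stratified by class so both halves
always contain both classes — a refinement of plain random splitting that
removes a failure mode on small cohorts without changing expected class
balance. Probe modes exploit the frozen body: features are computed once per
repeat and the head is trained on them, which is mathematically identical to
re-encoding every epoch.

## The synthetic claims generator

Real claims corpora are access-restricted, so the package ships a generator
whose draws have the statistical structure the framework relies on:

* a first-order Markov chain over K = 4 latent health states per patient
  (self-transition 0.7) drives everything clinically variable;
* visit counts are shifted Poisson with mean 10.4 and code counts per visit
  shifted Poisson with mean 2.8 — the marginals of a large pediatric
  Medicaid population; 49.8% of patients are male and ages at first visit
  are uniform over 0–18;
* inter-visit gaps are log-normal with median 30 days (sdlog 0.8):
  uneven spacing with a heavy right tail;
* code draws are state-conditional: within-channel Zipf popularity (a
  long-tailed frequency distribution) modulated by a per-state log-normal
  boost (sd 1.0), giving positive mutual information between the latent
  state and the emitted codes — computable exactly from the generator
  tables;
* categories are contiguous blocks of the popularity-sorted code list per
  channel, so the grouper is a deterministic total map;
* the binary label is Bernoulli with probability
  `plogis(label_effect * (f - 1/K))`, where `f` is the fraction of time in
  the designated high-risk state. Centring at `1/K` keeps the base rate
  near 0.5 for any effect size; `label_effect = 0` gives labels independent
  of the history. The default `label_effect = 4` was chosen so that the
  from-scratch control lands mid-range (AUC roughly 0.65–0.75) on a
  few-hundred-patient cohort, leaving headroom to observe a transfer gain;
* optionally an index-event diagnosis code is implanted in one visit (after
  the first) of each positive patient, enabling event-based cohort
  selection with truncation before the first event.

What the generator does **not** emulate: real ICD/CPT/NDC code semantics,
comorbidity structure, insurance churn, coding-practice drift, or costs.
Passing tests on this generator demonstrate that the machinery learns the
kinds of structure it targets (visit-level co-occurrence, temporal
correlation, ontology sharing), not that it reaches any particular accuracy
on real claims.

Transfer experiments use corpus pairs whose state-conditional code and
visit-type distributions are mixed with weight `overlap`: 1 emulates a
same-institution hold-out, 0 an unrelated institution.

## Numerical choices

* Weights are initialised N(0, 0.02²); layer norms start at identity;
  layer-norm epsilon is 1e-5.
* Softmaxes subtract row maxima; the sigmoid cross-entropy uses the
  softplus form, so both losses are stable at extreme logits.
* Max-pool gradients flow to the arg-max row per dimension (ties broken by
  first occurrence in channel order).
* Attention over each patient runs in a compiled kernel; the public
  `transformer_layer()` with an arbitrary mask runs a plain-R reference
  implementation, and the test suite checks the two paths agree to
  near machine precision. All gradients are verified against central finite
  differences.
* Dropout masks draw from R's RNG, so a single `set.seed` reproduces a run
  bit-for-bit (up to floating-point accumulation order).
* Visits sharing a service date are kept as separate visits in their input
  order (stable sort); the alternative — merging same-day claims — changes
  the sequence length semantics and is left to preprocessing.

## Problem sizes used in the checks

The package's own verification experiments run at sizes chosen to exercise
the claimed properties with adequate statistical power on a single CPU: the
default pre-training corpus is 5,000 patients over 500 codes (4 latent
states, 25 categories), calibration checks use 2,000 patients, and
fine-tuning cohorts hold 480 labelled patients — the scale of a real
population-specific cohort. Pre-training checks cap at 30 epochs (with
early stopping), fine-tuning at the default 20 epochs and 5 repeats.

## Known limitations

* One transformer layer is the default (configurable); very long-range
  structure may need more.
* The NVP softmax is dense over the vocabulary; vocabularies far beyond
  10^4 codes would want a sampled or hierarchical softmax.
* The probe modes need a trained linear head; there is no fully
  head-free zero-shot scoring, which is the only coherent reading of
  frozen-representation scoring we found.
* Expenditure variables and visit-level downstream heads are out of scope.
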