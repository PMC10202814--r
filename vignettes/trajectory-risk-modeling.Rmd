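---
title: "Multi-horizon cancer risk from disease-code trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-horizon cancer risk from disease-code trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(trajrisk)
```

## The problem

Pancreatic-type cancers are rare (population incidence well under one percent),
usually detected late, and far more treatable when found early. Population-wide
imaging is unaffordable, so the practical question is *enrichment*: can the
time-ordered sequence of ordinary hospital diagnosis codes — a disease
trajectory — identify a small group of patients whose risk is tens of times the
background rate, so that intensive surveillance becomes economical?

`trajrisk` implements a complete framework for this question: trajectory
ingestion and labelling, sequence risk models, rare-outcome evaluation
machinery, gradient-based attribution, and a synthetic cohort generator. Real
national-registry data of this kind are access-restricted; the generator
provides a cohort with known planted structure so every claim the package makes
can be tested end to end.

## Data model and trajectory construction

A patient record is an ordered sequence of `(date, code, system)` diagnosis
events plus birth date, end-of-records date and, for cases, the cancer
diagnosis date. Codes are truncated to the three-character ICD category
(`"C25.1"` → `"C25"`), and codes from different systems (e.g. ICD-8 vs ICD-10)
remain distinct vocabulary tokens — no semantic cross-walk is assumed.

Training examples are **partial trajectories**: every contiguous prefix with at
least 5 events. The date of the last event is the *time of assessment*, and the
model predicts cancer occurrence within 3, 6, 12, 36 and 60 calendar months of
it. This augmentation turns one patient into many examples with varying gaps
between assessment and outcome, which is what lets the model learn from
histories that end long before diagnosis. Three filters keep labels honest:

* patients with fewer than 5 events are removed;
* case trajectories must end strictly before the cancer date;
* control trajectories must end at least 24 months before the end of records,
  because an undiagnosed cancer could lurk in that window.

Horizon labels are a step function: `y_t = 1` iff the cancer date falls within
`t` calendar months of assessment (month arithmetic is calendar-exact with
day-of-month clamping; a fixed 30-day month would drift by days over a 60-month
horizon). For cancer trajectories the loss mask keeps every informative zero
label plus the *first* positive horizon and masks longer horizons out. The
source description of the masking ("only the timepoints before the cancer
diagnosis", with at most five active horizons) admits more than one reading —
taken literally it would leave no positive label at all, which contradicts the
loss being a cross-entropy against a step that reaches 1. Our convention uses
every pre-diagnosis zero and exactly one positive horizon; the alternative
(all five horizons unmasked) is available as `mask_mode = "all"`.

Splits are by patient (80/10/10), never by trajectory, so no patient
contributes to both training and evaluation. Because cases are typically under
0.5% of patients, training batches are class-balanced: each batch holds half
cancer and half control trajectories, the minority class resampled with
replacement, one epoch covering the negative class once.

## Model architecture

Each diagnosis code is embedded in a low-dimensional vector space (trained with
the rest of the model; the padding token is fixed at zero). Temporal
information enters through cosine waveforms evaluated at two times per event —
the patient's age at the diagnosis and the gap since the previous diagnosis —
at `n_frequencies = 128` geometrically spaced periods between 1 day and 100
years, a span covering acute episodes through lifetime history. Both channels
are measured in days inside the waveforms. The `2 x 128` features are projected
by a learned matrix to the embedding dimension and combined with the token
embedding multiplicatively, as a gate of the form `x * (1 + P)`: the `+ 1`
keeps the map near the identity at the small random initialization, so
gradients flow from the first step, while leaving the model free to learn
arbitrary positive or negative per-dimension weighting. An additive variant
(`temporal_mode = "additive"`, the convention of the attention literature the
encoding derives from) is one switch away.

Four interchangeable encoders compress a trajectory into a fingerprint:

* **bag_of_codes** — order-invariant mean pooling of raw token embeddings, a
  deliberate no-time-information control, with a single linear prediction
  layer;
* **mlp** — pooling of the temporally weighted embeddings followed by
  feed-forward layers;
* **gru** — a gated recurrent pass in date order. The fingerprint is the
  final hidden state by default; `gru_pooling = "max"` instead takes the
  elementwise maximum over the per-step states. The option exists because a
  final-state GRU attenuates its memory multiplicatively at every step: at
  the training scales this package targets (a few hundred balanced batches),
  a single informative code early in a long history demonstrably does not
  survive to the final state, while max pooling keeps its trace at any
  distance. The update-gate bias is initialized at +1.5 (the recurrent
  analogue of the LSTM forget-gate-bias convention) to favor retention from
  the start;
* **transformer** — self-attention blocks with the temporal weighting, mean
  pooled.

The prediction head concatenates the fingerprint with the age at assessment
(scaled to `[0, 1]` over 0–110 years — the scale is a bounded-input choice, not
a data statistic) and produces five risks through a sigmoid. An optional
monotone head (`monotone_head = TRUE`) builds the five logits as cumulative
sums of softplus increments, guaranteeing non-decreasing risk over horizons; it
is off by default because the target step function motivates but does not
mandate an architectural constraint, and the unconstrained head lets horizon
interactions be inspected.

The loss is the masked multi-horizon cross-entropy

$$\mathrm{loss} = \frac{1}{N}\sum_i \frac{1}{N_{T,i}} \sum_t m_{i,t}\,
  \mathrm{BCE}(y_{i,t}, \hat p_{i,t}) \;+\; \lambda_2 \lVert\Theta\rVert_2$$

with each trajectory normalized by its own number of informative horizons
\(N_{T,i}\), risks clipped to \([10^{-7}, 1-10^{-7}]\) before the logarithms,
and the penalty applied to the Euclidean norm (not its square) of all
parameters, as the loss is written in its source. All gradients come from a
package-internal reverse-mode autodifferentiation engine over dense matrices
(`R/autodiff.R`), written for this package because the modelling stack is the
package's own subject matter; its correctness is pinned by finite-difference
tests at `1e-4` relative tolerance across all four architectures.

Training uses Adam (learning rate `1e-3` by default; the optimizer is a
standard choice, not sourced), early stopping on development-set AUPRC, and
AUPRC-based checkpoint selection — AUPRC rather than AUROC because under
extreme class imbalance the precision–recall curve is the discriminating
summary. The selection horizon is configurable: a single horizon (36 months,
the headline interval of the underlying study design) or
`selection_horizon = "mean"`, the mean dev AUPRC over all five horizons. The
mean is what the worked configurations use: a development split at realistic
incidence holds only a handful of case patients, and single-horizon AUPRC
over so few positives makes checkpoint selection close to a lottery, while
averaging over horizons multiplies the effective positive count. With
`epochs > 0` the untrained initial parameters are not a selection candidate.

Two regularizers matter at this data scale. Fingerprint dropout is ordinary.
`token_dropout` hides a random fraction of input events (as padding) in each
training batch: when only a few dozen distinct case patients exist, balanced
resampling shows each of them to the model thousands of times, and without
token dropout the encoder memorizes their incidental code combinations
instead of the planted structure shared across patients. Long trajectories
keep their most recent `max_seq_len` events (package default 300; the worked
configurations below use 64, which covers >95% of the dk-like trajectories
and, empirically, drops a planted risk code from well under 1% of them).

## Evaluation machinery

Evaluation is per prediction interval and per trajectory: an outcome is
positive iff the cancer occurred within the interval from that trajectory's
assessment date (a cancer 40 months out is a *negative* at the 36-month
horizon). A patient-level mode (max score per patient) is available for
surveillance-style reading. The metric suite:

* AUROC (rank-based, ties one half) and AUPRC (step-wise, non-interpolated —
  conventions differ, so the choice is stated), each with percentile bootstrap
  confidence intervals over 200 resamples;
* the relative-risk curve `RR(n) = precision(top n) / incidence`, with ties at
  the cut broken by outcome id so the curve is deterministic; `RR = 1` for a
  random ranking, `1/incidence` for a perfect one;
* operational points: the F1-maximal threshold (ties resolved toward the lowest
  threshold, i.e. the largest flagged set) and top-n / top-fraction cuts, with
  the "1,000 of 1 million" surveillance point generalized to a 0.1% top
  fraction when the evaluated set is not a million trajectories;
* recall stratified by time-to-cancer bins at a fixed operational point;
* surveillance arithmetic: `round(top_n x PPV)` expected true positives among
  the flagged.

## Attribution

Integrated gradients attribute the 36-month risk output to individual events.
Gradients cannot flow into categorical code indices, so attribution is taken at
the output of the embedding layer, against a zero-embedding baseline (the
baseline is our choice; the method's source leaves it unstated), with the age
input interpolated along the same path. The path integral uses a midpoint
Riemann sum (`n_steps = 128` by default); completeness — attributions summing
to `F(input) - F(baseline)` — is verified within 1% in the test suite, and a
linear-logit model is attributed in closed form as an exact oracle. Per-event
scores are summed over embedding dimensions, then aggregated per code within
time-to-cancer bins (0–6, 6–12, 12–24, 24–36 months) as raw signed sums across
trajectories; whether to normalize per occurrence is left to the reader, so a
per-occurrence column is emitted alongside.

## The synthetic cohort generator

The generator exists so that the full pipeline — exclusion windows,
augmentation, balanced training, evaluation, attribution — can be exercised
with known ground truth. It emulates:

* two registry shapes: `dk_like` (spans uniform 2–44 years, about one
  diagnosis/patient-year with gamma heterogeneity; median ≈ 22 codes over ≈ 23
  years) and `va_like` (spans 1–23 years, dense coding; median ≈ 170 codes
  over ≈ 12 years);
* a long-tailed background code distribution (Zipf, exponent 1.2 — a standard
  long-tail shape, chosen once);
* cancer onset as a discrete monthly hazard `h0 x age_effect x` product of
  risk-code multipliers, with the hazard doubling per decade of age and `h0`
  calibrated so overall incidence lands in the 0.2–0.4% band;
* planted **early-risk codes** (rare carriage, 2–3% each; hazard multipliers
  in the hundreds; emitted early in the record) and **late-symptom codes**
  (emitted only within 3–6 months before diagnosis), giving the two
  lead-time profiles that exclusion-window and attribution analyses are
  about. The risk codes are deliberately near-deterministic — carriers
  account for about 95% of cases: with ~10,000 patients and realistic
  incidence a held-out split contains only a handful of case patients, and
  any weaker planted signal turns every downstream check into a measurement
  of which patients happened to land in the test split rather than of the
  pipeline under test;
* a reserved cancer code written at the diagnosis date, so the
  "trajectories end before diagnosis" logic is genuinely exercised.

What it does **not** emulate: real ICD semantics and comorbidity correlation
structure, registry coding artifacts (temporary/referral codes), demographic
composition, or care-seeking dynamics. Passing tests on this cohort validate
the machinery and the qualitative phenomena (exclusion windows reduce
performance; near-diagnosis symptoms dominate short-horizon attribution), not
clinical performance on any real registry.

## Study-scale choices and reproducibility

The worked configurations in `scripts/acceptance.R` and the test suite use a
10,000-patient dk-like cohort, a GRU with embedding/hidden size 12, 32 cosine
frequencies, sequence cap 64, `lambda2 = 1e-4`, dropout 0.1, balanced batches
of 64 and 60 steps/epoch for up to 12 epochs — sizes at which a full
simulate–train–evaluate–attribute cycle completes in minutes on one CPU while
leaving the planted signal comfortably recoverable. At this cohort size a
held-out split holds roughly 3–6 case patients, so single-split AUROC carries
sampling noise of order ±0.1; multi-seed checks therefore simulate three
independent cohorts and combine the per-cohort AUROCs as a stratified
average weighted by the number of positive–negative pairs. Raw pooling of
scores across the three models would be wrong: each model's risk scale is
calibrated to its own cohort, and concatenating them can produce an
aggregate below every per-cohort value. Every stochastic step — simulation,
splitting, batch sampling, initialization, dropout, bootstrap — is seeded, and
identical seeds reproduce cohorts byte-for-byte and training histories
exactly on a fixed platform.

## Known limitations

* The autodiff engine favors clarity over throughput; it is ample for the
  package's study sizes but is not a deep-learning framework replacement.
* The transformer encoder processes sequences one at a time (attribution and
  scoring are batched for the other encoders), making it the slowest option.
* Bootstrap intervals use the percentile convention; with very few positives
  the intervals are wide and the redraw-on-degenerate-resample policy (10
  attempts, then counted as a failure) matters.
* The generator's hazard is piecewise-constant monthly and code effects are
  multiplicative with no interactions; it is a testbed, not an epidemiological
  simulator.
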