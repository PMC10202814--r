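# trajrisk

Multi-horizon cancer risk prediction from longitudinal disease-code
trajectories.

## The problem

Aggressive low-incidence cancers (the motivating case is pancreatic cancer)
are usually diagnosed too late to treat well, yet population-wide screening is
impractical when fewer than 1 in 200 patients will develop the disease. A
workable surveillance program needs *enrichment*: a model that reads each
patient's time-ordered hospital diagnosis history — their disease trajectory —
and flags a small high-risk group whose cancer rate is tens of times the
background incidence.

`trajrisk` is a complete R implementation of that workflow for researchers in
clinical risk modelling:

* **Trajectory construction** — ingest per-patient ICD-coded event histories
  (level-3 code truncation, multi-system vocabularies), enumerate all partial
  trajectories of ≥ 5 events as training examples, label them with a
  step-function outcome over the prediction horizons {3, 6, 12, 36, 60}
  months, apply pre-diagnosis exclusion windows, patient-level 80/10/10
  splits and class-balanced batch sampling.
* **Risk models** — learned code embeddings with time-aware cosine positional
  weighting (age at diagnosis and inter-diagnosis gap at 128 geometric
  frequencies), interchangeable encoders (bag-of-codes, MLP, GRU,
  transformer), and a multi-horizon head trained with the masked loss

  `loss = (1/N) Σ_i (1/N_T,i) Σ_t −[y log p̂ + (1−y) log(1−p̂)] + λ₂‖Θ‖₂`

  on a package-internal reverse-mode autodiff engine (no deep-learning
  framework required).
* **Evaluation** — per-interval AUROC/AUPRC with bootstrap CIs, relative-risk
  curves over top-n operational points (`RR = precision / incidence`),
  F1-maximal and top-fraction operational points, recall by time-to-cancer,
  and surveillance-scenario arithmetic.
* **Attribution** — integrated gradients at the embedding output for the
  36-month risk, aggregated per diagnosis code within time-to-cancer bins.
* **Synthetic cohorts** — a seeded generator with planted hazard structure
  (early risk codes that multiply a monthly cancer hazard; late symptom codes
  emitted only near diagnosis) emulating long/sparse and short/dense registry
  regimes, so the whole pipeline is testable without access-restricted
  registry data.

See `vignettes/trajectory-risk-modeling.Rmd` for the model, its assumptions
and all numerical choices.

## Worked example

Simulate a cohort, fit a GRU risk model, and evaluate it on the withheld test
split:

```r
library(trajrisk)

cfg <- generator_config(n_patients = 4000, seed = 3)
cohort <- generate_cohort(cfg)
cohort
#> <trajrisk_cohort> 4000 patients (18 cancer cases), 120508 events

data <- prepare_trajectories(cohort, exclusion_months = 0, seed = 3)
mc <- risk_model_config("gru", embedding_dim = 12, hidden_dim = 12,
                        n_frequencies = 32, max_seq_len = 64,
                        token_dropout = 0.5, gru_pooling = "max", seed = 3)
run <- train_model(data, mc, lr = 2e-3, batch_size = 64, epochs = 8,
                   steps_per_epoch = 60, selection_horizon = "mean", seed = 3)

oc <- interval_outcomes(run$model, data, horizon = 36, split = "test")
compute_auroc(oc$score, oc$label)
#> [1] 0.9780574
f1_operational_point(oc$score, oc$label)[c("precision", "recall", "rr")]
#> $precision
#> [1] 0.6666667
#> $recall
#> [1] 0.4
#> $rr
#> [1] 657.5333
```

The AUROC says a random cancer-within-36-months trajectory outscores a random
negative trajectory ~98% of the time; at the F1 operational point two thirds
of the flagged trajectories are true positives, a ~660-fold enrichment over
the trajectory-level incidence. Attribution then shows *why*: for
trajectories assessed within 6 months of diagnosis the planted late-symptom
codes dominate the 36-month risk output:

```r
near <- data$trajectories[is_case == TRUE & time_to_cancer < 6]
agg <- aggregate_attributions(run$model, data, rows = near,
                              bin_edges = c(0, 6), n_steps = 64)
head(agg[, c("token", "contribution")], 3)
#>        token contribution
#>       <char>        <num>
#> 1: icd10:S10    17.031788
#> 2: icd10:S20    13.210914
#> 3: icd10:S30     3.311862
```

Numbers above are the output of this exact script (single CPU, ~3 minutes).
With only ~18 cases in a 4,000-patient cohort a held-out split can hold very
few — or zero — positive trajectories at a given horizon, so expect strong
seed-to-seed variation at this demonstration scale; the acceptance script
below works at 10,000 patients and aggregates three cohorts for that reason.

## Command line

A thin CLI over the same functions lives at `inst/cli/trajrisk.R`:

```sh
Rscript inst/cli/trajrisk.R simulate --n 10000 --out cohort --seed 1
Rscript inst/cli/trajrisk.R prepare --events cohort/events.tsv \
    --patients cohort/patients.tsv --exclusion-months 0 --seed 1 --out prep
Rscript inst/cli/trajrisk.R train --data prep --out model --seed 1
Rscript inst/cli/trajrisk.R evaluate --model model/checkpoint.rds --data prep \
    --split test --out report.json
Rscript inst/cli/trajrisk.R surveil --cohort-size 1000000 --top-n 1000 --ppv 0.32
```
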