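test_that("AUROC matches pair counting and handles ties", {
  expect_equal(compute_auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auroc(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(compute_auroc(1:3, c(1, 1, 1)), "both classes")
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    score <- round(runif(n), 1) # coarse grid forces ties
    label <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(compute_auroc(score, label), oracle_auroc(score, label))
  }
})

test_that("AUPRC matches an exhaustive threshold sweep", {
  expect_equal(compute_auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # constant scores collapse to the positive prevalence
  expect_equal(compute_auprc(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_error(compute_auprc(1:3, c(0, 0, 0)), "no positive")
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    score <- round(runif(n), 1)
    label <- c(1, rbinom(n - 1, 1, 0.4))
    expect_equal(compute_auprc(score, label), oracle_auprc(score, label))
  }
})

test_that("rank metrics are invariant under monotone score transforms", {
  set.seed(13)
  score <- runif(30)
  label <- rbinom(30, 1, 0.3)
  label[1] <- 1; label[2] <- 0
  for (f in list(function(x) 10 * x - 3, function(x) x^3,
                 function(x) plogis(5 * x))) {
    expect_equal(compute_auroc(f(score), label), compute_auroc(score, label))
    expect_equal(compute_auprc(f(score), label), compute_auprc(score, label))
  }
})

test_that("relative-risk curves follow the precision/incidence identity", {
  # 10 outcomes, 2 positives, both inside the top 5
  score <- c(0.95, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1)
  label <- c(1, 0, 1, 0, 0, 0, 0, 0, 0, 0)
  rrc <- compute_rr_curve(score, label, c(5, 10))
  expect_equal(rrc$precision[1], 0.4)
  expect_equal(rrc$rr[1], 2.0) # precision 0.4 over incidence 0.2
  expect_equal(rrc$rr[2], 1.0) # flagging everyone is a random pick
  # perfect top-n: maximal enrichment 1/incidence
  rr2 <- compute_rr_curve(score, c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0), 2)
  expect_equal(rr2$rr, 1 / 0.2)
  expect_warning(compute_rr_curve(score, label, 99), "truncated")

  set.seed(14)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    s <- round(runif(n), 1)
    l <- c(1, 0, rbinom(n - 2, 1, 0.5))
    for (k in c(1, 3, n)) {
      expect_equal(compute_rr_curve(s, l, k)$rr, oracle_rr(s, l, k))
    }
    # bounds: 0 <= RR <= 1/incidence
    rrs <- compute_rr_curve(s, l, seq_len(n))$rr
    expect_true(all(rrs >= 0 & rrs <= 1 / mean(l) + 1e-12))
  }
})

test_that("a random ranking has expected relative risk one", {
  set.seed(15)
  label <- c(rep(1, 30), rep(0, 270))
  rr <- replicate(300, compute_rr_curve(runif(300), label, 30)$rr)
  expect_equal(mean(rr), 1, tolerance = 0.1)
})

test_that("the F1 operational point maximizes F1 over every threshold", {
  # perfect separation
  op <- f1_operational_point(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(op$f1, 1)
  expect_equal(op$threshold, 0.8)
  # a single top-ranked positive is found exactly
  op1 <- f1_operational_point(c(0.99, runif(9, 0, 0.5)),
                              c(1, rep(0, 9)))
  expect_equal(op1$f1, 1)
  expect_equal(op1$n_flagged, 1)
  set.seed(16)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    s <- round(runif(n), 1)
    l <- c(1, rbinom(n - 1, 1, 0.4))
    got <- f1_operational_point(s, l)
    want <- oracle_f1(s, l)
    expect_equal(got$f1, want$f1)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("top-n and top-fraction operational points count flags correctly", {
  score <- c(0.9, 0.8, 0.7, 0.1, 0.05)
  label <- c(1, 0, 1, 0, 0)
  op <- operational_point(score, label, "top_n", n = 3)
  expect_equal(op$n_flagged, 3)
  expect_equal(op$precision, 2 / 3)
  expect_equal(op$recall, 1)
  opf <- operational_point(rep(0.5, 1000), c(1, rep(0, 999)), "top_fraction",
                           fraction = 0.001)
  expect_equal(opf$n_flagged, 1)
})

test_that("bootstrap intervals are seeded, ordered and size sensitive", {
  set.seed(17)
  score <- runif(400)
  label <- rbinom(400, 1, plogis(6 * score - 3))
  label[1] <- 1; label[2] <- 0
  ci <- bootstrap_ci(score, label, compute_auroc, n_resamples = 200, seed = 4)
  expect_identical(ci, bootstrap_ci(score, label, compute_auroc,
                                    n_resamples = 200, seed = 4))
  expect_lte(ci$low, ci$point)
  expect_gte(ci$high, ci$point)
  # a perfectly separated large sample collapses near 1
  ps <- c(runif(200, 0.6, 1), runif(200, 0, 0.4))
  pl <- rep(c(1, 0), each = 200)
  cip <- bootstrap_ci(ps, pl, compute_auroc, seed = 1)
  expect_gt(cip$low, 0.999)
  # smaller samples give wider intervals
  ci_small <- bootstrap_ci(score[1:60], label[1:60], compute_auroc,
                           n_resamples = 200, seed = 4)
  expect_gt(ci_small$high - ci_small$low, ci$high - ci$low)
})

test_that("recall stratifies by time to cancer at a fixed threshold", {
  score <- c(0.9, 0.8, 0.3, 0.7, 0.1, 0.2)
  label <- c(1, 1, 1, 1, 0, 0)
  ttc <- c(2, 5, 9, 20, NA, NA)
  out <- recall_by_time_to_cancer(score, label, ttc, threshold = 0.5,
                                  bin_edges = c(0, 6, 12, 24, 36))
  expect_equal(out$recall, c(1, 0, 1, NA))
  expect_equal(out$n_cases, c(2L, 1L, 1L, 0L)) # empty bin: 0 cases
  # a threshold above every score finds nothing
  out0 <- recall_by_time_to_cancer(score, label, ttc, threshold = 2)
  expect_true(all(out0$recall[out0$n_cases > 0] == 0))
})

test_that("surveillance arithmetic reproduces the flagged-cohort yield", {
  s <- surveillance_scenario(1e6, 1000, 0.32)
  expect_equal(s$expected_true_positives, 320)
  expect_equal(s$flag_fraction, 0.001)
  expect_equal(surveillance_scenario(1e6, 1000, 0.07)$expected_true_positives,
               70)
  expect_equal(surveillance_scenario(5000, 0, 0.9)$expected_true_positives, 0)
  expect_error(surveillance_scenario(100, 200, 0.5), "top_n")
  expect_error(surveillance_scenario(100, 50, 1.2), "ppv")
})

test_that("interval outcomes follow the per-interval confusion semantics", {
  d <- small_gen_data()
  m <- init_risk_model(tiny_model_config("bag_of_codes"), d$vocab)
  oc36 <- interval_outcomes(m, d, 36, split = NULL)
  # positive iff cancer within the interval: a case 40 months out is a
  # negative at 36 months but a positive at 60
  oc60 <- interval_outcomes(m, d, 60, split = NULL)
  far <- !is.na(oc36$time_to_cancer) & oc36$time_to_cancer > 36 &
    oc36$time_to_cancer <= 60
  if (any(far)) {
    expect_true(all(oc36$label[far] == 0))
    expect_true(all(oc60$label[far] == 1))
  }
  expect_equal(nrow(oc36), nrow(d$trajectories))
  # age filter empties a young cohort
  young <- interval_outcomes(m, d, 36, split = NULL, age_min = 200)
  expect_equal(nrow(young), 0)
  expect_error(interval_outcomes(m, d, 17), "not in model")
  # patient level keeps one (max-score) outcome per patient
  ocp <- interval_outcomes(m, d, 36, split = NULL, level = "patient")
  expect_equal(nrow(ocp), length(unique(d$trajectories$patient_id)))
})
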