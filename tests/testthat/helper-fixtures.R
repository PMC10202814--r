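# shared fixtures, all built in code

d_ <- function(x) as.Date(x)

# a hand-crafted five-patient cohort exercising the eligibility rules:
#   A: control, 7 events all well before the buffer cutoff
#   B: control, 5 events, single admissible endpoint
#   C: cancer patient, 8 events of which the last two fall after diagnosis
#   D: control with only 4 events (too few)
#   E: control whose events all fall inside the 24-month buffer
toy_cohort <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C", "D", "E"),
    birth_date = d_(c("1950-01-01", "1940-06-15", "1945-03-10",
                      "1960-01-01", "1955-05-05")),
    sex = c("F", "M", "F", "M", "F"),
    end_of_data = d_(rep("2018-12-31", 5)),
    cancer_date = d_(c(NA, NA, "2010-06-15", NA, NA)))
  ev <- function(id, dates, codes) {
    data.frame(patient_id = id, date = d_(dates), code = codes,
               system = "icd10")
  }
  events <- rbind(
    ev("A", sprintf("200%d-01-10", 0:6), sprintf("A0%d", 0:6)),
    ev("B", sprintf("199%d-07-01", 1:5), rep("B20", 5)),
    ev("C", c("2001-05-01", "2003-02-01", "2005-08-01", "2007-01-01",
              "2009-03-01", "2010-01-20", "2010-07-01", "2011-02-01"),
       c("C10", "C11", "C12", "C13", "C14", "C15", "C16", "C17")),
    ev("D", sprintf("2000-0%d-01", 1:4), rep("D40", 4)),
    ev("E", sprintf("2018-0%d-01", 1:6), rep("E50", 6)))
  as_cohort(patients, events)
}

# generator config with a single moderate-penetrance risk code, for tests
# that need a denser case count than the package defaults produce
test_gen_config <- function(n_patients, seed, baseline_incidence = 8e-4) {
  generator_config(
    n_patients = n_patients, seed = seed,
    baseline_incidence = baseline_incidence,
    risk_codes = list(risk_code_spec("R10", hazard_multiplier = 50,
                                     carrier_prob = 0.05)))
}

# small seeded generated cohort + prepared data, shared across tests
small_gen_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- test_gen_config(600, seed = 424242, baseline_incidence = 0.004)
      cache <<- prepare_trajectories(generate_cohort(cfg), seed = 99)
    }
    cache
  }
})

tiny_model_config <- function(architecture = "gru", seed = 11, ...) {
  risk_model_config(architecture, embedding_dim = 6, hidden_dim = 5,
                    n_frequencies = 8, max_seq_len = 40, seed = seed, ...)
}

# brute-force metric oracles (independent of the package implementations)

oracle_auroc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

oracle_pr_points <- function(score, label) {
  ths <- sort(unique(score), decreasing = TRUE)
  prec <- rec <- numeric(length(ths))
  np <- sum(label == 1)
  for (i in seq_along(ths)) {
    sel <- score >= ths[i]
    prec[i] <- sum(label[sel] == 1) / sum(sel)
    rec[i] <- sum(label[sel] == 1) / np
  }
  list(precision = prec, recall = rec, thresholds = ths)
}

oracle_auprc <- function(score, label) {
  pts <- oracle_pr_points(score, label)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

oracle_f1 <- function(score, label) {
  pts <- oracle_pr_points(score, label)
  f1 <- ifelse(pts$precision + pts$recall > 0,
               2 * pts$precision * pts$recall / (pts$precision + pts$recall), 0)
  best <- max(f1)
  i <- max(which(f1 == best)) # lowest threshold on ties
  list(f1 = best, threshold = pts$thresholds[i], precision = pts$precision[i],
       recall = pts$recall[i])
}

oracle_rr <- function(score, label, n) {
  ord <- order(-score, seq_along(score))
  top <- ord[seq_len(n)]
  prec <- mean(label[top] == 1)
  prec / mean(label == 1)
}

# scalar (unbatched) oracle for the multi-horizon loss
oracle_loss <- function(p_hat, y, mask, lambda2 = 0, params = NULL) {
  eps <- 1e-7
  total <- 0
  for (i in seq_len(nrow(p_hat))) {
    nt <- sum(mask[i, ])
    s <- 0
    for (t in seq_len(ncol(p_hat))) {
      if (mask[i, t] == 0) next
      p <- min(max(p_hat[i, t], eps), 1 - eps)
      s <- s - (y[i, t] * log(p) + (1 - y[i, t]) * log(1 - p))
    }
    total <- total + s / nt
  }
  pen <- 0
  if (lambda2 > 0 && !is.null(params)) {
    sq <- 0
    for (m in params) for (v in m) sq <- sq + v * v
    pen <- lambda2 * sqrt(sq)
  }
  as.numeric(total / nrow(p_hat) + pen)
}
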