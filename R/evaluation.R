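#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counting one
#' half. Invariant under monotone transformations of the scores.
#'
#' @param score numeric risk scores.
#' @param label binary outcomes (0/1 or logical).
#' @return scalar in \[0, 1\].
#' @export
compute_auroc <- function(score, label) {
  label <- as.integer(label)
  np <- sum(label == 1L)
  nn <- sum(label == 0L)
  if (np == 0L || nn == 0L) {
    stop("compute_auroc: needs both classes (", np, " positives, ", nn,
         " negatives)")
  }
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) AUPRC: scores are swept from the highest
#' distinct value down, tied scores entering as one block, and each block
#' contributes its recall increment times the precision at that cut. Equals
#' average precision; for a constant score it reduces to the positive
#' prevalence.
#'
#' @inheritParams compute_auroc
#' @return scalar in (0, 1].
#' @export
compute_auprc <- function(score, label) {
  label <- as.integer(label)
  np <- sum(label == 1L)
  if (np == 0L) stop("compute_auprc: no positive outcomes")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  y <- label[ord]
  # block boundaries at distinct scores
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(y)
  cum_n <- seq_along(y)
  tp_b <- cum_tp[last_of_block]
  n_b <- cum_n[last_of_block]
  prec <- tp_b / n_b
  rec <- tp_b / np
  sum(diff(c(0, rec)) * prec)
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples outcomes with replacement `n_resamples` times and reports the
#' 2.5/97.5 percentile interval of the metric. Degenerate resamples on which
#' the metric fails (e.g. a single-class resample for AUROC) are redrawn up
#' to 10 times and then counted as failures; more than 50% failures aborts.
#'
#' @inheritParams compute_auroc
#' @param metric function of `(score, label)` returning a scalar.
#' @param n_resamples bootstrap resamples (default 200).
#' @param seed RNG seed; the interval is deterministic given it.
#' @param conf confidence level (default 0.95).
#' @return list with `point`, `low`, `high`, `n_failed`.
#' @export
bootstrap_ci <- function(score, label, metric = compute_auroc,
                         n_resamples = 200L, seed = 1L, conf = 0.95) {
  n <- length(score)
  stopifnot(length(label) == n, n > 0L)
  point <- metric(score, label)
  vals <- with_preserved_seed(seed, {
    out <- rep(NA_real_, n_resamples)
    for (b in seq_len(n_resamples)) {
      for (try in seq_len(10L)) {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(metric(score[idx], label[idx]), error = function(e) NA_real_)
        if (!is.na(v)) break
      }
      out[b] <- v
    }
    out
  })
  n_failed <- sum(is.na(vals))
  if (n_failed > n_resamples / 2) {
    stop("bootstrap_ci: metric failed on more than half of the resamples")
  }
  a <- (1 - conf) / 2
  q <- stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(point = point, low = q[1L], high = q[2L], n_failed = n_failed)
}

rank_outcomes <- function(score, id = seq_along(score)) {
  order(-score, id) # ties broken by ascending id: deterministic top-n cuts
}

#' Relative-risk curve over top-n operational points
#'
#' At each operational point the `n` highest-scored outcomes are flagged as
#' high risk, and the relative risk is the precision in the flagged set over
#' the outcome incidence in the whole set:
#' `RR = (TP/(TP+FP)) / ((TP+FN)/(TP+FP+TN+FN))`. A random ranking has
#' expected RR 1; a perfect ranking attains `1/incidence`. Ties are broken
#' by ascending outcome id, so the curve is deterministic.
#'
#' @inheritParams compute_auroc
#' @param n_values increasing integer vector of top-n cuts; values above the
#'   sample size are truncated with a warning.
#' @param id optional tie-break identifier (default input order).
#' @return a `data.table` with columns `n`, `tp`, `precision`, `rr`, plus
#'   attribute `"incidence"`.
#' @export
compute_rr_curve <- function(score, label, n_values, id = seq_along(score)) {
  label <- as.integer(label)
  if (!any(label == 1L) || !any(label == 0L)) {
    stop("compute_rr_curve: needs both classes")
  }
  if (any(n_values > length(score))) {
    warning("compute_rr_curve: n_values above sample size truncated")
    n_values <- pmin(n_values, length(score))
  }
  n_values <- sort(unique(as.integer(n_values)))
  incidence <- mean(label)
  ord <- rank_outcomes(score, id)
  cum_tp <- cumsum(label[ord])
  out <- data.table(n = n_values, tp = cum_tp[n_values])
  out[, precision := tp / n]
  out[, rr := precision / incidence]
  setattr(out, "incidence", incidence)
  out[]
}

threshold_confusion <- function(score, label, threshold) {
  pred <- score >= threshold
  tp <- sum(pred & label == 1L)
  fp <- sum(pred & label == 0L)
  fn <- sum(!pred & label == 1L)
  tn <- sum(!pred & label == 0L)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Operational points on the risk-score scale
#'
#' `f1_operational_point()` sweeps every distinct score as a `>=` threshold
#' and returns the point maximizing the F1 score (harmonic mean of precision
#' and recall); ties go to the lowest threshold (largest flagged set).
#' `operational_point()` instead fixes the flagged set by top-n count or by
#' top fraction of the evaluated set.
#'
#' @inheritParams compute_auroc
#' @return list with `kind`, `threshold`, `n_flagged`, `precision`,
#'   `recall`, `f1`, `rr`.
#' @export
f1_operational_point <- function(score, label) {
  label <- as.integer(label)
  if (!any(label == 1L)) stop("f1_operational_point: no positives")
  np <- sum(label == 1L)
  incidence <- mean(label)
  ord <- rank_outcomes(score)
  s <- score[ord]
  y <- label[ord]
  cum_tp <- cumsum(y)
  k <- seq_along(y)
  # candidate cuts: ends of tied-score blocks (threshold = that score)
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  prec <- cum_tp / k
  rec <- cum_tp / np
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  f1[!last_of_block] <- -Inf
  # which.max takes the first (highest-threshold) argmax; prefer the lowest
  # threshold among ties instead
  best <- max(f1)
  i <- max(which(f1 == best))
  list(kind = "f1_max", threshold = s[i], n_flagged = k[i],
       precision = prec[i], recall = rec[i], f1 = f1[i],
       rr = prec[i] / incidence)
}

#' @rdname f1_operational_point
#' @param kind `"top_n"` or `"top_fraction"`.
#' @param n,fraction size of the flagged set for the corresponding kind.
#' @param id optional tie-break identifier.
#' @export
operational_point <- function(score, label, kind = c("top_n", "top_fraction"),
                              n = NULL, fraction = NULL,
                              id = seq_along(score)) {
  kind <- match.arg(kind)
  label <- as.integer(label)
  if (kind == "top_fraction") {
    stopifnot(!is.null(fraction), fraction > 0, fraction <= 1)
    n <- max(1L, round(fraction * length(score)))
  }
  stopifnot(!is.null(n), n >= 1L, n <= length(score))
  np <- sum(label == 1L)
  incidence <- mean(label)
  ord <- rank_outcomes(score, id)
  flagged <- ord[seq_len(n)]
  tp <- sum(label[flagged] == 1L)
  prec <- tp / n
  rec <- if (np > 0) tp / np else NA_real_
  f1 <- if (!is.na(rec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(kind = kind, threshold = min(score[flagged]), n_flagged = n,
       precision = prec, recall = rec, f1 = f1,
       rr = if (incidence > 0) prec / incidence else NA_real_)
}

#' Recall stratified by time to cancer
#'
#' At a fixed decision threshold, the recall (sensitivity) among cancer
#' outcomes whose time between assessment and diagnosis falls in each
#' `[edge_i, edge_{i+1})` bin. Empty bins are reported as `NA`.
#'
#' @inheritParams compute_auroc
#' @param time_to_cancer months from assessment to diagnosis (`NA` for
#'   non-cancer outcomes).
#' @param threshold decision threshold (scores `>=` are flagged).
#' @param bin_edges increasing numeric bin edges in months.
#' @return a `data.table` with columns `bin`, `n_cases`, `n_detected`,
#'   `recall`.
#' @export
recall_by_time_to_cancer <- function(score, label, time_to_cancer, threshold,
                                     bin_edges = c(0, 6, 12, 24, 36)) {
  label <- as.integer(label)
  pos <- label == 1L & !is.na(time_to_cancer)
  bins <- cut(time_to_cancer[pos], breaks = bin_edges, right = FALSE)
  det <- score[pos] >= threshold
  out <- data.table(bin = levels(bins))
  counts <- table(bins)
  hits <- tapply(det, bins, sum)
  out[, n_cases := as.integer(counts[bin])]
  out[, n_detected := as.integer(hits[bin])]
  out[is.na(n_detected) & n_cases > 0, n_detected := 0L]
  out[, recall := ifelse(n_cases > 0, n_detected / n_cases, NA_real_)]
  out[]
}

#' Surveillance-program arithmetic
#'
#' For a screening program that flags the `top_n` highest-risk patients in a
#' population of `cohort_size`, the expected number of flagged patients who
#' truly develop the cancer is `round(top_n * ppv)`, at a flag fraction of
#' `top_n / cohort_size`.
#'
#' @param cohort_size number of patients assessed.
#' @param top_n number flagged as high risk (`<= cohort_size`).
#' @param ppv positive predictive value at that operational point, in
#'   \[0, 1\].
#' @return list with `expected_true_positives` and `flag_fraction`.
#' @examples
#' surveillance_scenario(1e6, 1000, 0.32) # ~320 true positives
#' @export
surveillance_scenario <- function(cohort_size, top_n, ppv) {
  if (top_n > cohort_size) stop("surveillance_scenario: top_n > cohort_size")
  if (top_n < 0 || cohort_size <= 0) stop("surveillance_scenario: bad sizes")
  if (ppv < 0 || ppv > 1) stop("surveillance_scenario: ppv outside [0, 1]")
  list(expected_true_positives = round(top_n * ppv),
       flag_fraction = top_n / cohort_size)
}

#' Per-interval outcomes for a scored trajectory set
#'
#' Scores trajectories of a withheld split and pairs each with its binary
#' outcome for one prediction interval: positive iff the cancer diagnosis
#' occurred within `horizon` months of the assessment date. Optionally
#' restricts to assessments at or above an age cutoff before scoring.
#'
#' @param model a `trajrisk_model`.
#' @param data a `trajrisk_data`.
#' @param horizon months; must be one of the model's horizons.
#' @param split which split to evaluate (default `"test"`); `NULL` uses all
#'   trajectories.
#' @param age_min optional minimum age at assessment in years.
#' @param level `"trajectory"` (default; every partial trajectory is one
#'   outcome, as performance is computed over trajectories) or `"patient"`
#'   (one outcome per patient: the maximum score, with the patient's
#'   worst-case label).
#' @return a `data.table` with columns `traj_id`, `patient_id`, `score`,
#'   `label`, `time_to_cancer`, `age_at_assessment`.
#' @export
interval_outcomes <- function(model, data, horizon, split = "test",
                              age_min = NULL,
                              level = c("trajectory", "patient")) {
  level <- match.arg(level)
  if (!horizon %in% model$config$horizons) {
    stop("interval_outcomes: horizon ", horizon, " not in model horizons")
  }
  keep <- if (is.null(split)) rep(TRUE, nrow(data$trajectories))
          else data$trajectories[["split"]] == split
  rows <- data$trajectories[keep]
  if (!is.null(age_min)) rows <- rows[age_at_assessment >= age_min]
  if (nrow(rows) == 0L) {
    return(data.table(traj_id = integer(0), patient_id = character(0),
                      score = numeric(0), label = integer(0),
                      time_to_cancer = numeric(0),
                      age_at_assessment = numeric(0)))
  }
  p <- predict_risk(model, data, rows)
  out <- data.table(traj_id = rows$traj_id, patient_id = rows$patient_id,
                    score = p[, paste0("p", horizon)],
                    label = rows[[paste0("y", horizon)]],
                    time_to_cancer = rows$time_to_cancer,
                    age_at_assessment = rows$age_at_assessment)
  if (level == "patient") {
    out <- out[order(-score), .(traj_id = traj_id[1L], score = score[1L],
                                label = max(label),
                                time_to_cancer = time_to_cancer[1L],
                                age_at_assessment = age_at_assessment[1L]),
               by = patient_id]
  }
  out[]
}

#' Full evaluation report for a trained model
#'
#' Per prediction interval: AUROC and AUPRC with bootstrap confidence
#' intervals, the relative-risk curve, the F1-maximal operational point and
#' a top-fraction operational point (0.1% by default, the "1,000 of 1
#' million" surveillance cut generalized to the evaluated set size).
#'
#' @inheritParams interval_outcomes
#' @param horizons horizons to evaluate (default: the model's).
#' @param n_resamples bootstrap resamples (default 200).
#' @param top_fraction flagged fraction for the surveillance operational
#'   point.
#' @param rr_n_values top-n grid for the RR curve (default: log-spaced up to
#'   the sample size).
#' @param seed bootstrap seed.
#' @return a `trajrisk_report`: list keyed by horizon with elements
#'   `auroc`, `auprc` (each `list(point, low, high)`), `rr_curve`,
#'   `f1_point`, `top_point`, `n`, `incidence`, plus `metadata`.
#' @export
evaluate_model <- function(model, data, horizons = NULL, split = "test",
                           age_min = NULL, level = c("trajectory", "patient"),
                           n_resamples = 200L, top_fraction = 0.001,
                           rr_n_values = NULL, seed = 1L) {
  level <- match.arg(level)
  if (is.null(horizons)) horizons <- model$config$horizons
  report <- list()
  for (h in horizons) {
    oc <- interval_outcomes(model, data, h, split = split, age_min = age_min,
                            level = level)
    if (nrow(oc) == 0L || !any(oc$label == 1L) || !any(oc$label == 0L)) {
      report[[paste0("h", h)]] <- list(n = nrow(oc), skipped = TRUE)
      next
    }
    nv <- rr_n_values
    if (is.null(nv)) {
      nv <- unique(pmin(nrow(oc), round(10^seq(1, log10(nrow(oc)), length.out = 12L))))
    }
    report[[paste0("h", h)]] <- list(
      n = nrow(oc), incidence = mean(oc$label),
      auroc = bootstrap_ci(oc$score, oc$label, compute_auroc,
                           n_resamples, seed),
      auprc = bootstrap_ci(oc$score, oc$label, compute_auprc,
                           n_resamples, seed),
      rr_curve = compute_rr_curve(oc$score, oc$label, nv, id = oc$traj_id),
      f1_point = f1_operational_point(oc$score, oc$label),
      top_point = operational_point(oc$score, oc$label, "top_fraction",
                                    fraction = top_fraction, id = oc$traj_id))
  }
  structure(list(horizons = report,
                 metadata = list(split = split, age_min = age_min,
                                 level = level,
                                 exclusion_months = data$exclusion_months,
                                 n_resamples = n_resamples, seed = seed)),
            class = "trajrisk_report")
}

#' @export
print.trajrisk_report <- function(x, ...) {
  cat("<trajrisk_report> split=", x$metadata$split, "\n", sep = "")
  for (nm in names(x$horizons)) {
    h <- x$horizons[[nm]]
    if (isTRUE(h$skipped)) {
      cat(sprintf("  %s: skipped (n=%d)\n", nm, h$n)); next
    }
    cat(sprintf("  %s: n=%d AUROC %.3f (%.3f-%.3f) AUPRC %.3f RR@F1 %.1f\n",
                nm, h$n, h$auroc$point, h$auroc$low, h$auroc$high,
                h$auprc$point, h$f1_point$rr))
  }
  invisible(x)
}

utils::globalVariables(c("precision", "rr", "tp", "n_detected", "n_cases"))
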