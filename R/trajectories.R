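#' Remove near-diagnosis events from cancer patients' histories
#'
#' Diagnosis codes recorded shortly before a cancer diagnosis may directly or
#' indirectly reflect the cancer itself. To measure how much predictive
#' performance rests on such near-diagnosis codes, models are retrained with
#' the last `exclusion_months` of pre-diagnosis events removed: every event
#' with date in `[cancer_date - exclusion_months, cancer_date)` is dropped.
#' Controls are returned unchanged, and `cancer_date` itself is untouched.
#' Patients that fall below the minimum event count afterwards are removed
#' downstream by [eligibility_filter()].
#'
#' @param cohort a `trajrisk_cohort`.
#' @param exclusion_months non-negative integer (0 = identity; the study
#'   design uses 0, 3, 6 or 12).
#' @return a `trajrisk_cohort` with the filtered event table.
#' @export
apply_exclusion_window <- function(cohort, exclusion_months) {
  stopifnot(inherits(cohort, "trajrisk_cohort"),
            length(exclusion_months) == 1L, exclusion_months >= 0)
  if (exclusion_months == 0) return(cohort)
  cases <- cohort$patients[!is.na(cancer_date),
                           .(patient_id, cancer_date,
                             window_start = add_months(cancer_date,
                                                       -as.integer(exclusion_months)))]
  if (nrow(cases) == 0L) return(cohort)
  ev <- merge(cohort$events, cases, by = "patient_id", all.x = TRUE,
              sort = FALSE)
  drop <- !is.na(ev$cancer_date) & ev$date >= ev$window_start &
    ev$date < ev$cancer_date
  ev <- ev[!drop][, c("cancer_date", "window_start") := NULL]
  structure(list(patients = cohort$patients, events = ev),
            class = "trajrisk_cohort")
}

# admissible events: pre-cancer for cases, pre-buffer-cutoff for controls
count_admissible <- function(dates, cancer_date, control_cutoff) {
  if (!is.na(cancer_date)) sum(dates < cancer_date)
  else sum(dates <= control_cutoff)
}

#' Filter a cohort to patients that can yield at least one trajectory
#'
#' Two exclusion rules: patients with fewer than `min_events` diagnoses are
#' removed outright; and patients with no admissible assessment date are
#' removed — for cancer patients an assessment must fall strictly before the
#' cancer diagnosis, and for controls at least `control_buffer_months` before
#' the end of their records (the buffer guards against undiagnosed cancer
#' near the record end).
#'
#' @param cohort a `trajrisk_cohort` (exclusion window, if any, already
#'   applied).
#' @param min_events minimum number of diagnosis events (default 5).
#' @param control_buffer_months control assessment buffer (default 24).
#' @return a `trajrisk_cohort` with attribute `"tally"`: named counts of
#'   patients kept and removed per reason.
#' @export
eligibility_filter <- function(cohort, min_events = 5L,
                               control_buffer_months = 24L) {
  stopifnot(inherits(cohort, "trajrisk_cohort"))
  ev <- cohort$events
  counts <- ev[, .N, by = patient_id]
  pts <- merge(cohort$patients, counts, by = "patient_id", all.x = TRUE)
  pts[is.na(N), N := 0L]
  too_few <- pts$N < min_events

  keep_ids <- pts$patient_id[!too_few]
  meta <- cohort$patients[, .(patient_id, cancer_date,
                              control_cutoff = add_months(
                                end_of_data, -as.integer(control_buffer_months)))]
  evm <- merge(ev[patient_id %in% keep_ids], meta, by = "patient_id",
               sort = FALSE)
  adm <- evm[, .(n_adm = count_admissible(date, cancer_date[1L],
                                          control_cutoff[1L])),
             by = patient_id]
  no_assess <- adm$patient_id[adm$n_adm < min_events]

  kept <- setdiff(keep_ids, no_assess)
  tally <- c(input = nrow(pts),
             too_few_events = sum(too_few),
             no_admissible_assessment = length(no_assess),
             kept = length(kept))
  out <- structure(
    list(patients = cohort$patients[patient_id %in% kept],
         events = ev[patient_id %in% kept]),
    class = "trajrisk_cohort")
  attr(out, "tally") <- tally
  out
}

#' Multi-horizon step-function labels for one assessment date
#'
#' Cancer occurrence is annotated as a step function over the prediction
#' horizons: `y_t = 1` iff the cancer diagnosis falls within `t` calendar
#' months of the assessment date, 0 before. The per-horizon `mask` selects
#' which horizons contribute to the training loss. For controls every horizon
#' is informative (mask all ones, labels all zeros). For cancer patients the
#' default `"first_positive"` convention keeps every pre-diagnosis zero label
#' plus the first horizon that covers the diagnosis, and masks longer
#' horizons out, so each cancer trajectory trains on at most one positive
#' label and `N_T <= 5` informative horizons; `"all"` leaves all five
#' horizons unmasked.
#'
#' @param assessment_date `Date`, the end of the partial trajectory.
#' @param cancer_date `Date` or `NA` for controls; must be strictly after
#'   `assessment_date` when present.
#' @param horizons integer months (default `c(3, 6, 12, 36, 60)`).
#' @param mask_mode `"first_positive"` (default) or `"all"`.
#' @return list with integer vectors `y` and `mask` (one entry per horizon).
#' @export
label_horizons <- function(assessment_date, cancer_date,
                           horizons = c(3L, 6L, 12L, 36L, 60L),
                           mask_mode = c("first_positive", "all")) {
  mask_mode <- match.arg(mask_mode)
  if (!is.na(cancer_date) && assessment_date >= cancer_date) {
    stop("label_horizons: assessment_date must precede cancer_date")
  }
  if (is.na(cancer_date)) {
    return(list(y = integer(length(horizons)),
                mask = rep(1L, length(horizons))))
  }
  y <- as.integer(vapply(horizons, function(t) {
    cancer_date <= add_months(assessment_date, t)
  }, logical(1)))
  mask <- rep(1L, length(horizons))
  if (mask_mode == "first_positive" && any(y == 1L)) {
    first_pos <- which(y == 1L)[1L]
    mask <- as.integer(seq_along(horizons) <= first_pos)
  }
  list(y = y, mask = mask)
}

#' Enumerate labelled partial trajectories for a cohort
#'
#' Data augmentation over the longitudinal records: for each patient, every
#' contiguous prefix of at least `min_len` events is a partial trajectory
#' whose last event date is its time of assessment. Cancer patients
#' contribute only prefixes ending strictly before the cancer diagnosis;
#' controls only prefixes ending at least `control_buffer_months` before the
#' end of their records. A patient with `n` admissible events therefore
#' yields `max(0, n - min_len + 1)` trajectories.
#'
#' @param cohort a `trajrisk_cohort` (exclusion window already applied and
#'   eligibility assumed checked; inadmissible patients simply yield zero
#'   trajectories).
#' @param min_len minimum trajectory length (default 5).
#' @param control_buffer_months control assessment buffer (default 24).
#' @inheritParams label_horizons
#' @return a `data.table`, one row per trajectory: `traj_id`, `patient_id`,
#'   `end_idx` (prefix length), `assessment_date`, `age_at_assessment`
#'   (years), `is_case`, `time_to_cancer` (months, `NA` for controls), label
#'   columns `y3 ... y60` and mask columns `m3 ... m60`.
#' @export
enumerate_partial_trajectories <- function(cohort, min_len = 5L,
                                           control_buffer_months = 24L,
                                           horizons = c(3L, 6L, 12L, 36L, 60L),
                                           mask_mode = c("first_positive",
                                                         "all")) {
  mask_mode <- match.arg(mask_mode)
  stopifnot(inherits(cohort, "trajrisk_cohort"))
  ev <- merge(cohort$events,
              cohort$patients[, .(patient_id, birth_date, cancer_date,
                                  control_cutoff = add_months(
                                    end_of_data,
                                    -as.integer(control_buffer_months)))],
              by = "patient_id", sort = FALSE)
  setorder(ev, patient_id) # stable within patient (events pre-sorted by date)
  per <- ev[, {
    n_adm <- count_admissible(date, cancer_date[1L], control_cutoff[1L])
    ks <- if (n_adm >= min_len) seq.int(min_len, n_adm) else integer(0)
    .(end_idx = ks, assessment_date = date[ks],
      age_at_assessment = years_between(birth_date[1L], date[ks]),
      cancer_date = rep(cancer_date[1L], length(ks)))
  }, by = patient_id]
  if (nrow(per) == 0L) {
    return(data.table(traj_id = integer(0), patient_id = character(0),
                      end_idx = integer(0),
                      assessment_date = as.Date(character(0)),
                      age_at_assessment = numeric(0), is_case = logical(0),
                      time_to_cancer = numeric(0)))
  }
  per[, is_case := !is.na(cancer_date)]
  per[, time_to_cancer := ifelse(is_case,
                                 months_between(assessment_date, cancer_date),
                                 NA_real_)]
  # vectorized step-function labels and masks
  nh <- length(horizons)
  Y <- matrix(0L, nrow(per), nh)
  for (j in seq_len(nh)) {
    Y[, j] <- as.integer(per$is_case &
                           per$cancer_date <= add_months(per$assessment_date,
                                                         horizons[j]))
  }
  M <- matrix(1L, nrow(per), nh)
  if (mask_mode == "first_positive") {
    npos <- rowSums(Y)
    has_pos <- npos > 0L
    first_pos <- nh - npos + 1L # labels are a step function
    for (j in seq_len(nh)) {
      M[, j] <- as.integer(!has_pos | j <= first_pos)
    }
  }
  for (j in seq_len(nh)) {
    set(per, j = paste0("y", horizons[j]), value = Y[, j])
    set(per, j = paste0("m", horizons[j]), value = M[, j])
  }
  per[, cancer_date := NULL]
  per[, traj_id := seq_len(.N)]
  setcolorder(per, "traj_id")
  per[]
}

#' Patient-level train/dev/test split
#'
#' Patients (never trajectories) are the unit of splitting, so that all
#' trajectories of one patient land in the same partition and no information
#' leaks from training into evaluation. Deterministic given `seed`; realized
#' group sizes are within one patient of the exact ratios.
#'
#' @param patient_ids unique patient identifiers.
#' @param ratios train/dev/test fractions summing to 1 (default
#'   `c(0.8, 0.1, 0.1)`).
#' @param seed integer RNG seed.
#' @return an object of class `trajrisk_split`: list with `assignment` (named
#'   character vector over patients with values `"train"`, `"dev"`,
#'   `"test"`), `ratios` and `seed`.
#' @export
split_by_patient <- function(patient_ids, ratios = c(0.8, 0.1, 0.1), seed) {
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(patient_ids)) stop("split_by_patient: duplicated ids")
  n <- length(patient_ids)
  if (n < 3L) stop("split_by_patient: need at least 3 patients")
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  perm <- with_preserved_seed(seed, sample.int(n))
  shuffled <- patient_ids[perm]
  n_dev <- round(n * ratios[2L])
  n_test <- round(n * ratios[3L])
  n_train <- n - n_dev - n_test
  assignment <- rep(c("train", "dev", "test"), c(n_train, n_dev, n_test))
  names(assignment) <- shuffled
  assignment <- assignment[patient_ids]
  structure(list(assignment = assignment, ratios = ratios, seed = seed),
            class = "trajrisk_split")
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Class-balanced batch sampling for rare-outcome training
#'
#' Cancer trajectories are orders of magnitude rarer than control
#' trajectories, so uniform batches would be almost entirely negative. Each
#' batch instead holds exactly `ceiling(batch_size/2)` positive and
#' `floor(batch_size/2)` negative trajectories. The majority class is
#' shuffled and consumed in chunks (one epoch = the batches needed to cover
#' the negative class once); the minority class is resampled with
#' replacement. A trajectory is positive iff it comes from a cancer patient.
#'
#' @param is_positive logical vector over trajectories.
#' @param batch_size batch size (>= 2).
#' @param seed integer RNG seed; the batch stream is deterministic given it.
#' @param n_batches optional number of batches; default covers the negative
#'   class once.
#' @return list of integer index vectors (positives first within each batch).
#' @export
balanced_batch_sampler <- function(is_positive, batch_size, seed,
                                   n_batches = NULL) {
  stopifnot(batch_size >= 2L)
  pos <- which(is_positive)
  neg <- which(!is_positive)
  if (length(pos) == 0L) stop("balanced_batch_sampler: no positive trajectories")
  if (length(neg) == 0L) stop("balanced_batch_sampler: no negative trajectories")
  n_pos_b <- as.integer(ceiling(batch_size / 2))
  n_neg_b <- as.integer(floor(batch_size / 2))
  if (is.null(n_batches)) n_batches <- ceiling(length(neg) / n_neg_b)
  with_preserved_seed(seed, {
    neg_stream <- rep_len(neg[sample.int(length(neg))], n_batches * n_neg_b)
    need_pos <- n_batches * n_pos_b
    pos_stream <- if (length(pos) >= need_pos) {
      pos[sample.int(length(pos))][seq_len(need_pos)]
    } else {
      pos[sample.int(length(pos), need_pos, replace = TRUE)]
    }
    lapply(seq_len(n_batches), function(b) {
      c(pos_stream[((b - 1L) * n_pos_b + 1L):(b * n_pos_b)],
        neg_stream[((b - 1L) * n_neg_b + 1L):(b * n_neg_b)])
    })
  })
}
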