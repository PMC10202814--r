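#' Prepare a cohort for model training
#'
#' Runs the full input pipeline: exclusion window, eligibility filter,
#' vocabulary construction, partial-trajectory enumeration with multi-horizon
#' labels, and a patient-level train/dev/test split. The result carries both
#' the trajectory table and the per-patient tokenized event sequences the
#' models consume.
#'
#' @param cohort a `trajrisk_cohort`.
#' @param min_events minimum events per patient / minimum trajectory length.
#' @param exclusion_months pre-diagnosis exclusion window (0, 3, 6 or 12).
#' @param control_buffer_months control assessment buffer (default 24).
#' @param ratios train/dev/test fractions.
#' @param seed RNG seed for the split.
#' @param vocab optional pre-built `trajrisk_vocab` (e.g. from a training
#'   cohort when preparing external data); default builds one from the
#'   eligible patients' events. Events whose token is absent from a supplied
#'   vocabulary are dropped with a count in the tally.
#' @param keep_codes optional character vector of tokens (`"system:code"`);
#'   when supplied the event stream is restricted to these codes before
#'   enumeration (e.g. to train on a known-risk-factor subset).
#' @inheritParams label_horizons
#' @return an object of class `trajrisk_data`: list with `trajectories`
#'   (the table from [enumerate_partial_trajectories()] plus a `split`
#'   column), `sequences` (per-patient list with vocabulary indices, event
#'   dates, ages in years and inter-event gaps in days), `vocab`, `split`,
#'   `horizons`, `mask_mode`, `exclusion_months` and the eligibility `tally`.
#' @export
prepare_trajectories <- function(cohort, min_events = 5L, exclusion_months = 0L,
                                 control_buffer_months = 24L,
                                 ratios = c(0.8, 0.1, 0.1), seed = 1L,
                                 vocab = NULL, keep_codes = NULL,
                                 horizons = c(3L, 6L, 12L, 36L, 60L),
                                 mask_mode = c("first_positive", "all")) {
  mask_mode <- match.arg(mask_mode)
  # the split is fixed on the full input cohort, before any exclusion or
  # eligibility filtering, so the same patients are held out whatever
  # exclusion window is applied
  all_ids <- cohort$patients$patient_id
  split_obj <- split_by_patient(all_ids, ratios, seed)
  cohort <- apply_exclusion_window(cohort, exclusion_months)
  n_oov <- 0L
  if (!is.null(keep_codes) || !is.null(vocab)) {
    allowed <- if (!is.null(keep_codes)) keep_codes else vocab$tokens
    tok <- paste(cohort$events$system, cohort$events$code, sep = ":")
    keep <- tok %in% allowed
    n_oov <- sum(!keep)
    cohort <- structure(list(patients = cohort$patients,
                             events = cohort$events[keep]),
                        class = "trajrisk_cohort")
  }
  cohort <- eligibility_filter(cohort, min_events, control_buffer_months)
  tally <- attr(cohort, "tally")
  tally <- c(tally, dropped_out_of_vocabulary_events = n_oov)
  if (nrow(cohort$patients) == 0L) stop("prepare_trajectories: no eligible patients")
  if (is.null(vocab)) vocab <- build_vocabulary(cohort$events)

  traj <- enumerate_partial_trajectories(cohort, min_len = min_events,
                                         control_buffer_months = control_buffer_months,
                                         horizons = horizons,
                                         mask_mode = mask_mode)
  assignment <- split_obj$assignment
  traj[, split := unname(assignment[patient_id])]

  ev <- merge(cohort$events, cohort$patients[, .(patient_id, birth_date)],
              by = "patient_id", sort = FALSE)
  setorder(ev, patient_id)
  ev[, token_index := vocab_lookup(vocab, system, code)]
  sequences <- ev[, .(seq = list(list(
    idx = token_index,
    dates = date,
    ages = years_between(birth_date[1L], date),
    deltas = c(0, as.numeric(diff(date)))))), by = patient_id]
  seq_list <- sequences$seq
  names(seq_list) <- sequences$patient_id

  structure(list(trajectories = traj, sequences = seq_list, vocab = vocab,
                 split = split_obj, horizons = horizons, mask_mode = mask_mode,
                 exclusion_months = exclusion_months, tally = tally),
            class = "trajrisk_data")
}

#' @export
print.trajrisk_data <- function(x, ...) {
  tab <- table(x$trajectories$split, x$trajectories$is_case)
  cat("<trajrisk_data> ", nrow(x$trajectories), " trajectories from ",
      length(x$sequences), " patients; ", length(x$vocab$tokens),
      " tokens; exclusion ", x$exclusion_months, "m\n", sep = "")
  print(tab)
  invisible(x)
}

utils::globalVariables(c("token_index", "control_cutoff", "window_start",
                         "N", "seq"))
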