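#' Specification of a planted risk or symptom code
#'
#' The synthetic generator plants two kinds of signal codes. *Risk codes*
#' are carried by a fixed fraction of patients, appear early in the record,
#' and multiply the patient's monthly cancer hazard from their first
#' occurrence onward — emulating early risk factors such as diabetes.
#' *Late-symptom codes* never occur in the background; once cancer onset is
#' drawn they are emitted within a short lead window before the diagnosis —
#' emulating near-diagnosis symptoms such as jaundice.
#'
#' @param code three-character code token.
#' @param hazard_multiplier multiplicative effect (`>= 1`) on the monthly
#'   cancer hazard after first occurrence (risk codes; 1 for symptom codes).
#' @param lead_window_months window before diagnosis in which the code is
#'   emitted (symptom codes; 0 for risk codes).
#' @param emit_prob probability a symptom code is emitted for a given case.
#' @param carrier_prob per-patient probability of carrying a risk code
#'   (carried codes appear once, at a uniform date in the first half of the
#'   observation window, so the hazard effect is active for most of it).
#'   Carriage is a population property here, deliberately independent of the
#'   regime's coding density.
#' @return a `risk_code_spec` list.
#' @export
risk_code_spec <- function(code, hazard_multiplier = 1,
                           lead_window_months = 0, emit_prob = 1,
                           carrier_prob = 0) {
  stopifnot(hazard_multiplier >= 1, lead_window_months >= 0,
            emit_prob >= 0, emit_prob <= 1, carrier_prob >= 0,
            carrier_prob <= 1)
  structure(list(code = truncate_code(code),
                 hazard_multiplier = hazard_multiplier,
                 lead_window_months = lead_window_months,
                 emit_prob = emit_prob,
                 carrier_prob = carrier_prob),
            class = "risk_code_spec")
}

default_risk_codes <- function() {
  # rare, high-penetrance early risk factors: ~7% of patients carry one,
  # but carriers account for ~95% of the cancer cases. The planted signal is
  # deliberately dominant: the generator exists to test signal recovery, and
  # at realistic incidence a held-out split holds so few case patients that
  # a weaker signal would be swamped by case-composition sampling noise
  list(risk_code_spec("R10", hazard_multiplier = 400, carrier_prob = 0.02),
       risk_code_spec("R20", hazard_multiplier = 300, carrier_prob = 0.02),
       risk_code_spec("R30", hazard_multiplier = 200, carrier_prob = 0.03))
}

default_late_symptom_codes <- function() {
  list(risk_code_spec("S10", lead_window_months = 6, emit_prob = 0.95),
       risk_code_spec("S20", lead_window_months = 6, emit_prob = 0.80),
       risk_code_spec("S30", lead_window_months = 3, emit_prob = 0.60))
}

#' Synthetic cohort generator configuration
#'
#' Two regimes calibrated to the two registry shapes the models must cope
#' with: `"dk_like"` (long, sparse histories: observation spans drawn
#' uniformly on 2-44 years, about one diagnosis per patient-year, median
#' around 22 codes over 23 years) and `"va_like"` (short, dense histories:
#' spans 1-23 years, median around 170 codes over 12 years). Visit rates are
#' gamma-heterogeneous across patients; background codes follow a Zipf
#' distribution with exponent 1.2 over the vocabulary. Cancer onset is a
#' discrete-time monthly hazard `h_t = h0 * age_effect(age_t) * prod`
#' (multipliers of risk codes present by `t`), with the hazard doubling per
#' decade of age; `h0` is set so a never-carrier at the reference age
#' accumulates `baseline_incidence` over the regime's median span. Onset
#' triggers the late-symptom emissions and a reserved cancer-code event at
#' the diagnosis date.
#'
#' @param n_patients cohort size.
#' @param vocab_size number of distinct background codes (including the risk
#'   codes, excluding symptom and cancer codes).
#' @param regime `"dk_like"` or `"va_like"`.
#' @param baseline_incidence cumulative cancer probability of a
#'   never-carrier at the reference age over the median span; the overall
#'   incidence ends up a small multiple of this (kept in the 0.1-0.4% range
#'   by the defaults). Configs implying expected incidence above 5% are
#'   rejected.
#' @param risk_codes,late_symptom_codes lists of [risk_code_spec()].
#' @param cancer_code reserved diagnosis code written at the cancer date.
#' @param seed generation seed.
#' @return a `trajrisk_gen_config` list.
#' @export
generator_config <- function(n_patients = 10000L, vocab_size = 200L,
                             regime = c("dk_like", "va_like"),
                             baseline_incidence = 5.7e-5,
                             risk_codes = default_risk_codes(),
                             late_symptom_codes = default_late_symptom_codes(),
                             cancer_code = "C25", seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(baseline_incidence > 0, baseline_incidence <= 0.05,
            n_patients >= 1, vocab_size >= 10)
  reg <- switch(regime,
                dk_like = list(span_min = 2, span_max = 44,
                               rate_shape = 2, rate_rate = 1.55,
                               end_date = as.Date("2018-12-31")),
                va_like = list(span_min = 1, span_max = 23,
                               rate_shape = 3, rate_rate = 0.19,
                               end_date = as.Date("2020-12-31")))
  cfg <- structure(list(n_patients = as.integer(n_patients),
                        vocab_size = as.integer(vocab_size), regime = regime,
                        regime_params = reg,
                        baseline_incidence = baseline_incidence,
                        risk_codes = risk_codes,
                        late_symptom_codes = late_symptom_codes,
                        cancer_code = truncate_code(cancer_code),
                        zipf_exponent = 1.2, seed = as.integer(seed)),
                   class = "trajrisk_gen_config")
  inc <- expected_incidence(cfg)
  if (inc > 0.05) {
    stop(sprintf("generator_config: expected incidence %.3f exceeds 0.05; %s",
                 inc, "the evaluation machinery assumes a low-incidence label"))
  }
  cfg
}

# background (filler) code tokens and Zipf popularity weights; risk, symptom
# and cancer codes have no background rate, so prefixes C/R/S are reserved
background_codes <- function(cfg) {
  n <- cfg$vocab_size - length(cfg$risk_codes)
  prefixes <- setdiff(LETTERS, c("C", "R", "S"))
  filler <- sprintf("%s%02d", rep(prefixes, each = 100, length.out = n),
                    rep(0:99, length.out = n))
  w <- seq_len(n)^(-cfg$zipf_exponent)
  list(codes = filler, weights = w / sum(w))
}

# crude analytic expected-incidence check for configuration validation
expected_incidence <- function(cfg) {
  extra <- 0
  for (rc in cfg$risk_codes) {
    extra <- extra + rc$carrier_prob * (rc$hazard_multiplier - 1)
  }
  mean_age_mult <- 2.5 # typical level of the doubling-per-decade age effect
  min(1, cfg$baseline_incidence * mean_age_mult * (1 + extra))
}

age_hazard_multiplier <- function(age_years) {
  pmin(pmax(2^((age_years - 50) / 10), 0.25), 16)
}

#' Generate a synthetic cohort with planted hazard structure
#'
#' Draws the full cohort described by a [generator_config()]: per-patient
#' observation spans, gamma-heterogeneous visit processes, Zipf-distributed
#' background codes, monthly-hazard cancer onsets driven by age and planted
#' risk-code carriage, late-symptom emissions, and a reserved cancer-code
#' event at each diagnosis date. Identical config and seed give a
#' byte-identical cohort.
#'
#' @param cfg a `trajrisk_gen_config`.
#' @return a `trajrisk_cohort` with attribute `"gen_config"`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "trajrisk_gen_config"))
  reg <- cfg$regime_params
  bg <- background_codes(cfg)
  h0 <- cfg$baseline_incidence /
    (12 * (reg$span_min + reg$span_max) / 2) # monthly baseline at age 50
  with_preserved_seed(cfg$seed, {
    pat_rows <- vector("list", cfg$n_patients)
    ev_rows <- vector("list", cfg$n_patients)
    for (i in seq_len(cfg$n_patients)) {
      pid <- sprintf("P%06d", i)
      span <- stats::runif(1, reg$span_min, reg$span_max)
      rate <- stats::rgamma(1, shape = reg$rate_shape, rate = reg$rate_rate)
      n_bg <- stats::rpois(1, rate * span)
      obs_end <- reg$end_date
      obs_start <- obs_end - round(span * 365.25)
      # age at end of records between 30 and 90, and at least 18 at the
      # first possible contact
      age_end <- stats::runif(1, max(30, span + 18), 90)
      birth <- obs_end - round(age_end * 365.25)
      sex <- sample(c("F", "M"), 1L)

      days <- sort(stats::runif(n_bg, 0, span * 365.25))
      codes <- if (n_bg > 0) {
        sample(bg$codes, n_bg, replace = TRUE, prob = bg$weights)
      } else character(0)
      # planted risk-code carriage: one occurrence early in the window
      risk_day <- rep(NA_real_, length(cfg$risk_codes))
      for (k in seq_along(cfg$risk_codes)) {
        rc <- cfg$risk_codes[[k]]
        if (stats::runif(1) < rc$carrier_prob) {
          risk_day[k] <- stats::runif(1, 0, span * 365.25 / 2)
          days <- c(days, risk_day[k])
          codes <- c(codes, rc$code)
        }
      }
      dates <- obs_start + round(days)

      # monthly hazard over the observation window
      M <- max(1L, ceiling(span * 12))
      mid_days <- ((seq_len(M) - 0.5) / 12) * 365.25
      ages <- as.numeric(obs_start - birth) / 365.25 + mid_days / 365.25
      mult <- rep(1, M)
      for (k in seq_along(cfg$risk_codes)) {
        if (!is.na(risk_day[k])) {
          m0 <- min(M, floor(risk_day[k] / 30.4375) + 1L)
          if (m0 < M) {
            mult[(m0 + 1L):M] <- mult[(m0 + 1L):M] *
              cfg$risk_codes[[k]]$hazard_multiplier
          }
        }
      }
      h <- pmin(h0 * age_hazard_multiplier(ages) * mult, 0.5)
      surv <- cumprod(1 - h)
      u <- stats::runif(1)
      onset <- which(surv < u)[1L]

      cancer_date <- as.Date(NA)
      if (!is.na(onset)) {
        cancer_date <- obs_start + round((onset - 0.5) * 30.4375)
        if (cancer_date > obs_end) cancer_date <- obs_end
        for (sc in cfg$late_symptom_codes) {
          if (stats::runif(1) < sc$emit_prob) {
            back <- stats::runif(1, 0, sc$lead_window_months * 30.4375)
            sdate <- max(obs_start, cancer_date - round(back) - 1L)
            dates <- c(dates, sdate)
            codes <- c(codes, sc$code)
          }
        }
        dates <- c(dates, cancer_date)
        codes <- c(codes, cfg$cancer_code)
      }

      pat_rows[[i]] <- data.table(patient_id = pid, birth_date = birth,
                                  sex = sex, end_of_data = obs_end,
                                  cancer_date = cancer_date)
      if (length(codes)) {
        o <- order(dates)
        ev_rows[[i]] <- data.table(patient_id = pid, date = dates[o],
                                   code = codes[o], system = "icd10")
      }
    }
    cohort <- as_cohort(rbindlist(pat_rows), rbindlist(ev_rows))
    attr(cohort, "gen_config") <- cfg
    cohort
  })
}

#' Write a generated cohort (and provenance manifest) to a directory
#'
#' Emits `patients.tsv`, `events.tsv` and `manifest.yaml` (config, seed and
#' package version), the on-disk interface consumed by [read_cohort()].
#'
#' @param cohort a `trajrisk_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patient_file(cohort$patients, file.path(dir, "patients.tsv"))
  write_event_file(cohort$events, file.path(dir, "events.tsv"))
  cfg <- attr(cohort, "gen_config")
  if (!is.null(cfg)) {
    manifest <- list(
      generator = list(
        n_patients = cfg$n_patients, vocab_size = cfg$vocab_size,
        regime = cfg$regime, baseline_incidence = cfg$baseline_incidence,
        zipf_exponent = cfg$zipf_exponent, seed = cfg$seed,
        cancer_code = cfg$cancer_code,
        risk_codes = lapply(cfg$risk_codes, unclass),
        late_symptom_codes = lapply(cfg$late_symptom_codes, unclass)),
      package_version = as.character(utils::packageVersion("trajrisk")))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  invisible(dir)
}
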