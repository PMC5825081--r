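#' Configuration for the synthetic ICU cohort generator
#'
#' Defaults emulate the qualitative structure the classifier exploits in
#' ICU blood-pressure data: class-NA records fluctuate around a normal
#' baseline; class-A records drift linearly from a pre-episode baseline
#' into a sustained sub-60 mmHg plateau at least 30 minutes long; a
#' configurable fraction of "fluctuating" records oscillate across the
#' 60 mmHg line so that some 30-minute windows dip low without satisfying
#' the 27-of-30 rule and their window means land near the decision
#' boundaries. Auxiliary vitals are class-uninformative noise unless
#' `aux_shift` is set.
#'
#' @param n_patients Number of records.
#' @param ahe_fraction Fraction of AHE-positive records (default
#'   `1307/4593`, the class balance of the 4,593-record ICU cohort).
#' @param record_minutes Record length in minutes (>= 360; default 720).
#' @param baseline_map Cohort baseline MAP in mmHg (default 85).
#' @param baseline_sd Between-patient SD of the baseline (default 4;
#'   draws are truncated at three SDs so every class-A record has room for
#'   its full drift and plateau).
#' @param noise_sd Within-record measurement noise SD in mmHg (default 6).
#' @param drift_onset_minute Minute the class-A downward drift starts
#'   (>= 300 so generated onsets pass the 5-hour filter; default 420).
#' @param drift_rate Drift slope in mmHg/min (default 0.5).
#' @param plateau_map Plateau level the drift descends to (default 45).
#'   Realised plateau values are capped at 58 mmHg, guaranteeing the
#'   sustained sub-60 episode.
#' @param fluctuator_fraction Fraction of fluctuating records (default 0.1).
#' @param fluct_amplitude,fluct_period Sinusoid amplitude (mmHg, default 18)
#'   and period (minutes, default 60); the oscillation is centred at
#'   `60 + 0.9 * fluct_amplitude` so troughs cross 60 mmHg.
#' @param vitals Vitals to generate (subset of [VITAL_NAMES]; MAP always
#'   included).
#' @param aux_shift Additive class-A mean shift for auxiliary vitals
#'   (default 0 = uninformative).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients, ahe_fraction = 1307 / 4593,
                         record_minutes = 720L, baseline_map = 85,
                         baseline_sd = 4, noise_sd = 6,
                         drift_onset_minute = 420L, drift_rate = 0.5,
                         plateau_map = 45, fluctuator_fraction = 0.1,
                         fluct_amplitude = 18, fluct_period = 60,
                         vitals = "MAP", aux_shift = 0, seed = 1L) {
  n_patients <- as.integer(n_patients)
  record_minutes <- as.integer(record_minutes)
  drift_onset_minute <- as.integer(drift_onset_minute)
  if (n_patients < 0L) stop("n_patients must be non-negative")
  if (ahe_fraction < 0 || ahe_fraction > 1)
    stop("ahe_fraction must be in [0, 1]")
  if (fluctuator_fraction < 0 || fluctuator_fraction > 1)
    stop("fluctuator_fraction must be in [0, 1]")
  if (record_minutes < 360L) stop("record_minutes must be >= 360")
  if (drift_onset_minute < 300L)
    stop("drift_onset_minute must be >= 300 so onsets pass the 5-hour filter")
  if (drift_rate <= 0) stop("drift_rate must be positive")
  if (plateau_map >= 60) stop("plateau_map must be below 60 mmHg")
  vitals <- union("MAP", match.arg(vitals, VITAL_NAMES, several.ok = TRUE))
  # worst-case (high-baseline) drift must reach the plateau and leave room
  # for a full 30-minute episode window inside the record
  worst_plateau_start <- drift_onset_minute +
    ceiling((baseline_map + 3 * baseline_sd - plateau_map) / drift_rate)
  if (n_patients > 0L && ahe_fraction > 0 &&
      worst_plateau_start + 30L > record_minutes)
    stop("record_minutes too short for the configured drift to complete a 30-minute plateau")
  structure(list(n_patients = n_patients, ahe_fraction = ahe_fraction,
                 record_minutes = record_minutes, baseline_map = baseline_map,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 drift_onset_minute = drift_onset_minute,
                 drift_rate = drift_rate, plateau_map = plateau_map,
                 fluctuator_fraction = fluctuator_fraction,
                 fluct_amplitude = fluct_amplitude,
                 fluct_period = fluct_period, vitals = vitals,
                 aux_shift = aux_shift, seed = as.integer(seed)),
            class = "synth_config")
}

# auxiliary vital baselines: mean, sd, class-A shift sign
AUX_PARAMS <- list(HR = c(mean = 85, sd = 8, sign = 1),
                   PUL = c(mean = 82, sd = 8, sign = 1),
                   RR = c(mean = 18, sd = 3, sign = 1),
                   OSAT = c(mean = 97, sd = 1.5, sign = -1))

synth_map_values <- function(cfg, is_ahe, is_fluct, base, t) {
  mu <- rep(base, length(t))
  if (is_fluct) {
    centre <- 60 + 0.9 * cfg$fluct_amplitude
    phase <- stats::runif(1, 0, cfg$fluct_period)
    mu <- centre + cfg$fluct_amplitude *
      sin(2 * pi * (t + phase) / cfg$fluct_period)
  }
  if (is_ahe) {
    drifted <- base - cfg$drift_rate * (t - cfg$drift_onset_minute)
    after <- t >= cfg$drift_onset_minute
    mu[after] <- pmax(pmin(mu[after], drifted[after]), cfg$plateau_map)
  }
  x <- mu + stats::rnorm(length(t), 0, cfg$noise_sd)
  if (is_ahe) {
    # once the drift mean has bottomed out, cap realised values below the
    # hypotension threshold so the sustained sub-60 plateau is guaranteed
    plateau <- t >= cfg$drift_onset_minute & mu <= cfg$plateau_map
    x[plateau] <- pmin(x[plateau], 58)
  }
  pmax(x, 20)
}

#' Generate a seeded synthetic ICU cohort
#'
#' See [synth_config()] for the generative families. The AHE-positive
#' count is `round(ahe_fraction * n_patients)`; class and fluctuator
#' assignments and all noise are drawn from a single stream seeded by
#' `config$seed`, so identical configurations yield identical cohorts
#' sample for sample.
#'
#' @param config A [synth_config()].
#' @return A list of [patient_record()]s (raw: not yet truncated at the
#'   first AHE; see [prepare_cohort()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_patients
  if (n == 0L) return(list())
  with_local_seed(config$seed, {
    n_A <- round(config$ahe_fraction * n)
    is_ahe <- sample(rep(c(TRUE, FALSE), c(n_A, n - n_A)))
    is_fluct <- stats::runif(n) < config$fluctuator_fraction
    t <- 0:(config$record_minutes - 1L)
    lapply(seq_len(n), function(i) {
      id <- sprintf("P%05d", i)
      base <- config$baseline_map +
        max(-3, min(3, stats::rnorm(1))) * config$baseline_sd
      series <- list(MAP = vital_series(
        id, "MAP", t,
        synth_map_values(config, is_ahe[i], is_fluct[i], base, t)))
      for (v in setdiff(config$vitals, "MAP")) {
        p <- AUX_PARAMS[[v]]
        mu <- p[["mean"]] + if (is_ahe[i]) p[["sign"]] * config$aux_shift else 0
        val <- mu + stats::rnorm(length(t), 0, p[["sd"]])
        if (v == "OSAT") val <- pmin(val, 100)
        series[[v]] <- vital_series(id, v, t, val)
      }
      patient_record(id, series)
    })
  })
}

#' Truncate and filter a raw cohort
#'
#' Convenience pipeline: [truncate_at_first_ahe()] on every record, then
#' [filter_cohort()].
#'
#' @param records List of [patient_record()]s.
#' @param ... Passed to [filter_cohort()].
#' @return The prepared cohort.
#' @export
prepare_cohort <- function(records, ...) {
  filter_cohort(lapply(records, truncate_at_first_ahe), ...)
}

#' Summarise a cohort record by record
#'
#' One row per record: class label as determined by the AHE detector (not
#' the generator's intent), record span, onset of the first detected AHE
#' and per-vital coverage (present minutes / span).
#'
#' @param records List of [patient_record()]s (raw or truncated).
#' @return A data frame with columns `patient_id`, `class`, `record_minutes`,
#'   `ahe_onset`, and one `coverage_<vital>` column per vital present.
#' @export
cohort_manifest <- function(records) {
  all_vitals <- unique(unlist(lapply(records, function(r) names(r$series))))
  cov_cols <- paste0("coverage_", all_vitals)
  if (!length(records)) {
    out <- data.frame(patient_id = character(0), class = character(0),
                      record_minutes = integer(0), ahe_onset = integer(0))
    return(out)
  }
  rows <- lapply(records, function(r) {
    ev <- if (!is.null(r$ahe_onset)) ahe_event(r$ahe_onset, NA_integer_)
          else detect_ahe(r$series$MAP)
    span <- record_end(r)
    row <- data.frame(patient_id = r$patient_id,
                      class = if (is.null(ev)) "NA" else "A",
                      record_minutes = span,
                      ahe_onset = if (is.null(ev)) NA_integer_
                                  else ev$start_minute)
    for (v in all_vitals) {
      s <- r$series[[v]]
      row[[paste0("coverage_", v)]] <-
        if (is.null(s) || span == 0L) 0 else length(s$times) / span
    }
    row
  })
  do.call(rbind, rows)
}
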