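#' Read vital-sign series from CSV
#'
#' Accepts two dialects: `patient_id,vital,minute,value` (minute-sampled)
#' and `patient_id,vital,second,value` (per-second, resampled to minute
#' means on read).
#'
#' @param path CSV file path.
#' @return A list of [patient_record()]s (one per patient, `ahe_onset`
#'   unset).
#' @export
read_vitals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "vital", "value")
  if (!all(need %in% names(df)) ||
      !any(c("minute", "second") %in% names(df)))
    stop("expected columns patient_id, vital, minute|second, value")
  per_second <- "second" %in% names(df)
  tcol <- if (per_second) "second" else "minute"
  by_patient <- split(df, df$patient_id)
  lapply(by_patient, function(pd) {
    series <- lapply(split(pd, pd$vital), function(vd) {
      vd <- vd[order(vd[[tcol]]), , drop = FALSE]
      if (per_second) {
        resample_to_minutes(vd[[tcol]], vd$value, vd$patient_id[1L],
                            vd$vital[1L])
      } else {
        vital_series(vd$patient_id[1L], vd$vital[1L], vd[[tcol]], vd$value)
      }
    })
    patient_record(pd$patient_id[1L], series)
  })
}

#' Write vital-sign series to CSV (minute dialect)
#'
#' @param records List of [patient_record()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vitals <- function(records, path) {
  rows <- lapply(records, function(r)
    do.call(rbind, lapply(r$series, function(s)
      data.frame(patient_id = s$patient_id, vital = s$vital,
                 minute = s$times, value = s$values))))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Detect and report first AHE events for a cohort
#'
#' @param records List of [patient_record()]s (raw, untruncated).
#' @param path Optional CSV path; when given the report is also written as
#'   `patient_id,ahe_onset_minute,n_low`.
#' @param ... Passed to [detect_ahe()].
#' @return A data frame with one row per record; `NA` onset for records
#'   without an AHE.
#' @export
ahe_report <- function(records, path = NULL, ...) {
  rows <- lapply(records, function(r) {
    ev <- detect_ahe(r$series$MAP, ...)
    data.frame(patient_id = r$patient_id,
               ahe_onset_minute = if (is.null(ev)) NA_integer_
                                  else ev$start_minute,
               n_low = if (is.null(ev)) NA_integer_ else ev$n_low)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Write window summaries to CSV
#'
#' @param summaries List of `window_summary` objects (see
#'   [summarize_window()]) with an accompanying label per summary.
#' @param labels Character vector of `"A"`/`"NA"` labels, one per summary.
#' @param kinds Character vector of window kinds (`"observation"` or
#'   `"test"`), one per summary.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_window_summaries <- function(summaries, labels, kinds, path) {
  rows <- Map(function(s, lab, kind)
    data.frame(patient_id = s$patient_id, vital = s$vital,
               window_kind = kind, start = s$start, end = s$end,
               mean = s$mean_value, n = s$n_samples, label = lab),
    summaries, labels, kinds)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Serialise a trained model to JSON
#'
#' The document holds, per vital, the 7-tuple
#' `[n_A, n_NA, mu_A, sigma_A, mu_NA, sigma_NA, kappa_star]`, the
#' variances consumed by the distance rule, the retained coordinate
#' multisets used for online kappa refits, the round index and the kappa
#' grid size. Numbers are written at full double precision so the model
#' round-trips bit-stably.
#'
#' @param model A [dbc_model()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dbc_model <- function(model, path) {
  stopifnot(inherits(model, "dbc_model"))
  doc <- list(
    round_index = model$round_index,
    grid_size = model$grid_size,
    vote_tiebreak_vital = model$vote_tiebreak_vital,
    vitals = lapply(model$vitals, function(vm) list(
      vital = vm$vital,
      n_A = vm$summary_A$n, n_NA = vm$summary_NA$n,
      mu_A = vm$summary_A$mean, sigma_A = summary_sd(vm$summary_A),
      mu_NA = vm$summary_NA$mean, sigma_NA = summary_sd(vm$summary_NA),
      nu_A = vm$summary_A$variance, nu_NA = vm$summary_NA$variance,
      kappa_star = vm$kappa_star, degenerate_mode = vm$degenerate_mode,
      coords_A = vm$coords_A, coords_NA = vm$coords_NA)))
  # digits = I(17): IEEE doubles round-trip exactly at 17 significant digits
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' Read a model serialised by [write_dbc_model()]
#'
#' @param path JSON path.
#' @return A [dbc_model()].
#' @export
read_dbc_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  vitals <- lapply(doc$vitals, function(d) {
    ks <- if (is.null(d$kappa_star)) NA_real_ else d$kappa_star
    vital_model(d$vital,
                class_summary(d$n_A, d$mu_A, d$nu_A),
                class_summary(d$n_NA, d$mu_NA, d$nu_NA),
                kappa_star = ks, degenerate_mode = d$degenerate_mode,
                coords_A = unlist(d$coords_A),
                coords_NA = unlist(d$coords_NA))
  })
  names(vitals) <- vapply(doc$vitals, `[[`, character(1), "vital")
  dbc_model(vitals, round_index = doc$round_index,
            grid_size = doc$grid_size)
}

#' Read a run configuration file
#'
#' YAML key-value file carrying window grids (`O`, `P`, `T`), generator
#' settings, `anchor_policy`, `coverage_floor`, `distance` and `seed`.
#' Missing keys fall back to package defaults downstream.
#'
#' @param path YAML path.
#' @return A named list.
#' @export
read_dbc_config <- function(path) yaml::read_yaml(path)
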