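#' Observation/prediction/test window configuration
#'
#' The `[O, P, T]` triple (all in minutes) positions windows relative to a
#' prediction anchor: the prediction window `[anchor - P, anchor)` is the
#' lead time before a potential event onset; the observation window
#' `[anchor - P - O, anchor - P)` supplies training features; the test
#' window `[anchor - P - T, anchor - P)` supplies the mean classified at
#' prediction time. Observation and test lengths vary independently.
#'
#' @param observation,prediction,test Positive window lengths in minutes.
#' @return An object of class `window_config` with fields `O`, `P`, `T`.
#' @export
window_config <- function(observation, prediction, test) {
  O <- as.integer(observation); P <- as.integer(prediction)
  Tw <- as.integer(test)
  if (any(c(O, P, Tw) <= 0L)) stop("O, P, T must all be positive")
  structure(list(O = O, P = P, T = Tw), class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("<window_config> O=%d P=%d T=%d minutes\n", x$O, x$P, x$T))
  invisible(x)
}

#' Default window-parameter grids
#'
#' Six observation lengths, twenty-four prediction horizons and six test
#' lengths; their product enumerates 864 `[O,P,T]` settings.
#'
#' @return A list with integer vectors `O`, `P`, `T`.
#' @export
default_grids <- function() {
  list(O = seq(20L, 120L, by = 20L),
       P = seq(5L, 120L, by = 5L),
       T = seq(20L, 120L, by = 20L))
}

#' Enumerate window-parameter settings
#'
#' @param O,P,T Integer vectors of window lengths (minutes); defaults are
#'   the grids of [default_grids()].
#' @return A data frame with one row per `(O, P, T)` triple.
#' @export
grid_settings <- function(O = default_grids()$O, P = default_grids()$P,
                          T = default_grids()$T) {
  if (!length(O) || !length(P) || !length(T)) stop("grids must be non-empty")
  expand.grid(O = as.integer(O), P = as.integer(P), T = as.integer(T),
              KEEP.OUT.ATTRS = FALSE)
}

# Run expr with the RNG seeded locally, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Apply the cohort inclusion filters
#'
#' Retains records with at least 360 minutes (6 hours) of MAP measurements
#' and, for AHE-positive records, an onset at minute 300 (5 hours) or
#' later. Records are expected to be truncated at their first AHE (see
#' [truncate_at_first_ahe()]).
#'
#' @param records List of [patient_record()]s.
#' @param min_map_minutes Minimum count of MAP measurements (default 360).
#' @param min_onset_minute Earliest admissible AHE onset (default 300).
#' @return The retained sublist (possibly empty).
#' @export
filter_cohort <- function(records, min_map_minutes = 360L,
                          min_onset_minute = 300L) {
  keep <- vapply(records, function(r) {
    map <- r$series$MAP
    if (is.null(map) || length(map$times) < min_map_minutes) return(FALSE)
    is.null(r$ahe_onset) || r$ahe_onset >= min_onset_minute
  }, logical(1))
  records[keep]
}

#' Position observation and test windows for one record
#'
#' For class-A records the anchor is the AHE onset; for class-NA records it
#' is set by `anchor_policy`: the end of the usable record (default,
#' deterministic) or a seeded random minute at least 360 minutes into the
#' record. Intervals are half-open `[start, end)` in 0-based minutes.
#'
#' @param record A filtered, truncated [patient_record()].
#' @param config A [window_config()].
#' @param anchor_policy `"record_end"` or `"seeded_random"` (class-NA
#'   records only; class-A records always anchor at onset).
#' @param seed Integer seed, required for `"seeded_random"`.
#' @return A list with elements `observation`, `test` (each `c(start, end)`)
#'   and `anchor`, or `NULL` when the record is too short for
#'   `anchor - P - max(O, T) >= 0`.
#' @export
place_windows <- function(record, config,
                          anchor_policy = c("record_end", "seeded_random"),
                          seed = NULL) {
  stopifnot(inherits(record, "patient_record"),
            inherits(config, "window_config"))
  anchor_policy <- match.arg(anchor_policy)
  need <- config$P + max(config$O, config$T)
  if (!is.null(record$ahe_onset)) {
    anchor <- record$ahe_onset
  } else if (anchor_policy == "record_end") {
    anchor <- record_end(record)
  } else {
    if (is.null(seed))
      stop("anchor_policy = 'seeded_random' requires a seed")
    lo <- max(360L, need)
    hi <- record_end(record)
    if (hi < lo) return(NULL)
    anchor <- with_local_seed(seed, lo + sample.int(hi - lo + 1L, 1L) - 1L)
  }
  if (anchor - need < 0L) return(NULL)
  pred_start <- anchor - config$P
  list(observation = c(pred_start - config$O, pred_start),
       test = c(pred_start - config$T, pred_start),
       anchor = as.integer(anchor))
}

#' Summarise a window by its mean
#'
#' Mean of the present samples of one vital over a half-open minute
#' interval. Returns `NULL` when the fraction of present minutes falls
#' below `coverage_floor`, so that window means are never dominated by
#' imputation-free gaps.
#'
#' @param record A [patient_record()].
#' @param interval `c(start, end)`, half-open minutes.
#' @param vital Vital name (default MAP).
#' @param coverage_floor Minimum present-sample fraction (default 0.9).
#' @return A list of class `window_summary` with `patient_id`, `vital`,
#'   `start`, `end`, `mean_value`, `n_samples`, or `NULL`.
#' @export
summarize_window <- function(record, interval, vital = "MAP",
                             coverage_floor = 0.9) {
  s <- record$series[[vital]]
  if (is.null(s)) return(NULL)
  start <- interval[1L]; end <- interval[2L]
  if (end <= start) stop("interval must have positive length")
  sel <- s$times >= start & s$times < end
  n <- sum(sel)
  if (n < coverage_floor * (end - start)) return(NULL)
  structure(list(patient_id = record$patient_id, vital = vital,
                 start = as.integer(start), end = as.integer(end),
                 mean_value = mean(s$values[sel]), n_samples = n),
            class = "window_summary")
}

#' Build one training round's class vectors
#'
#' Collects, per vital, the vector of per-patient observation-window means
#' for class A (`y_A`) and class NA (`y_NA`). Round 1 uses the window
#' adjacent to each patient's prediction window; round `r > 1` uses the
#' window ending `(r-1)*O` minutes earlier (successive non-overlapping
#' windows stepping back through each patient's history — class-A records
#' hold no data after the onset, so later rounds draw on earlier data).
#' Patients whose round-`r` window would start before minute 0, or whose
#' window fails the coverage floor, drop out of the round.
#'
#' @param records List of filtered, truncated [patient_record()]s.
#' @param config A [window_config()].
#' @param round_index Positive round number (default 1).
#' @param vitals Vitals to collect (default `"MAP"`).
#' @param coverage_floor Passed to [summarize_window()].
#' @param anchor_policy,seed Passed to [place_windows()].
#' @return Named list: per vital, a list with named numeric vectors `y_A`
#'   and `y_NA` (names are patient ids). Errors when either class ends up
#'   with fewer than 2 usable patients for some requested vital.
#' @export
build_round <- function(records, config, round_index = 1L, vitals = "MAP",
                        coverage_floor = 0.9,
                        anchor_policy = "record_end", seed = NULL) {
  round_index <- as.integer(round_index)
  if (round_index < 1L) stop("round_index must be >= 1")
  out <- lapply(vitals, function(v) list(y_A = numeric(0), y_NA = numeric(0)))
  names(out) <- vitals
  for (r in records) {
    pw <- place_windows(r, config, anchor_policy = anchor_policy, seed = seed)
    if (is.null(pw)) next
    end_r <- pw$observation[2L] - (round_index - 1L) * config$O
    start_r <- end_r - config$O
    if (start_r < 0L) next
    lab <- record_label(r)
    for (v in vitals) {
      sw <- summarize_window(r, c(start_r, end_r), v, coverage_floor)
      if (is.null(sw)) next
      slot <- if (lab == "A") "y_A" else "y_NA"
      out[[v]][[slot]][r$patient_id] <- sw$mean_value
    }
  }
  for (v in vitals) {
    if (length(out[[v]]$y_A) < 2L || length(out[[v]]$y_NA) < 2L)
      stop(sprintf(
        "degenerate class for vital %s: each class needs >= 2 usable patients",
        v))
  }
  out
}
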