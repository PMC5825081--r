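#' Supported vital-sign names
#'
#' Mean arterial pressure (MAP, mmHg), heart rate (HR, beats/min), pulse
#' rate (PUL, beats/min), respiratory rate (RR, breaths/min) and oxygen
#' saturation (OSAT, percent).
#' @export
VITAL_NAMES <- c("MAP", "HR", "PUL", "RR", "OSAT")

#' Construct a minute-indexed vital-sign series
#'
#' A `vital_series` holds one patient's measurements of one vital on an
#' integer minute grid (offsets from record start). Minutes with no
#' measurement are simply absent from `times`; they are never interpolated.
#'
#' @param patient_id Opaque patient identifier.
#' @param vital One of [VITAL_NAMES].
#' @param times Integer minute offsets, strictly increasing.
#' @param values Finite measurements, same length as `times`.
#' @return An object of class `vital_series`.
#' @export
vital_series <- function(patient_id, vital, times, values) {
  vital <- match.arg(vital, VITAL_NAMES)
  times <- as.integer(times)
  values <- as.double(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0L))
    stop("times must be strictly increasing")
  if (anyNA(times))
    stop("times must not contain NA")
  if (length(values) && any(!is.finite(values)))
    stop("values must be finite")
  structure(
    list(patient_id = patient_id, vital = vital, times = times,
         values = values),
    class = "vital_series"
  )
}

#' @export
print.vital_series <- function(x, ...) {
  span <- if (length(x$times)) sprintf("[%d, %d]", min(x$times), max(x$times))
          else "(empty)"
  cat(sprintf("<vital_series> patient %s, vital %s, %d samples over minutes %s\n",
              x$patient_id, x$vital, length(x$times), span))
  invisible(x)
}

#' @export
length.vital_series <- function(x) length(x$times)

#' Construct a patient record
#'
#' Bundles one patient's vital series. `ahe_onset`, when present, is the
#' start minute of the first detected acute hypotensive episode; series in a
#' truncated record end strictly before it.
#'
#' @param patient_id Opaque patient identifier.
#' @param series Named list of [vital_series()], names being vital names.
#'   A MAP series is required for event detection and classification.
#' @param ahe_onset Optional integer minute of first AHE onset.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, series, ahe_onset = NULL) {
  if (!length(series) || is.null(names(series)) || any(names(series) == ""))
    stop("series must be a non-empty named list")
  for (v in names(series)) {
    s <- series[[v]]
    if (!inherits(s, "vital_series")) stop("series elements must be vital_series")
    if (!identical(s$patient_id, patient_id))
      stop("all member series must share patient_id")
    if (!identical(s$vital, v)) stop("series name must match its vital")
  }
  if (!is.null(ahe_onset)) ahe_onset <- as.integer(ahe_onset)
  structure(
    list(patient_id = patient_id, series = series, ahe_onset = ahe_onset),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: vitals {%s}%s\n", x$patient_id,
              paste(names(x$series), collapse = ", "),
              if (is.null(x$ahe_onset)) ", no AHE"
              else sprintf(", AHE onset minute %d", x$ahe_onset)))
  invisible(x)
}

#' Class label of a record
#'
#' `"A"` (at risk / AHE observed) when an AHE onset is recorded, `"NA"`
#' otherwise.
#' @param record A [patient_record()].
#' @return `"A"` or `"NA"`.
#' @export
record_label <- function(record) {
  if (is.null(record$ahe_onset)) "NA" else "A"
}

#' End of a record's usable extent
#'
#' One past the last observed minute of the given vital (half-open
#' convention), or 0 for an empty series.
#' @param record A [patient_record()].
#' @param vital Vital name, default MAP.
#' @return Integer minute.
#' @export
record_end <- function(record, vital = "MAP") {
  s <- record$series[[vital]]
  if (is.null(s) || !length(s$times)) return(0L)
  max(s$times) + 1L
}

#' Resample a per-second signal to minute means
#'
#' Each minute bucket `[m*60, (m+1)*60)` seconds receives the arithmetic
#' mean of the raw samples falling in it. Minutes with no samples are left
#' absent (missing), never interpolated.
#'
#' @param raw_times Non-decreasing sample times in seconds.
#' @param raw_values Measurements, same length as `raw_times`.
#' @param patient_id,vital Identity of the resulting series.
#' @return A [vital_series()] on the minute grid.
#' @export
resample_to_minutes <- function(raw_times, raw_values, patient_id = "p",
                                vital = "MAP") {
  if (!length(raw_times)) stop("empty input: at least one sample required")
  if (length(raw_times) != length(raw_values))
    stop("raw_times and raw_values must have equal length")
  if (is.unsorted(raw_times)) stop("raw_times must be non-decreasing")
  minute <- floor(raw_times / 60)
  means <- vapply(split(as.double(raw_values), minute), mean, numeric(1))
  mins <- as.integer(names(means))
  o <- order(mins)
  vital_series(patient_id, vital, mins[o], unname(means[o]))
}

#' Approximate mean arterial pressure from systolic/diastolic readings
#'
#' The conventional approximation weights diastole twice:
#' `MAP = (X + 2Y)/3` for systolic `X` and diastolic `Y`. An alternative
#' convention, `MAP = (2/3)X - (1/3)Y`, is available behind
#' `convention = "paper_literal"`; it does not satisfy `MAP = X` when
#' `X = Y` and is provided only for comparison.
#'
#' @param systolic,diastolic Pressures in mmHg; `systolic >= diastolic > 0`.
#' @param convention `"standard"` (default) or `"paper_literal"`.
#' @return MAP in mmHg (vectorised).
#' @export
approximate_map <- function(systolic, diastolic,
                            convention = c("standard", "paper_literal")) {
  convention <- match.arg(convention)
  if (any(diastolic <= 0)) stop("diastolic pressure must be positive")
  if (any(systolic < diastolic))
    stop("systolic pressure must be >= diastolic pressure")
  switch(convention,
    standard = (systolic + 2 * diastolic) / 3,
    paper_literal = (2 / 3) * systolic - (1 / 3) * diastolic
  )
}

#' An acute hypotensive episode event
#'
#' @param start_minute Start minute of the qualifying window.
#' @param n_low Count of sub-threshold measurements inside it.
#' @return An object of class `ahe_event`.
#' @export
ahe_event <- function(start_minute, n_low) {
  structure(list(start_minute = as.integer(start_minute),
                 n_low = as.integer(n_low)),
            class = "ahe_event")
}

#' @export
print.ahe_event <- function(x, ...) {
  cat(sprintf("<ahe_event> start minute %d, %d low measurements\n",
              x$start_minute, x$n_low))
  invisible(x)
}

#' Detect the first acute hypotensive episode in a MAP series
#'
#' Scans all 30-minute windows left to right with stride 1 minute and
#' returns the earliest window in which at least `min_low_count` of the
#' `window_minutes` samples are no greater than `low_threshold` mmHg
#' (at least 27 of 30 at the defaults, i.e. 90%). Only complete windows —
#' all minutes present — are eligible; windows containing missing minutes
#' are skipped so the 27-of-30 count keeps its exact meaning.
#'
#' @param series A minute-resampled MAP [vital_series()].
#' @param window_minutes Window length in minutes (default 30).
#' @param low_threshold Hypotension threshold in mmHg (default 60).
#' @param min_low_count Minimum sub-threshold samples per window (default 27).
#' @return An [ahe_event()], or `NULL` when no window qualifies (including
#'   series shorter than one window).
#' @export
detect_ahe <- function(series, window_minutes = 30L, low_threshold = 60,
                       min_low_count = 27L) {
  stopifnot(inherits(series, "vital_series"))
  if (!identical(series$vital, "MAP"))
    stop("detect_ahe expects a MAP series")
  w <- as.integer(window_minutes)
  if (length(series$times) < w) return(NULL)
  t0 <- min(series$times)
  n <- max(series$times) - t0 + 1L
  present <- logical(n)
  low <- logical(n)
  pos <- series$times - t0 + 1L
  present[pos] <- TRUE
  low[pos] <- series$values <= low_threshold
  if (n < w) return(NULL)
  cp <- c(0L, cumsum(present))
  cl <- c(0L, cumsum(low))
  i <- seq_len(n - w + 1L)
  n_present <- cp[i + w] - cp[i]
  n_low <- cl[i + w] - cl[i]
  hit <- which(n_present == w & n_low >= min_low_count)
  if (!length(hit)) return(NULL)
  ahe_event(t0 + hit[1L] - 1L, n_low[hit[1L]])
}

#' Truncate a record at its first acute hypotensive episode
#'
#' Keeps, for every vital, only measurements strictly before the onset of
#' the first detected AHE, and records the onset in `ahe_onset`. Records
#' without an AHE are returned unchanged with `ahe_onset` absent.
#'
#' @param record A [patient_record()] containing a MAP series.
#' @param ... Passed to [detect_ahe()] (window length, thresholds).
#' @return A [patient_record()].
#' @export
truncate_at_first_ahe <- function(record, ...) {
  stopifnot(inherits(record, "patient_record"))
  if (is.null(record$series$MAP)) stop("record has no MAP series")
  ev <- detect_ahe(record$series$MAP, ...)
  if (is.null(ev)) {
    record$ahe_onset <- NULL
    return(record)
  }
  onset <- ev$start_minute
  record$series <- lapply(record$series, function(s) {
    keep <- s$times < onset
    vital_series(s$patient_id, s$vital, s$times[keep], s$values[keep])
  })
  record$ahe_onset <- onset
  record
}
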