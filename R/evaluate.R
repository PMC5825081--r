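#' Confusion counts and classification metrics
#'
#' Positive = class A (at risk of AHE). Sensitivity is the fraction of
#' true class-A cases predicted A, specificity the fraction of true
#' class-NA cases predicted NA, accuracy the fraction of all cases
#' predicted correctly.
#'
#' @param predictions,truths Character vectors of `"A"`/`"NA"` labels,
#'   equal length >= 1.
#' @return A list of class `metrics_result` with `sensitivity`,
#'   `specificity`, `accuracy`, `TP`, `FP`, `TN`, `FN`. A metric whose
#'   denominator is zero is `NA`.
#' @export
score <- function(predictions, truths) {
  if (!length(predictions)) stop("empty input: no predictions to score")
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length")
  if (!all(c(predictions, truths) %in% c("A", "NA")))
    stop("labels must be 'A' or 'NA'")
  TP <- sum(predictions == "A" & truths == "A")
  FP <- sum(predictions == "A" & truths == "NA")
  TN <- sum(predictions == "NA" & truths == "NA")
  FN <- sum(predictions == "NA" & truths == "A")
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  structure(list(sensitivity = ratio(TP, TP + FN),
                 specificity = ratio(TN, TN + FP),
                 accuracy = (TP + TN) / length(predictions),
                 TP = TP, FP = FP, TN = TN, FN = FN),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf(
    "<metrics_result> sens=%.3f spec=%.3f acc=%.3f (TP=%d FP=%d TN=%d FN=%d)\n",
    x$sensitivity, x$specificity, x$accuracy, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

# Per-record observation and test window means for the requested vitals.
# Records lacking a usable MAP observation or test mean are dropped.
cohort_window_means <- function(cohort, config, vitals = "MAP",
                                coverage_floor = 0.9,
                                anchor_policy = "record_end", seed = NULL) {
  out <- list()
  for (r in cohort) {
    pw <- place_windows(r, config, anchor_policy = anchor_policy, seed = seed)
    if (is.null(pw)) next
    obs <- test <- stats::setNames(rep(NA_real_, length(vitals)), vitals)
    for (v in vitals) {
      so <- summarize_window(r, pw$observation, v, coverage_floor)
      st <- summarize_window(r, pw$test, v, coverage_floor)
      if (!is.null(so)) obs[[v]] <- so$mean_value
      if (!is.null(st)) test[[v]] <- st$mean_value
    }
    if (!is.finite(obs[["MAP"]]) || !is.finite(test[["MAP"]])) next
    out[[r$patient_id]] <- list(patient_id = r$patient_id,
                                label = record_label(r), obs = obs,
                                test = test)
  }
  out
}

round_vectors_from <- function(means, vitals) {
  out <- lapply(vitals, function(v) {
    y_A <- y_NA <- numeric(0)
    for (m in means) {
      if (!is.finite(m$obs[[v]])) next
      if (m$label == "A") y_A[m$patient_id] <- m$obs[[v]]
      else y_NA[m$patient_id] <- m$obs[[v]]
    }
    list(y_A = y_A, y_NA = y_NA)
  })
  names(out) <- vitals
  out
}

decisions_frame <- function(ids, truths, preds, regions, extra = NULL) {
  d <- data.frame(patient_id = ids, truth = truths, pred = preds,
                  region = regions, stringsAsFactors = FALSE)
  if (!is.null(extra)) d <- cbind(d, extra)
  d
}

#' Offline evaluation by stratified k-fold cross-validation
#'
#' Patients are assigned to folds stratified by class (seeded). For each
#' fold a model is trained offline on the training patients' observation
#' windows and the held-out patients' test-window means are classified;
#' confusion counts are pooled over folds.
#'
#' @param cohort List of prepared [patient_record()]s (see
#'   [prepare_cohort()]).
#' @param config A [window_config()].
#' @param folds Number of folds (default 5); each class must have at least
#'   this many usable patients.
#' @param seed Seed governing fold assignment.
#' @param vitals Vitals used (default `"MAP"`).
#' @param coverage_floor,distance,grid_size Passed through to windowing and
#'   classification.
#' @return A list of class `dbc_cv` with `metrics` ([score()] result pooled
#'   over folds), `fold_counts` (per-fold confusion counts), `decisions`
#'   (data frame with per-patient truth, prediction and MAP region) and the
#'   call settings.
#' @export
run_offline_cv <- function(cohort, config, folds = 5L, seed = 1L,
                           vitals = "MAP", coverage_floor = 0.9,
                           distance = "sum", grid_size = 201L) {
  folds <- as.integer(folds)
  means <- cohort_window_means(cohort, config, vitals, coverage_floor)
  labels <- vapply(means, `[[`, character(1), "label")
  ids_A <- names(means)[labels == "A"]
  ids_NA <- names(means)[labels == "NA"]
  if (length(ids_A) < folds || length(ids_NA) < folds)
    stop(sprintf("each class needs at least %d usable patients", folds))
  fold_of <- with_local_seed(seed, {
    fa <- stats::setNames(rep_len(seq_len(folds), length(ids_A)),
                          sample(ids_A))
    fn <- stats::setNames(rep_len(seq_len(folds), length(ids_NA)),
                          sample(ids_NA))
    c(fa, fn)
  })
  all_dec <- list()
  fold_counts <- vector("list", folds)
  for (k in seq_len(folds)) {
    test_ids <- names(fold_of)[fold_of == k]
    train_ids <- setdiff(names(means), test_ids)
    model <- train_offline(round_vectors_from(means[train_ids], vitals),
                           grid_size = grid_size)
    ids <- truths <- preds <- regions <- character(length(test_ids))
    for (j in seq_along(test_ids)) {
      m <- means[[test_ids[j]]]
      cp <- classify_patient(model, m$test, distance = distance)
      ids[j] <- m$patient_id; truths[j] <- m$label
      preds[j] <- cp$label
      regions[j] <- cp$decisions$MAP$region
    }
    fold_counts[[k]] <- score(preds, truths)
    all_dec[[k]] <- decisions_frame(ids, truths, preds, regions,
                                    extra = data.frame(fold = k))
  }
  decisions <- do.call(rbind, all_dec)
  structure(list(metrics = score(decisions$pred, decisions$truth),
                 fold_counts = fold_counts, decisions = decisions,
                 config = config, folds = folds, seed = seed,
                 n_used = length(means)),
            class = "dbc_cv")
}

#' Plan the initial training split for the online protocol
#'
#' Computes initial per-class training counts from a fraction and class
#' ratio, or from explicitly supplied counts, and the resulting prediction
#' cohort sizes. When the exact ratio is unattainable, the nearest integer
#' split preserving at least 2 patients per class is used.
#'
#' @param n_A,n_NA Class sizes in the cohort.
#' @param initial_fraction Fraction of the cohort used for initial
#'   training (default 0.2).
#' @param class_ratio Fraction of the initial set that is class A; default
#'   is the cohort's own class ratio.
#' @param initial_n_A,initial_n_NA Optional explicit counts overriding the
#'   fraction/ratio arithmetic.
#' @return A list with `initial_A`, `initial_NA`, `n_initial`,
#'   `predict_A`, `predict_NA`, `n_predict`.
#' @export
plan_initial_split <- function(n_A, n_NA, initial_fraction = 0.2,
                               class_ratio = NULL, initial_n_A = NULL,
                               initial_n_NA = NULL) {
  n <- n_A + n_NA
  if (is.null(initial_n_A) || is.null(initial_n_NA)) {
    if (is.null(class_ratio)) class_ratio <- n_A / n
    n_init <- round(initial_fraction * n)
    initial_n_A <- max(2L, round(class_ratio * n_init))
    initial_n_NA <- max(2L, n_init - initial_n_A)
  }
  initial_n_A <- as.integer(initial_n_A)
  initial_n_NA <- as.integer(initial_n_NA)
  if (initial_n_A < 2L || initial_n_NA < 2L ||
      initial_n_A > n_A || initial_n_NA > n_NA)
    stop("initial class ratio unattainable for this cohort")
  list(initial_A = initial_n_A, initial_NA = initial_n_NA,
       n_initial = initial_n_A + initial_n_NA,
       predict_A = as.integer(n_A - initial_n_A),
       predict_NA = as.integer(n_NA - initial_n_NA),
       n_predict = as.integer(n - initial_n_A - initial_n_NA))
}

#' Online incremental evaluation
#'
#' A seeded initial subset of the cohort (about `initial_fraction`, at the
#' requested class ratio) trains the model offline; the remaining patients
#' arrive in a seeded random order and are processed predict-then-update:
#' the patient's test-window mean is classified first, then the true label
#' is revealed and the patient's observation-window mean updates the class
#' statistics as a new online round (batch size `batch_size`, default 1).
#' Metrics cover all post-initial predictions.
#'
#' @inheritParams run_offline_cv
#' @inheritParams plan_initial_split
#' @param batch_size Arrivals folded into each model update (default 1).
#' @return A list of class `dbc_online` with `metrics`, `decisions`,
#'   `split` (the realised initial split), the final `model` and the call
#'   settings.
#' @export
run_online <- function(cohort, config, initial_fraction = 0.2,
                       class_ratio = NULL, initial_n_A = NULL,
                       initial_n_NA = NULL, batch_size = 1L, seed = 1L,
                       vitals = "MAP", coverage_floor = 0.9,
                       distance = "sum", grid_size = 201L) {
  means <- cohort_window_means(cohort, config, vitals, coverage_floor)
  labels <- vapply(means, `[[`, character(1), "label")
  split <- plan_initial_split(sum(labels == "A"), sum(labels == "NA"),
                              initial_fraction, class_ratio,
                              initial_n_A, initial_n_NA)
  order_ids <- with_local_seed(seed, {
    init_ids <- c(sample(names(means)[labels == "A"], split$initial_A),
                  sample(names(means)[labels == "NA"], split$initial_NA))
    rest <- sample(setdiff(names(means), init_ids))
    list(init = init_ids, arrivals = rest)
  })
  model <- train_offline(round_vectors_from(means[order_ids$init], vitals),
                         grid_size = grid_size)
  arrivals <- order_ids$arrivals
  n_arr <- length(arrivals)
  ids <- truths <- preds <- regions <- character(n_arr)
  pending <- list()
  for (j in seq_len(n_arr)) {
    m <- means[[arrivals[j]]]
    cp <- classify_patient(model, m$test, distance = distance)
    ids[j] <- m$patient_id; truths[j] <- m$label
    preds[j] <- cp$label
    regions[j] <- cp$decisions$MAP$region
    pending[[length(pending) + 1L]] <- m
    if (length(pending) >= batch_size || j == n_arr) {
      rv <- round_vectors_from(pending, vitals)
      model <- update_online(model, rv)
      pending <- list()
    }
  }
  decisions <- decisions_frame(ids, truths, preds, regions)
  structure(list(metrics = score(preds, truths), decisions = decisions,
                 split = split, model = model, config = config, seed = seed,
                 n_used = length(means)),
            class = "dbc_online")
}

#' Evaluate over a grid of window-parameter settings
#'
#' Runs the offline cross-validated or online protocol independently for
#' every `(O, P, T)` triple and collects overall metrics per row. The
#' across-settings mean and standard deviation of each metric are attached
#' as the `"summary"` attribute (dispersion is across settings, not across
#' patients or folds).
#'
#' @param cohort List of prepared [patient_record()]s.
#' @param O,P,T Grid vectors (defaults: [default_grids()]).
#' @param mode `"offline"` (default) or `"online"`.
#' @param folds,seed,vitals,coverage_floor,distance,grid_size Passed to the
#'   protocol runners.
#' @param ... Further arguments passed to [run_online()].
#' @return A data frame of class `dbc_grid`, one row per setting, with
#'   columns `O`, `P`, `T`, `mode`, `region` (`"overall"`), the three
#'   metrics and the confusion counts.
#' @export
run_grid <- function(cohort, O = default_grids()$O, P = default_grids()$P,
                     T = default_grids()$T, mode = c("offline", "online"),
                     folds = 5L, seed = 1L, vitals = "MAP",
                     coverage_floor = 0.9, distance = "sum",
                     grid_size = 201L, ...) {
  mode <- match.arg(mode)
  settings <- grid_settings(O, P, T)
  rows <- vector("list", nrow(settings))
  for (i in seq_len(nrow(settings))) {
    cfg <- window_config(settings$O[i], settings$P[i], settings$T[i])
    m <- if (mode == "offline") {
      run_offline_cv(cohort, cfg, folds = folds, seed = seed, vitals = vitals,
                     coverage_floor = coverage_floor, distance = distance,
                     grid_size = grid_size)$metrics
    } else {
      run_online(cohort, cfg, seed = seed, vitals = vitals,
                 coverage_floor = coverage_floor, distance = distance,
                 grid_size = grid_size, ...)$metrics
    }
    rows[[i]] <- data.frame(O = settings$O[i], P = settings$P[i],
                            T = settings$T[i], mode = mode,
                            region = "overall",
                            sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            accuracy = m$accuracy,
                            TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN)
  }
  out <- do.call(rbind, rows)
  metric_cols <- c("sensitivity", "specificity", "accuracy")
  attr(out, "summary") <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(cn) mean(out[[cn]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_cols, function(cn) stats::sd(out[[cn]], na.rm = TRUE),
                numeric(1)))
  class(out) <- c("dbc_grid", class(out))
  out
}

#' Region-wise performance breakdown
#'
#' Splits predictions by the region the MAP test mean fell into (MAP is
#' the tie-break vital, so its region attributes each case) and computes
#' metrics per region. Region confusion counts partition the overall
#' counts. Regions with no cases get `NA` metrics and zero counts.
#'
#' @param decisions A data frame with columns `truth`, `pred`, `region`
#'   (as returned in `$decisions` by [run_offline_cv()] / [run_online()]).
#' @return A data frame with one row per region
#'   (`ahe_region`, `non_ahe_region`, `uncertainty`) plus `overall`.
#' @export
region_breakdown <- function(decisions) {
  regions <- c("ahe_region", "non_ahe_region", "uncertainty")
  one <- function(reg, sub) {
    if (!nrow(sub)) {
      return(data.frame(region = reg, n = 0L, sensitivity = NA_real_,
                        specificity = NA_real_, accuracy = NA_real_,
                        TP = 0L, FP = 0L, TN = 0L, FN = 0L))
    }
    m <- score(sub$pred, sub$truth)
    data.frame(region = reg, n = nrow(sub), sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy,
               TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN)
  }
  rows <- lapply(regions, function(reg)
    one(reg, decisions[decisions$region == reg, , drop = FALSE]))
  rows[[length(rows) + 1L]] <- one("overall", decisions)
  do.call(rbind, rows)
}
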