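#' Running per-class statistics
#'
#' Count, mean and *population* variance (divisor `n`) of the accumulated
#' observation-window means of one class for one vital, maintained across
#' online rounds by the incremental recurrences of [summary_update()].
#'
#' @param n Count of accumulated coordinates.
#' @param mean,variance Running mean and population variance (`NA` at n=0).
#' @return An object of class `class_summary`.
#' @export
class_summary <- function(n = 0L, mean = NA_real_, variance = NA_real_) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative")
  if (n > 0L && (!is.finite(mean) || !is.finite(variance) || variance < 0))
    stop("mean must be finite and variance finite and non-negative")
  structure(list(n = n, mean = as.double(mean), variance = as.double(variance)),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("<class_summary> n=%d mean=%.4g sd=%.4g\n", x$n, x$mean,
              summary_sd(x)))
  invisible(x)
}

#' Standard deviation of a class summary
#' @param s A [class_summary()].
#' @return `sqrt(variance)` (population convention).
#' @export
summary_sd <- function(s) sqrt(s$variance)

#' Incrementally update a class summary
#'
#' Folds new coordinates into the running count, mean and population
#' variance one observation at a time using the streaming recurrences
#' `mu_n = mu_{n-1} + (x - mu_{n-1})/n` and
#' `nu_n = ((n-1) nu_{n-1} + (x - mu_{n-1})(x - mu_n))/n`,
#' so earlier rounds' raw values are never needed. The result equals the
#' single-batch statistics of all coordinates seen so far (to floating
#' point round-off).
#'
#' @param s A [class_summary()].
#' @param x Numeric vector of new coordinates (may be empty).
#' @return The updated [class_summary()].
#' @export
summary_update <- function(s, x) {
  stopifnot(inherits(s, "class_summary"))
  x <- as.double(x)
  if (length(x) && any(!is.finite(x))) stop("coordinates must be finite")
  n <- s$n
  mu <- if (n == 0L) 0 else s$mean
  nu <- if (n == 0L) 0 else s$variance
  for (xi in x) {
    n1 <- n + 1L
    d <- xi - mu
    mu1 <- mu + d / n1
    nu <- (n * nu + d * (xi - mu1)) / n1
    mu <- mu1
    n <- n1
  }
  if (n == 0L) class_summary() else class_summary(n, mu, max(nu, 0))
}

# Interval boundaries (L, U) for a given kappa.
kappa_interval <- function(mu_A, sd_A, mu_NA, sd_NA, kappa) {
  c(L = mu_A + kappa * sd_A, U = mu_NA - kappa * sd_NA)
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Dual-boundary misfit counts at a given kappa
#'
#' For boundaries `L = mu_A + kappa*sigma_A` and `U = mu_NA - kappa*sigma_NA`
#' counts the training coordinates a dual-boundary rule would mishandle:
#' `n1` class-A values above `U`, `n2` class-A values strictly inside
#' `(L, U)`, `n3` class-NA values below `L`, and `n4` class-NA values
#' strictly inside `(L, U)`. Class statistics are population moments of the
#' supplied vectors unless overridden.
#'
#' @param y_A,y_NA Class coordinate vectors (each length >= 2).
#' @param kappa Non-negative boundary-width multiplier.
#' @param mu_A,sd_A,mu_NA,sd_NA Optional statistics overriding the vectors'
#'   own population moments (used when refitting online from running
#'   summaries).
#' @return A list of class `kappa_objective` with `kappa`, `n1`..`n4` and
#'   `total`. Errors when `kappa` is infeasible (`L >= U`).
#' @export
kappa_objective <- function(y_A, y_NA, kappa, mu_A = NULL, sd_A = NULL,
                            mu_NA = NULL, sd_NA = NULL) {
  if (length(y_A) < 2L || length(y_NA) < 2L)
    stop("each class needs at least 2 coordinates")
  if (kappa < 0) stop("kappa must be non-negative")
  if (is.null(mu_A)) mu_A <- mean(y_A)
  if (is.null(sd_A)) sd_A <- sqrt(pop_var(y_A))
  if (is.null(mu_NA)) mu_NA <- mean(y_NA)
  if (is.null(sd_NA)) sd_NA <- sqrt(pop_var(y_NA))
  b <- kappa_interval(mu_A, sd_A, mu_NA, sd_NA, kappa)
  if (b["L"] >= b["U"])
    stop(sprintf("infeasible kappa %.6g: mu_A + kappa*sd_A >= mu_NA - kappa*sd_NA",
                 kappa))
  n1 <- sum(y_A > b["U"])
  n2 <- sum(y_A > b["L"] & y_A < b["U"])
  n3 <- sum(y_NA < b["L"])
  n4 <- sum(y_NA > b["L"] & y_NA < b["U"])
  structure(list(kappa = kappa, n1 = n1, n2 = n2, n3 = n3, n4 = n4,
                 total = n1 + n2 + n3 + n4),
            class = "kappa_objective")
}

#' One-dimensional search for the boundary-width multiplier kappa
#'
#' Minimises the misfit count of [kappa_objective()] over the feasible
#' range `[0, kappa_max)`, where
#' `kappa_max = (mu_NA - mu_A)/(sigma_A + sigma_NA)` is the largest
#' feasible multiplier (capped at `kappa_cap` when both standard
#' deviations vanish). The count objective is piecewise constant in kappa,
#' changing only at breakpoints where one boundary crosses a training
#' coordinate, so the default `"breakpoints"` method evaluates every
#' breakpoint and every interval midpoint between consecutive breakpoints
#' — equivalent to an arbitrarily fine grid — and returns the global
#' minimiser; `method = "grid"` instead scans `grid_size` equally spaced
#' values, which can miss plateaus narrower than its step. Ties are
#' broken by the smallest kappa, deferring borderline cases to the
#' distance rule.
#'
#' @param y_A,y_NA Class coordinate vectors (each length >= 2).
#' @param grid_size Number of grid points `K` for `method = "grid"`
#'   (default 201).
#' @param kappa_cap Cap replacing an infinite `kappa_max` (default 1e6).
#' @param method `"breakpoints"` (default, exact) or `"grid"`.
#' @inheritParams kappa_objective
#' @return A list with `kappa_star`, `objective` (the [kappa_objective()]
#'   at the minimiser), `kappa_max`, `grid_size`, `method` and
#'   `degenerate`. When `mu_A >= mu_NA` no kappa is feasible:
#'   `degenerate` is `TRUE` and `kappa_star` is `NA` (callers fall back to
#'   an all-uncertainty model).
#' @export
fit_kappa <- function(y_A, y_NA, grid_size = 201L, kappa_cap = 1e6,
                      mu_A = NULL, sd_A = NULL, mu_NA = NULL, sd_NA = NULL,
                      method = c("breakpoints", "grid")) {
  if (length(y_A) < 2L || length(y_NA) < 2L)
    stop("each class needs at least 2 coordinates")
  method <- match.arg(method)
  grid_size <- as.integer(grid_size)
  if (grid_size < 1L) stop("grid_size must be >= 1")
  if (is.null(mu_A)) mu_A <- mean(y_A)
  if (is.null(sd_A)) sd_A <- sqrt(pop_var(y_A))
  if (is.null(mu_NA)) mu_NA <- mean(y_NA)
  if (is.null(sd_NA)) sd_NA <- sqrt(pop_var(y_NA))
  if (mu_A >= mu_NA) {
    return(list(kappa_star = NA_real_, objective = NULL,
                kappa_max = NA_real_, grid_size = grid_size,
                method = method, degenerate = TRUE))
  }
  denom <- sd_A + sd_NA
  kappa_max <- if (denom > 0) (mu_NA - mu_A) / denom else kappa_cap
  if (method == "grid") {
    grid <- kappa_max * (seq_len(grid_size) - 1L) / grid_size
  } else {
    vals <- c(y_A, y_NA)
    br <- numeric(0)
    if (sd_A > 0) br <- c(br, (vals - mu_A) / sd_A)
    if (sd_NA > 0) br <- c(br, (mu_NA - vals) / sd_NA)
    br <- sort(unique(br[br > 0 & br < kappa_max]))
    # evaluate on plateau interiors (midpoints between consecutive
    # breakpoints): the count at a breakpoint itself is a knife-edge of
    # the strict inequalities, not a value any boundary placement away
    # from the data attains
    mids <- (c(0, br) + c(br, kappa_max)) / 2
    grid <- sort(unique(c(0, mids)))
  }
  L <- mu_A + grid * sd_A
  U <- mu_NA - grid * sd_NA
  sA <- sort(y_A)
  sNA <- sort(y_NA)
  nA <- length(sA)
  # counts via sorted-vector rank lookups; strict/non-strict matches
  # kappa_objective exactly
  n1 <- nA - findInterval(U, sA)                                 # y_A >  U
  n2 <- findInterval(U, sA, left.open = TRUE) - findInterval(L, sA)
  n3 <- findInterval(L, sNA, left.open = TRUE)                   # y_NA < L
  n4 <- findInterval(U, sNA, left.open = TRUE) - findInterval(L, sNA)
  total <- n1 + n2 + n3 + n4
  i <- which.min(total)  # first minimum = smallest kappa
  list(kappa_star = grid[i],
       objective = structure(list(kappa = grid[i], n1 = n1[i], n2 = n2[i],
                                  n3 = n3[i], n4 = n4[i], total = total[i]),
                             class = "kappa_objective"),
       kappa_max = kappa_max, grid_size = grid_size, method = method,
       degenerate = FALSE)
}

#' Per-vital trained model
#'
#' The trained state for one vital: the 7-tuple
#' `[n_A, n_NA, mu_A, sigma_A, mu_NA, sigma_NA, kappa_star]` (held as two
#' [class_summary()]s plus `kappa_star`; variances are retained because the
#' distance rule consumes them), the retained multisets of per-patient
#' observation-window means needed to recompute the misfit counts when
#' kappa is refit online, and a degeneracy flag.
#'
#' @param vital Vital name.
#' @param summary_A,summary_NA [class_summary()]s for classes A and NA.
#' @param kappa_star Fitted boundary multiplier (`NA` when degenerate).
#' @param degenerate_mode `"none"` or `"all_uncertainty"` (every test value
#'   takes the distance path when the class means do not separate).
#' @param coords_A,coords_NA Retained coordinate multisets.
#' @return An object of class `vital_model`.
#' @export
vital_model <- function(vital, summary_A, summary_NA, kappa_star,
                        degenerate_mode = c("none", "all_uncertainty"),
                        coords_A = numeric(0), coords_NA = numeric(0)) {
  degenerate_mode <- match.arg(degenerate_mode)
  if (degenerate_mode == "none") {
    b <- kappa_interval(summary_A$mean, summary_sd(summary_A),
                        summary_NA$mean, summary_sd(summary_NA), kappa_star)
    if (!(b["L"] < b["U"]))
      stop("kappa_star infeasible for the supplied summaries")
  }
  structure(list(vital = vital, summary_A = summary_A,
                 summary_NA = summary_NA, kappa_star = kappa_star,
                 degenerate_mode = degenerate_mode,
                 coords_A = as.double(coords_A),
                 coords_NA = as.double(coords_NA)),
            class = "vital_model")
}

#' @export
print.vital_model <- function(x, ...) {
  cat(sprintf("<vital_model> %s: n_A=%d n_NA=%d kappa*=%s%s\n", x$vital,
              x$summary_A$n, x$summary_NA$n,
              if (is.na(x$kappa_star)) "NA" else sprintf("%.4g", x$kappa_star),
              if (x$degenerate_mode != "none") " [all-uncertainty]" else ""))
  invisible(x)
}

#' A dual boundary classifier model
#'
#' @param vitals Named list of [vital_model()]s; must include MAP, the
#'   majority-vote tie-break vital.
#' @param round_index Training round counter.
#' @param grid_size Kappa grid size used for fitting/refitting.
#' @return An object of class `dbc_model`.
#' @export
dbc_model <- function(vitals, round_index = 1L, grid_size = 201L) {
  if (is.null(vitals$MAP)) stop("a MAP vital model is mandatory")
  structure(list(vitals = vitals, round_index = as.integer(round_index),
                 grid_size = as.integer(grid_size),
                 vote_tiebreak_vital = "MAP"),
            class = "dbc_model")
}

#' @export
print.dbc_model <- function(x, ...) {
  cat(sprintf("<dbc_model> round %d, vitals: %s\n", x$round_index,
              paste(names(x$vitals), collapse = ", ")))
  for (vm in x$vitals) print(vm)
  invisible(x)
}

fit_vital <- function(vital, y_A, y_NA, grid_size) {
  if (length(y_A) < 2L || length(y_NA) < 2L)
    stop(sprintf("vital %s: each class needs at least 2 coordinates", vital))
  sA <- summary_update(class_summary(), y_A)
  sNA <- summary_update(class_summary(), y_NA)
  fk <- fit_kappa(y_A, y_NA, grid_size = grid_size,
                  mu_A = sA$mean, sd_A = summary_sd(sA),
                  mu_NA = sNA$mean, sd_NA = summary_sd(sNA))
  vital_model(vital, sA, sNA,
              kappa_star = fk$kappa_star,
              degenerate_mode = if (fk$degenerate) "all_uncertainty" else "none",
              coords_A = unname(y_A), coords_NA = unname(y_NA))
}

#' Train a dual boundary classifier offline
#'
#' The offline mode is the single-round special case: per vital, class
#' summaries are accumulated from the full observation-window mean vectors
#' (population variance) and `kappa_star` is fitted by [fit_kappa()].
#'
#' @param round_vectors Named list (per vital) of lists with numeric
#'   vectors `y_A` and `y_NA`, as produced by [build_round()]. MAP is
#'   mandatory; every supplied class vector needs at least 2 coordinates.
#' @param grid_size Kappa grid size (default 201).
#' @return A [dbc_model()] with `round_index = 1`.
#' @export
train_offline <- function(round_vectors, grid_size = 201L) {
  if (is.null(round_vectors$MAP))
    stop("MAP round vectors are mandatory")
  vitals <- lapply(names(round_vectors), function(v)
    fit_vital(v, round_vectors[[v]]$y_A, round_vectors[[v]]$y_NA, grid_size))
  names(vitals) <- names(round_vectors)
  dbc_model(vitals, round_index = 1L, grid_size = grid_size)
}

#' Update a dual boundary classifier with a new online round
#'
#' Class counts, means and population variances are advanced one
#' coordinate at a time by the streaming recurrences (see
#' [summary_update()]); prior rounds' raw patient series are never needed.
#' `kappa_star` is then refit on the updated summaries, with the misfit
#' counts recomputed over the retained multiset of all observation-window
#' means seen so far. A class absent from the new round is left untouched.
#'
#' @param model A trained [dbc_model()].
#' @param round_vectors Named list (per vital, all must already exist in
#'   the model) of lists with numeric vectors `y_A` and/or `y_NA`; either
#'   may be empty or omitted.
#' @return The updated [dbc_model()] with `round_index` incremented.
#' @export
update_online <- function(model, round_vectors) {
  stopifnot(inherits(model, "dbc_model"))
  for (v in names(round_vectors)) {
    vm <- model$vitals[[v]]
    if (is.null(vm))
      stop(sprintf("vital %s not present in the model", v))
    new_A <- round_vectors[[v]]$y_A
    new_NA <- round_vectors[[v]]$y_NA
    sA <- summary_update(vm$summary_A, new_A)
    sNA <- summary_update(vm$summary_NA, new_NA)
    coords_A <- c(vm$coords_A, unname(as.double(new_A)))
    coords_NA <- c(vm$coords_NA, unname(as.double(new_NA)))
    fk <- fit_kappa(coords_A, coords_NA, grid_size = model$grid_size,
                    mu_A = sA$mean, sd_A = summary_sd(sA),
                    mu_NA = sNA$mean, sd_NA = summary_sd(sNA))
    model$vitals[[v]] <- vital_model(
      v, sA, sNA, kappa_star = fk$kappa_star,
      degenerate_mode = if (fk$degenerate) "all_uncertainty" else "none",
      coords_A = coords_A, coords_NA = coords_NA)
  }
  model$round_index <- model$round_index + 1L
  model
}

#' Classify one test-window mean with a per-vital model
#'
#' Applies the three-rule procedure. With boundaries
#' `L = mu_A + kappa* sigma_A` and `U = mu_NA - kappa* sigma_NA`:
#' `z < L` falls in the AHE region (vote A); `z > U` falls in the non-AHE
#' region (vote NA); otherwise `z` lies in the uncertainty region and the
#' squared deviation of `z` from all stored training coordinates of each
#' class decides. That total has the closed form
#' `d = n * ((z - mu)^2 + nu)` per class, so only the summary statistics
#' are needed; the vote is NA iff `d_A > d_NA` (ties go to A). The
#' count-free variant `distance = "mean"` divides out the class size,
#' removing the bias toward voting against the larger class.
#'
#' @param vm A [vital_model()].
#' @param z Finite test-window mean.
#' @param distance `"sum"` (default; total squared deviation) or `"mean"`.
#' @return A list of class `region_decision` with `vital`, `region`
#'   (`"ahe_region"`, `"non_ahe_region"` or `"uncertainty"`), distances
#'   `d_A`/`d_NA` (set only in the uncertainty region) and `vote`
#'   (`"A"` or `"NA"`).
#' @export
classify_vital <- function(vm, z, distance = c("sum", "mean")) {
  stopifnot(inherits(vm, "vital_model"))
  distance <- match.arg(distance)
  if (!is.finite(z)) stop("test-window mean z must be finite")
  sA <- vm$summary_A; sNA <- vm$summary_NA
  if (vm$degenerate_mode == "none") {
    b <- kappa_interval(sA$mean, summary_sd(sA), sNA$mean, summary_sd(sNA),
                        vm$kappa_star)
    if (z < b[["L"]])
      return(region_decision(vm$vital, "ahe_region", NA_real_, NA_real_, "A"))
    if (z > b[["U"]])
      return(region_decision(vm$vital, "non_ahe_region", NA_real_, NA_real_,
                             "NA"))
  }
  d_A <- (z - sA$mean)^2 + sA$variance
  d_NA <- (z - sNA$mean)^2 + sNA$variance
  if (distance == "sum") {
    d_A <- sA$n * d_A
    d_NA <- sNA$n * d_NA
  }
  region_decision(vm$vital, "uncertainty", d_A, d_NA,
                  if (d_A > d_NA) "NA" else "A")
}

#' A single test-window verdict
#' @param vital Vital name.
#' @param region Region the test mean fell into.
#' @param d_A,d_NA Distances (uncertainty region only, else `NA`).
#' @param vote Per-vital class vote, `"A"` or `"NA"`.
#' @return An object of class `region_decision`.
#' @export
region_decision <- function(vital,
                            region = c("ahe_region", "non_ahe_region",
                                       "uncertainty"),
                            d_A = NA_real_, d_NA = NA_real_, vote) {
  region <- match.arg(region)
  vote <- match.arg(vote, c("A", "NA"))
  structure(list(vital = vital, region = region, d_A = d_A, d_NA = d_NA,
                 vote = vote),
            class = "region_decision")
}

#' @export
print.region_decision <- function(x, ...) {
  cat(sprintf("<region_decision> %s: %s -> %s\n", x$vital, x$region, x$vote))
  invisible(x)
}

#' Classify a patient from per-vital test-window means
#'
#' Each available vital votes via [classify_vital()]; the final label is
#' the majority vote, with exact ties broken by the MAP vote. A MAP test
#' mean is mandatory.
#'
#' @param model A [dbc_model()].
#' @param z Named numeric vector of test-window means (names are vitals;
#'   must include `MAP`). Vitals absent from the model or with missing
#'   means are skipped.
#' @param distance Passed to [classify_vital()].
#' @return A list with `label` (`"A"` or `"NA"`) and `decisions` (named
#'   list of [region_decision()]s).
#' @export
classify_patient <- function(model, z, distance = c("sum", "mean")) {
  stopifnot(inherits(model, "dbc_model"))
  distance <- match.arg(distance)
  if (!("MAP" %in% names(z)) || !is.finite(z[["MAP"]]))
    stop("a finite MAP test-window mean is mandatory")
  use <- intersect(names(model$vitals), names(z)[is.finite(unlist(z))])
  decisions <- lapply(use, function(v)
    classify_vital(model$vitals[[v]], z[[v]], distance = distance))
  names(decisions) <- use
  votes <- vapply(decisions, `[[`, character(1), "vote")
  n_A <- sum(votes == "A")
  n_NA <- sum(votes == "NA")
  label <- if (n_A > n_NA) "A"
           else if (n_NA > n_A) "NA"
           else decisions[[model$vote_tiebreak_vital]]$vote
  list(label = label, decisions = decisions)
}
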