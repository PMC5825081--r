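# Independent oracles and small fixture builders used across the suite.

# MAP series on consecutive minutes starting at `start`
map_series <- function(values, id = "p1", start = 0L) {
  vital_series(id, "MAP", start + seq_along(values) - 1L, values)
}

map_record <- function(values, id = "p1", start = 0L) {
  patient_record(id, list(MAP = map_series(values, id, start)))
}

# Brute-force AHE scan: enumerate every window start on the minute grid,
# count sub-threshold values directly, return the earliest complete hit.
brute_force_ahe <- function(series, w = 30L, thr = 60, min_low = 27L) {
  if (length(series$times) < w) return(NULL)
  t0 <- min(series$times); t1 <- max(series$times)
  if (t1 - t0 + 1L < w) return(NULL)
  for (s in t0:(t1 - w + 1L)) {
    idx <- series$times >= s & series$times < s + w
    if (sum(idx) != w) next
    nl <- sum(series$values[idx] <= thr)
    if (nl >= min_low) return(list(start = s, n_low = nl))
  }
  NULL
}

# Direct-count kappa objective (population moments), independent of the
# package's findInterval-based counting.
naive_kappa_counts <- function(y_A, y_NA, kappa) {
  mu_A <- mean(y_A); sd_A <- sqrt(mean((y_A - mu_A)^2))
  mu_NA <- mean(y_NA); sd_NA <- sqrt(mean((y_NA - mu_NA)^2))
  L <- mu_A + kappa * sd_A
  U <- mu_NA - kappa * sd_NA
  c(n1 = sum(y_A > U), n2 = sum(y_A > L & y_A < U),
    n3 = sum(y_NA < L), n4 = sum(y_NA > L & y_NA < U))
}

# A seeded random 8-hour MAP series with a slow low-pressure phase and
# optional missing minutes, used for detector oracle checks.
random_map_series <- function(id = "p1", minutes = 480L, missing_frac = 0) {
  t <- 0:(minutes - 1L)
  v <- 65 + 18 * sin(2 * pi * (t + runif(1, 0, minutes)) / 240) +
    rnorm(minutes, 0, 8)
  keep <- runif(minutes) >= missing_frac
  vital_series(id, "MAP", t[keep], pmax(v[keep], 20))
}

# Tiny well-separated prepared cohort for protocol tests.
separable_cohort <- function(n = 60, seed = 5) {
  cfg <- synth_config(n_patients = n, noise_sd = 2, baseline_sd = 1,
                      fluctuator_fraction = 0, seed = seed)
  prepare_cohort(generate_cohort(cfg))
}

pooled_sd <- function(y_A, y_NA) {
  sqrt((length(y_A) * mean((y_A - mean(y_A))^2) +
        length(y_NA) * mean((y_NA - mean(y_NA))^2)) /
       (length(y_A) + length(y_NA)))
}
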