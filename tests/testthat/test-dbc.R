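test_that("streaming summary recurrences reproduce batch population moments", {
  set.seed(12)
  x <- rnorm(200, 70, 8)
  s <- summary_update(class_summary(), x)
  expect_identical(s$n, 200L)
  expect_equal(s$mean, mean(x), tolerance = 1e-12)
  expect_equal(s$variance, mean((x - mean(x))^2), tolerance = 1e-9)
  expect_equal(summary_sd(s)^2, s$variance, tolerance = 1e-12)
  # appending a value equal to the running mean shrinks nu by (n-1)/n
  s0 <- summary_update(class_summary(), c(1, 2, 3))
  s1 <- summary_update(s0, s0$mean)
  expect_equal(s1$mean, s0$mean)
  expect_equal(s1$variance, 3 * s0$variance / 4, tolerance = 1e-12)
})

test_that("incremental updates equal batch statistics over random partitions", {
  set.seed(77)
  for (rep in 1:25) {
    x <- rnorm(sample(20:120, 1), 75, 10)
    n_rounds <- sample(1:10, 1)
    cuts <- sort(sample(seq_len(length(x) - 1L), min(n_rounds - 1L,
                                                     length(x) - 1L)))
    parts <- split(x, findInterval(seq_along(x), cuts + 1L) + 1L)
    s <- class_summary()
    for (p in parts) s <- summary_update(s, p)
    expect_identical(s$n, length(x))
    expect_equal(s$mean, mean(x), tolerance = 1e-9)
    expect_equal(s$variance, mean((x - mean(x))^2), tolerance = 1e-9)
  }
})

test_that("kappa misfit counts match direct counting", {
  # perfectly separated constant classes, degenerate sigma
  ko <- kappa_objective(c(40, 40), c(80, 80), 1)
  expect_equal(ko$total, 0L + 0L)
  expect_equal(c(ko$n1, ko$n2, ko$n3, ko$n4), rep(0L, 4),
               ignore_attr = TRUE)
  # sweep against the direct-count oracle
  y_A <- c(50, 55, 58, 62); y_NA <- c(65, 70, 72, 75)
  kmax <- (mean(y_NA) - mean(y_A)) / (sqrt(mean((y_A - mean(y_A))^2)) +
                                      sqrt(mean((y_NA - mean(y_NA))^2)))
  for (k in seq(0, kmax * 0.999, length.out = 60)) {
    ko <- kappa_objective(y_A, y_NA, k)
    want <- naive_kappa_counts(y_A, y_NA, k)
    expect_equal(c(ko$n1, ko$n2, ko$n3, ko$n4), unname(want),
                 ignore_attr = TRUE)
  }
  # infeasible kappa rejected at the constraint boundary
  expect_error(kappa_objective(y_A, y_NA, kmax * 1.01), "infeasible")
  expect_error(kappa_objective(c(1), c(2, 3), 0), "at least 2")
})

test_that("kappa fitting finds the global count minimum with smallest-kappa ties", {
  # perfectly separated constant classes: flat objective, kappa* = 0
  fk <- fit_kappa(c(40, 40), c(80, 80))
  expect_equal(fk$kappa_star, 0)
  expect_equal(fk$objective$total, 0L, ignore_attr = TRUE)
  # overlapping classes with mu_A >= mu_NA: degenerate signal
  expect_true(fit_kappa(c(70, 80), c(60, 65))$degenerate)
  # fitted objective equals an exhaustive fine-scan minimum
  set.seed(901)
  for (i in 1:30) {
    y_A <- rnorm(sample(8:40, 1), 65, 4)
    y_NA <- rnorm(sample(8:40, 1), 65 + runif(1, 2, 15), 4)
    if (mean(y_A) >= mean(y_NA)) next
    fk <- fit_kappa(y_A, y_NA)
    fine <- fk$kappa_max * (0:9999) / 10000
    totals <- vapply(fine, function(k)
      sum(naive_kappa_counts(y_A, y_NA, k)), numeric(1))
    expect_equal(fk$objective$total, min(totals), ignore_attr = TRUE)
  }
})

test_that("offline training fills the per-vital 7-tuple", {
  y_A <- c(50, 55, 60); y_NA <- c(78, 82, 86, 90)
  m <- train_offline(list(MAP = list(y_A = y_A, y_NA = y_NA)))
  vm <- m$vitals$MAP
  expect_identical(vm$summary_A$n, 3L)
  expect_identical(vm$summary_NA$n, 4L)
  expect_equal(vm$summary_A$mean, 55)
  expect_equal(vm$summary_NA$mean, 84)
  expect_false(is.na(vm$kappa_star))
  expect_identical(m$round_index, 1L)
  # model feasibility invariant
  b_lo <- vm$summary_A$mean + vm$kappa_star * summary_sd(vm$summary_A)
  b_hi <- vm$summary_NA$mean - vm$kappa_star * summary_sd(vm$summary_NA)
  expect_lt(b_lo, b_hi)
  # constant class: zero variance
  m2 <- train_offline(list(MAP = list(y_A = c(50, 50, 50), y_NA = y_NA)))
  expect_equal(m2$vitals$MAP$summary_A$variance, 0)
  expect_error(train_offline(list(HR = list(y_A = y_A, y_NA = y_NA))),
               "MAP")
})

test_that("online updates equal refitting on concatenated rounds", {
  set.seed(41)
  for (rep in 1:10) {
    y_A1 <- rnorm(20, 60, 5); y_NA1 <- rnorm(30, 85, 5)
    y_A2 <- rnorm(8, 60, 5); y_NA2 <- rnorm(12, 85, 5)
    m1 <- train_offline(list(MAP = list(y_A = y_A1, y_NA = y_NA1)))
    m2 <- update_online(m1, list(MAP = list(y_A = y_A2, y_NA = y_NA2)))
    mb <- train_offline(list(MAP = list(y_A = c(y_A1, y_A2),
                                        y_NA = c(y_NA1, y_NA2))))
    va <- m2$vitals$MAP; vb <- mb$vitals$MAP
    expect_identical(va$summary_A$n, vb$summary_A$n)
    expect_identical(va$summary_NA$n, vb$summary_NA$n)
    expect_equal(va$summary_A$mean, vb$summary_A$mean, tolerance = 1e-9)
    expect_equal(va$summary_A$variance, vb$summary_A$variance,
                 tolerance = 1e-9)
    expect_equal(va$summary_NA$mean, vb$summary_NA$mean, tolerance = 1e-9)
    expect_equal(va$summary_NA$variance, vb$summary_NA$variance,
                 tolerance = 1e-9)
    expect_identical(m2$round_index, 2L)
  }
})

test_that("an empty round changes only the round counter", {
  m1 <- train_offline(list(MAP = list(y_A = c(50, 55), y_NA = c(80, 85))))
  m2 <- update_online(m1, list(MAP = list(y_A = numeric(0),
                                          y_NA = numeric(0))))
  expect_identical(m2$round_index, 2L)
  m2$round_index <- m1$round_index
  expect_equal(m2, m1)
  expect_error(update_online(m1, list(HR = list(y_A = 1))), "not present")
})

test_that("the three-region rule is monotone with strict boundaries", {
  y_A <- c(50, 52, 54, 56); y_NA <- c(80, 82, 84, 86)
  m <- train_offline(list(MAP = list(y_A = y_A, y_NA = y_NA)))
  vm <- m$vitals$MAP
  L <- vm$summary_A$mean + vm$kappa_star * summary_sd(vm$summary_A)
  U <- vm$summary_NA$mean - vm$kappa_star * summary_sd(vm$summary_NA)
  for (z in seq(40, 100, by = 0.5)) {
    d <- classify_vital(vm, z)
    if (z < L) {
      expect_identical(d$region, "ahe_region")
      expect_identical(d$vote, "A")
      expect_true(is.na(d$d_A) && is.na(d$d_NA))
    } else if (z > U) {
      expect_identical(d$region, "non_ahe_region")
      expect_identical(d$vote, "NA")
    } else {
      expect_identical(d$region, "uncertainty")
      expect_false(is.na(d$d_A) || is.na(d$d_NA))
    }
  }
  # a value exactly on the lower bound takes the distance path
  expect_identical(classify_vital(vm, L)$region, "uncertainty")
  expect_error(classify_vital(vm, NaN), "finite")
})

test_that("uncertainty distances equal explicit sums over stored coordinates", {
  set.seed(55)
  for (i in 1:120) {
    y_A <- rnorm(sample(5:60, 1), 60, 6)
    y_NA <- rnorm(sample(5:60, 1), 75, 6)
    sA <- summary_update(class_summary(), y_A)
    sNA <- summary_update(class_summary(), y_NA)
    vm <- vital_model("MAP", sA, sNA, NA_real_,
                      degenerate_mode = "all_uncertainty",
                      coords_A = y_A, coords_NA = y_NA)
    z <- runif(1, 40, 95)
    d <- classify_vital(vm, z)
    expect_equal(d$d_A, sum((z - y_A)^2), tolerance = 1e-9)
    expect_equal(d$d_NA, sum((z - y_NA)^2), tolerance = 1e-9)
    expect_identical(d$vote, if (d$d_A > d$d_NA) "NA" else "A")
  }
})

test_that("distance ties and the count-free variant behave as documented", {
  sA <- summary_update(class_summary(), c(59, 61))
  sNA <- summary_update(class_summary(), c(79, 81))
  vm <- vital_model("MAP", sA, sNA, NA_real_,
                    degenerate_mode = "all_uncertainty",
                    coords_A = c(59, 61), coords_NA = c(79, 81))
  # z equidistant between symmetric classes: tie goes to A
  expect_identical(classify_vital(vm, 70)$vote, "A")
  # count-free variant drops the class-size factor
  sNA_big <- summary_update(class_summary(), rep(c(79, 81), 10))
  vm2 <- vital_model("MAP", sA, sNA_big, NA_real_,
                     degenerate_mode = "all_uncertainty",
                     coords_A = c(59, 61), coords_NA = rep(c(79, 81), 10))
  z <- 72  # nearer NA, but the sum form is inflated by n_NA = 20
  expect_identical(classify_vital(vm2, z, distance = "sum")$vote, "A")
  expect_identical(classify_vital(vm2, z, distance = "mean")$vote, "NA")
})

test_that("majority voting breaks exact ties with the MAP vote", {
  y_lo <- c(50, 52, 54); y_hi <- c(80, 82, 84)
  vitals <- list(MAP = train_offline(
    list(MAP = list(y_A = y_lo, y_NA = y_hi)))$vitals$MAP)
  for (v in c("HR", "PUL", "RR", "OSAT")) {
    vm <- vitals$MAP; vm$vital <- v
    vitals[[v]] <- vm
  }
  m <- dbc_model(vitals)
  # MAP votes A, HR votes NA: 1-1 tie resolved by MAP
  res <- classify_patient(m, c(MAP = 45, HR = 95))
  expect_identical(res$label, "A")
  # simple majority {A, A, NA, NA, NA}
  res <- classify_patient(m, c(MAP = 45, HR = 45, PUL = 95, RR = 95,
                               OSAT = 95))
  expect_identical(res$label, "NA")
  res <- classify_patient(m, c(MAP = 95, HR = 95, PUL = 95, RR = 95,
                               OSAT = 95))
  expect_identical(res$label, "NA")
  expect_error(classify_patient(m, c(HR = 45)), "MAP")
})

test_that("parameter recovery on well-separated Gaussian window means", {
  set.seed(321)
  y_A <- rnorm(120, 62, 4); y_NA <- rnorm(280, 84, 4)
  expect_gte((mean(y_NA) - mean(y_A)) / pooled_sd(y_A, y_NA), 3)
  m <- train_offline(list(MAP = list(y_A = y_A, y_NA = y_NA)))
  z_A <- rnorm(200, 62, 4); z_NA <- rnorm(200, 84, 4)
  pred_A <- vapply(z_A, function(z)
    classify_patient(m, c(MAP = z))$label, character(1))
  pred_NA <- vapply(z_NA, function(z)
    classify_patient(m, c(MAP = z))$label, character(1))
  expect_gte(mean(pred_A == "A"), 0.95)
  expect_gte(mean(pred_NA == "NA"), 0.95)
})

test_that("training cost grows linearly in the class sizes", {
  # sanity check on the complexity contract, not a hard timing test
  set.seed(9)
  sizes <- c(200L, 400L, 800L, 1600L)
  times <- vapply(sizes, function(n) {
    y_A <- rnorm(n, 60, 5); y_NA <- rnorm(n, 80, 5)
    system.time(for (i in 1:20) fit_kappa(y_A, y_NA))[["elapsed"]]
  }, numeric(1))
  fit <- stats::lm(times ~ sizes)
  # doubling n must not come close to quadrupling cost
  expect_lt(times[4] / max(times[2], 1e-3), 8)
  expect_true(is.finite(stats::coef(fit)[2]))
})
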