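test_that("metrics follow their confusion-count definitions", {
  m <- score(c("A", "A", "NA"), c("A", "A", "NA"))
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy), c(1, 1, 1))
  # all predicted NA on a mixed set
  m <- score(rep("NA", 4), c("A", "A", "NA", "NA"))
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
  # TP=3 FN=1 TN=4 FP=2
  pred <- c(rep("A", 3), "NA", rep("NA", 4), rep("A", 2))
  truth <- c(rep("A", 4), rep("NA", 6))
  m <- score(pred, truth)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$accuracy, 0.7)
  expect_identical(c(m$TP, m$FP, m$TN, m$FN), c(3L, 2L, 4L, 1L))
  expect_error(score(character(0), character(0)), "empty")
  expect_error(score("A", c("A", "NA")), "equal length")
})

test_that("cross-validation is deterministic and additive over folds", {
  coh <- separable_cohort(n = 60, seed = 10)
  cfg <- window_config(40, 10, 40)
  r1 <- run_offline_cv(coh, cfg, seed = 4)
  r2 <- run_offline_cv(coh, cfg, seed = 4)
  expect_identical(r1$decisions, r2$decisions)
  # a cohort separated by >= 5 SDs classifies perfectly
  expect_equal(r1$metrics$accuracy, 1)
  # pooled counts equal the sum of per-fold counts
  for (f in c("TP", "FP", "TN", "FN")) {
    expect_identical(r1$metrics[[f]],
                     sum(vapply(r1$fold_counts, `[[`, integer(1), f)))
  }
  expect_identical(nrow(r1$decisions), r1$n_used)
  expect_error(run_offline_cv(coh[1:6], cfg), "at least")
})

test_that("the initial online split reproduces the protocol arithmetic", {
  # cohort of 100 at a 26:65-style ratio: initial set of 20 with 6 A
  s <- plan_initial_split(29, 71, initial_fraction = 0.2,
                          class_ratio = 26 / 91)
  expect_identical(s$n_initial, 20L)
  expect_identical(s$initial_A, 6L)
  expect_identical(s$initial_NA, 14L)
  expect_identical(s$n_predict, 80L)
  expect_error(plan_initial_split(3, 97, initial_n_A = 10,
                                  initial_n_NA = 10), "unattainable")
})

test_that("online mode predicts before updating and tracks offline closely", {
  coh <- separable_cohort(n = 80, seed = 19)
  cfg <- window_config(40, 10, 40)
  on <- run_online(coh, cfg, seed = 6)
  expect_identical(nrow(on$decisions), on$split$n_predict)
  expect_identical(on$model$round_index, on$split$n_predict + 1L)
  off <- run_offline_cv(coh, cfg, seed = 6)
  expect_gte(on$metrics$accuracy, off$metrics$accuracy - 0.05)
  expect_gte(on$metrics$sensitivity, off$metrics$sensitivity - 0.05)
})

test_that("class summaries freeze when no arrivals of that class appear", {
  coh <- separable_cohort(n = 80, seed = 19)
  # drop class-A patients from the arrival stream by training on all of them
  man_lab <- vapply(coh, record_label, character(1))
  n_A <- sum(man_lab == "A")
  on <- run_online(coh, window_config(40, 10, 40), seed = 2,
                   initial_n_A = n_A, initial_n_NA = 2L)
  expect_true(all(on$decisions$truth == "NA"))
  first_A_n <- on$model$vitals$MAP$summary_A$n
  expect_identical(first_A_n, n_A)
  expect_identical(on$model$vitals$MAP$summary_NA$n,
                   2L + sum(man_lab == "NA") - 2L)
})

test_that("grid evaluation enumerates settings independently of order", {
  coh <- separable_cohort(n = 50, seed = 23)
  g1 <- run_grid(coh, O = c(20, 40), P = c(10, 30), T = 40, seed = 5)
  expect_identical(nrow(g1), 4L)
  expect_true(all(g1$sensitivity >= 0 & g1$sensitivity <= 1))
  g2 <- run_grid(coh, O = c(40, 20), P = c(30, 10), T = 40, seed = 5)
  key <- function(g) g[order(g$O, g$P, g$T),
                       c("O", "P", "T", "sensitivity", "specificity",
                         "accuracy")]
  expect_equal(key(as.data.frame(g1)), key(as.data.frame(g2)),
               ignore_attr = TRUE)
  # singleton grid, and the across-settings summary attribute
  gs <- run_grid(coh, O = 40, P = 10, T = 40, seed = 5)
  expect_identical(nrow(gs), 1L)
  smry <- attr(g1, "summary")
  expect_equal(smry$mean[smry$metric == "accuracy"], mean(g1$accuracy))
})

test_that("region rows partition the overall confusion counts", {
  coh <- prepare_cohort(generate_cohort(synth_config(150, seed = 61)))
  cv <- run_offline_cv(coh, window_config(40, 10, 40), seed = 7)
  rb <- region_breakdown(cv$decisions)
  reg <- rb[rb$region != "overall", ]
  ov <- rb[rb$region == "overall", ]
  for (f in c("TP", "FP", "TN", "FN", "n")) {
    expect_identical(sum(reg[[f]]), ov[[f]])
  }
  # a breakdown with every case in one region marks the others empty
  dec <- data.frame(truth = c("A", "NA"), pred = c("A", "NA"),
                    region = "uncertainty")
  rb2 <- region_breakdown(dec)
  expect_identical(rb2$n[rb2$region == "ahe_region"], 0L)
  expect_true(is.na(rb2$accuracy[rb2$region == "non_ahe_region"]))
  expect_equal(rb2$accuracy[rb2$region == "uncertainty"], 1)
})
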