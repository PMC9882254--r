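test_that("printed-parameter LCA respects the collapse window and t0", {
  d <- small_design(n_trials = 40, seed = 6)
  b <- simulate_lca(d, lca_params(), n_reps = 200, seed = 1)
  expect_true(all(b$decision_time <= 0.75 + 1e-12))
  expect_true(all(b$rt >= 0.25 + 1e-12))
  expect_true(all(b$choice %in% c("left", "right")))  # no missed trials
})

test_that("noiseless dominance always picks the stronger accumulator", {
  d <- compute_regressors(data.frame(subject_id = 1, trial_id = 1,
                                     left_max = 0.8, left_min = 0.6,
                                     right_max = 0.3, right_min = 0.1))
  b <- simulate_lca(d, lca_params(s = 0), n_reps = 100, seed = 2)
  expect_true(all(b$choice == "left"))
  expect_equal(length(unique(b$rt)), 1L)  # identical deterministic RT
})

test_that("noiseless ties are split by the randomised tie-break", {
  d <- compute_regressors(data.frame(subject_id = 1, trial_id = 1,
                                     left_max = 0.5, left_min = 0.3,
                                     right_max = 0.5, right_min = 0.3))
  b <- simulate_lca(d, lca_params(s = 0), n_reps = 2000, seed = 3)
  # both accumulators meet the bound at the same deterministic time;
  # the choice is split ~50/50 by the randomised tie-break
  expect_equal(length(unique(b$decision_time)), 1L)
  expect_lt(abs(mean(b$choice == "left") - 0.5), 4 * sqrt(0.25 / 2000))
})

test_that("LCA simulation is reproducible and validates parameters", {
  d <- small_design(n_trials = 5, seed = 8)
  b1 <- simulate_lca(d, n_reps = 10, seed = 9)
  b2 <- simulate_lca(d, n_reps = 10, seed = 9)
  expect_identical(b1, b2)
  expect_error(lca_params(step = 1), "invalid parameter")
  expect_error(lca_params(z0 = -1), "invalid parameter")
})

test_that("swapping bundles mirrors LCA choice proportions", {
  d <- small_design(n_trials = 30, seed = 10)
  swapped <- d
  swapped[, c("left_max", "left_min", "right_max", "right_min")] <-
    d[, c("right_max", "right_min", "left_max", "left_min")]
  swapped <- compute_regressors(swapped)
  b1 <- simulate_lca(d, n_reps = 400, seed = 12)
  b2 <- simulate_lca(swapped, n_reps = 400, seed = 13)
  p1 <- mean(b1$choice == "left")
  p2 <- mean(b2$choice == "right")
  expect_lt(abs(p1 - p2), 4 * sqrt(0.5 / (30 * 400)))
})

test_that("LCA behaviour shows the value-guided choice signature", {
  d <- generate_design(1, 160, seed = 14)
  b <- simulate_lca(d, n_reps = 200, seed = 15)
  s <- lca_behavior_summary(b, d)
  expect_gt(s$correlations["accuracy_absvd"], 0)
  expect_lt(s$correlations["rt_absvd"], 0)
  expect_lt(s$correlations["rt_ov"], 0)
  # mean RT non-increasing across weighted-OV bins
  expect_true(all(diff(s$by_ov$mean_rt) < 0.01))
})

test_that("shuffled choice labels destroy the accuracy correlation", {
  d <- generate_design(1, 160, seed = 16)
  b <- simulate_lca(d, n_reps = 50, seed = 17)
  b$choice <- with_seed(18, sample(b$choice))
  s <- lca_behavior_summary(b, d)
  expect_lt(abs(s$correlations["accuracy_absvd"]), 0.15)
})

test_that("deterministic dominance yields perfect accuracy in every bin", {
  d <- generate_design(1, 80, seed = 19)
  # drop exact weighted ties, where accuracy is undefined
  w <- 0.8 * d$left_max + 0.2 * d$left_min -
    (0.8 * d$right_max + 0.2 * d$right_min)
  d <- d[abs(w) > 1e-9, ]
  b <- simulate_lca(d, lca_params(s = 0), n_reps = 1, seed = 20)
  s <- lca_behavior_summary(b, d)
  expect_true(all(s$by_absvd$accuracy == 1))
})

test_that("empty behaviour is rejected", {
  d <- small_design(n_trials = 5, seed = 21)
  b <- simulate_lca(d, n_reps = 1, seed = 22)
  b$choice[] <- "missed"
  expect_error(lca_behavior_summary(b, d), "empty summary")
})
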