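test_that("regressors reproduce the worked bundle example", {
  # left bundle worth 0.90/0.70, right bundle 0.40/0.30 (euros)
  d <- compute_regressors(data.frame(left_max = 0.9, left_min = 0.7,
                                     right_max = 0.4, right_min = 0.3))
  expect_equal(d$signVD, 0.45)
  expect_equal(d$absVD, 0.45)
  expect_equal(d$maxVD, 0.5)
  expect_equal(d$minVD, 0.4)
  expect_equal(d$absMaxVD, 0.5)
  expect_equal(d$absMinVD, 0.4)
  expect_equal(d$maxOV, 1.3)
  expect_equal(d$minOV, 1.0)
})

test_that("regressors are symmetric/antisymmetric under left-right swap", {
  d <- small_design(n_trials = 60, seed = 3)
  swapped <- data.frame(
    left_max = d$right_max, left_min = d$right_min,
    right_max = d$left_max, right_min = d$left_min
  )
  ds <- compute_regressors(swapped)
  expect_equal(ds$signVD, -d$signVD)
  expect_equal(ds$maxVD, -d$maxVD)
  expect_equal(ds$minVD, -d$minVD)
  expect_equal(ds$absVD, d$absVD)
  expect_equal(ds$maxOV, d$maxOV)
  expect_equal(ds$minOV, d$minOV)
  # identical bundles: all differences vanish
  di <- compute_regressors(data.frame(left_max = 0.6, left_min = 0.2,
                                      right_max = 0.6, right_min = 0.2))
  expect_equal(di$signVD, 0)
  expect_equal(di$absVD, 0)
  expect_equal(di$maxVD, 0)
  expect_equal(di$minVD, 0)
})

test_that("generate_design respects size, grid, and determinism", {
  d <- generate_design(n_subjects = 2, n_trials = 160, seed = 1)
  expect_equal(nrow(d), 320)
  expect_equal(as.integer(table(d$subject_id)), c(160L, 160L))
  vals <- c(d$left_max, d$left_min, d$right_max, d$right_min)
  expect_true(all(vals %in% seq(0.1, 0.8, by = 0.1)))
  expect_true(all(d$left_max >= d$left_min))
  expect_true(all(d$right_max >= d$right_min))
  d2 <- generate_design(n_subjects = 2, n_trials = 160, seed = 1)
  expect_identical(d, d2)
  d3 <- generate_design(n_subjects = 2, n_trials = 160, seed = 2)
  expect_false(identical(d$left_max, d3$left_max))
})

test_that("generate_design rejects degenerate inputs", {
  expect_error(generate_design(n_trials = 0), "invalid design")
  expect_error(generate_design(value_grid = 0.5), "invalid design")
  expect_error(generate_design(value_grid = c(0.3, 0.1)), "invalid design")
})

test_that("equal-weight OV and absVD are near-orthogonal at any seed", {
  for (seed in c(1, 7, 19, 101, 2024)) {
    d <- generate_design(n_subjects = 1, n_trials = 160, seed = seed)
    ov <- d$left_max + d$left_min + d$right_max + d$right_min
    expect_lt(abs(cor(ov, d$absVD)), 0.1)
  }
})

test_that("unequal weighting re-correlates overall value and difference", {
  d <- generate_design(n_subjects = 1, n_trials = 160, seed = 5)
  r_eq <- design_correlations(d, c(0.5, 0.5))$r
  r_uneq <- design_correlations(d, c(0.8, 0.2))$r
  expect_lt(abs(r_eq), 0.1)
  expect_gt(abs(r_uneq), abs(r_eq))
})

test_that("design_correlations validates input", {
  d <- generate_design(seed = 1)
  expect_error(design_correlations(d, c(0.9, 0.2)), "summing to 1")
  expect_error(design_correlations(d[1, ], c(0.5, 0.5)),
               "undefined correlation")
})

test_that("design CSV round trip preserves values", {
  d <- generate_design(n_subjects = 1, n_trials = 20, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(d2$left_max, d$left_max)
  expect_equal(d2$signVD, d$signVD)
  unlink(path)
})
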