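test_that("the registry reproduces every model's regression formulas", {
  expected <- list(
    "Original" = c(v = "v ~ [hard, easy]", a = "a ~ [hard, easy]",
                   z = "z ~ [hard, easy]"),
    "Original*" = c(v = "v ~ -1 + signVD", a = "a ~ 1 + absVD"),
    "VD" = c(v = "v ~ -1 + maxVD + minVD",
             a = "a ~ 1 + absMaxVD + absMinVD"),
    "OV" = c(v = "v ~ -1 + maxVD + minVD", a = "a ~ 1 + maxOV + minOV"),
    "VDOV" = c(v = "v ~ -1 + maxVD + minVD",
               a = "a ~ 1 + absMaxVD + absMinVD + maxOV + minOV"),
    "VD both" = c(v = "v ~ -1 + maxVD + minVD",
                  a = "a ~ 1 + absMaxVD + absMinVD",
                  theta = "theta ~ 1 + absMaxVD + absMinVD"),
    "VD init" = c(v = "v ~ -1 + maxVD + minVD",
                  a = "a ~ 1 + absMaxVD + absMinVD"),
    "VD rate" = c(v = "v ~ -1 + maxVD + minVD",
                  theta = "theta ~ 1 + absMaxVD + absMinVD"),
    "OV both" = c(v = "v ~ -1 + maxVD + minVD", a = "a ~ 1 + maxOV + minOV",
                  theta = "theta ~ 1 + maxOV + minOV"),
    "OV init" = c(v = "v ~ -1 + maxVD + minVD", a = "a ~ 1 + maxOV + minOV"),
    "OV rate" = c(v = "v ~ -1 + maxVD + minVD",
                  theta = "theta ~ 1 + maxOV + minOV"),
    "VDOV both" = c(v = "v ~ -1 + maxVD + minVD",
                    a = "a ~ 1 + absMaxVD + absMinVD + maxOV + minOV",
                    theta = "theta ~ 1 + absMaxVD + absMinVD + maxOV + minOV"),
    "VDOV init" = c(v = "v ~ -1 + maxVD + minVD",
                    a = "a ~ 1 + absMaxVD + absMinVD + maxOV + minOV"),
    "VDOV rate" = c(v = "v ~ -1 + maxVD + minVD",
                    theta = "theta ~ 1 + absMaxVD + absMinVD + maxOV + minOV")
  )
  for (nm in names(expected)) {
    spec <- build_model_spec(nm)
    expect_identical(spec$formulas, expected[[nm]], info = nm)
  }
  expect_equal(nrow(list_models()), 14)
  # static vs collapsing bound types
  expect_identical(build_model_spec("VDOV")$bound, "static")
  expect_identical(build_model_spec("VD rate")$bound, "angle")
  expect_identical(build_model_spec("VD rate")$a$terms, character(0))
  expect_identical(build_model_spec("VD init")$theta, "free")
})

test_that("unknown model names raise a lookup error listing valid names", {
  expect_error(build_model_spec("bogus"), "unknown model")
  expect_error(build_model_spec("bogus"), "VDOV both")
})

test_that("name normalisation accepts separators and case variants", {
  expect_identical(build_model_spec("vdov_both")$name, "VDOV both")
  expect_identical(build_model_spec("VD-rate")$name, "VD rate")
})

test_that("parameter links behave as documented", {
  d <- small_design(n_trials = 20, seed = 30)
  sp <- build_model_spec("VDOV")
  zero <- setNames(rep(0, 7), c("v_maxVD", "v_minVD", "a_Intercept",
                                "a_absMaxVD", "a_absMinVD", "a_maxOV",
                                "a_minOV"))
  pars <- map_parameters(sp, d, c(zero, z_rel = 0.5, p_outlier = 0,
                                  t0 = 0.25))
  expect_true(all(pars$v == 0))
  expect_true(all(pars$a == 1))   # exp(0)
  expect_true(all(pars$theta == 0))

  # linearity of the drift map (Original*: v = beta * signVD)
  sp2 <- build_model_spec("Original*")
  co <- c(v_signVD = 2, a_Intercept = 0, a_absVD = 0, z_rel = 0.5,
          p_outlier = 0, t0 = 0.25)
  pars2 <- map_parameters(sp2, d, co)
  expect_equal(pars2$v, 2 * d$signVD)
  one_trial <- compute_regressors(data.frame(left_max = 0.9, left_min = 0.7,
                                             right_max = 0.4,
                                             right_min = 0.3))
  expect_equal(map_parameters(sp2, one_trial, co)$v, 2 * 0.45)

  # threshold is monotone in a regressor iff its coefficient is positive
  grid <- compute_regressors(data.frame(left_max = seq(0.2, 0.8, 0.1),
                                        left_min = 0.1, right_max = 0.1,
                                        right_min = 0.1))
  co_pos <- c(v_maxVD = 0, v_minVD = 0, a_Intercept = 0, a_absMaxVD = 0.5,
              a_absMinVD = 0, a_maxOV = 0, a_minOV = 0, z_rel = 0.5,
              p_outlier = 0, t0 = 0.25)
  a_pos <- map_parameters(sp, grid, co_pos)$a
  expect_true(all(diff(a_pos) > 0))
  co_neg <- co_pos
  co_neg["a_absMaxVD"] <- -0.5
  a_neg <- map_parameters(sp, grid, co_neg)$a
  expect_true(all(diff(a_neg) < 0))
  expect_true(all(a_pos > 0) && all(a_neg > 0))  # log link: structural > 0
})

test_that("missing coefficients raise a configuration error", {
  d <- small_design(n_trials = 5, seed = 31)
  sp <- build_model_spec("Original*")
  expect_error(map_parameters(sp, d, c(v_signVD = 1)),
               "missing coefficient")
})

test_that("drawn coefficient sets map to valid parameters for every model", {
  d <- small_design(n_trials = 20, seed = 32)
  for (nm in list_models()$name) {
    co <- draw_coefficients(nm, n_subjects = 3, seed = 33)
    dd <- if (build_model_spec(nm)$coding == "accuracy") {
      accumimic:::add_difficulty_split(d[d$absVD > 0, ])
    } else d
    pars <- map_parameters(co$spec, dd, co, subject = 2)
    expect_true(all(pars$a > 0), info = nm)
    expect_true(all(pars$theta >= 0 & pars$theta < pi / 2), info = nm)
    expect_true(all(pars$z_rel > 0 & pars$z_rel < 1), info = nm)
    expect_true(all(pars$p_outlier >= 0 & pars$p_outlier <= 1), info = nm)
    expect_true(all(pars$t0 > 0), info = nm)
  }
})
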