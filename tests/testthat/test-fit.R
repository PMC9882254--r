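test_that("R-hat matches its defining cases", {
  # identical chains: exactly 1
  ch <- cbind(rnorm(200), 0)
  ch[, 2] <- ch[, 1]
  expect_identical(compute_rhat(ch), 1)
  # well-separated chains: far above the 1.1 convergence bound
  ch2 <- cbind(rnorm(500, 0, 1), rnorm(500, 10, 1))
  expect_gt(compute_rhat(ch2), 5)
  # long chains from one distribution: within 0.01 of 1
  ch3 <- with_seed(5, matrix(rnorm(4000 * 4), ncol = 4))
  expect_lt(compute_rhat(ch3), 1.01)
  expect_error(compute_rhat(list(rnorm(10), rnorm(9))), "equal lengths")
  expect_error(compute_rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
})

test_that("DIC arithmetic matches hand computation", {
  # constant trace: no effective parameters, DIC = -2c
  d0 <- dic_from_trace(rep(-50, 20), -50, 100)
  expect_equal(d0$pd, 0)
  expect_equal(d0$dic, 100)
  # 3-sample trace, hand arithmetic: Dbar = -2*mean(ll), Dhat = -2*ll_hat
  ll <- c(-10, -12, -11)
  d1 <- dic_from_trace(ll, -10.5, 10)
  expect_equal(d1$dbar, 22)
  expect_equal(d1$dhat, 21)
  expect_equal(d1$pd, 1)
  expect_equal(d1$dic, 23)
  expect_equal(d1$trial_avg_deviance, 2.2)
})

test_that("posterior tail probabilities count draws below the threshold", {
  # synthetic two-chain fit object
  fake <- structure(list(
    param_table = data.frame(name = c("a_absVD", "a_maxOV"),
                             block = c("a", "a")),
    chains = list(
      list(mu = cbind(mu_a_absVD = c(-1, -1), mu_a_maxOV = c(1, 1)),
           sigma = cbind(sigma_a_absVD = c(1, 1),
                         sigma_a_maxOV = c(1, 1))),
      list(mu = cbind(mu_a_absVD = c(1, 1), mu_a_maxOV = c(1, 1)),
           sigma = cbind(sigma_a_absVD = c(1, 1),
                         sigma_a_maxOV = c(1, 1)))
    )), class = "acc_fit")
  expect_equal(posterior_tail_prob(fake, "a_absVD"), 0.5)
  expect_equal(posterior_tail_prob(fake, "a_maxOV"), 0)
  expect_equal(posterior_tail_prob(fake, "a_maxOV", threshold = 2), 1)
  # standard-normal draws: half below zero up to binomial error
  n <- 4000
  fake$chains[[1]]$mu <- cbind(mu_a_absVD = with_seed(6, rnorm(n)),
                               mu_a_maxOV = rep(0, n))
  fake$chains[[2]]$mu <- cbind(mu_a_absVD = with_seed(7, rnorm(n)),
                               mu_a_maxOV = rep(0, n))
  expect_lt(abs(posterior_tail_prob(fake, "a_absVD") - 0.5),
            4 * sqrt(0.25 / (2 * n)))
  expect_error(posterior_tail_prob(fake, "nope"), "unknown parameter")
})

test_that("sampler settings are validated", {
  expect_error(mcmc_settings(n_chains = 1), "settings error")
  expect_error(mcmc_settings(n_samples = 100, n_burn = 100),
               "settings error")
})

test_that("the fit's internal likelihood equals summed trial log densities", {
  d <- small_design(n_trials = 30, seed = 40)
  co <- draw_coefficients("Original*", 1, seed = 41)
  b <- simulate_from_coefs(co, d, seed = 42)
  spec <- build_model_spec("Original*")
  fd <- accumimic:::prepare_fit_data(b, d, spec, deadline = 0.75)
  pt <- fd$pt
  par <- co$subject[1, ]
  internal <- accumimic:::subject_loglik(par, fd$data[[1]], spec, pt, 0.75)
  nat <- accumimic:::natural_from_sampler(par, pt, spec)
  md <- merge(as.data.frame(b), as.data.frame(d),
              by = c("subject_id", "trial_id"))
  pars <- map_parameters(spec, md, nat)
  obs <- md$choice != "missed"
  external <- sum(trial_loglik(md$rt[obs], md$choice[obs], pars[obs, ],
                               deadline = 0.75))
  expect_equal(internal, external, tolerance = 1e-10)
})

test_that("hierarchical fits are deterministic and recover group structure", {
  d <- generate_design(4, 120, seed = 50)
  co <- draw_coefficients("Original*", 4, seed = 51)
  b <- simulate_from_coefs(co, d, seed = 52)
  st <- mcmc_settings(n_chains = 2, n_samples = 260, n_burn = 120,
                      seed = 53)
  f1 <- suppressWarnings(fit_model(b, d, "Original*", st))
  f2 <- suppressWarnings(fit_model(b, d, "Original*", st))
  expect_identical(f1$group_mean, f2$group_mean)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(compute_dic(f1)$dic, compute_dic(f2)$dic)
  # drift coefficient is strongly identified even in a short run
  expect_gt(f1$group_mean["v_signVD"], 2)
  expect_true(all(c("mu_v_signVD", "sigma_v_signVD") %in% names(f1$rhat)))
  # starting-point draws stay on the sane side
  expect_gt(cor(co$subject[, "v_signVD"], f1$beta_mean[, "v_signVD"]), 0.5)
})

test_that("degenerate fitting inputs are rejected", {
  d <- small_design(n_trials = 10, seed = 60)
  co <- draw_coefficients("Original*", 1, seed = 61)
  b <- simulate_from_coefs(co, d, seed = 62)
  expect_error(
    suppressWarnings(fit_model(b, d, "Original*",
                               mcmc_settings(n_samples = 60, n_burn = 20))),
    ">= 2 subjects")
  expect_error(
    suppressWarnings(fit_model(b[0, ], d, "Original*",
                               mcmc_settings(n_samples = 60, n_burn = 20))),
    "empty behavior")
})
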