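test_that("analytic first-passage density integrates to choice probabilities", {
  tg <- seq(5e-5, 10, by = 1e-4)
  for (ps in list(c(v = 1, a = 1.5, z = 0.5), c(v = -0.8, a = 1, z = 0.35),
                  c(v = 0, a = 1.2, z = 0.5))) {
    fu <- accumimic:::.wfpt_pdf_cpp(tg, ps["v"], ps["a"], ps["z"], TRUE)
    fl <- accumimic:::.wfpt_pdf_cpp(tg, ps["v"], ps["a"], ps["z"], FALSE)
    expect_equal(sum(fu + fl) * 1e-4, 1, tolerance = 1e-3)
    expect_equal(sum(fu) * 1e-4,
                 p_upper_closed(ps["v"], ps["a"], ps["z"]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
  # v = 0, central start: both boundaries get mass 1/2
  fu <- accumimic:::.wfpt_pdf_cpp(tg, 0, 1.5, 0.5, TRUE)
  expect_equal(sum(fu) * 1e-4, 0.5, tolerance = 1e-3)
})

test_that("mirror symmetry: negating drift and reflecting start swaps sides", {
  tg <- seq(0.01, 3, by = 0.01)
  fu <- accumimic:::.wfpt_pdf_cpp(tg, 1.2, 1.4, 0.4, TRUE)
  fl_m <- accumimic:::.wfpt_pdf_cpp(tg, -1.2, 1.4, 0.6, FALSE)
  expect_equal(fu, fl_m, tolerance = 1e-10)
  su <- fpt_solve_angle(ddm_params(v = 0.8, a = 1.2, z_rel = 0.4,
                                   theta = 0.25), deadline = 0.8)
  sm <- fpt_solve_angle(ddm_params(v = -0.8, a = 1.2, z_rel = 0.6,
                                   theta = 0.25), deadline = 0.8)
  expect_equal(su$f_upper, sm$f_lower, tolerance = 1e-6)
  expect_equal(su$f_lower, sm$f_upper, tolerance = 1e-6)
})

test_that("angle solver reduces to the analytic static density", {
  s <- fpt_solve_angle(ddm_params(v = 1, a = 1.5, theta = 0), deadline = 3)
  fu <- accumimic:::.wfpt_pdf_cpp(s$t, 1, 1.5, 0.5, TRUE)
  fl <- accumimic:::.wfpt_pdf_cpp(s$t, 1, 1.5, 0.5, FALSE)
  expect_lt(max(abs(s$f_upper - fu)), 1e-3)
  expect_lt(max(abs(s$f_lower - fl)), 1e-3)
})

test_that("angle solver conserves probability mass", {
  for (ps in list(c(1, 1.5, 0.5, 0.3), c(2, 1, 0.6, 0.6),
                  c(-0.5, 0.8, 0.4, 0.9), c(0, 2, 0.5, 0.45))) {
    s <- fpt_solve_angle(ddm_params(v = ps[1], a = ps[2], z_rel = ps[3],
                                    theta = ps[4]), deadline = 0.75)
    mass <- sum(s$f_upper + s$f_lower) * s$dt + s$survival
    expect_equal(mass, 1, tolerance = 1e-3)
  }
})

test_that("angle solver enforces its resolution precondition", {
  expect_error(
    fpt_solve_angle(ddm_params(v = 1, a = 0.2, theta = 1.2),
                    deadline = 0.75, grid_dt = 0.002),
    "resolution"
  )
})

test_that("simulated absorption matches the closed form (static bounds)", {
  d <- data.frame(subject_id = 1, trial_id = 1)
  sets <- list(c(1, 1.5, 0.5), c(0.5, 1, 0.3), c(2, 2, 0.6),
               c(-1, 1.2, 0.5))
  for (ps in sets) {
    b <- simulate_ddm(d, ddm_params(v = ps[1], a = ps[2], z_rel = ps[3]),
                      n_reps = 40000, dt = 0.001, deadline = 20,
                      seed = 101)
    p_hat <- mean(b$choice == "left")
    p_true <- p_upper_closed(ps[1], ps[2], ps[3])
    se <- sqrt(p_true * (1 - p_true) / 40000)
    expect_lt(abs(p_hat - p_true), 4 * se)
  }
})

test_that("zero drift with central start splits choices evenly", {
  d <- data.frame(subject_id = 1, trial_id = 1)
  b <- simulate_ddm(d, ddm_params(v = 0, a = 1.2), n_reps = 20000,
                    deadline = 20, seed = 7)
  expect_lt(abs(mean(b$choice == "left") - 0.5), 4 * sqrt(0.25 / 20000))
})

test_that("collapsing bounds confine decision times to the collision time", {
  p <- ddm_params(v = 0.3, a = 1.5, theta = 0.9)
  t_star <- (p$a / 2) / tan(p$theta)
  d <- data.frame(subject_id = 1, trial_id = 1)
  b <- simulate_ddm(d, p, n_reps = 5000, deadline = 5, seed = 3)
  dec <- b$rt[b$choice != "missed"] - p$t0
  expect_true(all(dec <= t_star + 1e-9))
})

test_that("simulation is reproducible given a seed", {
  d <- small_design(n_trials = 10, seed = 2)
  p <- ddm_params(v = 1, a = 1, p_outlier = 0.1)
  b1 <- simulate_ddm(d, p, n_reps = 5, seed = 42)
  b2 <- simulate_ddm(d, p, n_reps = 5, seed = 42)
  expect_identical(b1, b2)
})

test_that("trial_loglik dispatches exactly to the static density at theta=0", {
  p <- ddm_params(v = 1.1, a = 1.3, z_rel = 0.45, t0 = 0.2,
                  p_outlier = 0.04)
  rt <- seq(0.25, 0.7, by = 0.05)
  ch <- rep(c("left", "right"), length.out = length(rt))
  expect_identical(trial_loglik(rt, ch, p), wfpt_loglik_static(rt, ch, p))
})

test_that("pure-lapse limit returns the uniform lapse density", {
  p <- ddm_params(v = 1, a = 1, p_outlier = 1)
  ll <- trial_loglik(c(0.3, 0.5, 0.74), c("left", "right", "left"), p,
                     deadline = 0.75)
  expect_equal(ll, rep(log(0.5 / 0.75), 3))
})

test_that("responses at or below t0 fall back to the lapse density", {
  p <- ddm_params(v = 1, a = 1, t0 = 0.25, p_outlier = 0.1)
  ll <- wfpt_loglik_static(0.2, "left", p, deadline = 0.75)
  expect_equal(ll, log(0.1 * 0.5 / 0.75))
})

test_that("collapse rate orders the density of fast correct responses", {
  # simulation oracle (2e5 replicates, v = 1.5, a = 1.5, t0 = 0.25,
  # rt = 0.35): binned densities 1.52, 1.77, 2.19, 2.92 across
  # theta = 0.05, 0.3, 0.6, 0.9 -- a fast correct response becomes
  # monotonically MORE likely as the bound collapses faster, because less
  # evidence is required at the already-lowered bound.  The solver must
  # reproduce that ordering.
  thetas <- c(0.05, 0.3, 0.6, 0.9)
  dens_fast <- vapply(thetas, function(th) {
    exp(trial_loglik(0.35, "left",
                     ddm_params(v = 1.5, a = 1.5, t0 = 0.25, theta = th),
                     deadline = 0.8, method = "exact"))
  }, 0)
  expect_true(all(diff(dens_fast) > 0))
  expect_equal(dens_fast, c(1.52, 1.77, 2.19, 2.92), tolerance = 0.1)
})

test_that("angle solver choice fractions match simulation", {
  p <- ddm_params(v = 1, a = 1.5, theta = 0.3, t0 = 0)
  s <- fpt_solve_angle(p, deadline = 0.75)
  n <- 2e5
  b <- simulate_ddm(data.frame(subject_id = 1, trial_id = 1), p,
                    n_reps = n, dt = 0.001, deadline = 0.75, seed = 11)
  p_up_sol <- sum(s$f_upper) * s$dt
  p_up_sim <- mean(b$choice == "left")
  se <- sqrt(p_up_sol * (1 - p_up_sol) / n)
  expect_lt(abs(p_up_sim - p_up_sol), 3.5 * se)
  expect_lt(abs(mean(b$choice == "missed") - s$survival),
            3.5 * sqrt(s$survival * (1 - s$survival) / n) + 0.002)
})

test_that("behaviour CSV round trip preserves choices, RTs and deadline", {
  d <- small_design(n_trials = 12, seed = 4)
  b <- simulate_ddm(d, ddm_params(v = 0.5, a = 1.4), n_reps = 1,
                    deadline = 0.75, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_behavior(b, path)
  b2 <- read_behavior(path)
  expect_equal(b2$choice, b$choice)
  expect_equal(b2$rt, b$rt, tolerance = 1e-6)
  expect_equal(attr(b2, "deadline"), 0.75)
  unlink(c(path, paste0(path, ".yaml")))
})

test_that("invalid parameters are rejected", {
  expect_error(ddm_params(v = 1, a = -1), "invalid parameter")
  expect_error(ddm_params(v = Inf, a = 1), "invalid parameter")
  expect_error(ddm_params(v = 1, a = 1, z_rel = 1.2), "invalid parameter")
  expect_error(ddm_params(v = 1, a = 1, theta = 2), "invalid parameter")
  d <- data.frame(subject_id = 1, trial_id = 1)
  expect_error(simulate_ddm(d, data.frame(v = NaN, a = 1), seed = 1),
               "invalid parameter")
})
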