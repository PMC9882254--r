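#' MCMC sampler settings
#'
#' @param n_chains Number of chains (>= 2, required for the Gelman-Rubin
#'   diagnostic).
#' @param n_samples Total iterations per chain (including burn-in).
#' @param n_burn Burn-in iterations discarded from each chain (proposal
#'   scales adapt only during burn-in).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param init_jitter SD of the random initialisation jitter.
#' @return List of class `acc_mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_samples = 2000, n_burn = 500,
                          seed = 1, init_jitter = 0.1) {
  if (n_chains < 2) {
    stop("settings error: at least 2 chains are required (R-hat is ",
         "undefined for a single chain)", call. = FALSE)
  }
  if (n_burn >= n_samples) {
    stop("settings error: `n_burn` must be smaller than `n_samples`",
         call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 n_burn = as.integer(n_burn), seed = as.integer(seed),
                 init_jitter = init_jitter),
            class = "acc_mcmc_settings")
}

# per-subject fitting data: response vectors and block design matrices
prepare_fit_data <- function(behavior, design, spec, deadline,
                             censor_missed = FALSE) {
  design <- as.data.frame(design)
  if (!"absVD" %in% names(design)) design <- compute_regressors(design)
  if (spec$coding == "accuracy") {
    design <- add_difficulty_split(design[design$absVD > 0, ])
  }
  dat <- merge(as.data.frame(behavior), design,
               by = c("subject_id", "trial_id"))
  if (nrow(dat) == 0) stop("empty behavior table", call. = FALSE)
  subjects <- sort(unique(dat$subject_id))
  pt <- param_table(spec)
  out <- lapply(subjects, function(s) {
    d <- dat[dat$subject_id == s, ]
    obs <- d[d$choice %in% c("left", "right"), ]
    n_missed <- sum(d$choice == "missed")
    if (spec$coding == "accuracy") {
      y <- as.integer((obs$choice == "left") == (obs$signVD > 0))
    } else {
      y <- as.integer(obs$choice == "left")
    }
    list(
      subject = s,
      rt = obs$rt, y = y, n_missed = n_missed,
      X_v = block_matrix(spec$v, obs, "v"),
      X_a = block_matrix(spec$a, obs, "a"),
      X_theta = if (is.list(spec$theta)) block_matrix(spec$theta, obs,
                                                      "theta") else NULL,
      X_z = if (is.list(spec$z)) block_matrix(spec$z, obs, "z") else NULL,
      X_missed_v = if (censor_missed && n_missed > 0)
        block_matrix(spec$v, d[d$choice == "missed", ], "v") else NULL,
      missed_rows = if (censor_missed && n_missed > 0)
        d[d$choice == "missed", ] else NULL
    )
  })
  list(subjects = subjects, data = out, pt = pt, deadline = deadline,
       n_trials = sum(vapply(out, function(d) length(d$rt), 0L)))
}

# log-likelihood of one subject's data at sampler-scale parameters
subject_loglik <- function(par, sd_data, spec, pt, deadline,
                           use_cache = TRUE, censor_missed = FALSE) {
  names(par) <- pt$name
  v <- as.vector(sd_data$X_v %*% par[colnames(sd_data$X_v)])
  a <- exp(as.vector(sd_data$X_a %*% par[colnames(sd_data$X_a)]))
  n <- length(sd_data$rt)
  theta <- if (!is.null(sd_data$X_theta)) {
    pmin(softplus(as.vector(sd_data$X_theta %*%
                              par[colnames(sd_data$X_theta)])), THETA_CAP)
  } else if (identical(spec$theta, "free")) {
    rep(pmin(softplus(par[["theta"]]), THETA_CAP), n)
  } else {
    rep(0, n)
  }
  z <- if (!is.null(sd_data$X_z)) {
    as.vector(sd_data$X_z %*% plogis(par[colnames(sd_data$X_z)]))
  } else {
    rep(plogis(par[["z"]]), n)
  }
  p_out <- if ("p_outlier" %in% pt$name) plogis(par[["p_outlier"]]) else 0
  t0 <- T0_MAX * plogis(par[["t0"]])
  ll <- .ddm_loglik_cpp(sd_data$rt, sd_data$y, v, a, theta, z, t0, p_out,
                        deadline, use_cache)
  if (censor_missed && sd_data$n_missed > 0) {
    md <- sd_data$missed_rows
    vm <- as.vector(sd_data$X_missed_v %*% par[colnames(sd_data$X_missed_v)])
    am <- exp(as.vector(block_matrix(spec$a, md, "a") %*%
                          par[colnames(sd_data$X_a)]))
    thm <- if (is.list(spec$theta)) {
      pmin(softplus(as.vector(block_matrix(spec$theta, md, "theta") %*%
                                par[colnames(sd_data$X_theta)])), THETA_CAP)
    } else if (identical(spec$theta, "free")) {
      rep(pmin(softplus(par[["theta"]]), THETA_CAP), nrow(md))
    } else rep(0, nrow(md))
    zm <- rep(if (is.null(sd_data$X_z)) plogis(par[["z"]]) else 0.5, nrow(md))
    surv <- .ddm_survival_cpp(vm, am, thm, zm, t0, deadline)
    ll <- ll + sum(log(pmax((1 - p_out) * surv, 1e-300)))
  }
  ll
}

#' Fit a model hierarchically by MCMC
#'
#' Hierarchical Bayesian estimation: each subject-level parameter (sampler
#' scale) is drawn from an independent normal group-level distribution,
#' `beta_s ~ Normal(mu, sigma)`, with weakly-informative priors
#' `mu ~ Normal(0, 5)` and `sigma ~ half-Normal(2)`.  Sampling uses adaptive
#' blockwise random-walk Metropolis on the subject parameters (blocks: drift
#' coefficients, threshold coefficients, collapse coefficients, and
#' bias/lapse/non-decision), a conjugate Gibbs update for `mu`, and a
#' random-walk update for `log(sigma)`; proposal scales adapt during burn-in
#' only.  The likelihood is the product of [trial_loglik()] over non-missed
#' trials (missed trials can contribute their survival mass via
#' `censor_missed = TRUE`).  Runs are deterministic given the settings seed.
#'
#' @param behavior Behaviour rows (subject_id, trial_id, choice, rt).
#' @param design Matching design table.
#' @param spec Model specification or name.
#' @param settings [mcmc_settings()].
#' @param deadline Response deadline (s) on the RT clock.
#' @param censor_missed Add the log survival mass of missed trials.
#' @param use_cache Use the cached-lattice collapsing-bound likelihood
#'   (recommended; `FALSE` solves exactly per evaluation and is very slow).
#' @return An object of class `acc_fit`; see [compute_dic()],
#'   [posterior_tail_prob()], [posterior_predictive()].
#' @export
fit_model <- function(behavior, design, spec, settings = mcmc_settings(),
                      deadline = 0.75, censor_missed = FALSE,
                      use_cache = TRUE) {
  if (is.character(spec)) spec <- build_model_spec(spec)
  stopifnot(inherits(spec, "acc_model_spec"),
            inherits(settings, "acc_mcmc_settings"))
  fd <- prepare_fit_data(behavior, design, spec, deadline, censor_missed)
  S <- length(fd$subjects)
  if (S < 2) stop("need >= 2 subjects for the hierarchy", call. = FALSE)
  pt <- fd$pt
  P <- nrow(pt)
  blocks <- split(seq_len(P), pt$block)
  n_post <- settings$n_samples - settings$n_burn

  # prior hyperparameters
  mu0 <- 0; tau0 <- 5; sigma_hn <- 2

  init_mean <- vapply(pt$name, function(nm) {
    switch(nm, p_outlier = -2.5, t0 = 0, 0)
  }, 0)
  # proposal base scales per parameter (block factors adapt multiplicatively)
  base_scale <- vapply(seq_len(P), function(j) {
    switch(pt$block[j], v = 0.25, a = 0.08, theta = 0.10,
           z = 0.12, lapse = if (pt$name[j] == "t0") 0.08 else 0.30, 0.15)
  }, 0)

  run_chain <- function(chain) {
    with_seed(settings$seed + chain, {
      beta <- matrix(rep(init_mean, each = S), nrow = S) +
        matrix(rnorm(S * P, 0, settings$init_jitter), nrow = S)
      mu <- init_mean + rnorm(P, 0, settings$init_jitter)
      sigma <- rep(0.5, P)
      ll <- vapply(seq_len(S), function(s) {
        subject_loglik(beta[s, ], fd$data[[s]], spec, pt, deadline,
                       use_cache, censor_missed)
      }, 0)
      prop <- matrix(1, nrow = S, ncol = length(blocks))
      prop_sig <- rep(0.25, P)
      acc <- matrix(0, nrow = S, ncol = length(blocks))
      tries <- 0

      keep_mu <- matrix(NA_real_, n_post, P)
      keep_sigma <- matrix(NA_real_, n_post, P)
      keep_beta <- array(NA_real_, c(n_post, S, P))
      keep_ll <- numeric(n_post)

      for (it in seq_len(settings$n_samples)) {
        for (s in seq_len(S)) {
          for (bi in seq_along(blocks)) {
            idx <- blocks[[bi]]
            cand <- beta[s, ]
            cand[idx] <- cand[idx] +
              rnorm(length(idx), 0, base_scale[idx] * prop[s, bi])
            ll_new <- subject_loglik(cand, fd$data[[s]], spec, pt, deadline,
                                     use_cache, censor_missed)
            lpr <- sum(dnorm(cand[idx], mu[idx], sigma[idx], log = TRUE)) -
              sum(dnorm(beta[s, idx], mu[idx], sigma[idx], log = TRUE))
            if (is.finite(ll_new) &&
                log(runif(1)) < ll_new - ll[s] + lpr) {
              beta[s, ] <- cand
              ll[s] <- ll_new
              acc[s, bi] <- acc[s, bi] + 1
            }
          }
        }
        tries <- tries + 1
        # group mean: conjugate normal update
        for (j in seq_len(P)) {
          prec <- S / sigma[j]^2 + 1 / tau0^2
          m <- (sum(beta[, j]) / sigma[j]^2 + mu0 / tau0^2) / prec
          mu[j] <- rnorm(1, m, sqrt(1 / prec))
          # group sd: random walk on log sigma, half-Normal(2) prior
          cand_s <- sigma[j] * exp(rnorm(1, 0, prop_sig[j]))
          lr <- sum(dnorm(beta[, j], mu[j], cand_s, log = TRUE)) -
            sum(dnorm(beta[, j], mu[j], sigma[j], log = TRUE)) -
            (cand_s^2 - sigma[j]^2) / (2 * sigma_hn^2) +
            log(cand_s) - log(sigma[j])  # Jacobian of the log walk
          if (is.finite(lr) && log(runif(1)) < lr) sigma[j] <- cand_s
        }
        # adapt proposal scales during burn-in
        if (it <= settings$n_burn && it %% 25 == 0) {
          rate <- acc / tries
          prop <- pmin(pmax(prop * exp(rate - 0.3), 0.05), 10)
          acc[] <- 0
          tries <- 0
        }
        if (it > settings$n_burn) {
          k <- it - settings$n_burn
          keep_mu[k, ] <- mu
          keep_sigma[k, ] <- sigma
          keep_beta[k, , ] <- beta
          keep_ll[k] <- sum(ll)
        }
      }
      colnames(keep_mu) <- paste0("mu_", pt$name)
      colnames(keep_sigma) <- paste0("sigma_", pt$name)
      list(mu = keep_mu, sigma = keep_sigma, beta = keep_beta, ll = keep_ll)
    })
  }

  chains <- lapply(seq_len(settings$n_chains), run_chain)

  # convergence: R-hat for group-level and subject-level parameters
  rhat <- c(
    vapply(seq_len(P), function(j) {
      compute_rhat(sapply(chains, function(ch) ch$mu[, j]))
    }, 0),
    vapply(seq_len(P), function(j) {
      compute_rhat(sapply(chains, function(ch) ch$sigma[, j]))
    }, 0)
  )
  names(rhat) <- c(paste0("mu_", pt$name), paste0("sigma_", pt$name))
  rhat_subject <- matrix(NA_real_, S, P,
                         dimnames = list(NULL, pt$name))
  for (s in seq_len(S)) {
    for (j in seq_len(P)) {
      rhat_subject[s, j] <-
        compute_rhat(sapply(chains, function(ch) ch$beta[, s, j]))
    }
  }

  beta_mean <- apply(
    do.call(abind3, lapply(chains, `[[`, "beta")), c(2, 3), mean)
  colnames(beta_mean) <- pt$name
  ll_at_mean <- sum(vapply(seq_len(S), function(s) {
    subject_loglik(beta_mean[s, ], fd$data[[s]], spec, pt, deadline,
                   use_cache, censor_missed)
  }, 0))

  fit <- structure(list(
    spec = spec, settings = settings, deadline = deadline,
    param_table = pt, subjects = fd$subjects,
    chains = chains, rhat = rhat, rhat_subject = rhat_subject,
    converged = all(rhat < 1.1, na.rm = TRUE),
    beta_mean = beta_mean,
    group_mean = setNames(colMeans(do.call(rbind,
                                           lapply(chains, `[[`, "mu"))),
                          pt$name),
    loglik = unlist(lapply(chains, `[[`, "ll")),
    ll_at_mean = ll_at_mean,
    n_trials = fd$n_trials,
    censor_missed = censor_missed,
    fit_data = fd
  ), class = "acc_fit")
  if (!fit$converged) {
    warning("fit flagged as non-converged: max R-hat = ",
            round(max(rhat, na.rm = TRUE), 3), call. = FALSE)
  }
  fit
}

# bind chain arrays (iter x subject x param) along the iteration margin
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n_tot <- sum(vapply(arrs, function(a) dim(a)[1], 0L))
  out <- array(NA_real_, c(n_tot, d[2], d[3]))
  off <- 0L
  for (a in arrs) {
    out[off + seq_len(dim(a)[1]), , ] <- a
    off <- off + dim(a)[1]
  }
  out
}

#' @export
print.acc_fit <- function(x, ...) {
  cat("<acc_fit> ", x$spec$name, ": ", length(x$subjects), " subjects, ",
      x$n_trials, " trials\n", sep = "")
  cat("  chains: ", x$settings$n_chains, " x ", x$settings$n_samples,
      " (burn ", x$settings$n_burn, "), max R-hat = ",
      round(max(x$rhat, na.rm = TRUE), 3),
      if (x$converged) " (converged)" else " (NOT converged)", "\n",
      sep = "")
  dic <- compute_dic(x)
  cat("  DIC = ", round(dic$dic, 1), " (pD = ", round(dic$pd, 1), ")\n",
      sep = "")
  invisible(x)
}

#' Posterior draws of a group-level parameter
#'
#' @param fit An `acc_fit`.
#' @param parameter Parameter name(s); `"a_absVD"` refers to the group mean
#'   `mu_a_absVD`.  If several names are given the draws are summed
#'   (posterior of the summed coefficients).
#' @param level "mu" (group means, default) or "sigma" (group SDs).
#' @return Numeric vector of pooled post-burn draws.
#' @export
posterior_draws <- function(fit, parameter, level = c("mu", "sigma")) {
  level <- match.arg(level)
  pn <- fit$param_table$name
  parameter <- sub("^mu_", "", parameter)
  bad <- setdiff(parameter, pn)
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(pn, collapse = ", "), call. = FALSE)
  }
  draws <- lapply(fit$chains, function(ch) {
    m <- if (level == "mu") ch$mu else ch$sigma
    rowSums(m[, paste0(level, "_", parameter), drop = FALSE])
  })
  unlist(draws)
}

#' Posterior tail probability
#'
#' Fraction of pooled post-burn posterior draws of a group-level parameter
#' (or sum of parameters) that fall below `threshold` -- the P(x < 0)
#' statistic used to decide coefficient signs.
#'
#' @inheritParams posterior_draws
#' @param threshold Threshold value (default 0).
#' @return Probability in `[0, 1]`.
#' @export
posterior_tail_prob <- function(fit, parameter, threshold = 0) {
  mean(posterior_draws(fit, parameter) < threshold)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor from the classic between/within-chain
#' variance ratio: with m chains of length n, `W` the mean within-chain
#' variance and `B/n` the between-chain variance of the chain means,
#' `R-hat = sqrt(((n-1)/n W + B/n) / W)`, floored at 1 (finite-sample
#' deflation below 1 is reported as exact convergence).
#'
#' @param chains Matrix (iterations x chains) or list of equal-length
#'   numeric vectors, one per chain.
#' @return R-hat (scalar).
#' @export
compute_rhat <- function(chains) {
  if (is.list(chains)) {
    len <- vapply(chains, length, 0L)
    if (length(unique(len)) != 1) {
      stop("chains must have equal lengths", call. = FALSE)
    }
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  if (n < 2) stop("need at least 2 iterations per chain", call. = FALSE)
  W <- mean(apply(chains, 2, var))
  B_n <- var(colMeans(chains))  # = B/n
  if (W == 0) return(1)
  max(1, sqrt(((n - 1) / n * W + B_n) / W))
}

#' Deviance information criterion
#'
#' From the post-burn log-likelihood trace: `Dbar` is the posterior mean of
#' the deviance `-2 log L`, `Dhat` the deviance at the posterior means of
#' the subject-level parameters, `pD = Dbar - Dhat` the effective number of
#' parameters, and `DIC = Dhat + 2 pD = Dbar + pD`.  The trial-averaged
#' deviance `Dbar / n_trials` normalises fits across datasets with
#' different trial counts.
#'
#' @param fit An `acc_fit`.
#' @return List with `dic`, `pd`, `dbar`, `dhat`, `n_trials`,
#'   `trial_avg_deviance`.
#' @export
compute_dic <- function(fit) {
  ll <- fit$loglik
  if (length(ll) < 10) {
    stop("need at least 10 post-burn samples for DIC", call. = FALSE)
  }
  dic_from_trace(ll, fit$ll_at_mean, fit$n_trials)
}

#' DIC from a raw log-likelihood trace
#'
#' The arithmetic core of [compute_dic()], exposed for direct use on a
#' log-likelihood trace and the log-likelihood evaluated at the posterior
#' means.
#'
#' @param loglik Per-iteration total log-likelihood trace.
#' @param loglik_at_mean Log-likelihood at the posterior parameter means.
#' @param n_trials Trial count for the trial-averaged deviance.
#' @return Same structure as [compute_dic()].
#' @export
dic_from_trace <- function(loglik, loglik_at_mean, n_trials = NA_integer_) {
  dbar <- mean(-2 * loglik)
  dhat <- -2 * loglik_at_mean
  pd <- dbar - dhat
  list(dic = dhat + 2 * pd, pd = pd, dbar = dbar, dhat = dhat,
       n_trials = n_trials,
       trial_avg_deviance = dbar / n_trials)
}
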