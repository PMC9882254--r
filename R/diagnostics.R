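#' Adjusted Fisher-Pearson sample skewness
#'
#' Thin wrapper over `e1071::skewness(type = 2)`.
#' @param x Numeric vector (NAs dropped).
#' @return Skewness estimate.
#' @export
rt_skewness <- function(x) {
  e1071::skewness(x, na.rm = TRUE, type = 2)
}

#' Posterior predictive check on RT distributions
#'
#' Simulates behaviour from posterior draws of a fitted model and compares
#' the simulated RT distributions against the observed ones, split into
#' easy/hard halves by a pooled median split on the equal-weight absolute
#' value difference.  Densities are Gaussian kernel density estimates; the
#' report also contains the adjusted Fisher-Pearson skewness of each RT
#' distribution and the observed vs. simulated choice proportions.  A
#' static-bound model fitted to collapse-generated behaviour characteristically
#' over-predicts RT skew.
#'
#' @param fit An `acc_fit`.
#' @param design Design table used for the fit.
#' @param behavior Observed behaviour rows.
#' @param n_sim Total number of simulated trials (>= number of observed
#'   trials); posterior draws are consumed until `n_sim` is reached.
#' @param seed Integer seed.
#' @return List of class `acc_ppc` with per-group densities, skewness table
#'   and choice proportions.
#' @export
posterior_predictive <- function(fit, design, behavior, n_sim = NULL,
                                 seed = 1) {
  design <- as.data.frame(design)
  if (!"absVD" %in% names(design)) design <- compute_regressors(design)
  spec <- fit$spec
  if (spec$coding == "accuracy") {
    design <- add_difficulty_split(design[design$absVD > 0, ])
  }
  behavior <- as.data.frame(behavior)
  n_obs <- nrow(behavior)
  if (is.null(n_sim)) n_sim <- 10L * n_obs
  if (n_sim < n_obs) {
    stop("`n_sim` must be at least the observed trial count", call. = FALSE)
  }
  n_draws <- ceiling(n_sim / n_obs)

  pt <- fit$param_table
  iters <- nrow(fit$chains[[1]]$mu)
  sims <- with_seed(seed, {
    draw_ids <- cbind(sample(length(fit$chains), n_draws, replace = TRUE),
                      sample(iters, n_draws, replace = TRUE))
    out <- vector("list", n_draws)
    for (d in seq_len(n_draws)) {
      ch <- fit$chains[[draw_ids[d, 1]]]
      rows <- vector("list", length(fit$subjects))
      for (i in seq_along(fit$subjects)) {
        s <- fit$subjects[i]
        ds <- design[design$subject_id == s, ]
        par <- ch$beta[draw_ids[d, 2], i, ]
        nat <- natural_from_sampler(par, pt, spec)
        pars <- map_parameters(spec, ds, nat)
        if (spec$coding == "accuracy") {
          pars <- accuracy_to_response_params(pars, ds)
        }
        rows[[i]] <- simulate_ddm(ds, pars, n_reps = 1,
                                  deadline = fit$deadline,
                                  seed = sample.int(2^30, 1))
      }
      out[[d]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
  })

  med <- median(design$absVD[design$absVD > 0])
  grp <- function(d) ifelse(d <= med, "hard", "easy")
  design$ppc_group <- grp(design$absVD)
  key <- paste(design$subject_id, design$trial_id)
  behavior$ppc_group <- design$ppc_group[match(
    paste(behavior$subject_id, behavior$trial_id), key)]
  sims$ppc_group <- design$ppc_group[match(
    paste(sims$subject_id, sims$trial_id), key)]

  summarise_group <- function(d) {
    rt <- d$rt[d$choice %in% c("left", "right")]
    list(rt = rt,
         dens = if (length(rt) > 3) density(rt, na.rm = TRUE) else NULL,
         skew = if (length(rt) > 3) rt_skewness(rt) else NA_real_,
         p_left = mean(d$choice == "left"),
         p_missed = mean(d$choice == "missed"))
  }
  groups <- c("easy", "hard")
  obs <- lapply(setNames(groups, groups), function(g) {
    summarise_group(behavior[!is.na(behavior$ppc_group) &
                               behavior$ppc_group == g, ])
  })
  sim <- lapply(setNames(groups, groups), function(g) {
    summarise_group(sims[!is.na(sims$ppc_group) & sims$ppc_group == g, ])
  })
  skew_tab <- data.frame(
    group = groups,
    observed = vapply(obs, `[[`, 0, "skew"),
    simulated = vapply(sim, `[[`, 0, "skew"),
    row.names = NULL
  )
  skew_tab$gap <- skew_tab$simulated - skew_tab$observed
  structure(list(observed = obs, simulated = sim, skewness = skew_tab,
                 model = spec$name, n_sim = n_sim),
            class = "acc_ppc")
}

#' @export
print.acc_ppc <- function(x, ...) {
  cat("<acc_ppc> model:", x$model, "\n")
  print(x$skewness, row.names = FALSE)
  invisible(x)
}

#' @export
plot.acc_ppc <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  for (g in c("easy", "hard")) {
    o <- x$observed[[g]]$dens
    s <- x$simulated[[g]]$dens
    ylim <- range(0, o$y, s$y)
    plot(o, main = paste0(g, " trials"), xlab = "RT (s)", ylim = ylim, ...)
    graphics::lines(s, lty = 2)
    graphics::legend("topright", c("observed", "simulated"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

#' Parameter recovery experiment
#'
#' Draws generating subject-level parameters from the model's group
#' distributions, simulates behaviour, refits the model, and compares the
#' generating parameters with the recovered posterior means (on the sampler
#' scale, where the comparison is monotone-invariant for the regression
#' coefficients).  Per-parameter Pearson correlations and mean bias are
#' pooled over datasets; failed fits are recorded per dataset rather than
#' raised.
#'
#' @param spec Model specification or name.
#' @param n_datasets Number of simulated datasets.
#' @param n_subjects Subjects per dataset.
#' @param n_trials Trials per subject.
#' @param settings [mcmc_settings()] for the refits.
#' @param seed Integer seed.
#' @param deadline Response deadline (s).
#' @param group Optional generating group table (see
#'   [draw_coefficients()]).
#' @return List of class `acc_recovery`: `pairs` (one row per generated
#'   parameter), `by_parameter` (correlation and bias), and `errors`.
#' @export
parameter_recovery <- function(spec, n_datasets = 1, n_subjects = 20,
                               n_trials = 160, settings = mcmc_settings(),
                               seed = 1, deadline = 0.75, group = NULL) {
  if (is.character(spec)) spec <- build_model_spec(spec)
  pairs <- list()
  errors <- list()
  for (d in seq_len(n_datasets)) {
    res <- tryCatch({
      dseed <- seed + 1000 * (d - 1)
      design <- generate_design(n_subjects, n_trials, seed = dseed)
      coefs <- draw_coefficients(spec, n_subjects, seed = dseed + 1,
                                 group = group)
      beh <- simulate_from_coefs(coefs, design, deadline = deadline,
                                 seed = dseed + 2)
      st <- settings
      st$seed <- dseed + 3
      fit <- suppressWarnings(
        fit_model(beh, design, spec, settings = st, deadline = deadline))
      data.frame(
        dataset = d,
        parameter = rep(fit$param_table$name, each = n_subjects),
        generated = as.vector(coefs$subject),
        recovered = as.vector(fit$beta_mean),
        converged = fit$converged
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1]] <- list(dataset = d,
                                           message = conditionMessage(res))
    } else {
      pairs[[length(pairs) + 1]] <- res
    }
  }
  if (!length(pairs)) stop("all recovery fits failed", call. = FALSE)
  pairs <- do.call(rbind, pairs)
  by_par <- do.call(rbind, lapply(split(pairs, pairs$parameter), function(p) {
    data.frame(parameter = p$parameter[1],
               r = suppressWarnings(cor(p$generated, p$recovered)),
               bias = mean(p$recovered - p$generated),
               n = nrow(p), row.names = NULL)
  }))
  structure(list(pairs = pairs, by_parameter = by_par, errors = errors,
                 model = spec$name),
            class = "acc_recovery")
}

#' @export
print.acc_recovery <- function(x, ...) {
  cat("<acc_recovery> model:", x$model, "\n")
  print(x$by_parameter, row.names = FALSE)
  if (length(x$errors)) cat(length(x$errors), "dataset(s) failed\n")
  invisible(x)
}

#' Model recovery (confusion) experiment
#'
#' For each generating model, simulates `n_datasets` datasets from its
#' generating distributions, fits every candidate model to each dataset, and
#' records the DIC matrix, the best-fitting-model counts, and the DIC bias
#' toward collapsing-bound models on static-bound-generated data (mean
#' static-minus-collapse DIC difference; positive values mean the collapse
#' models look better even when the data were not generated by one).
#'
#' @param specs Character vector or list of model specifications (>= 2);
#'   default is the trio Original*, VD (static) and VD both (collapsing).
#' @param n_datasets Datasets per generating model.
#' @param n_subjects,n_trials Size of each dataset.
#' @param settings [mcmc_settings()] for the fits.
#' @param seed Integer seed.
#' @param deadline Response deadline (s).
#' @return List of class `acc_confusion`: `dic` (long data frame), `counts`
#'   (generator x fitted best-DIC counts), `collapse_bias`.
#' @export
model_recovery <- function(specs = c("Original*", "VD", "VD both"),
                           n_datasets = 8, n_subjects = 8, n_trials = 160,
                           settings = mcmc_settings(), seed = 1,
                           deadline = 0.75) {
  specs <- lapply(specs, function(s) {
    if (is.character(s)) build_model_spec(s) else s
  })
  if (length(specs) < 2) {
    stop("need at least 2 model specifications", call. = FALSE)
  }
  nm <- vapply(specs, `[[`, "", "name")
  rows <- list()
  errors <- list()
  for (g in seq_along(specs)) {
    for (d in seq_len(n_datasets)) {
      dseed <- seed + 10000 * g + 100 * d
      design <- generate_design(n_subjects, n_trials, seed = dseed)
      coefs <- draw_coefficients(specs[[g]], n_subjects, seed = dseed + 1)
      beh <- simulate_from_coefs(coefs, design, deadline = deadline,
                                 seed = dseed + 2)
      for (f in seq_along(specs)) {
        res <- tryCatch({
          st <- settings
          st$seed <- dseed + 3 + f
          fit <- suppressWarnings(
            fit_model(beh, design, specs[[f]], settings = st,
                      deadline = deadline))
          compute_dic(fit)$dic
        }, error = function(e) e)
        if (inherits(res, "error")) {
          errors[[length(errors) + 1]] <-
            list(generator = nm[g], fitted = nm[f], dataset = d,
                 message = conditionMessage(res))
          res <- NA_real_
        }
        rows[[length(rows) + 1]] <- data.frame(
          generator = nm[g], dataset = d, fitted = nm[f], dic = res)
      }
    }
  }
  dic <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(
    split(dic, list(dic$generator, dic$dataset), drop = TRUE),
    function(p) {
      p[which.min(p$dic), c("generator", "dataset", "fitted")]
    }))
  counts <- table(generator = factor(best$generator, levels = nm),
                  best = factor(best$fitted, levels = nm))

  # DIC bias toward collapsing bounds on static-generated data
  is_angle <- vapply(specs, function(s) s$bound == "angle", TRUE)
  collapse_bias <- NA_real_
  if (any(is_angle) && any(!is_angle)) {
    static_gen <- dic[dic$generator %in% nm[!is_angle], ]
    per <- split(static_gen, list(static_gen$generator, static_gen$dataset),
                 drop = TRUE)
    deltas <- vapply(per, function(p) {
      min(p$dic[p$fitted %in% nm[!is_angle]], na.rm = TRUE) -
        min(p$dic[p$fitted %in% nm[is_angle]], na.rm = TRUE)
    }, 0)
    collapse_bias <- mean(deltas, na.rm = TRUE)
  }
  structure(list(dic = dic, counts = counts, collapse_bias = collapse_bias,
                 models = nm, errors = errors),
            class = "acc_confusion")
}

#' @export
print.acc_confusion <- function(x, ...) {
  cat("<acc_confusion> best-DIC counts (rows = generator):\n")
  print(x$counts)
  cat("DIC bias toward collapsing bounds on static-generated data: ",
      round(x$collapse_bias, 1), "\n", sep = "")
  invisible(x)
}

#' Model-mimicry experiment: fit threshold-control DDMs to LCA behaviour
#'
#' Simulates behaviour from the control-free leaky competing accumulator
#' (one replicate per design trial per synthetic subject), then fits DDM
#' variants in which option values regress onto the decision threshold.
#' Because the LCA contains no threshold-control mechanism, any recovered
#' value-threshold coupling is an artifact of model mimicry.  The report
#' contains, per fitted model, the posterior summaries and tail
#' probabilities of the threshold-related coefficients: for Original* the
#' probability that the absVD coefficient on threshold is positive (apparent
#' difficulty-dependent threshold lowering), and for VDOV both the
#' probability that the summed overall-value coefficients on threshold are
#' negative (apparent value-dependent threshold lowering).
#'
#' @param lca LCA parameters ([lca_params()]; printed set by default).
#' @param design Optional design table; by default a fresh design with
#'   `n_subjects` subjects x 160 trials is generated.
#' @param fitted_specs Model names/specs to fit.
#' @param settings [mcmc_settings()].
#' @param seed Integer seed.
#' @param n_subjects Synthetic cohort size (default 22).
#' @return List of class `acc_mimicry` with per-model fits, tail
#'   probabilities and a `noninformative` flag for degenerate inputs.
#' @export
run_mimicry <- function(lca = lca_params(), design = NULL,
                        fitted_specs = c("Original*", "VDOV both"),
                        settings = mcmc_settings(), seed = 1,
                        n_subjects = 22) {
  if (is.null(design)) {
    design <- generate_design(n_subjects, 160, seed = seed)
  }
  beh <- simulate_lca(design, lca, n_reps = 1, seed = seed + 1)
  deadline <- lca$deadline + lca$t0

  # degenerate generator (e.g. s = 0): no response variability to fit
  rts <- beh$rt[beh$choice %in% c("left", "right")]
  noninformative <- length(unique(round(rts, 6))) < 5 ||
    stats::sd(rts) < 1e-6
  results <- list()
  if (!noninformative) {
    for (i in seq_along(fitted_specs)) {
      spec <- fitted_specs[[i]]
      if (is.character(spec)) spec <- build_model_spec(spec)
      st <- settings
      st$seed <- settings$seed + 17 * i
      fit <- suppressWarnings(
        fit_model(beh, design, spec, settings = st, deadline = deadline))
      a_terms <- spec$a$terms
      tails <- list()
      for (term in a_terms) {
        nm <- paste0("a_", term)
        tails[[nm]] <- c(p_below_0 = posterior_tail_prob(fit, nm),
                         mean = mean(posterior_draws(fit, nm)))
      }
      ov_terms <- intersect(c("maxOV", "minOV"), a_terms)
      if (length(ov_terms) == 2) {
        tails[["a_OV_sum"]] <- c(
          p_below_0 = posterior_tail_prob(fit, paste0("a_", ov_terms)),
          mean = mean(posterior_draws(fit, paste0("a_", ov_terms))))
      }
      results[[spec$name]] <- list(fit = fit, tails = tails)
    }
  }
  structure(list(results = results, lca = lca,
                 noninformative = noninformative, deadline = deadline),
            class = "acc_mimicry")
}

#' @export
print.acc_mimicry <- function(x, ...) {
  if (x$noninformative) {
    cat("<acc_mimicry> degenerate generator: fits flagged non-informative\n")
    return(invisible(x))
  }
  cat("<acc_mimicry> threshold-coefficient tail probabilities:\n")
  for (nm in names(x$results)) {
    cat(" ", nm, "\n")
    for (t in names(x$results[[nm]]$tails)) {
      v <- x$results[[nm]]$tails[[t]]
      cat(sprintf("   %-12s mean = %7.3f   P(<0) = %.3f\n", t,
                  v["mean"], v["p_below_0"]))
    }
  }
  invisible(x)
}
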