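#' Leaky competing accumulator parameters
#'
#' Constructor for the LCA parameter set.  Defaults are the hand-tuned values
#' used for the control-free generative simulations: initial bound height
#' `z0 = 10`, noise `s = 4.5`, decay `k = 0.153`, mutual inhibition
#' `w_inh = 0.5`, item weights 4/5 (higher-valued) and 1/5 (lower-valued),
#' non-decision time 250 ms, integration step 5 ms, and a bound that collapses
#' linearly to zero at the 750 ms response window.
#'
#' Accumulator inputs are the weighted average of each bundle's two item
#' values expressed in points (`input_scale * euros`, default scale 100,
#' i.e. a 0.80-euro item contributes 80); the printed noise and bound
#' parameters are calibrated to that scale.
#'
#' @param w_max,w_min Input weights for the higher-/lower-valued item of each
#'   bundle (sum to 1).
#' @param k Decay (leak) rate, 1/s.
#' @param w_inh Mutual inhibition weight, 1/s.
#' @param s Noise standard deviation scale.
#' @param z0 Initial bound height (activation units).
#' @param deadline Collapse window (s): the bound reaches zero here
#'   (decision-time clock; non-decision time is appended afterwards).
#' @param t0 Non-decision time (s).
#' @param step Integration step (s).
#' @param input_scale Multiplier from euros to accumulator input units.
#' @return A list of class `acc_lca_params`.
#' @export
lca_params <- function(w_max = 4 / 5, w_min = 1 / 5, k = 0.153, w_inh = 0.5,
                       s = 4.5, z0 = 10, deadline = 0.75, t0 = 0.25,
                       step = 0.005, input_scale = 100) {
  p <- list(w_max = w_max, w_min = w_min, k = k, w_inh = w_inh, s = s,
            z0 = z0, deadline = deadline, t0 = t0, step = step,
            input_scale = input_scale)
  if (!all(vapply(p, function(x) is.numeric(x) && is.finite(x), TRUE))) {
    stop("invalid parameter: LCA parameters must be finite numbers",
         call. = FALSE)
  }
  if (z0 <= 0 || s < 0 || k < 0 || w_inh < 0 || step <= 0 || deadline <= 0 ||
      t0 < 0) {
    stop("invalid parameter: LCA parameter out of range", call. = FALSE)
  }
  if (step >= deadline) {
    stop("invalid parameter: `step` must be smaller than `deadline`",
         call. = FALSE)
  }
  class(p) <- "acc_lca_params"
  p
}

#' Simulate choices from the leaky competing accumulator
#'
#' Two accumulators (left / right bundle) race toward a bound that collapses
#' linearly from `z0` at decision time 0 to zero at `deadline`.  Per
#' integration step each activation is updated as
#' `y <- y + step * (I - k * y - w_inh * y_other) + sqrt(step) * s * N(0,1)`
#' with independent standard-normal noise per accumulator; activations are
#' unbounded and may go negative.  The input `I` to each accumulator is the
#' weighted average of the bundle's item values
#' (`input_scale * (w_max * max + w_min * min)`).  The first accumulator to
#' meet or exceed the current bound wins; if both cross in the same step the
#' larger activation wins; if neither has crossed when the bound reaches
#' zero the larger activation wins (exact ties are resolved by a fair coin),
#' so no trial is missed.  Reported RT is decision time plus `t0`.
#'
#' @param design A design table from [generate_design()].
#' @param params An [lca_params()] object.
#' @param n_reps Replicates per design trial.
#' @param seed Integer seed.
#' @return A data frame of class `acc_behavior` with columns `subject_id`,
#'   `trial_id`, `rep`, `choice` ("left"/"right"), `rt` (s) and
#'   `decision_time` (s).
#' @examples
#' d <- generate_design(n_trials = 8, seed = 1)
#' b <- simulate_lca(d, n_reps = 10, seed = 1)
#' range(b$decision_time)
#' @export
simulate_lca <- function(design, params = lca_params(), n_reps = 1000,
                         seed = 1) {
  stopifnot(inherits(params, "acc_lca_params"))
  if (n_reps < 1) stop("`n_reps` must be positive", call. = FALSE)
  I1 <- params$input_scale *
    (params$w_max * design$left_max + params$w_min * design$left_min)
  I2 <- params$input_scale *
    (params$w_max * design$right_max + params$w_min * design$right_min)
  sim <- with_seed(seed, {
    .sim_lca_cpp(I1, I2, as.integer(n_reps), params$k, params$w_inh,
                 params$s, params$z0, params$deadline, params$t0,
                 params$step)
  })
  out <- data.frame(
    subject_id = design$subject_id[sim$trial],
    trial_id = design$trial_id[sim$trial],
    rep = rep(seq_len(n_reps), times = nrow(design)),
    choice = ifelse(sim$choice == 1, "left", "right"),
    rt = sim$rt,
    decision_time = sim$decision_time
  )
  attr(out, "deadline") <- params$deadline + params$t0
  attr(out, "t0") <- params$t0
  class(out) <- c("acc_behavior", "data.frame")
  out
}

#' Summarise simulated behaviour against the design's value structure
#'
#' Computes, per absolute-value-difference bin, accuracy (probability of
#' choosing the bundle with the higher weighted value) and mean RT, plus mean
#' RT per weighted overall-value bin, and Spearman rank correlations across
#' trials of accuracy vs. absVD, RT vs. absVD, and RT vs. weighted OV.  The
#' qualitative signature of value-guided speeded choice is positive
#' accuracy-absVD and negative RT-absVD and RT-OV correlations.
#'
#' @param rows Behaviour rows (e.g. from [simulate_lca()]).
#' @param design The matching design table.
#' @param weighting `c(w_max, w_min)` weights defining the "better" bundle
#'   and the weighted overall value; defaults to the LCA's 4/5, 1/5.
#' @param n_bins Number of bins for the per-bin summaries.
#' @return A list of class `acc_lca_summary` with elements `by_absvd`,
#'   `by_ov`, and `correlations`.
#' @export
lca_behavior_summary <- function(rows, design, weighting = c(4 / 5, 1 / 5),
                                 n_bins = 4) {
  dat <- merge(as.data.frame(rows), as.data.frame(design),
               by = c("subject_id", "trial_id"))
  dat <- dat[dat$choice %in% c("left", "right"), ]
  if (nrow(dat) == 0) {
    stop("empty summary: no non-missed responses", call. = FALSE)
  }
  wl <- weighting[1] * dat$left_max + weighting[2] * dat$left_min
  wr <- weighting[1] * dat$right_max + weighting[2] * dat$right_min
  dat$w_ov <- wl + wr
  dat$correct <- ifelse(wl == wr, NA,
                        (dat$choice == "left") == (wl > wr))
  if (length(unique(dat$absVD)) < 2 || length(unique(dat$w_ov)) < 2) {
    stop("need at least 2 distinct levels of absVD and OV", call. = FALSE)
  }

  # per-trial aggregates, then rank correlations across trials
  agg <- aggregate(cbind(rt = dat$rt) ~ subject_id + trial_id + absVD + w_ov,
                   data = dat, FUN = mean)
  acc <- aggregate(correct ~ subject_id + trial_id, data = dat, FUN = mean,
                   na.action = stats::na.omit)
  agg <- merge(agg, acc, by = c("subject_id", "trial_id"), all.x = TRUE)

  bin_idx <- function(x) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  agg$absvd_bin <- bin_idx(agg$absVD)
  agg$ov_bin <- bin_idx(agg$w_ov)
  by_absvd <- aggregate(cbind(accuracy = correct, mean_rt = rt) ~ absvd_bin,
                        data = agg, FUN = mean, na.action = stats::na.pass,
                        na.rm = TRUE)
  by_ov <- aggregate(cbind(mean_rt = rt) ~ ov_bin, data = agg, FUN = mean)

  ok <- !is.na(agg$correct)
  cors <- c(
    accuracy_absvd = suppressWarnings(
      cor(agg$correct[ok], agg$absVD[ok], method = "spearman")),
    rt_absvd = suppressWarnings(cor(agg$rt, agg$absVD, method = "spearman")),
    rt_ov = suppressWarnings(cor(agg$rt, agg$w_ov, method = "spearman"))
  )
  structure(list(by_absvd = by_absvd, by_ov = by_ov, correlations = cors),
            class = "acc_lca_summary")
}
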