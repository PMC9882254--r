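#' Generate a balanced value-choice task design
#'
#' Creates synthetic trial designs for a deadlined two-alternative choice
#' between bundles of two valued items ("fractals").  Each trial presents a
#' left and a right bundle; each bundle holds a higher-valued and a
#' lower-valued item drawn from a fixed value grid.  Trials are drawn by
#' stratified sampling over a grid of equal-weight overall-value x
#' value-difference cells so that, as in the original task, overall value
#' (the sum of all four item values) and absolute value difference (between
#' equal-weight bundle means) are approximately orthogonal across trials.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per subject.
#' @param value_grid Allowed item values in euros, sorted and strictly
#'   positive.  Default: 0.10 to 0.80 euro in 0.10 steps.
#' @param seed Integer seed; the same seed always yields the same design.
#' @param n_bins Number of strata per dimension for the balancing grid.
#' @return A data frame of class `acc_design` with columns `subject_id`,
#'   `trial_id`, `left_max`, `left_min`, `right_max`, `right_min` and the
#'   eight value regressors (see [compute_regressors()]).  The achieved
#'   correlation between equal-weight overall value and absolute value
#'   difference is attached as attribute `balance_r`.
#' @examples
#' d <- generate_design(n_subjects = 1, n_trials = 160, seed = 1)
#' attr(d, "balance_r")
#' @export
generate_design <- function(n_subjects = 1, n_trials = 160,
                            value_grid = seq(0.1, 0.8, by = 0.1),
                            seed = 1, n_bins = 4) {
  if (length(value_grid) < 2) {
    stop("invalid design: `value_grid` needs at least 2 levels", call. = FALSE)
  }
  if (any(!is.finite(value_grid)) || any(value_grid <= 0) ||
      is.unsorted(value_grid, strictly = TRUE)) {
    stop("invalid design: `value_grid` must be strictly positive and sorted",
         call. = FALSE)
  }
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop("invalid design: `n_trials` must be positive", call. = FALSE)
  }
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("invalid design: `n_subjects` must be positive", call. = FALSE)
  }

  # candidate pool: all ordered pairs of bundles (bundle = unordered value
  # pair with max >= min)
  g <- value_grid
  bundles <- expand.grid(min = g, max = g)
  bundles <- bundles[bundles$max >= bundles$min, ]
  idx <- expand.grid(l = seq_len(nrow(bundles)), r = seq_len(nrow(bundles)))
  cand <- data.frame(
    left_max = bundles$max[idx$l], left_min = bundles$min[idx$l],
    right_max = bundles$max[idx$r], right_min = bundles$min[idx$r]
  )
  ov <- cand$left_max + cand$left_min + cand$right_max + cand$right_min
  avd <- abs((cand$left_max + cand$left_min) / 2 -
             (cand$right_max + cand$right_min) / 2)

  bin_of <- function(x, k) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1)))
    if (length(br) < 3) br <- range(x)
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  cell <- interaction(bin_of(ov, n_bins), bin_of(avd, n_bins), drop = TRUE)
  cells <- split(seq_len(nrow(cand)), cell)

  design <- with_seed(seed, {
    draw_table <- function() {
      picks <- integer(n_trials)
      # cycle the strata, drawing one candidate per visit, so every cell
      # contributes (almost) equally often
      order_cells <- rep(seq_along(cells), length.out = n_trials +
                           length(cells))
      order_cells <-
        order_cells[sample.int(length(order_cells))][seq_len(n_trials)]
      for (i in seq_len(n_trials)) {
        pool <- cells[[order_cells[i]]]
        picks[i] <- pool[sample.int(length(pool), 1L)]
      }
      picks
    }
    rows <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      # draw several stratified tables and keep the best-balanced one,
      # as an experimenter would when preparing a stimulus list
      best <- NULL
      best_r <- Inf
      for (try in 1:25) {
        picks <- draw_table()
        ov_t <- ov[picks]
        avd_t <- avd[picks]
        r <- if (stats::sd(ov_t) > 0 && stats::sd(avd_t) > 0) {
          abs(cor(ov_t, avd_t))
        } else Inf
        if (r < best_r) {
          best <- picks
          best_r <- r
        }
        if (best_r < 0.02) break
      }
      rows[[s]] <- data.frame(subject_id = s, trial_id = seq_len(n_trials),
                              cand[best, ], row.names = NULL)
    }
    do.call(rbind, rows)
  })
  design <- compute_regressors(design)
  ew_ov <- design$left_max + design$left_min + design$right_max +
    design$right_min
  attr(design, "balance_r") <- if (stats::sd(ew_ov) > 0 &&
                                   stats::sd(design$absVD) > 0) {
    cor(ew_ov, design$absVD)
  } else NA_real_
  attr(design, "seed") <- as.integer(seed)
  class(design) <- c("acc_design", "data.frame")
  design
}

#' Attach value regressors to a design table
#'
#' Computes the eight value regressors used by the model registry from the
#' four item values of each trial:
#' \describe{
#'   \item{signVD}{equal-weight signed value difference, mean(left bundle) -
#'     mean(right bundle), in euros}
#'   \item{absVD}{absolute value of signVD}
#'   \item{maxVD, minVD}{value difference between the higher-valued
#'     (resp. lower-valued) items of the two bundles}
#'   \item{absMaxVD, absMinVD}{absolute values of maxVD and minVD}
#'   \item{maxOV, minOV}{summed value of the two higher-valued
#'     (resp. lower-valued) items}
#' }
#' The equal-weight difference uses bundle means (not sums) so that its scale
#' matches single-item euros.
#'
#' @param design Data frame with columns `left_max`, `left_min`, `right_max`,
#'   `right_min` (values may also come from outside the standard grid, e.g.
#'   points / 100).
#' @param standardize If `TRUE`, z-score all eight regressors; the flag is
#'   recorded in attribute `standardized`.
#' @return The design with regressor columns appended/overwritten.
#' @examples
#' d <- data.frame(left_max = 0.9, left_min = 0.7,
#'                 right_max = 0.4, right_min = 0.3)
#' compute_regressors(d)[, c("signVD", "maxVD", "minVD", "maxOV", "minOV")]
#' @export
compute_regressors <- function(design, standardize = FALSE) {
  need <- c("left_max", "left_min", "right_max", "right_min")
  if (!all(need %in% names(design))) {
    stop("design must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(design$left_max < design$left_min) ||
      any(design$right_max < design$right_min)) {
    stop("invalid design: bundle max below bundle min", call. = FALSE)
  }
  old_class <- class(design)
  design$signVD <- (design$left_max + design$left_min) / 2 -
    (design$right_max + design$right_min) / 2
  design$absVD <- abs(design$signVD)
  design$maxVD <- design$left_max - design$right_max
  design$minVD <- design$left_min - design$right_min
  design$absMaxVD <- abs(design$maxVD)
  design$absMinVD <- abs(design$minVD)
  design$maxOV <- design$left_max + design$right_max
  design$minOV <- design$left_min + design$right_min
  if (standardize) {
    regs <- c("signVD", "absVD", "maxVD", "minVD", "absMaxVD", "absMinVD",
              "maxOV", "minOV")
    for (r in regs) {
      s <- stats::sd(design[[r]])
      design[[r]] <- (design[[r]] - mean(design[[r]])) / ifelse(s > 0, s, 1)
    }
  }
  attr(design, "standardized") <- standardize
  class(design) <- unique(c("acc_design", old_class, "data.frame"))
  design
}

#' Correlation of weighted overall value and weighted value difference
#'
#' Re-weights each bundle's value as `w_max * max + w_min * min` and returns
#' the Pearson correlation across trials between weighted overall value
#' (left + right) and the absolute weighted value difference.  With equal
#' weights on a design from [generate_design()] the two are approximately
#' orthogonal; overweighting the higher-valued item (as participants do)
#' reintroduces a correlation, which is the confound at the heart of the
#' re-analysis this package supports.
#'
#' @param design A design table (regressor columns not required).
#' @param weighting Length-2 weights `c(w_max, w_min)`, non-negative, summing
#'   to 1.
#' @return A list with elements `r`, `w_max`, `w_min`.
#' @examples
#' d <- generate_design(seed = 2)
#' design_correlations(d)$r                       # ~ 0
#' design_correlations(d, c(0.8, 0.2))$r          # clearly non-zero
#' @export
design_correlations <- function(design, weighting = c(0.5, 0.5)) {
  if (length(weighting) != 2 || any(weighting < 0) ||
      abs(sum(weighting) - 1) > 1e-8) {
    stop("`weighting` must be two non-negative weights summing to 1",
         call. = FALSE)
  }
  wl <- weighting[1] * design$left_max + weighting[2] * design$left_min
  wr <- weighting[1] * design$right_max + weighting[2] * design$right_min
  w_ov <- wl + wr
  w_vd <- abs(wl - wr)
  if (nrow(design) < 2 || stats::sd(w_ov) == 0 || stats::sd(w_vd) == 0) {
    stop("undefined correlation: design is degenerate (no variance)",
         call. = FALSE)
  }
  list(r = cor(w_ov, w_vd), w_max = weighting[1], w_min = weighting[2])
}
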