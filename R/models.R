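
# ---------------------------------------------------------------------------
# Model registry: the 14 DDM variants.  "ddm" = static bound, "angle" =
# linearly collapsing bound.  Formula strings are kept verbatim; `terms`
# drive the design matrices.  All models except "Original" are
# response-coded (upper boundary = left) with a free starting point and a
# lapse term; "Original" is accuracy-coded with per-condition (easy/hard)
# drift, threshold and bias, and drops zero-difference trials.
# ---------------------------------------------------------------------------

vd_terms <- c("absMaxVD", "absMinVD")
ov_terms <- c("maxOV", "minOV")

model_registry <- list(
  "original" = list(
    name = "Original", bound = "static", coding = "accuracy",
    formulas = c(v = "v ~ [hard, easy]", a = "a ~ [hard, easy]",
                 z = "z ~ [hard, easy]"),
    v = list(intercept = FALSE, terms = c("hard", "easy")),
    a = list(intercept = FALSE, terms = c("hard", "easy")),
    theta = NULL,
    z = list(intercept = FALSE, terms = c("hard", "easy")),
    p_outlier = FALSE
  ),
  "original*" = list(
    name = "Original*", bound = "static", coding = "response",
    formulas = c(v = "v ~ -1 + signVD", a = "a ~ 1 + absVD"),
    v = list(intercept = FALSE, terms = "signVD"),
    a = list(intercept = TRUE, terms = "absVD"),
    theta = NULL, z = "free", p_outlier = TRUE
  ),
  "vd" = list(
    name = "VD", bound = "static", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD",
                 a = "a ~ 1 + absMaxVD + absMinVD"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = vd_terms),
    theta = NULL, z = "free", p_outlier = TRUE
  ),
  "ov" = list(
    name = "OV", bound = "static", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD", a = "a ~ 1 + maxOV + minOV"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = ov_terms),
    theta = NULL, z = "free", p_outlier = TRUE
  ),
  "vdov" = list(
    name = "VDOV", bound = "static", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD",
                 a = "a ~ 1 + absMaxVD + absMinVD + maxOV + minOV"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = c(vd_terms, ov_terms)),
    theta = NULL, z = "free", p_outlier = TRUE
  ),
  "vd both" = list(
    name = "VD both", bound = "angle", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD",
                 a = "a ~ 1 + absMaxVD + absMinVD",
                 theta = "theta ~ 1 + absMaxVD + absMinVD"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = vd_terms),
    theta = list(intercept = TRUE, terms = vd_terms),
    z = "free", p_outlier = TRUE
  ),
  "vd init" = list(
    name = "VD init", bound = "angle", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD",
                 a = "a ~ 1 + absMaxVD + absMinVD"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = vd_terms),
    theta = "free", z = "free", p_outlier = TRUE
  ),
  "vd rate" = list(
    name = "VD rate", bound = "angle", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD",
                 theta = "theta ~ 1 + absMaxVD + absMinVD"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = character(0)),
    theta = list(intercept = TRUE, terms = vd_terms),
    z = "free", p_outlier = TRUE
  ),
  "ov both" = list(
    name = "OV both", bound = "angle", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD", a = "a ~ 1 + maxOV + minOV",
                 theta = "theta ~ 1 + maxOV + minOV"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = ov_terms),
    theta = list(intercept = TRUE, terms = ov_terms),
    z = "free", p_outlier = TRUE
  ),
  "ov init" = list(
    name = "OV init", bound = "angle", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD", a = "a ~ 1 + maxOV + minOV"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = ov_terms),
    theta = "free", z = "free", p_outlier = TRUE
  ),
  "ov rate" = list(
    name = "OV rate", bound = "angle", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD",
                 theta = "theta ~ 1 + maxOV + minOV"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = character(0)),
    theta = list(intercept = TRUE, terms = ov_terms),
    z = "free", p_outlier = TRUE
  ),
  "vdov both" = list(
    name = "VDOV both", bound = "angle", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD",
                 a = "a ~ 1 + absMaxVD + absMinVD + maxOV + minOV",
                 theta = "theta ~ 1 + absMaxVD + absMinVD + maxOV + minOV"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = c(vd_terms, ov_terms)),
    theta = list(intercept = TRUE, terms = c(vd_terms, ov_terms)),
    z = "free", p_outlier = TRUE
  ),
  "vdov init" = list(
    name = "VDOV init", bound = "angle", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD",
                 a = "a ~ 1 + absMaxVD + absMinVD + maxOV + minOV"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = c(vd_terms, ov_terms)),
    theta = "free", z = "free", p_outlier = TRUE
  ),
  "vdov rate" = list(
    name = "VDOV rate", bound = "angle", coding = "response",
    formulas = c(v = "v ~ -1 + maxVD + minVD",
                 theta = "theta ~ 1 + absMaxVD + absMinVD + maxOV + minOV"),
    v = list(intercept = FALSE, terms = c("maxVD", "minVD")),
    a = list(intercept = TRUE, terms = character(0)),
    theta = list(intercept = TRUE, terms = c(vd_terms, ov_terms)),
    z = "free", p_outlier = TRUE
  )
)

normalize_model_name <- function(name) {
  tolower(gsub("\\s+", " ", trimws(gsub("[-_]", " ", name))))
}

#' Build a model specification from the registry
#'
#' Looks up one of the 14 registered DDM variants by name and returns its
#' specification: bound type (static "ddm" vs. collapsing "angle"), response
#' coding, and the regression formula for each mapped parameter.  Names are
#' case-insensitive and accept spaces, dashes or underscores (e.g.
#' `"VDOV both"`, `"vdov_both"`).
#'
#' @param name Model name (see [list_models()]).
#' @return A list of class `acc_model_spec`.
#' @examples
#' build_model_spec("VDOV both")$formulas
#' @export
build_model_spec <- function(name) {
  key <- normalize_model_name(name)
  if (!key %in% names(model_registry)) {
    stop("unknown model '", name, "'; valid names: ",
         paste(vapply(model_registry, `[[`, "", "name"), collapse = ", "),
         call. = FALSE)
  }
  spec <- model_registry[[key]]
  class(spec) <- "acc_model_spec"
  spec
}

#' List the registered model variants
#'
#' @return Data frame with the name, bound type, coding and regression
#'   formulas of every registered model.
#' @export
list_models <- function() {
  do.call(rbind, lapply(model_registry, function(m) {
    data.frame(name = m$name, bound = m$bound, coding = m$coding,
               formula = paste(m$formulas, collapse = ", "),
               row.names = NULL)
  }))
}

#' @export
print.acc_model_spec <- function(x, ...) {
  cat("<acc_model_spec> ", x$name, " (", x$bound, " bound, ", x$coding,
      "-coded)\n", sep = "")
  for (f in x$formulas) cat("  ", f, "\n", sep = "")
  extras <- c("z", if (isTRUE(x$p_outlier)) "p_outlier",
              if (identical(x$theta, "free")) "theta", "t0")
  cat("  free: ", paste(extras, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parameter layout.  Subject-level parameters live on an unconstrained
# sampler scale; links map linear predictors / free values to DDM
# parameters:  v identity, a = exp(lp), theta = softplus(lp) (capped below
# pi/2), z_rel = plogis(u), p_outlier = plogis(u), t0 = 0.5 * plogis(u).
# ---------------------------------------------------------------------------

THETA_CAP <- 1.40
T0_MAX <- 0.5

param_table <- function(spec) {
  rows <- list()
  add <- function(name, block) {
    rows[[length(rows) + 1]] <<- data.frame(name = name, block = block)
  }
  vt <- c(if (spec$v$intercept) "Intercept", spec$v$terms)
  for (t in vt) add(paste0("v_", t), "v")
  at <- c(if (spec$a$intercept) "Intercept", spec$a$terms)
  for (t in at) add(paste0("a_", t), "a")
  if (is.list(spec$theta)) {
    tt <- c(if (spec$theta$intercept) "Intercept", spec$theta$terms)
    for (t in tt) add(paste0("theta_", t), "theta")
  } else if (identical(spec$theta, "free")) {
    add("theta", "theta")
  }
  if (is.list(spec$z)) {
    for (t in spec$z$terms) add(paste0("z_", t), "z")
  } else {
    add("z", "z")
  }
  if (isTRUE(spec$p_outlier)) add("p_outlier", "lapse")
  add("t0", "lapse")
  do.call(rbind, rows)
}

# design matrix for one block ("Intercept" column first when present)
block_matrix <- function(block_spec, data, prefix) {
  if (is.null(block_spec)) return(NULL)
  cols <- list()
  nm <- character(0)
  if (isTRUE(block_spec$intercept)) {
    cols[[1]] <- rep(1, nrow(data))
    nm <- "Intercept"
  }
  for (t in block_spec$terms) {
    if (!t %in% names(data)) {
      stop("configuration error: regressor '", t, "' missing from design",
           call. = FALSE)
    }
    cols[[length(cols) + 1]] <- data[[t]]
    nm <- c(nm, t)
  }
  m <- do.call(cbind, cols)
  colnames(m) <- paste0(prefix, "_", nm)
  m
}

#' Map regression coefficients to per-trial DDM parameters
#'
#' Applies a model specification's regression formulas to a design's
#' regressors: drift `v` is the identity-linked linear predictor (no
#' intercept where the formula says `-1`), threshold `a = exp(lp)` (log
#' link, so positivity is structural), collapse angle
#' `theta = softplus(lp)` when regressed (or the free value), and `z_rel`,
#' `p_outlier`, `t0` are passed through.
#'
#' @param spec An [build_model_spec()] specification.
#' @param design Design table with regressor columns (see
#'   [compute_regressors()]).
#' @param coefs Named numeric vector: regression coefficients on the
#'   linear-predictor scale (`v_signVD`, `a_Intercept`, `a_absVD`,
#'   `theta_maxOV`, ...) plus natural-scale `z_rel` (or `z`), `p_outlier`
#'   and `t0` entries.  Alternatively a coefficient set from
#'   [draw_coefficients()] together with `subject`.
#' @param subject Subject index when `coefs` is a coefficient set.
#' @return Data frame with one row per design trial: `v`, `a`, `theta`,
#'   `z_rel`, `t0`, `p_outlier`.
#' @examples
#' sp <- build_model_spec("Original*")
#' d <- generate_design(n_trials = 4, seed = 1)
#' map_parameters(sp, d, c(v_signVD = 6, a_Intercept = 0, a_absVD = 0.3,
#'                         z_rel = 0.5, p_outlier = 0.05, t0 = 0.25))
#' @export
map_parameters <- function(spec, design, coefs, subject = 1) {
  stopifnot(inherits(spec, "acc_model_spec"))
  if (inherits(coefs, "acc_coefs")) {
    coefs <- subject_natural_coefs(coefs, subject)
  }
  getc <- function(nm) {
    if (!nm %in% names(coefs)) {
      stop("configuration error: missing coefficient '", nm, "'",
           call. = FALSE)
    }
    unname(coefs[[nm]])
  }
  lp <- function(block_spec, prefix) {
    X <- block_matrix(block_spec, design, prefix)
    if (is.null(X)) return(NULL)
    beta <- vapply(colnames(X), getc, 0)
    as.vector(X %*% beta)
  }
  n <- nrow(design)
  v <- lp(spec$v, "v")
  a <- exp(lp(spec$a, "a"))
  theta <- if (is.list(spec$theta)) {
    pmin(softplus(lp(spec$theta, "theta")), THETA_CAP)
  } else if (identical(spec$theta, "free")) {
    rep(pmin(softplus(getc("theta")), THETA_CAP), n)
  } else {
    rep(0, n)
  }
  z <- if (is.list(spec$z)) {
    as.vector(block_matrix(spec$z, design, "z") %*%
                vapply(paste0("z_", spec$z$terms), getc, 0))
  } else {
    nm <- if ("z_rel" %in% names(coefs)) "z_rel" else "z"
    rep(getc(nm), n)
  }
  p_out <- if (isTRUE(spec$p_outlier)) rep(getc("p_outlier"), n) else rep(0, n)
  t0 <- rep(getc("t0"), n)
  data.frame(v = v, a = a, theta = theta, z_rel = z, t0 = t0,
             p_outlier = p_out)
}

# transforms between the unconstrained sampler scale and the natural scale
# for the pass-through parameters
natural_from_sampler <- function(par, pt, spec) {
  out <- as.list(par)
  names(out) <- pt$name
  for (nm in pt$name[pt$block == "z"]) out[[nm]] <- plogis(out[[nm]])
  if ("p_outlier" %in% pt$name) out$p_outlier <- plogis(out$p_outlier)
  out$t0 <- T0_MAX * plogis(out$t0)
  if (is.list(spec$z) || !"z" %in% names(out)) {
    # per-condition z parameters already handled above
  } else {
    names(out)[names(out) == "z"] <- "z_rel"
  }
  unlist(out)
}

subject_natural_coefs <- function(coefs, subject) {
  natural_from_sampler(coefs$subject[subject, ], coefs$param_table,
                       coefs$spec)
}

# ---------------------------------------------------------------------------
# Generating distributions used by recovery suites (sampler scale).  Chosen
# once to give realistic behaviour under the 750 ms deadline: accuracies in
# the 0.7-0.9 range, mean RTs near 0.45-0.55 s, miss rates below ~10%.
# ---------------------------------------------------------------------------
default_group_params <- function(spec) {
  pt <- param_table(spec)
  mean_of <- function(nm) {
    switch(nm,
      v_signVD = 6, v_maxVD = 5, v_minVD = 1.25,
      v_hard = 1.2, v_easy = 2.5,
      a_hard = 0, a_easy = 0.1,
      a_Intercept = 0, a_absVD = 0.4,
      a_absMaxVD = 0.25, a_absMinVD = 0.1,
      a_maxOV = -0.15, a_minOV = -0.1,
      theta_Intercept = 0, theta = 0,
      z_hard = 0, z_easy = 0,
      z = 0, p_outlier = -2.9, t0 = 0,
      0)
  }
  sd_of <- function(nm) {
    switch(nm,
      v_signVD = 1.2, v_maxVD = 1.0, v_minVD = 0.5,
      v_hard = 0.4, v_easy = 0.6,
      a_hard = 0.15, a_easy = 0.15,
      a_Intercept = 0.15, a_absVD = 0.3,
      a_absMaxVD = 0.25, a_absMinVD = 0.2,
      a_maxOV = 0.2, a_minOV = 0.15,
      theta_Intercept = 0.3, theta = 0.3,
      z_hard = 0.25, z_easy = 0.25,
      z = 0.25, p_outlier = 0.5, t0 = 0.2,
      0.15)
  }
  data.frame(name = pt$name, block = pt$block,
             mean = vapply(pt$name, mean_of, 0),
             sd = vapply(pt$name, sd_of, 0), row.names = NULL)
}

#' Draw subject-level coefficients from group-level distributions
#'
#' Samples one coefficient vector per subject from independent normal
#' group-level distributions on the sampler scale (regression coefficients
#' are linear-predictor scale; starting point, lapse rate and non-decision
#' time are logit-scaled).  Used as the generating side of parameter- and
#' model-recovery experiments; defaults are the package's reference
#' generating distributions.
#'
#' @param spec Model specification or name.
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param group Optional data frame `name`, `mean`, `sd` overriding the
#'   defaults from `default_group_params()`.
#' @return List of class `acc_coefs`: `spec`, `group`, `param_table`, and a
#'   `subject` matrix (subjects x parameters, sampler scale).
#' @export
draw_coefficients <- function(spec, n_subjects, seed = 1, group = NULL) {
  if (is.character(spec)) spec <- build_model_spec(spec)
  pt <- param_table(spec)
  if (is.null(group)) group <- default_group_params(spec)
  if (!all(pt$name %in% group$name)) {
    stop("configuration error: `group` must cover every model parameter",
         call. = FALSE)
  }
  group <- group[match(pt$name, group$name), ]
  subj <- with_seed(seed, {
    m <- matrix(rnorm(n_subjects * nrow(pt), mean = rep(group$mean,
                                                        each = n_subjects),
                      sd = rep(group$sd, each = n_subjects)),
                nrow = n_subjects)
    colnames(m) <- pt$name
    m
  })
  structure(list(spec = spec, group = group, param_table = pt,
                 subject = subj),
            class = "acc_coefs")
}

#' Simulate behaviour for every subject of a coefficient set
#'
#' Maps each subject's coefficients to per-trial DDM parameters for that
#' subject's design rows and simulates responses.
#'
#' @param coefs An `acc_coefs` set from [draw_coefficients()].
#' @param design Design table covering the subjects in `coefs`.
#' @param deadline Response deadline (s).
#' @param dt Simulation step (s).
#' @param seed Integer seed.
#' @return Behaviour rows for all subjects.
#' @export
simulate_from_coefs <- function(coefs, design, deadline = 0.75, dt = 0.001,
                                seed = 1) {
  stopifnot(inherits(coefs, "acc_coefs"))
  spec <- coefs$spec
  if (spec$coding == "accuracy") {
    design <- add_difficulty_split(design[design$absVD > 0, ])
  }
  subjects <- sort(unique(design$subject_id))
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    ds <- design[design$subject_id == s, ]
    pars <- map_parameters(spec, ds, coefs, subject = i)
    if (spec$coding == "accuracy") {
      pars <- accuracy_to_response_params(pars, ds)
    }
    out[[i]] <- simulate_ddm(ds, pars, n_reps = 1, dt = dt,
                             deadline = deadline, seed = seed + i)
  }
  b <- do.call(rbind, out)
  attr(b, "deadline") <- deadline
  class(b) <- c("acc_behavior", "data.frame")
  b
}

# accuracy-coded parameter sets are expressed with the upper boundary as
# "correct"; convert to response coding (upper = left) for simulation
accuracy_to_response_params <- function(pars, design) {
  left_better <- design$signVD > 0
  flip <- !left_better  # right side is correct: mirror drift and bias
  pars$v[flip] <- -pars$v[flip]
  pars$z_rel[flip] <- 1 - pars$z_rel[flip]
  pars
}

# per-trial condition indicators for the accuracy-coded Original model:
# easy/hard by median split on absVD (pooled by default), zero-difference
# trials excluded upstream
add_difficulty_split <- function(design, per_subject = FALSE) {
  split_one <- function(d) {
    med <- median(d$absVD)
    d$hard <- as.numeric(d$absVD <= med)
    d$easy <- 1 - d$hard
    d
  }
  if (per_subject) {
    parts <- lapply(split(design, design$subject_id), split_one)
    design <- do.call(rbind, parts)
    rownames(design) <- NULL
    design
  } else {
    split_one(design)
  }
}
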