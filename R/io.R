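#' Read and write design tables as CSV
#'
#' Designs are stored with the header `subject,trial,left_max,left_min,
#' right_max,right_min` plus the regressor columns; values are euros.
#'
#' @param design Design table.
#' @param path CSV path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns an `acc_design` data frame (regressors recomputed if absent).
#' @export
write_design <- function(design, path) {
  d <- as.data.frame(design)
  names(d)[names(d) == "subject_id"] <- "subject"
  names(d)[names(d) == "trial_id"] <- "trial"
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- read.csv(path)
  names(d)[names(d) == "subject"] <- "subject_id"
  names(d)[names(d) == "trial"] <- "trial_id"
  compute_regressors(d)
}

#' Read and write behaviour tables as CSV
#'
#' Behaviour is stored as `subject,trial,choice,rt_ms` with choices coded
#' `L`/`R` and missed responses as empty cells; RTs are in milliseconds in
#' the file and seconds in memory.  A YAML sidecar (`<path>.yaml`) records
#' the deadline and time unit.
#'
#' @param behavior Behaviour rows.
#' @param path CSV path.
#' @param deadline Deadline (s) recorded in the sidecar; taken from the
#'   `deadline` attribute when present.
#' @return `write_behavior()` returns `path` invisibly; `read_behavior()`
#'   returns an `acc_behavior` data frame with the deadline attribute set
#'   from the sidecar when available.
#' @export
write_behavior <- function(behavior, path, deadline = NULL) {
  b <- as.data.frame(behavior)
  if (is.null(deadline)) deadline <- attr(behavior, "deadline")
  out <- data.frame(
    subject = b$subject_id,
    trial = b$trial_id,
    choice = ifelse(b$choice == "left", "L",
                    ifelse(b$choice == "right", "R", NA)),
    rt_ms = round(b$rt * 1000, 3)
  )
  write.csv(out, path, row.names = FALSE, na = "")
  yaml::write_yaml(list(time_unit = "ms",
                        deadline_s = if (is.null(deadline)) NA else deadline),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  b <- read.csv(path)
  out <- data.frame(
    subject_id = b$subject,
    trial_id = b$trial,
    choice = ifelse(is.na(b$choice) | b$choice == "", "missed",
                    ifelse(b$choice == "L", "left", "right")),
    rt = b$rt_ms / 1000
  )
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    cfg <- yaml::read_yaml(sidecar)
    if (!is.null(cfg$deadline_s) && !is.na(cfg$deadline_s)) {
      attr(out, "deadline") <- cfg$deadline_s
    }
  }
  class(out) <- c("acc_behavior", "data.frame")
  out
}
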