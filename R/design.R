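#' Build a design specification for one experiment
#'
#' The paradigm presents two sequential Gabor targets (T1, T2) separated by
#' a 250 ms SOA, with a response cue selecting which one to report. The
#' discrimination experiments cross tilt (clockwise / counterclockwise) and
#' reference axis (vertical / horizontal) independently per stimulus with
#' per-stimulus contrast and the cued target, yielding
#' 2^7 = 128 unique design cells. The estimation experiment crosses only
#' per-stimulus contrast and cue (8 cells) and draws both stimulus
#' orientations uniformly from 0-179 degrees on every trial.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param repetitions_per_cell replicates of each design cell per session.
#'   Defaults: 3 for the discrimination experiments (128 x 3 = 384 trials
#'   per session) and 40 for the estimation experiment (8 x 40 x 2 sessions
#'   = 640 trials).
#' @param sessions number of sessions (default 3 for exp1/exp2, 2 for exp3).
#' @param contrast_levels named vector giving Michelson contrast fractions
#'   for the `"high"` and `"low"` labels. Defaults: 0.64 / 0.04 for exp1,
#'   0.64 / 0.16 for exp2 and exp3.
#' @return An object of class `"design_spec"`.
#' @export
#' @examples
#' spec <- design_spec("exp1")
#' nrow(enumerate_trials(spec, seed = 1))  # 1152
design_spec <- function(experiment = c("exp1", "exp2", "exp3"),
                        repetitions_per_cell = NULL,
                        sessions = NULL,
                        contrast_levels = NULL) {
  experiment <- match.arg(experiment)
  repetitions_per_cell <- repetitions_per_cell %||%
    switch(experiment, exp1 = 3L, exp2 = 3L, exp3 = 40L)
  sessions <- sessions %||% switch(experiment, exp1 = 3L, exp2 = 3L, exp3 = 2L)
  contrast_levels <- contrast_levels %||%
    if (experiment == "exp1") c(high = 0.64, low = 0.04) else c(high = 0.64, low = 0.16)
  if (repetitions_per_cell < 1) stop_input("repetitions_per_cell must be >= 1")
  if (sessions < 1) stop_input("sessions must be >= 1")
  if (!all(c("high", "low") %in% names(contrast_levels)))
    stop_input("contrast_levels must be named with 'high' and 'low'")
  structure(list(
    experiment = experiment,
    repetitions_per_cell = as.integer(repetitions_per_cell),
    sessions = as.integer(sessions),
    contrast_levels = contrast_levels,
    soa_ms = 250,
    stimulus_duration_ms = if (experiment == "exp1") 100 else 50
  ), class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Design spec: %s | %d session(s) x %d repetition(s)/cell\n",
              x$experiment, x$sessions, x$repetitions_per_cell))
  cat(sprintf("  contrasts high/low = %.2f/%.2f, SOA %d ms, duration %d ms\n",
              x$contrast_levels[["high"]], x$contrast_levels[["low"]],
              x$soa_ms, x$stimulus_duration_ms))
  invisible(x)
}

#' Enumerate a full factorial trial plan
#'
#' Builds the complete crossing of design factors, replicates each cell
#' `repetitions_per_cell` times within every session, and shuffles trial
#' order within session with a seeded generator, so the same seed always
#' yields the same plan. For the estimation experiment only contrast and
#' cue are crossed; the two stimulus orientations are sampled independently
#' and uniformly from 0-179 degrees per trial.
#'
#' @param spec a [design_spec()].
#' @param seed integer seed controlling shuffling (and exp3 orientations).
#' @param participant participant label stamped on every row (default 1).
#' @return A data frame with one row per trial and columns
#'   `participant, session, trial, experiment, t1_contrast, t2_contrast,
#'   cue, t1_tilt, t1_axis, t2_tilt, t2_axis, t1_ori, t2_ori` (tilt/axis
#'   columns are `NA` for exp3; orientation columns are `NA` for exp1/2).
#' @export
enumerate_trials <- function(spec, seed = NULL, participant = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  cl <- spec$contrast_levels
  if (spec$experiment %in% c("exp1", "exp2")) {
    cells <- expand.grid(
      t1_contrast = unname(cl), t2_contrast = unname(cl),
      cue = c("T1", "T2"),
      t1_tilt = c("cw", "ccw"), t1_axis = c("vertical", "horizontal"),
      t2_tilt = c("cw", "ccw"), t2_axis = c("vertical", "horizontal"),
      stringsAsFactors = FALSE)
  } else {
    cells <- expand.grid(
      t1_contrast = unname(cl), t2_contrast = unname(cl),
      cue = c("T1", "T2"),
      stringsAsFactors = FALSE)
    cells$t1_tilt <- NA_character_; cells$t1_axis <- NA_character_
    cells$t2_tilt <- NA_character_; cells$t2_axis <- NA_character_
  }
  with_seed(seed, {
    per_session <- lapply(seq_len(spec$sessions), function(s) {
      block <- cells[rep(seq_len(nrow(cells)), times = spec$repetitions_per_cell), ]
      block <- block[sample.int(nrow(block)), ]
      block$session <- s
      block
    })
    plan <- do.call(rbind, per_session)
    rownames(plan) <- NULL
    n <- nrow(plan)
    if (spec$experiment == "exp3") {
      plan$t1_ori <- as.numeric(sample(0:179, n, replace = TRUE))
      plan$t2_ori <- as.numeric(sample(0:179, n, replace = TRUE))
    } else {
      plan$t1_ori <- NA_real_; plan$t2_ori <- NA_real_
    }
    plan$participant <- participant
    plan$trial <- stats::ave(seq_len(n), plan$session, FUN = seq_along)
    plan$experiment <- spec$experiment
    plan[, c("participant", "session", "trial", "experiment",
             "t1_contrast", "t2_contrast", "cue",
             "t1_tilt", "t1_axis", "t2_tilt", "t2_axis",
             "t1_ori", "t2_ori")]
  })
}

#' Enumerate a multi-participant trial plan
#'
#' Convenience wrapper calling [enumerate_trials()] once per participant
#' with participant-specific seeds derived from `seed`.
#'
#' @inheritParams enumerate_trials
#' @param participants number of participants.
#' @return Row-bound trial plan across participants.
#' @export
enumerate_cohort <- function(spec, participants, seed = NULL) {
  stopifnot(participants >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, participants))
  do.call(rbind, lapply(seq_len(participants), function(p)
    enumerate_trials(spec, seed = seeds[p], participant = p)))
}
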