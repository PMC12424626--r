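#' Asymptotic accuracy of a 1-up/N-down staircase
#'
#' A staircase that makes the task harder after `n_correct_down`
#' consecutive correct responses and easier after a single error converges
#' where the probability of a down step equals that of an up step, i.e. at
#' the percent-correct `p` solving `p^N = 0.5`.
#'
#' @param n_correct_down number of consecutive correct responses required
#'   before difficulty increases (`N >= 1`).
#' @return The asymptotic proportion correct `0.5^(1/N)`.
#' @export
#' @examples
#' staircase_convergence_accuracy(5)  # ~0.8706, the ~87% training target
#' staircase_convergence_accuracy(3)  # ~0.7937, the ~80% training target
staircase_convergence_accuracy <- function(n_correct_down) {
  if (!is.numeric(n_correct_down) || length(n_correct_down) != 1L ||
      n_correct_down < 1 || n_correct_down != round(n_correct_down))
    stop_input("n_correct_down must be a single integer >= 1")
  0.5^(1 / n_correct_down)
}

#' Staircase configuration
#'
#' @param n_correct_down consecutive correct responses required for a
#'   down (harder) step; 5 for the first discrimination experiment, 3 for
#'   the later ones.
#' @param start_tilt_deg starting tilt in degrees (default: `max_tilt_deg`).
#' @param step_deg tilt change per step in degrees.
#' @param max_tilt_deg ceiling tilt; a threshold at the ceiling flags
#'   non-convergence (the training rule repeats the staircase).
#' @param min_tilt_deg floor tilt (tilts cannot go below this).
#' @param n_interleaved number of interleaved staircases run trial-by-trial.
#' @param stop_reversals reversals per staircase before stopping.
#' @param max_trials hard cap on total trials across staircases.
#' @param burn_in_reversals reversals discarded before averaging.
#' @return An object of class `"staircase_config"`.
#' @export
staircase_config <- function(n_correct_down = 5L,
                             start_tilt_deg = NULL,
                             step_deg = 0.4,
                             max_tilt_deg = 8,
                             min_tilt_deg = 0.1,
                             n_interleaved = 2L,
                             stop_reversals = 12L,
                             max_trials = 600L,
                             burn_in_reversals = 2L) {
  if (n_correct_down < 1) stop_input("n_correct_down must be >= 1")
  if (!(step_deg > 0 && step_deg < max_tilt_deg))
    stop_input("step_deg must be in (0, max_tilt_deg)")
  start_tilt_deg <- start_tilt_deg %||% max_tilt_deg
  structure(list(
    n_correct_down = as.integer(n_correct_down),
    start_tilt_deg = start_tilt_deg, step_deg = step_deg,
    max_tilt_deg = max_tilt_deg, min_tilt_deg = min_tilt_deg,
    n_interleaved = as.integer(n_interleaved),
    stop_reversals = as.integer(stop_reversals),
    max_trials = as.integer(max_trials),
    burn_in_reversals = as.integer(burn_in_reversals)
  ), class = "staircase_config")
}

#' Simulate an adaptive 1-up/N-down thresholding run
#'
#' Runs `n_interleaved` staircases, alternating trial-by-trial. Each
#' staircase lowers the tilt by `step_deg` after `n_correct_down`
#' consecutive correct responses and raises it after any error. A run
#' stops once every staircase has logged `stop_reversals` reversals (or at
#' `max_trials`). The threshold of each staircase is the mean of its
#' reversal tilts after discarding the first `burn_in_reversals`; the
#' run's threshold is their mean. A run whose threshold reaches the
#' ceiling tilt is flagged as non-converged, mirroring the training rule
#' that repeats staircasing in that case.
#'
#' @param config a [staircase_config()].
#' @param observer function mapping tilt in degrees to probability of a
#'   correct response (must return values in `[0, 1]`).
#' @param seed integer seed for the simulated responses.
#' @return A list of class `"staircase_run"` with elements
#'   `threshold_deg`, `converged`, `per_staircase` (threshold per
#'   staircase), and `trial_log` (data frame of staircase, tilt, correct,
#'   reversal).
#' @export
run_staircase <- function(config, observer, seed = NULL) {
  stopifnot(inherits(config, "staircase_config"), is.function(observer))
  with_seed(seed, {
    k <- config$n_interleaved
    state <- lapply(seq_len(k), function(i) list(
      tilt = config$start_tilt_deg, streak = 0L, last_dir = 0L,
      reversals = numeric(0), log = list()))
    done <- function(s) length(s$reversals) >= config$stop_reversals
    n_tot <- 0L
    while (n_tot < config$max_trials && !all(vapply(state, done, logical(1)))) {
      for (i in seq_len(k)) {
        s <- state[[i]]
        if (done(s)) next
        p <- observer(s$tilt)
        if (!is.finite(p) || p < 0 || p > 1)
          stop_input("observer returned a probability outside [0, 1]")
        correct <- runif(1) < p
        dir <- 0L
        if (correct) {
          s$streak <- s$streak + 1L
          if (s$streak >= config$n_correct_down) { dir <- -1L; s$streak <- 0L }
        } else {
          s$streak <- 0L
          dir <- 1L
        }
        reversal <- FALSE
        if (dir != 0L) {
          if (s$last_dir != 0L && dir != s$last_dir) {
            s$reversals <- c(s$reversals, s$tilt)
            reversal <- TRUE
          }
          s$last_dir <- dir
          s$tilt <- min(config$max_tilt_deg,
                        max(config$min_tilt_deg, s$tilt + dir * config$step_deg))
        }
        s$log[[length(s$log) + 1L]] <- c(i, s$tilt, correct, reversal)
        state[[i]] <- s
        n_tot <- n_tot + 1L
      }
    }
    per_sc <- vapply(state, function(s) {
      r <- s$reversals
      if (length(r) > config$burn_in_reversals)
        mean(r[-seq_len(config$burn_in_reversals)])
      else if (length(r)) mean(r) else NA_real_
    }, numeric(1))
    threshold <- mean(per_sc)
    # a threshold within one step of the ceiling means the staircase was
    # pinned at the maximum tilt: treat as the repeat-staircasing case
    converged <- all(is.finite(per_sc)) &&
      all(per_sc < config$max_tilt_deg - config$step_deg) &&
      all(vapply(state, done, logical(1)))
    log_mat <- do.call(rbind, unlist(lapply(state, `[[`, "log"), recursive = FALSE))
    trial_log <- data.frame(staircase = log_mat[, 1], tilt = log_mat[, 2],
                            correct = as.logical(log_mat[, 3]),
                            reversal = as.logical(log_mat[, 4]))
    structure(list(threshold_deg = threshold, converged = converged,
                   per_staircase = per_sc, trial_log = trial_log,
                   config = config),
              class = "staircase_run")
  })
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf("Staircase run: threshold %.2f deg (%s), %d trials\n",
              x$threshold_deg, if (x$converged) "converged" else "NOT converged",
              nrow(x$trial_log)))
  invisible(x)
}
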