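#' Per-trial orientation errors relative to target and non-target
#'
#' Computes, for every trial of an estimation trial table, the signed
#' circular error of the reported orientation relative to the cued target
#' (`error_target`) and relative to the other stimulus
#' (`error_nontarget`), both in `(-90, 90]` degrees.
#'
#' @param trials estimation trial table with `response_ori`, `t1_ori`,
#'   `t2_ori` and `cue` columns.
#' @return A data frame of class `"trial_errors"` with columns
#'   `error_target`, `error_nontarget`, `delta` (signed non-target minus
#'   target orientation difference) plus any bookkeeping columns
#'   (`participant`, `session`, `trial`, contrasts, `cue`, `visibility`)
#'   present in the input.
#' @export
trial_errors <- function(trials) {
  check_columns(trials, c("response_ori", "t1_ori", "t2_ori", "cue"),
                "estimation trial table")
  tori <- ifelse(trials$cue == "T1", trials$t1_ori, trials$t2_ori)
  nori <- ifelse(trials$cue == "T1", trials$t2_ori, trials$t1_ori)
  keep <- intersect(c("participant", "session", "trial", "t1_contrast",
                      "t2_contrast", "cue", "visibility"), names(trials))
  out <- cbind(trials[, keep, drop = FALSE],
               data.frame(error_target = circ_diff_ori(trials$response_ori, tori),
                          error_nontarget = circ_diff_ori(trials$response_ori, nori),
                          delta = circ_diff_ori(nori, tori)))
  class(out) <- c("trial_errors", "data.frame")
  out
}

as_trial_errors <- function(errors) {
  if (inherits(errors, "trial_errors")) return(errors)
  check_columns(errors, c("error_target", "error_nontarget"), "errors table")
  errors
}

#' Log-likelihood of the three-component orientation mixture
#'
#' The probability density of a reported orientation `R` on trial `n` is
#' modelled as a mixture of a von Mises centred on the target, a von Mises
#' centred on the non-target (the swap component, sharing the same
#' circular SD `sigma`), and a uniform guess component:
#' `alpha * vm(R - T) + beta * vm(R - N) + gamma / (2 * pi)`,
#' with `gamma = 1 - alpha - beta` and all densities per radian of doubled
#' angle.
#'
#' @param alpha,beta mixture weights of the target and swap components
#'   (`alpha, beta >= 0`, `alpha + beta <= 1`).
#' @param sigma_deg shared circular SD of the von Mises components,
#'   in orientation degrees.
#' @param errors a [trial_errors()] table (or any data frame with
#'   `error_target` and `error_nontarget` columns, degrees).
#' @return The summed log-likelihood over trials.
#' @export
mixture_loglik <- function(alpha, beta, sigma_deg, errors) {
  errors <- as_trial_errors(errors)
  if (alpha < 0 || beta < 0 || alpha + beta > 1 + 1e-12)
    stop_input("mixture weights must satisfy alpha, beta >= 0 and alpha + beta <= 1")
  if (nrow(errors) < 1) stop_input("at least one trial is required")
  kappa <- kappa_from_sd(sigma_deg)
  loglik_kappa(alpha, beta, kappa,
               errors$error_target, errors$error_nontarget)
}

loglik_kappa <- function(alpha, beta, kappa, e_t, e_n) {
  gamma <- 1 - alpha - beta
  dens <- alpha * vm_density_kappa(e_t, kappa) +
    beta * vm_density_kappa(e_n, kappa) + gamma / (2 * pi)
  sum(log(pmax(dens, 1e-300)))
}

# unconstrained parameterization: softmax logits for (alpha, beta) against
# a reference gamma logit of 0, and a logit-scaled log-sigma inside bounds
par_to_theta <- function(par, sigma_bounds) {
  w <- exp(c(par[[1]], par[[2]], 0))
  w <- w / sum(w)
  ls <- log(sigma_bounds)
  sigma <- exp(ls[1] + (ls[2] - ls[1]) * stats::plogis(par[[3]]))
  list(alpha = w[[1]], beta = w[[2]], sigma_deg = sigma)
}

theta_to_par <- function(alpha, beta, sigma_deg, sigma_bounds) {
  gamma <- max(1 - alpha - beta, 1e-6)
  ls <- log(sigma_bounds)
  frac <- (log(sigma_deg) - ls[1]) / (ls[2] - ls[1])
  c(log(max(alpha, 1e-6) / gamma), log(max(beta, 1e-6) / gamma),
    stats::qlogis(min(max(frac, 1e-6), 1 - 1e-6)))
}

#' Fit the orientation-report mixture model by maximum likelihood
#'
#' Maximizes [mixture_loglik()] over `alpha, beta >= 0`,
#' `alpha + beta <= 1` and `sigma` within `sigma_bounds`, using
#' multi-start Nelder-Mead on an unconstrained reparameterization
#' (softmax weight simplex, bounded log sigma). Deterministic given
#' `seed`.
#'
#' @param errors a [trial_errors()] table.
#' @param n_restarts number of random starting points (default 10).
#' @param seed integer seed controlling the random starts.
#' @param sigma_bounds lower/upper bounds on `sigma` in degrees.
#' @param min_trials minimum number of trials required to attempt a fit.
#' @return An object of class `"vmmix"` with components `alpha`, `beta`,
#'   `gamma`, `sigma_deg`, `loglik`, `n`, `converged`, `boundary` (TRUE
#'   when the fitted sigma sits at a bound, where target and guess
#'   components become hard to tell apart), `restarts` (per-restart log)
#'   and the input `errors`. Supports `print`, `summary`, `coef`,
#'   `logLik`, `predict`, `simulate` and `plot` methods.
#' @export
#' @examples
#' set.seed(1)
#' err <- data.frame(error_target = rvm_error(200, 12),
#'                   error_nontarget = runif(200, -90, 90))
#' fit <- fit_mixture(err, n_restarts = 3, seed = 1)
#' coef(fit)
fit_mixture <- function(errors, n_restarts = 10L, seed = NULL,
                        sigma_bounds = c(0.5, 45), min_trials = 20L) {
  errors <- as_trial_errors(errors)
  n <- nrow(errors)
  if (n < min_trials)
    stop_input(sprintf("only %d trials; at least %d required for a stable fit",
                       n, min_trials))
  if (n_restarts < 1) stop_input("n_restarts must be >= 1")
  e_t <- errors$error_target
  e_n <- errors$error_nontarget

  negll <- function(par) {
    th <- par_to_theta(par, sigma_bounds)
    kappa <- kappa_from_sd(th$sigma_deg)
    -loglik_kappa(th$alpha, th$beta, kappa, e_t, e_n)
  }

  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      if (i == 1L) {
        # moment-flavoured start: most mass on target, sigma from the
        # central spread of target-relative errors
        s0 <- stats::sd(e_t[abs(e_t) < 45])
        theta_to_par(0.75, 0.1, min(max(s0, sigma_bounds[1] * 1.5),
                                    sigma_bounds[2] * 0.9), sigma_bounds)
      } else {
        w <- stats::rexp(3); w <- w / sum(w)
        theta_to_par(w[1], w[2],
                     exp(stats::runif(1, log(sigma_bounds[1] * 1.2),
                                      log(sigma_bounds[2] * 0.9))),
                     sigma_bounds)
      }
    })
  })

  restarts <- lapply(starts, function(p0) {
    opt <- stats::optim(p0, negll, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-10))
    c(value = opt$value, convergence = opt$convergence, opt$par)
  })
  vals <- vapply(restarts, `[[`, numeric(1), "value")
  best <- restarts[[which.min(vals)]]
  th <- par_to_theta(unname(best[3:5]), sigma_bounds)
  alpha <- th$alpha; beta <- th$beta
  gamma <- 1 - alpha - beta
  sig <- th$sigma_deg
  boundary <- sig <= sigma_bounds[1] * 1.01 || sig >= sigma_bounds[2] * 0.99
  structure(list(
    alpha = alpha, beta = beta, gamma = gamma, sigma_deg = sig,
    loglik = -best[["value"]], n = n,
    converged = best[["convergence"]] == 0,
    boundary = boundary,
    n_restarts = n_restarts,
    restarts = do.call(rbind, restarts),
    sigma_bounds = sigma_bounds,
    errors = errors,
    call = match.call()
  ), class = "vmmix")
}

#' @export
print.vmmix <- function(x, digits = 3, ...) {
  cat("Orientation-report mixture model (target / swap / guess)\n")
  cat(sprintf("  n = %d trials, logLik = %.2f%s\n", x$n, x$loglik,
              if (x$boundary) " [sigma at bound]" else ""))
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.vmmix <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, gamma = object$gamma,
    sigma_deg = object$sigma_deg)
}

#' @export
logLik.vmmix <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}

#' @export
summary.vmmix <- function(object, ...) {
  resp <- predict(object, type = "responsibility")
  out <- list(coef = coef(object), loglik = object$loglik, n = object$n,
              converged = object$converged, boundary = object$boundary,
              mean_responsibility = colMeans(resp))
  class(out) <- "summary.vmmix"
  out
}

#' @export
print.summary.vmmix <- function(x, digits = 3, ...) {
  cat("Orientation-report mixture model\n")
  cat(sprintf("  n = %d, logLik = %.2f, converged = %s, sigma at bound = %s\n",
              x$n, x$loglik, x$converged, x$boundary))
  cat("  parameters:\n"); print(round(x$coef, digits))
  cat("  mean posterior responsibilities (target / swap / guess):\n")
  print(round(x$mean_responsibility, digits))
  invisible(x)
}

#' Predict from a fitted orientation mixture
#'
#' @param object a [fit_mixture()] result.
#' @param newdata optional errors table; defaults to the fitting data.
#' @param type `"density"` returns the mixture density per trial;
#'   `"responsibility"` returns the per-trial posterior probabilities of
#'   the target, swap and guess components (rows sum to 1).
#' @param ... unused.
#' @return Numeric vector (`"density"`) or 3-column matrix
#'   (`"responsibility"`).
#' @export
predict.vmmix <- function(object, newdata = NULL,
                          type = c("responsibility", "density"), ...) {
  type <- match.arg(type)
  errors <- as_trial_errors(newdata %||% object$errors)
  kappa <- kappa_from_sd(object$sigma_deg)
  w_t <- object$alpha * vm_density_kappa(errors$error_target, kappa)
  w_n <- object$beta * vm_density_kappa(errors$error_nontarget, kappa)
  w_g <- rep.int(object$gamma / (2 * pi), nrow(errors))
  tot <- w_t + w_n + w_g
  if (type == "density") return(tot)
  cbind(target = w_t / tot, swap = w_n / tot, guess = w_g / tot)
}

#' Simulate error tables from a fitted mixture
#'
#' Draws new `(error_target, error_nontarget)` pairs at the fitted
#' parameters, reusing the target/non-target separations of the fitting
#' data so the swap geometry is preserved.
#'
#' @param object a `"vmmix"` fit whose errors table has a `delta` column.
#' @param nsim number of simulated tables.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` data frames with columns `error_target`,
#'   `error_nontarget`, `delta` and `component`.
#' @export
simulate.vmmix <- function(object, nsim = 1, seed = NULL, ...) {
  errors <- object$errors
  if (is.null(errors$delta))
    stop_input("simulate() needs a 'delta' column; fit on trial_errors() output")
  delta <- errors$delta
  n <- length(delta)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      u <- runif(n)
      comp <- ifelse(u < object$alpha, "target",
                     ifelse(u < object$alpha + object$beta, "swap", "guess"))
      noise <- rvm_error(n, object$sigma_deg)
      e_t <- ifelse(comp == "target", noise,
                    ifelse(comp == "swap", circ_diff_ori(delta + noise, 0),
                           runif(n, -90, 90)))
      data.frame(error_target = e_t,
                 error_nontarget = circ_diff_ori(e_t - delta, 0),
                 delta = delta, component = comp)
    })
  })
}

#' Plot a fitted orientation mixture
#'
#' Histogram of target-relative errors with the fitted target + guess
#' density overlaid (the swap component has no fixed position on this
#' axis and is shown as its average contribution).
#'
#' @param x a `"vmmix"` fit.
#' @param breaks histogram breaks (degrees).
#' @param ... passed to [graphics::hist()].
#' @export
plot.vmmix <- function(x, breaks = seq(-90, 90, by = 7.5), ...) {
  e <- x$errors$error_target
  graphics::hist(e, breaks = breaks, freq = FALSE,
                 xlab = "error relative to target (deg)",
                 main = "Orientation-report mixture fit", ...)
  grid_deg <- seq(-90, 90, length.out = 361)
  # density per degree of orientation = density per radian * (2 pi / 180)
  scale <- 2 * pi / 180
  kappa <- kappa_from_sd(x$sigma_deg)
  dens <- (x$alpha * vm_density_kappa(grid_deg, kappa) +
             (x$beta + x$gamma) / (2 * pi)) * scale
  graphics::lines(grid_deg, dens, lwd = 2)
  invisible(x)
}

#' Stochastic trial tagging over repeated mixture fits
#'
#' Repeats the mixture fit `n_iterations` times from fresh random starting
#' points (the data stay fixed). On each iteration the per-trial component
#' scores -- `alpha * vm(error_target)`, `beta * vm(error_nontarget)` and
#' `gamma / (2 * pi)` -- are normalized to a categorical distribution and
#' one label (target / swap / guess) is sampled per trial with a single
#' uniform draw. The per-trial tag probabilities are the label frequencies
#' across iterations, and the condition-level SD estimate is the fitted
#' sigma averaged across iterations.
#'
#' @param errors a [trial_errors()] table.
#' @param n_iterations number of fit-and-tag iterations (default 1000).
#' @param n_restarts random starts per iteration (default 2).
#' @param seed integer seed.
#' @param weighted if `TRUE` (default) component scores are weighted by
#'   the mixture weights (posterior responsibilities); `FALSE` normalizes
#'   raw component densities only, for sensitivity analysis.
#' @param bootstrap if `TRUE`, each iteration refits on a resample of the
#'   trials (with replacement) while tagging all original trials; off by
#'   default.
#' @param sigma_bounds,min_trials passed to [fit_mixture()].
#' @return An object of class `"tag_result"`: `p` (n x 3 matrix of
#'   per-trial probabilities summing to 1), `labels` (n x n_iterations
#'   integer matrix, 1 = target, 2 = swap, 3 = guess), `fits` (per-
#'   iteration alpha, beta, gamma, sigma, loglik), `sigma_deg` (mean
#'   fitted sigma), `n_iterations`, and the `errors` table.
#' @export
tag_trials <- function(errors, n_iterations = 1000L, n_restarts = 2L,
                       seed = NULL, weighted = TRUE, bootstrap = FALSE,
                       sigma_bounds = c(0.5, 45), min_trials = 20L) {
  errors <- as_trial_errors(errors)
  if (n_iterations < 1) stop_input("n_iterations must be >= 1")
  n <- nrow(errors)
  with_seed(seed, {
    labels <- matrix(NA_integer_, n, n_iterations)
    fits <- matrix(NA_real_, n_iterations, 5,
                   dimnames = list(NULL, c("alpha", "beta", "gamma",
                                           "sigma_deg", "loglik")))
    iter_seeds <- sample.int(.Machine$integer.max, n_iterations)
    for (it in seq_len(n_iterations)) {
      fit_data <- if (bootstrap)
        errors[sample.int(n, n, replace = TRUE), , drop = FALSE] else errors
      fit <- fit_mixture(fit_data, n_restarts = n_restarts,
                         seed = iter_seeds[it], sigma_bounds = sigma_bounds,
                         min_trials = min_trials)
      kappa <- kappa_from_sd(fit$sigma_deg)
      if (weighted) {
        w_t <- fit$alpha * vm_density_kappa(errors$error_target, kappa)
        w_n <- fit$beta * vm_density_kappa(errors$error_nontarget, kappa)
        w_g <- rep.int(fit$gamma / (2 * pi), n)
      } else {
        w_t <- vm_density_kappa(errors$error_target, kappa)
        w_n <- vm_density_kappa(errors$error_nontarget, kappa)
        w_g <- rep.int(1 / (2 * pi), n)
      }
      tot <- w_t + w_n + w_g
      p_t <- w_t / tot; p_n <- w_n / tot
      u <- runif(n)
      labels[, it] <- ifelse(u < p_t, 1L, ifelse(u < p_t + p_n, 2L, 3L))
      fits[it, ] <- c(fit$alpha, fit$beta, fit$gamma, fit$sigma_deg, fit$loglik)
    }
    p <- cbind(target = rowMeans(labels == 1L),
               swap = rowMeans(labels == 2L),
               guess = rowMeans(labels == 3L))
    structure(list(p = p, labels = labels, fits = as.data.frame(fits),
                   sigma_deg = mean(fits[, "sigma_deg"]),
                   n_iterations = as.integer(n_iterations),
                   weighted = weighted, errors = errors),
              class = "tag_result")
  })
}

#' @export
print.tag_result <- function(x, digits = 3, ...) {
  cat(sprintf("Trial tagging over %d iterations (%d trials)\n",
              x$n_iterations, nrow(x$p)))
  cat(sprintf("  mean p(target/swap/guess) = %s; mean sigma = %.2f deg\n",
              paste(round(colMeans(x$p), digits), collapse = "/"),
              x$sigma_deg))
  invisible(x)
}

#' Mixture-based condition estimates for an estimation cohort
#'
#' Splits an estimation trial table by participant and condition (cued
#' target x target contrast x non-target contrast), removes trials marked
#' "missed" (visibility level 2), runs [tag_trials()] in each cell, and
#' assembles the per-cell measures: fitted circular SD (averaged over
#' iterations) and the percentage of trials tagged as swaps and guesses.
#' Cells below the trial floor are excluded with a warning and reported in
#' the `excluded` attribute.
#'
#' @param trials estimation trial table (with responses).
#' @param n_iterations,n_restarts,seed,weighted,sigma_bounds,min_trials
#'   passed to [tag_trials()].
#' @param visibility_max keep trials with visibility at or below this
#'   level (default 1, i.e. drop "missed" trials); `Inf` keeps all.
#' @return A data frame of class `"condition_estimates"` with one row per
#'   participant x condition: `participant, target, target_contrast,
#'   nontarget_contrast, alpha, beta, gamma, sigma_deg, swap_pct,
#'   guess_pct, n_trials`, with the per-cell [tag_trials()] objects in
#'   attribute `"tags"` (named `participant|target|tc|nc`).
#' @export
condition_estimates <- function(trials, n_iterations = 1000L, n_restarts = 2L,
                                seed = NULL, weighted = TRUE,
                                visibility_max = 1L,
                                sigma_bounds = c(0.5, 45), min_trials = 20L) {
  check_columns(trials, c("participant", "cue", "t1_contrast", "t2_contrast",
                          "response_ori", "t1_ori", "t2_ori"),
                "estimation trial table")
  if (is.finite(visibility_max)) {
    check_columns(trials, "visibility", "estimation trial table")
    trials <- trials[trials$visibility <= visibility_max, , drop = FALSE]
  }
  errs <- trial_errors(trials)
  tc <- ifelse(errs$cue == "T1", errs$t1_contrast, errs$t2_contrast)
  nc <- ifelse(errs$cue == "T1", errs$t2_contrast, errs$t1_contrast)
  errs$target_contrast <- contrast_label(tc)
  errs$nontarget_contrast <- contrast_label(nc)
  key <- interaction(errs$participant, errs$cue, errs$target_contrast,
                     errs$nontarget_contrast, sep = "|", drop = TRUE)
  groups <- split(seq_len(nrow(errs)), key)
  cell_seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(groups)))
  rows <- list(); tags <- list(); excluded <- character(0)
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    cell <- errs[idx, , drop = FALSE]
    nm <- names(groups)[gi]
    if (length(idx) < min_trials) {
      excluded <- c(excluded, nm)
      next
    }
    tg <- tag_trials(cell, n_iterations = n_iterations,
                     n_restarts = n_restarts, seed = cell_seeds[gi],
                     weighted = weighted, sigma_bounds = sigma_bounds,
                     min_trials = min_trials)
    tags[[nm]] <- tg
    rows[[nm]] <- data.frame(
      participant = cell$participant[1], target = cell$cue[1],
      target_contrast = cell$target_contrast[1],
      nontarget_contrast = cell$nontarget_contrast[1],
      alpha = mean(tg$fits$alpha), beta = mean(tg$fits$beta),
      gamma = mean(tg$fits$gamma), sigma_deg = tg$sigma_deg,
      swap_pct = 100 * mean(tg$p[, "swap"]),
      guess_pct = 100 * mean(tg$p[, "guess"]),
      n_trials = length(idx))
  }
  if (length(excluded))
    warning("excluded cells below the ", min_trials, "-trial floor: ",
            paste(excluded, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tags") <- tags
  attr(out, "excluded") <- excluded
  class(out) <- c("condition_estimates", "data.frame")
  out
}
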