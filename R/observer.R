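#' Label contrast fractions as high or low
#'
#' The paradigm uses two contrast levels per experiment (0.64 vs 0.04 or
#' 0.16 Michelson). Any fraction at or above 0.5 is labelled `"high"`.
#'
#' @param contrast numeric Michelson fractions.
#' @return Character vector of `"high"` / `"low"`.
#' @export
contrast_label <- function(contrast) ifelse(contrast >= 0.5, "high", "low")

#' The eight analysis conditions
#'
#' Canonical grid of cued target x target contrast x non-target contrast,
#' in the row order used by the parameter constructors.
#'
#' @return An 8-row data frame with columns `target`, `target_contrast`,
#'   `nontarget_contrast`.
#' @export
condition_grid <- function() expand.grid(
  target = c("T1", "T2"),
  target_contrast = c("high", "low"),
  nontarget_contrast = c("high", "low"),
  stringsAsFactors = FALSE)

#' Observer parameters for the orientation-estimation task
#'
#' One row per condition (cued target x target contrast x non-target
#' contrast), giving the generative mixture for that condition: with
#' probability `guess_rate` the report is uniform over orientation, with
#' probability `swap_rate` it is the non-target orientation plus von Mises
#' noise, and otherwise the target orientation, shifted toward the
#' non-target by `bias_gain * b(|delta|)` degrees (see
#' [attraction_profile()]), plus von Mises noise of circular SD `sd_deg`.
#' `p_missed` is the probability of a visibility "missed" report.
#'
#' Defaults emulate the qualitative pattern of the study: weaker (lower
#' contrast) targets are reported less precisely and swapped more often,
#' high-contrast non-targets increase swaps and lower precision, T1 suffers
#' more than T2 and carries an attractive bias toward T2, and the average
#' missed-report rate is 14.91%.
#'
#' @param sd_deg,swap_rate,guess_rate,bias_gain,p_missed optional length-8
#'   numeric vectors (condition order of the returned grid) or single
#'   values recycled to all 8 conditions; `NULL` keeps the defaults.
#' @return Data frame of class `"estimation_params"` with columns
#'   `target, target_contrast, nontarget_contrast, sd_deg, swap_rate,
#'   guess_rate, bias_gain, p_missed`.
#' @export
estimation_params <- function(sd_deg = NULL, swap_rate = NULL,
                              guess_rate = NULL, bias_gain = NULL,
                              p_missed = NULL) {
  g <- condition_grid()
  t1 <- g$target == "T1"
  tc_hi <- g$target_contrast == "high"
  nc_hi <- g$nontarget_contrast == "high"
  g$sd_deg <- ifelse(tc_hi, 11, 14) + ifelse(nc_hi, 1.6, 0) + ifelse(t1, 2.5, -2.5)
  g$swap_rate <- pmax(0.01,
                      ifelse(t1, 0.13, 0.04) +
                        ifelse(tc_hi, -0.07, 0.07) + ifelse(nc_hi, 0.04, -0.04))
  g$guess_rate <- 0.03
  g$bias_gain <- ifelse(t1, 2.5, 0)
  g$p_missed <- 0.1491
  for (nm in c("sd_deg", "swap_rate", "guess_rate", "bias_gain", "p_missed")) {
    val <- get(nm)
    if (!is.null(val)) g[[nm]] <- rep(val, length.out = 8L)
  }
  if (any(g$swap_rate + g$guess_rate > 1))
    stop_input("swap_rate + guess_rate must not exceed 1")
  if (any(g$sd_deg <= 0)) stop_input("sd_deg must be positive")
  if (any(g$p_missed < 0 | g$p_missed > 1)) stop_input("p_missed must be in [0, 1]")
  class(g) <- c("estimation_params", "data.frame")
  g
}

#' Observer parameters for the tilt-discrimination task
#'
#' Equal-variance signal-detection observer: the internal decision
#' variable is Normal(+d'/2, 1) for clockwise and Normal(-d'/2, 1) for
#' counterclockwise tilts of the cued target; the response is clockwise
#' when the variable exceeds `criterion`. Defaults build in the
#' suppression pattern of the study: sensitivity rises with target
#' contrast (+0.9 d' high vs low), falls with non-target contrast
#' (-0.4 d'), is higher for T2, and stimuli are missed (visibility level
#' 3) on 8.73% of trials.
#'
#' @param dprime,criterion,p_missed,p_unsure optional length-8 vectors or
#'   scalars as in [estimation_params()]; `p_unsure` is the probability of
#'   an intermediate (level 2) visibility report among seen trials.
#' @return Data frame of class `"discrimination_params"`.
#' @export
discrimination_params <- function(dprime = NULL, criterion = NULL,
                                  p_missed = NULL, p_unsure = NULL) {
  g <- condition_grid()
  g$dprime <- 1.7 +
    ifelse(g$target_contrast == "high", 0.45, -0.45) +
    ifelse(g$nontarget_contrast == "high", -0.2, 0.2) +
    ifelse(g$target == "T2", 0.4, -0.4)
  g$criterion <- 0
  g$p_missed <- 0.0873
  g$p_unsure <- 0.1
  for (nm in c("dprime", "criterion", "p_missed", "p_unsure")) {
    val <- get(nm)
    if (!is.null(val)) g[[nm]] <- rep(val, length.out = 8L)
  }
  if (any(g$dprime < 0)) stop_input("dprime must be non-negative")
  if (any(g$p_missed < 0 | g$p_missed > 1)) stop_input("p_missed must be in [0, 1]")
  class(g) <- c("discrimination_params", "data.frame")
  g
}

#' Attractive-bias profile over orientation difference
#'
#' Derivative-of-Gaussian-shaped attraction used by the synthetic
#' estimation observer: zero at zero separation, peaking at
#' `peak_deg` with unit height, decaying for larger separations. The
#' generated shift toward the non-target is `bias_gain *
#' attraction_profile(|delta|)` degrees.
#'
#' @param delta_abs_deg absolute target/non-target orientation difference
#'   in degrees.
#' @param peak_deg separation at which attraction peaks (default 25).
#' @return Attraction values in `[0, 1]`.
#' @export
attraction_profile <- function(delta_abs_deg, peak_deg = 25) {
  x <- delta_abs_deg / peak_deg
  x * exp((1 - x^2) / 2)
}

lookup_conditions <- function(trials, params) {
  target_c <- ifelse(trials$cue == "T1", trials$t1_contrast, trials$t2_contrast)
  nontarget_c <- ifelse(trials$cue == "T1", trials$t2_contrast, trials$t1_contrast)
  key <- paste(trials$cue, contrast_label(target_c), contrast_label(nontarget_c))
  pkey <- paste(params$target, params$target_contrast, params$nontarget_contrast)
  idx <- match(key, pkey)
  if (anyNA(idx))
    stop_input("observer parameters missing for condition(s): ",
               paste(unique(key[is.na(idx)]), collapse = "; "))
  idx
}

#' Simulate orientation-estimation responses
#'
#' Applies the generative mixture of [estimation_params()] to every trial
#' of an estimation (exp3) trial plan.
#'
#' @param plan trial plan from [enumerate_trials()] with `t1_ori`/`t2_ori`.
#' @param params an [estimation_params()] table covering every condition.
#' @param seed integer seed.
#' @param visibility_mode `"independent"` (default) samples missed reports
#'   independently of the response; `"missed_guess"` additionally forces
#'   missed trials to be uniform guesses, for stress-testing visibility
#'   filtering.
#' @return The plan with added columns `response_ori` (degrees in
#'   `[0, 180)`), `response_tilt` (`NA`), `visibility` (1 = seen,
#'   2 = missed) and `rt` (`NA`).
#' @export
simulate_estimation_responses <- function(plan, params = estimation_params(),
                                          seed = NULL,
                                          visibility_mode = c("independent", "missed_guess")) {
  visibility_mode <- match.arg(visibility_mode)
  check_columns(plan, c("cue", "t1_contrast", "t2_contrast", "t1_ori", "t2_ori"),
                "estimation plan")
  if (anyNA(plan$t1_ori) || anyNA(plan$t2_ori))
    stop_input("estimation plan has missing orientations; is this an exp3 plan?")
  idx <- lookup_conditions(plan, params)
  n <- nrow(plan)
  with_seed(seed, {
    tori <- ifelse(plan$cue == "T1", plan$t1_ori, plan$t2_ori)
    nori <- ifelse(plan$cue == "T1", plan$t2_ori, plan$t1_ori)
    u <- runif(n)
    p_guess <- params$guess_rate[idx]
    p_swap <- params$swap_rate[idx]
    comp <- ifelse(u < p_guess, "guess",
                   ifelse(u < p_guess + p_swap, "swap", "target"))
    visibility <- ifelse(runif(n) < params$p_missed[idx], 2L, 1L)
    if (visibility_mode == "missed_guess") comp[visibility == 2L] <- "guess"
    # von Mises noise drawn per condition so each group shares one sigma
    noise <- numeric(n)
    for (j in unique(idx)) {
      sel <- idx == j
      noise[sel] <- rvm_error(sum(sel), params$sd_deg[j])
    }
    delta <- circ_diff_ori(nori, tori)          # signed, toward non-target
    shift <- params$bias_gain[idx] * attraction_profile(abs(delta)) * sign(delta)
    resp <- ifelse(comp == "target", tori + shift + noise,
                   ifelse(comp == "swap", nori + noise, runif(n, 0, 180)))
    plan$response_ori <- wrap_orientation(resp)
    plan$response_tilt <- NA_character_
    plan$visibility <- visibility
    plan$rt <- NA_real_
    plan
  })
}

#' Simulate tilt-discrimination responses
#'
#' Equal-variance signal-detection generator for the discrimination
#' (exp1/exp2) experiments; see [discrimination_params()].
#'
#' @param plan trial plan with tilt/axis columns.
#' @param params a [discrimination_params()] table.
#' @param seed integer seed.
#' @return The plan with added columns `response_tilt` (`"cw"`/`"ccw"`),
#'   `response_ori` (`NA`), `visibility` (1-3) and `rt` (`NA`).
#' @export
simulate_discrimination_responses <- function(plan, params = discrimination_params(),
                                              seed = NULL) {
  check_columns(plan, c("cue", "t1_contrast", "t2_contrast", "t1_tilt", "t2_tilt"),
                "discrimination plan")
  idx <- lookup_conditions(plan, params)
  n <- nrow(plan)
  with_seed(seed, {
    tilt <- ifelse(plan$cue == "T1", plan$t1_tilt, plan$t2_tilt)
    mu <- ifelse(tilt == "cw", 0.5, -0.5) * params$dprime[idx]
    x <- rnorm(n, mean = mu, sd = 1)
    plan$response_tilt <- ifelse(x > params$criterion[idx], "cw", "ccw")
    plan$response_ori <- NA_real_
    miss <- runif(n) < params$p_missed[idx]
    unsure <- runif(n) < params$p_unsure[idx]
    plan$visibility <- ifelse(miss, 3L, ifelse(unsure, 2L, 1L))
    plan$rt <- NA_real_
    plan
  })
}
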