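#' Filter trials by reported visibility
#'
#' Keeps trials whose visibility level is at or below `max_allowed_level`
#' (level 3 = "missed at least one stimulus" in the discrimination
#' experiments, level 2 = "missed" in the estimation experiment). The
#' removed fraction per participant is attached as attribute
#' `"removed"`.
#'
#' @param trials trial table with a `visibility` column.
#' @param max_allowed_level highest visibility level retained.
#' @return Filtered trial table; `attr(., "removed")` is a data frame of
#'   per-participant removed fractions and `attr(., "removed_overall")`
#'   the pooled fraction.
#' @export
filter_by_visibility <- function(trials, max_allowed_level) {
  check_columns(trials, "visibility", "trial table")
  check_columns(trials, "participant", "trial table")
  keep <- trials$visibility <= max_allowed_level
  removed <- stats::aggregate(list(removed_fraction = !keep),
                              by = list(participant = trials$participant),
                              FUN = mean)
  out <- trials[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  attr(out, "removed_overall") <- mean(!keep)
  out
}

#' Signal-detection d-prime from response counts
#'
#' Computes `d' = z(hit rate) - z(false-alarm rate)` with clockwise tilts
#' as the signal class. Extreme rates (0 or 1) make `z` infinite, so a
#' correction is applied before the transform: `"loglinear"` (default)
#' adds 0.5 to each count and 1 to each total; `"clamp"` replaces 0 and 1
#' by `1/(2N)` and `1 - 1/(2N)`; `"none"` applies no correction.
#'
#' @param hits,misses,false_alarms,correct_rejections non-negative counts.
#' @param correction extreme-rate correction.
#' @return d-prime in z units.
#' @export
#' @examples
#' compute_dprime(84, 16, 16, 84, correction = "none")  # ~2
compute_dprime <- function(hits, misses, false_alarms, correct_rejections,
                           correction = c("loglinear", "clamp", "none")) {
  correction <- match.arg(correction)
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0)) stop_input("counts must be non-negative")
  n_sig <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_sig == 0 || n_noise == 0)
    stop_input("insufficient data: empty ",
               if (n_sig == 0) "signal (cw)" else "noise (ccw)", " class")
  hr <- switch(correction,
               loglinear = (hits + 0.5) / (n_sig + 1),
               clamp = min(max(hits / n_sig, 1 / (2 * n_sig)), 1 - 1 / (2 * n_sig)),
               none = hits / n_sig)
  far <- switch(correction,
                loglinear = (false_alarms + 0.5) / (n_noise + 1),
                clamp = min(max(false_alarms / n_noise, 1 / (2 * n_noise)),
                            1 - 1 / (2 * n_noise)),
                none = false_alarms / n_noise)
  stats::qnorm(hr) - stats::qnorm(far)
}

#' Condition-wise d-prime table for a discrimination cohort
#'
#' Splits trials into the eight conditions (cued target x target contrast
#' x non-target contrast; tilt axes are pooled), tallies hits / misses /
#' false alarms / correct rejections of the cued target's tilt (clockwise
#' = signal), and computes d-prime per participant x condition.
#'
#' @param trials discrimination trial table (with `response_tilt`).
#' @param correction passed to [compute_dprime()].
#' @return Data frame with columns `participant, target, target_contrast,
#'   nontarget_contrast, hits, misses, false_alarms, correct_rejections,
#'   n_trials, dprime`. Errors if any participant is missing one of the 8
#'   cells.
#' @export
build_dprime_table <- function(trials, correction = "loglinear") {
  check_columns(trials, c("participant", "cue", "t1_contrast", "t2_contrast",
                          "t1_tilt", "t2_tilt", "response_tilt"),
                "discrimination trial table")
  tilt <- ifelse(trials$cue == "T1", trials$t1_tilt, trials$t2_tilt)
  tc <- contrast_label(ifelse(trials$cue == "T1",
                              trials$t1_contrast, trials$t2_contrast))
  nc <- contrast_label(ifelse(trials$cue == "T1",
                              trials$t2_contrast, trials$t1_contrast))
  df <- data.frame(participant = trials$participant, target = trials$cue,
                   target_contrast = tc, nontarget_contrast = nc,
                   signal = tilt == "cw",
                   said_cw = trials$response_tilt == "cw")
  agg <- stats::aggregate(
    cbind(hits = df$signal & df$said_cw,
          misses = df$signal & !df$said_cw,
          false_alarms = !df$signal & df$said_cw,
          correct_rejections = !df$signal & !df$said_cw) ~
      participant + target + target_contrast + nontarget_contrast,
    data = df, FUN = sum)
  agg$n_trials <- agg$hits + agg$misses + agg$false_alarms + agg$correct_rejections
  counts <- table(agg$participant)
  if (any(counts != 8))
    stop_input("incomplete design: participant(s) ",
               paste(names(counts)[counts != 8], collapse = ", "),
               " missing condition cells")
  agg$dprime <- mapply(compute_dprime, agg$hits, agg$misses,
                       agg$false_alarms, agg$correct_rejections,
                       MoreArgs = list(correction = correction))
  agg[order(agg$participant, agg$target, agg$target_contrast,
            agg$nontarget_contrast), ]
}

anova_effects <- list(
  target_contrast = c("target_contrast"),
  nontarget_contrast = c("nontarget_contrast"),
  target = c("target"),
  `target_contrast:nontarget_contrast` = c("target_contrast", "nontarget_contrast"),
  `target_contrast:target` = c("target_contrast", "target"),
  `nontarget_contrast:target` = c("nontarget_contrast", "target"),
  `target_contrast:nontarget_contrast:target` =
    c("target_contrast", "nontarget_contrast", "target"))

#' 2x2x2 repeated-measures ANOVA on a participant x condition measure
#'
#' With three two-level within-participant factors, every effect has one
#' numerator degree of freedom and is equivalent to a one-sample t-test on
#' the per-participant contrast score (+/-1 coding over the 8 cells):
#' `F = t^2` with `df = (1, n - 1)`, and partial eta squared
#' `t^2 / (t^2 + n - 1)`. Main effects additionally report the estimated
#' marginal mean difference (EMMD, high minus low, or T2 minus T1) with a
#' t-based 95% confidence interval over the per-participant differences.
#'
#' @param table data frame with columns `participant, target,
#'   target_contrast, nontarget_contrast` and the measure column `value`
#'   (specify another name with `value_col`). Must be complete and
#'   balanced: 8 cells per participant.
#' @param value_col name of the measure column (default `"dprime"` if
#'   present, else `"value"`).
#' @param subset_target optionally restrict to `"T1"` or `"T2"`; the
#'   target factor is then dropped and a 2x2 ANOVA (3 effects) is run.
#' @return Data frame of class `"rm_anova"`: one row per effect with
#'   `effect, F, df1, df2, p, partial_eta_sq, emmd, ci_lo, ci_hi` (EMMD
#'   columns are `NA` for interactions).
#' @export
rm_anova_2x2x2 <- function(table, value_col = NULL, subset_target = NULL) {
  value_col <- value_col %||% if ("dprime" %in% names(table)) "dprime" else "value"
  factors <- c("target_contrast", "nontarget_contrast", "target")
  if (!is.null(subset_target)) {
    table <- table[table$target == subset_target, , drop = FALSE]
    factors <- setdiff(factors, "target")
  }
  check_columns(table, c("participant", factors, value_col), "measure table")
  cells_per <- 2^length(factors)
  tab <- table(table$participant)
  if (length(tab) < 2) stop_input("at least 2 participants required")
  if (any(tab != cells_per))
    stop_input("incomplete or unbalanced design: expected ", cells_per,
               " cells per participant")
  n <- length(tab)
  value <- table[[value_col]]
  codes <- lapply(factors, function(f) {
    lv <- table[[f]]
    if (f == "target") ifelse(lv == "T2", 1, -1) else ifelse(lv == "high", 1, -1)
  })
  names(codes) <- factors
  effects <- Filter(function(e) all(e %in% factors), anova_effects)
  rows <- lapply(names(effects), function(nm) {
    fs <- effects[[nm]]
    code <- Reduce(`*`, codes[fs])
    # per-participant marginal mean difference on this contrast
    d <- tapply(value * code, table$participant, mean) * 2
    if (stats::sd(d) == 0) {
      # all participants identical on this contrast: F is 0 for a null
      # effect and unbounded for a constant nonzero one
      t_stat <- if (mean(d) == 0) 0 else Inf
    } else {
      t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
    }
    Fv <- t_stat^2
    p <- stats::pf(Fv, 1, n - 1, lower.tail = FALSE)
    pes <- Fv / (Fv + n - 1)
    is_main <- length(fs) == 1
    half <- stats::qt(0.975, n - 1) * stats::sd(d) / sqrt(n)
    data.frame(effect = nm, F = Fv, df1 = 1, df2 = n - 1, p = p,
               partial_eta_sq = pes,
               emmd = if (is_main) mean(d) else NA_real_,
               ci_lo = if (is_main) mean(d) - half else NA_real_,
               ci_hi = if (is_main) mean(d) + half else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_participants") <- n
  attr(out, "value_col") <- value_col
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Repeated-measures ANOVA on '%s' (n = %d participants)\n",
              attr(x, "value_col"), attr(x, "n_participants")))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Two-tailed paired t-test
#'
#' Thin wrapper used for the per-condition high-vs-low non-target
#' contrasts. Zero-variance differences with a non-zero mean are reported
#' as infinite `t` with `p = 0` and a `degenerate` flag rather than an
#' error.
#'
#' @param values_a,values_b equal-length paired numeric vectors.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop_input("paired vectors must have equal length")
  if (length(values_a) < 2) stop_input("at least 2 pairs required")
  d <- values_a - values_b
  if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) < 1e-12)
      return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate), degenerate = FALSE)
}
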