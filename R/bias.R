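#' Signed orientation error toward the non-target
#'
#' Re-signs the target-relative error so that positive values mean the
#' report was displaced from the target along the shorter circular path
#' toward the non-target. Trials with identical target and non-target
#' orientations have no defined direction and return `NA`.
#'
#' @param errors a [trial_errors()] table (needs `error_target` and
#'   `delta` columns), or pass `error_target` and `delta` directly.
#' @param error_target,delta optional numeric vectors used when `errors`
#'   is missing: target-relative error and signed non-target minus target
#'   difference, degrees in `(-90, 90]`.
#' @return Numeric vector of signed errors in degrees (positive = toward
#'   the non-target); `NA` where `delta == 0`.
#' @export
#' @examples
#' signed_error_toward_nontarget(error_target = 5, delta = 30)   # +5
#' signed_error_toward_nontarget(error_target = -5, delta = 30)  # -5
signed_error_toward_nontarget <- function(errors = NULL, error_target = NULL,
                                          delta = NULL) {
  if (!is.null(errors)) {
    errors <- as_trial_errors(errors)
    error_target <- errors$error_target
    delta <- errors$delta
  }
  out <- error_target * sign(delta)
  out[delta == 0] <- NA_real_
  out
}

#' Per-participant bias curves over target/non-target separation
#'
#' Bins trials by the absolute target/non-target orientation difference
#' `|delta|` and averages the signed error toward the non-target within
#' each bin, per participant. When tagging results are supplied the
#' analysis is restricted to likely-target trials: with
#' `selection = "sampled"` (default) the restriction is applied per
#' tagging iteration (trials whose sampled label is "target") and the
#' per-iteration curves are averaged; `"argmax"` keeps trials whose
#' averaged tag probability is highest for the target component;
#' `"all"` uses every trial (which inflates apparent bias whenever swaps
#' are present).
#'
#' @param errors a [trial_errors()] table with a `participant` column.
#' @param tags optional named list of [tag_trials()] results (one per
#'   participant, names = participant ids) or a single `tag_result` when
#'   `errors` holds one participant; required unless `selection = "all"`.
#' @param selection `"sampled"`, `"argmax"` or `"all"`.
#' @param bin_width bin width in degrees over `(0, 90]` (default 15).
#' @param min_trials bins with fewer trials for a participant are masked
#'   (`NA`); default 5.
#' @return Object of class `"bias_curves"`: list with `bin_centers`,
#'   `curves` (participants x bins matrix of mean signed errors),
#'   `group_mean`, `group_sem`, `n_per_bin`, `bin_width`, `selection`.
#' @export
build_bias_curves <- function(errors, tags = NULL,
                              selection = c("sampled", "argmax", "all"),
                              bin_width = 15, min_trials = 5L) {
  selection <- match.arg(selection)
  errors <- as_trial_errors(errors)
  check_columns(errors, c("participant", "delta"), "errors table")
  if (selection != "all" && is.null(tags))
    stop_input("tagging results are required unless selection = \"all\"")
  if (inherits(tags, "tag_result")) {
    ids <- unique(errors$participant)
    if (length(ids) != 1)
      stop_input("a single tag_result was given for multiple participants")
    tags <- stats::setNames(list(tags), as.character(ids))
  }
  breaks <- seq(0, 90, by = bin_width)
  if (breaks[length(breaks)] < 90) breaks <- c(breaks, 90)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  parts <- sort(unique(errors$participant))
  curves <- matrix(NA_real_, length(parts), length(centers),
                   dimnames = list(as.character(parts), NULL))
  n_per_bin <- curves
  for (pi in seq_along(parts)) {
    sel <- errors$participant == parts[pi]
    e <- errors[sel, , drop = FALSE]
    s_err <- signed_error_toward_nontarget(e)
    bin <- cut(abs(e$delta), breaks = breaks, labels = FALSE)
    ok <- !is.na(s_err) & !is.na(bin)
    keep_w <- NULL
    if (selection == "argmax") {
      tg <- tags[[as.character(parts[pi])]]
      if (is.null(tg)) stop_input("no tags for participant ", parts[pi])
      lab <- max.col(tg$p, ties.method = "first")
      ok <- ok & (lab == 1L)
    }
    for (b in seq_along(centers)) {
      in_bin <- ok & bin == b
      nb <- sum(in_bin)
      if (selection == "sampled") {
        tg <- tags[[as.character(parts[pi])]]
        if (is.null(tg)) stop_input("no tags for participant ", parts[pi])
        # per-iteration mean over trials sampled as "target", then average
        L <- tg$labels[in_bin, , drop = FALSE] == 1L
        v <- s_err[in_bin]
        cnt <- colSums(L)
        means <- colSums(L * v) / cnt
        usable <- cnt >= 1L
        nb <- round(mean(cnt))
        curves[pi, b] <- if (sum(in_bin) >= min_trials && any(usable))
          mean(means[usable]) else NA_real_
      } else {
        curves[pi, b] <- if (nb >= min_trials) mean(s_err[in_bin]) else NA_real_
      }
      n_per_bin[pi, b] <- nb
    }
    if (all(is.na(curves[pi, ])))
      stop_input("all bins masked for participant ", parts[pi],
                 "; too few trials per bin")
  }
  structure(list(bin_centers = centers, curves = curves,
                 group_mean = colMeans(curves, na.rm = TRUE),
                 group_sem = apply(curves, 2, function(v)
                   stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
                 n_per_bin = n_per_bin, bin_width = bin_width,
                 selection = selection),
            class = "bias_curves")
}

#' @export
print.bias_curves <- function(x, digits = 2, ...) {
  cat(sprintf("Bias curves: %d participants x %d bins (width %g deg, selection '%s')\n",
              nrow(x$curves), length(x$bin_centers), x$bin_width, x$selection))
  df <- data.frame(bin_center = x$bin_centers,
                   mean = round(x$group_mean, digits),
                   sem = round(x$group_sem, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.bias_curves <- function(x, ...) {
  m <- x$group_mean; s <- x$group_sem
  graphics::plot(x$bin_centers, m, type = "o", pch = 16,
                 ylim = range(c(m - s, m + s, 0), na.rm = TRUE),
                 xlab = "|target - non-target| orientation difference (deg)",
                 ylab = "signed error toward non-target (deg)", ...)
  graphics::arrows(x$bin_centers, m - s, x$bin_centers, m + s,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Cluster-corrected permutation test on bias curves
#'
#' Tests the group bias curve against zero (one-sample) or the difference
#' of two aligned curve sets (paired) while controlling the family-wise
#' error over bins. Per bin, a t statistic is computed across
#' participants; contiguous runs of bins with `|t|` above the two-tailed
#' critical value at `cluster_alpha` form clusters with mass `sum(|t|)`.
#' The null distribution is the maximum cluster mass over random
#' participant-wise sign flips (zero null) or condition-label swaps
#' (difference null, equivalent to sign flips of the paired differences);
#' each observed cluster's corrected p is the proportion of null maxima at
#' or above its mass (with the +1 correction).
#'
#' @param curves a [build_bias_curves()] object or participants x bins
#'   matrix.
#' @param curves_b optional second curve set for a paired condition
#'   difference (`null = "condition_difference"`).
#' @param null `"zero"` or `"condition_difference"`.
#' @param n_permutations at least 100 (default 1000).
#' @param cluster_alpha cluster-forming alpha (default 0.05).
#' @param seed integer seed for the permutations.
#' @return Object of class `"cluster_result"`: data frame `clusters`
#'   (`start_bin, end_bin, mass, p_corrected`), plus `t_values`,
#'   `t_threshold`, `n_permutations`, `cluster_alpha`, `bin_centers`.
#' @export
cluster_permutation_test <- function(curves, curves_b = NULL,
                                     null = c("zero", "condition_difference"),
                                     n_permutations = 1000L,
                                     cluster_alpha = 0.05, seed = NULL) {
  null <- match.arg(null)
  if (n_permutations < 100)
    stop_input("n_permutations must be at least 100 for usable corrected p-values")
  centers <- NULL
  if (inherits(curves, "bias_curves")) {
    centers <- curves$bin_centers
    curves <- curves$curves
  }
  if (inherits(curves_b, "bias_curves")) curves_b <- curves_b$curves
  X <- as.matrix(curves)
  if (null == "condition_difference") {
    if (is.null(curves_b)) stop_input("curves_b required for the difference null")
    if (!all(dim(curves_b) == dim(X)))
      stop_input("condition curve sets must be aligned (same participants and bins)")
    X <- X - as.matrix(curves_b)
  }
  if (anyNA(X)) {
    keep <- colSums(is.na(X)) == 0
    if (!any(keep)) stop_input("no bins without missing values")
    X <- X[, keep, drop = FALSE]
    if (!is.null(centers)) centers <- centers[keep]
  }
  n <- nrow(X); nb <- ncol(X)
  if (n < 2) stop_input("at least 2 participants required")
  t_of <- function(m, v) m / sqrt(v / n)
  obs_mean <- colMeans(X)
  obs_var <- apply(X, 2, stats::var)
  t_obs <- t_of(obs_mean, obs_var)
  t_thr <- stats::qt(1 - cluster_alpha / 2, n - 1)

  find_clusters <- function(tv) {
    supra <- abs(tv) > t_thr
    if (!any(supra)) return(NULL)
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    idx <- which(r$values)
    data.frame(start_bin = starts[idx], end_bin = ends[idx],
               mass = vapply(idx, function(i)
                 sum(abs(tv[starts[i]:ends[i]])), numeric(1)))
  }
  obs_clusters <- find_clusters(t_obs)

  # sign flips leave squared values unchanged, so the permuted variance
  # follows from the permuted mean and the fixed sum of squares
  ssq <- colSums(X^2)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                n_permutations, n)
    M <- (S %*% X) / n
    V <- sweep(-M^2, 2, ssq / n, `+`) * n / (n - 1)
    Tm <- M / sqrt(V / n)
    apply(Tm, 1, function(tv) {
      cl <- find_clusters(tv)
      if (is.null(cl)) 0 else max(cl$mass)
    })
  })

  if (!is.null(obs_clusters)) {
    obs_clusters$p_corrected <- vapply(obs_clusters$mass, function(m)
      (sum(null_max >= m) + 1) / (n_permutations + 1), numeric(1))
  } else {
    obs_clusters <- data.frame(start_bin = integer(0), end_bin = integer(0),
                               mass = numeric(0), p_corrected = numeric(0))
  }
  structure(list(clusters = obs_clusters, t_values = t_obs,
                 t_threshold = t_thr, n_permutations = as.integer(n_permutations),
                 cluster_alpha = cluster_alpha, bin_centers = centers,
                 null = null, n_participants = n),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, digits = 3, ...) {
  cat(sprintf("Cluster permutation test (%s null, %d permutations, alpha %.3g)\n",
              x$null, x$n_permutations, x$cluster_alpha))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    df <- x$clusters
    df$mass <- round(df$mass, digits)
    df$p_corrected <- signif(df$p_corrected, digits)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
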