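trial_schema <- c("participant", "session", "trial", "experiment",
                  "t1_contrast", "t2_contrast", "cue",
                  "t1_tilt", "t1_axis", "t2_tilt", "t2_axis",
                  "t1_ori", "t2_ori")
response_schema <- c("response_ori", "response_tilt", "visibility", "rt")
known_contrasts <- c(0.04, 0.16, 0.64)

#' Write a trial table to CSV
#'
#' Serializes the documented trial schema (design columns, then response
#' columns if present) as UTF-8 CSV with a header row and `.` decimals.
#'
#' @param trials trial table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c(intersect(trial_schema, names(trials)),
            intersect(response_schema, names(trials)))
  utils::write.csv(trials[, cols, drop = FALSE], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read and validate a trial table
#'
#' Reads the documented CSV schema, types the columns, wraps orientation
#' columns into `[0, 180)` (with a warning when wrapping changed values),
#' validates contrast fractions against the study's levels (0.04, 0.16,
#' 0.64; other values warn), and rejects duplicate
#' (participant, session, trial) keys.
#'
#' @param path CSV file path.
#' @param experiment expected experiment id (`"exp1"`, `"exp2"`,
#'   `"exp3"`), or `NULL` to accept any.
#' @return Validated trial table.
#' @export
read_trials <- function(path, experiment = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("participant", "session", "trial", "experiment",
                      "t1_contrast", "t2_contrast", "cue"),
                basename(path))
  if (!is.null(experiment) && !all(df$experiment == experiment))
    stop_input("file contains experiment id(s) other than ", experiment)
  key <- paste(df$participant, df$session, df$trial)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop_input("duplicate (participant, session, trial) key at row ", dup,
               ": ", key[dup])
  }
  for (col in intersect(c("t1_ori", "t2_ori", "response_ori"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    wrapped <- wrap_orientation(v)
    changed <- which(!is.na(v) & abs(wrapped - v) > 1e-9)
    if (length(changed))
      warning(length(changed), " value(s) in '", col,
              "' wrapped into [0, 180), first at row ", changed[1])
    df[[col]] <- wrapped
  }
  for (col in c("t1_contrast", "t2_contrast")) {
    v <- as.numeric(df[[col]])
    off <- !is.na(v) & !vapply(v, function(x)
      any(abs(x - known_contrasts) < 1e-9), logical(1))
    if (any(off))
      warning(sum(off), " value(s) in '", col,
              "' outside the standard contrast levels (0.04, 0.16, 0.64)")
    df[[col]] <- v
  }
  if ("visibility" %in% names(df)) df$visibility <- as.integer(df$visibility)
  df
}

#' Run the end-to-end synthetic pipeline
#'
#' Dispatches simulate -> visibility filter -> analysis -> report for one
#' experiment, writing result CSVs plus a sidecar JSON with the fully
#' resolved configuration and seed, so every run is reproducible from
#' (config, seed).
#'
#' For `exp1`/`exp2` the analysis stage is the d-prime table and the
#' 2x2x2 repeated-measures ANOVA; for `exp3` it is the mixture-based
#' condition estimates (SD / swap% / guess%), their ANOVAs, and the
#' cluster-corrected bias test against zero on likely-target trials.
#'
#' @param config named list. Recognized keys (with defaults):
#'   `experiment` ("exp1"), `participants` (8 for exp1, 12 for exp2, 20
#'   for exp3), `seed` (1), `out_dir` (required to write files; `NULL`
#'   returns results only), `visibility_max` (`Inf` for exp1, 2 for exp2,
#'   1 for exp3), `correction` ("loglinear"), `n_iterations` (1000),
#'   `n_restarts` (2), `bin_width` (15), `n_permutations` (1000),
#'   `repetitions_per_cell` / `sessions` (design defaults). Unknown keys
#'   are rejected.
#' @return List of class `"run_report"`: `results` (stage outputs),
#'   `counts` (rows read / analyzed / excluded per stage), `config`
#'   (resolved), `files` (paths written, if any).
#' @export
run_pipeline <- function(config = list()) {
  defaults <- list(experiment = "exp1", participants = NULL, seed = 1L,
                   out_dir = NULL, visibility_max = NULL,
                   correction = "loglinear", n_iterations = 1000L,
                   n_restarts = 2L, bin_width = 15, n_permutations = 1000L,
                   repetitions_per_cell = NULL, sessions = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_input("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  exp <- match.arg(cfg$experiment, c("exp1", "exp2", "exp3"))
  cfg$experiment <- exp
  cfg$participants <- cfg$participants %||%
    switch(exp, exp1 = 8L, exp2 = 12L, exp3 = 20L)
  cfg$visibility_max <- cfg$visibility_max %||%
    switch(exp, exp1 = Inf, exp2 = 2L, exp3 = 1L)

  spec <- design_spec(exp, repetitions_per_cell = cfg$repetitions_per_cell,
                      sessions = cfg$sessions)
  cfg$repetitions_per_cell <- spec$repetitions_per_cell
  cfg$sessions <- spec$sessions
  plan <- enumerate_cohort(spec, cfg$participants, seed = cfg$seed)
  trials <- if (exp == "exp3")
    simulate_estimation_responses(plan, seed = cfg$seed + 1L)
  else simulate_discrimination_responses(plan, seed = cfg$seed + 1L)

  n_read <- nrow(trials)
  filtered <- if (is.finite(cfg$visibility_max))
    filter_by_visibility(trials, cfg$visibility_max) else trials
  n_kept <- nrow(filtered)
  counts <- data.frame(stage = c("simulated", "after_visibility_filter"),
                       rows = c(n_read, n_kept))
  stopifnot(n_read == n_kept + (n_read - n_kept))  # conservation

  results <- list(trials = trials)
  if (exp %in% c("exp1", "exp2")) {
    dtab <- build_dprime_table(filtered, correction = cfg$correction)
    results$dprime_table <- dtab
    results$anova <- rm_anova_2x2x2(dtab)
  } else {
    est <- condition_estimates(filtered, n_iterations = cfg$n_iterations,
                               n_restarts = cfg$n_restarts,
                               seed = cfg$seed + 2L,
                               visibility_max = Inf)  # already filtered
    results$estimates <- est
    results$anova_sd <- rm_anova_2x2x2(est, value_col = "sigma_deg")
    results$anova_swap <- rm_anova_2x2x2(est, value_col = "swap_pct")
    results$anova_guess <- rm_anova_2x2x2(est, value_col = "guess_pct")
    errs <- trial_errors(filtered)
    tags <- attr(est, "tags")
    # pool cells per participant for the bias analysis: curves use each
    # participant's full likely-target trial set
    by_part <- split(errs, errs$participant)
    part_tags <- lapply(names(by_part), function(p) {
      cell_names <- grep(paste0("^", p, "\\|"), names(tags), value = TRUE)
      merge_tag_results(tags[cell_names])
    })
    names(part_tags) <- names(by_part)
    errs_ordered <- do.call(rbind, lapply(names(by_part), function(p)
      attr(part_tags[[p]], "errors_ordered")))
    curves <- build_bias_curves(errs_ordered, tags = part_tags,
                                selection = "sampled",
                                bin_width = cfg$bin_width)
    results$bias_curves <- curves
    results$bias_clusters <- cluster_permutation_test(
      curves, null = "zero", n_permutations = cfg$n_permutations,
      seed = cfg$seed + 3L)
  }

  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(files, write_trials(trials, file.path(cfg$out_dir, "trials.csv")))
    if (exp %in% c("exp1", "exp2")) {
      utils::write.csv(results$dprime_table,
                       file.path(cfg$out_dir, "dprime.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(results$anova),
                       file.path(cfg$out_dir, "anova.csv"), row.names = FALSE)
      files <- c(files, file.path(cfg$out_dir, c("dprime.csv", "anova.csv")))
    } else {
      utils::write.csv(as.data.frame(results$estimates),
                       file.path(cfg$out_dir, "estimates.csv"), row.names = FALSE)
      utils::write.csv(results$bias_clusters$clusters,
                       file.path(cfg$out_dir, "bias_clusters.csv"),
                       row.names = FALSE)
      files <- c(files, file.path(cfg$out_dir, c("estimates.csv",
                                                 "bias_clusters.csv")))
    }
    sidecar <- file.path(cfg$out_dir, "run_config.json")
    jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))], sidecar,
                         auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, sidecar)
  }
  structure(list(results = results, counts = counts, config = cfg,
                 files = files),
            class = "run_report")
}

# combine per-cell tag results for one participant into a single object
# aligned with the row order of the concatenated cell errors
merge_tag_results <- function(tag_list) {
  tag_list <- Filter(Negate(is.null), tag_list)
  stopifnot(length(tag_list) >= 1)
  labels <- do.call(rbind, lapply(tag_list, `[[`, "labels"))
  p <- do.call(rbind, lapply(tag_list, `[[`, "p"))
  errs <- do.call(rbind, lapply(tag_list, `[[`, "errors"))
  out <- structure(list(p = p, labels = labels,
                        fits = do.call(rbind, lapply(tag_list, `[[`, "fits")),
                        sigma_deg = mean(vapply(tag_list, `[[`, numeric(1),
                                                "sigma_deg")),
                        n_iterations = tag_list[[1]]$n_iterations,
                        weighted = tag_list[[1]]$weighted,
                        errors = errs),
                   class = "tag_result")
  attr(out, "errors_ordered") <- errs
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run: %s, %d participants, seed %d\n",
              x$config$experiment, x$config$participants, x$config$seed))
  print(x$counts, row.names = FALSE)
  if (length(x$files)) cat("files:", paste(basename(x$files), collapse = ", "), "\n")
  invisible(x)
}
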