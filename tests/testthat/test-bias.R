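test_that("the sign convention points toward the non-target, with wraparound", {
  expect_equal(signed_error_toward_nontarget(
    error_target = circ_diff_ori(15, 10), delta = circ_diff_ori(40, 10)), 5)
  expect_equal(signed_error_toward_nontarget(
    error_target = circ_diff_ori(5, 10), delta = circ_diff_ori(40, 10)), -5)
  # wraparound: shorter path from 170 to 10 goes up through 180
  expect_equal(signed_error_toward_nontarget(
    error_target = circ_diff_ori(175, 170), delta = circ_diff_ori(10, 170)), 5)
  expect_true(is.na(signed_error_toward_nontarget(error_target = 3, delta = 0)))
})

test_that("the sign convention is antisymmetric and wrap-consistent on a grid", {
  # brute-force oracle over orientation triples: moving the response a
  # small step along the shorter T->N path must always give the positive
  # sign, and the mirrored response the negative sign
  grid <- expand.grid(T = seq(0, 179, by = 13), N = seq(2, 179, by = 17))
  grid <- grid[abs(circ_diff_ori(grid$N, grid$T)) > 2, ]
  step <- 1.5
  for (i in seq_len(nrow(grid))) {
    Tt <- grid$T[i]; Nn <- grid$N[i]
    dir <- sign(circ_diff_ori(Nn, Tt))
    r_toward <- wrap_orientation(Tt + dir * step)
    r_away <- wrap_orientation(Tt - dir * step)
    e_toward <- data.frame(error_target = circ_diff_ori(r_toward, Tt),
                           error_nontarget = circ_diff_ori(r_toward, Nn),
                           delta = circ_diff_ori(Nn, Tt))
    e_away <- e_toward
    e_away$error_target <- circ_diff_ori(r_away, Tt)
    expect_equal(signed_error_toward_nontarget(e_toward), step)
    expect_equal(signed_error_toward_nontarget(e_away), -step)
  }
})

make_bias_errors <- function(n_per_part, participants, shift, noise_sd, seed,
                             delta_range = c(-89, 89)) {
  set.seed(seed)
  out <- lapply(seq_len(participants), function(p) {
    delta <- runif(n_per_part, delta_range[1], delta_range[2])
    delta <- delta[abs(delta) > 1]
    e_t <- shift * sign(delta) + rnorm(length(delta), 0, noise_sd)
    data.frame(participant = p, error_target = e_t,
               error_nontarget = circ_diff_ori(e_t - delta, 0), delta = delta)
  })
  do.call(rbind, out)
}

test_that("bias curves recover a constant planted attraction", {
  errs <- make_bias_errors(600, 6, shift = 5, noise_sd = 6, seed = 50)
  bc <- build_bias_curves(errs, selection = "all")
  expect_equal(length(bc$bin_centers), 6)
  for (b in seq_along(bc$bin_centers)) {
    ci <- bc$group_mean[b] + c(-1, 1) * qt(0.975, 5) * bc$group_sem[b]
    expect_true(ci[1] < 5 & 5 < ci[2] + 1)      # CI covers the planted +5
  }
  # reversing the sign convention flips the curve exactly
  flipped <- errs
  flipped$delta <- -flipped$delta
  bc2 <- build_bias_curves(flipped, selection = "all")
  expect_equal(bc2$group_mean, -bc$group_mean, tolerance = 1e-12)
})

test_that("unbiased generators give curves near zero", {
  plan <- enumerate_cohort(design_spec("exp3", repetitions_per_cell = 700,
                                       sessions = 1), 9, seed = 51)  # ~50000
  tr <- simulate_estimation_responses(
    plan, estimation_params(sd_deg = 12, swap_rate = 0, guess_rate = 0,
                            bias_gain = 0, p_missed = 0), seed = 52)
  bc <- build_bias_curves(trial_errors(tr), selection = "all")
  for (b in seq_along(bc$bin_centers))
    expect_lt(abs(bc$group_mean[b]), 3 * bc$group_sem[b] + 0.2)
})

test_that("cluster tests find nothing in identically-zero curves", {
  X <- matrix(0, 8, 6)
  X <- X + matrix(rnorm(48, 0, 1e-9), 8, 6)     # break exact ties only
  res <- cluster_permutation_test(X, n_permutations = 200, seed = 53)
  # t-values are O(1) noise; no structure should survive correction
  expect_true(nrow(res$clusters) == 0 || all(res$clusters$p_corrected > 0.05))
  expect_error(cluster_permutation_test(X, n_permutations = 50), "at least 100")
})

test_that("an injected cluster is detected where it was planted", {
  set.seed(54)
  found <- vapply(1:20, function(r) {
    X <- matrix(rnorm(20 * 6, 0, 2), 20, 6)
    X[, 2:3] <- X[, 2:3] + 4                    # bins spanning 15-45 deg
    res <- cluster_permutation_test(X, n_permutations = 500, seed = r)
    sig <- res$clusters[res$clusters$p_corrected < 0.05, , drop = FALSE]
    any(sig$start_bin <= 3 & sig$end_bin >= 2)
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("condition-difference nulls use paired differences", {
  set.seed(55)
  A <- matrix(rnorm(10 * 6), 10, 6)
  B <- A + matrix(rnorm(60, 0, 0.1), 10, 6)
  B[, 4] <- B[, 4] + 3
  res <- cluster_permutation_test(A, B, null = "condition_difference",
                                  n_permutations = 500, seed = 56)
  sig <- res$clusters[res$clusters$p_corrected < 0.05, , drop = FALSE]
  expect_true(any(sig$start_bin <= 4 & sig$end_bin >= 4))
  expect_error(cluster_permutation_test(A, B[1:5, ],
                                        null = "condition_difference",
                                        n_permutations = 200), "aligned")
})

test_that("restricting to likely-target trials deflates swap-driven bias", {
  # with swaps present, the all-trials curve absorbs non-target-centred
  # reports and overstates attraction; the tagged restriction removes it
  e <- gen_mixture_errors(800, 0.7, 0.25, 10, seed = 57)
  e$participant <- 1
  tg <- tag_trials(e, n_iterations = 40, n_restarts = 1, seed = 58)
  bc_all <- build_bias_curves(e, selection = "all")
  bc_restricted <- build_bias_curves(e, tags = tg, selection = "sampled")
  m_all <- mean(bc_all$group_mean, na.rm = TRUE)
  m_res <- mean(bc_restricted$group_mean, na.rm = TRUE)
  expect_gt(m_all, m_res)
  # argmax mode agrees in direction
  bc_arg <- build_bias_curves(e, tags = tg, selection = "argmax")
  expect_gt(m_all, mean(bc_arg$group_mean, na.rm = TRUE))
})
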