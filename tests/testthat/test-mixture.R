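test_that("trial errors are wrapped into (-90, 90] with consistent geometry", {
  tr <- data.frame(response_ori = c(175, 5, 100), t1_ori = c(170, 10, 10),
                   t2_ori = c(10, 40, 95), cue = c("T1", "T1", "T2"))
  e <- trial_errors(tr)
  expect_equal(e$error_target, c(5, -5, 5))
  expect_true(all(abs(e$error_nontarget) <= 90))
  # delta is recoverable from the two errors: e_t - e_n = N - T (mod 180)
  expect_equal(circ_diff_ori(e$error_target - e$error_nontarget, 0), e$delta)
})

test_that("pure-guess log-likelihood matches the closed form n * log(1 / 2pi)", {
  set.seed(4)
  err <- data.frame(error_target = runif(100, -90, 90),
                    error_nontarget = runif(100, -90, 90))
  expect_equal(mixture_loglik(0, 0, 10, err), 100 * log(1 / (2 * pi)),
               tolerance = 1e-12)
})

test_that("log-likelihood matches an independent term-by-term oracle", {
  e <- gen_mixture_errors(50, 0.7, 0.2, 12, seed = 5)
  ll <- mixture_loglik(0.8, 0.1, 12, e)
  oracle <- sum(log(0.8 * oracle_vm_density(e$error_target, 12) +
                      0.1 * oracle_vm_density(e$error_nontarget, 12) +
                      0.1 / (2 * pi)))
  expect_equal(ll, oracle, tolerance = 1e-8)
  expect_error(mixture_loglik(-0.1, 0.5, 12, e), "weights")
  expect_error(mixture_loglik(0.7, 0.5, 12, e), "weights")
})

test_that("the likelihood is invariant under relabeling (T,N) with (alpha,beta)", {
  e <- gen_mixture_errors(80, 0.6, 0.25, 10, seed = 6)
  swapped <- data.frame(error_target = e$error_nontarget,
                        error_nontarget = e$error_target)
  expect_equal(mixture_loglik(0.6, 0.25, 10, e),
               mixture_loglik(0.25, 0.6, 10, swapped), tolerance = 1e-12)
})

test_that("fitting recovers degenerate generating regimes", {
  # all-target data: alpha-hat near 1, sigma within a degree
  ok <- vapply(1:20, function(r) {
    e <- gen_mixture_errors(500, 1, 0, 10, seed = 100 + r)
    f <- fit_mixture(e, n_restarts = 4, seed = r)
    f$alpha >= 0.95 && abs(f$sigma_deg - 10) <= 1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # pure-uniform data: gamma-hat dominates
  e <- gen_mixture_errors(500, 0, 0, 10, seed = 7)
  f <- fit_mixture(e, n_restarts = 6, seed = 8)
  expect_gte(f$gamma, 0.9)
})

test_that("the fitted likelihood dominates the generating parameters", {
  for (r in 1:5) {
    e <- gen_mixture_errors(300, 0.7, 0.15, 14, seed = 200 + r)
    f <- fit_mixture(e, n_restarts = 4, seed = r)
    expect_gte(f$loglik + 1e-6, mixture_loglik(0.7, 0.15, 14, e))
    expect_equal(f$alpha + f$beta + f$gamma, 1, tolerance = 1e-12)
  }
})

test_that("relabeling symmetry holds for the full fit", {
  e <- gen_mixture_errors(400, 0.65, 0.2, 12, seed = 9)
  swapped <- data.frame(error_target = e$error_nontarget,
                        error_nontarget = e$error_target, delta = -e$delta)
  f1 <- fit_mixture(e, n_restarts = 5, seed = 3)
  f2 <- fit_mixture(swapped, n_restarts = 5, seed = 3)
  expect_equal(f1$alpha, f2$beta, tolerance = 1e-4)
  expect_equal(f1$beta, f2$alpha, tolerance = 1e-4)
  expect_equal(f1$sigma_deg, f2$sigma_deg, tolerance = 1e-4)
})

test_that("fit guards work: trial floor, restarts, boundary reporting", {
  e <- gen_mixture_errors(10, 0.8, 0.1, 10, seed = 1)
  expect_error(fit_mixture(e), "at least")
  expect_error(fit_mixture(gen_mixture_errors(50, 0.8, 0.1, 10, 1),
                           n_restarts = 0), "n_restarts")
  # data tighter than the lower sigma bound pin the fit at the bound,
  # which is reported, not masked
  eu <- gen_mixture_errors(200, 1, 0, 2, seed = 2)
  f <- fit_mixture(eu, n_restarts = 4, seed = 2, sigma_bounds = c(5, 45))
  expect_true(f$boundary)
})

test_that("vmmix methods are coherent", {
  e <- gen_mixture_errors(300, 0.75, 0.1, 12, seed = 10)
  f <- fit_mixture(e, n_restarts = 5, seed = 4)
  expect_s3_class(f, "vmmix")
  expect_named(coef(f), c("alpha", "beta", "gamma", "sigma_deg"))
  expect_equal(as.numeric(logLik(f)), f$loglik)
  resp <- predict(f, type = "responsibility")
  expect_equal(rowSums(resp), rep(1, nrow(e)), tolerance = 1e-12)
  dens <- predict(f, type = "density")
  expect_true(all(dens > 0))
  sims <- simulate(f, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_identical(simulate(f, seed = 5)[[1]], sims[[1]])
  expect_output(print(f), "mixture")
  expect_output(print(summary(f)), "responsibilities")
})

test_that("tagging yields coherent probabilities and recovers dominant components", {
  e <- gen_mixture_errors(200, 0.85, 0.05, 8, seed = 11)
  tg <- tag_trials(e, n_iterations = 50, n_restarts = 1, seed = 12)
  expect_equal(rowSums(tg$p), rep(1, nrow(e)), tolerance = 1e-12)
  expect_identical(dim(tg$labels), c(nrow(e), 50L))
  # a trial sitting on the target and far from the non-target is tagged
  # target essentially always
  probe <- data.frame(error_target = 0, error_nontarget = 90, delta = 90)
  e2 <- rbind(e[, c("error_target", "error_nontarget", "delta")], probe)
  tg2 <- tag_trials(e2, n_iterations = 50, n_restarts = 1, seed = 13)
  expect_gte(tg2$p[nrow(e2), "target"], 0.99)
  expect_error(tag_trials(e, n_iterations = 0), "n_iterations")
})

test_that("pure-guess data are tagged as guesses", {
  e <- gen_mixture_errors(300, 0, 0, 10, seed = 14)
  tg <- tag_trials(e, n_iterations = 60, n_restarts = 2, seed = 15)
  expect_gte(mean(tg$p[, "guess"]), 0.85)
})

test_that("condition estimates recover the generator's swap ordering", {
  # two participants, swaps high in low-contrast-target cells (25%) and
  # low in high-contrast cells (2%)
  pars <- estimation_params(
    swap_rate = ifelse(condition_grid()$target_contrast == "low", 0.25, 0.02),
    guess_rate = 0.02, bias_gain = 0, p_missed = 0)
  plan <- enumerate_cohort(design_spec("exp3", repetitions_per_cell = 60,
                                       sessions = 2), 2, seed = 16)
  tr <- simulate_estimation_responses(plan, pars, seed = 17)
  est <- condition_estimates(tr, n_iterations = 40, n_restarts = 1, seed = 18)
  expect_equal(nrow(est), 16)                 # 2 participants x 8 cells
  expect_true(all(est$swap_pct >= 0 & est$swap_pct <= 100))
  expect_true(all(est$swap_pct + est$guess_pct <= 100))
  agg <- tapply(est$swap_pct, est$target_contrast, mean)
  expect_gt(agg[["low"]], agg[["high"]])
  # every low-contrast cell above its matching high-contrast cell, per
  # participant and condition pair
  wide <- reshape(est[, c("participant", "target", "target_contrast",
                          "nontarget_contrast", "swap_pct")],
                  direction = "wide", timevar = "target_contrast",
                  idvar = c("participant", "target", "nontarget_contrast"))
  expect_true(all(wide$swap_pct.low > wide$swap_pct.high))
})
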