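test_that("visibility filtering removes exactly the flagged trials", {
  tr <- data.frame(participant = rep(1:2, each = 50),
                   visibility = rep(1L, 100))
  out <- filter_by_visibility(tr, 2)
  expect_equal(nrow(out), 100)
  expect_equal(attr(out, "removed_overall"), 0)
  tr$visibility[sample.int(100, 10)] <- 3L
  out <- filter_by_visibility(tr, 2)
  expect_equal(attr(out, "removed_overall"), 0.10)
  expect_equal(nrow(out) + 10, 100)
  expect_error(filter_by_visibility(tr[, "participant", drop = FALSE], 2),
               "visibility")
})

test_that("missed-trial rates match the generating probability", {
  # exp2-style table with p(level 3) = 0.0873 per trial: the removed
  # fraction falls in the binomial 99% CI around 8.73%
  plan <- enumerate_trials(design_spec("exp2"), seed = 30)   # 1152 trials
  tr <- simulate_discrimination_responses(
    plan, discrimination_params(p_missed = 0.0873), seed = 31)
  out <- filter_by_visibility(tr, 2)
  p <- 0.0873; n <- nrow(plan)
  half <- qnorm(0.995) * sqrt(p * (1 - p) / n)
  expect_lt(abs(attr(out, "removed_overall") - p), half)
})

test_that("d-prime matches its closed forms and corrections", {
  expect_equal(compute_dprime(50, 50, 50, 50, correction = "none"), 0)
  expect_equal(compute_dprime(84134, 15866, 15866, 84134, correction = "none"),
               2, tolerance = 1e-4)
  # perfect 20/20 with log-linear correction
  expect_equal(compute_dprime(20, 0, 0, 20, correction = "loglinear"),
               qnorm(20.5 / 21) - qnorm(0.5 / 21), tolerance = 1e-12)
  expect_error(compute_dprime(0, 0, 5, 5), "signal")
  # antisymmetry under relabeling cw <-> ccw
  expect_equal(compute_dprime(30, 10, 5, 35),
               -compute_dprime(5, 35, 30, 10), tolerance = 1e-12)
})

test_that("the d-prime table recovers generator sensitivity per condition", {
  pars <- discrimination_params(
    dprime = ifelse(condition_grid()$target_contrast == "high", 2.5, 1.3))
  plan <- enumerate_cohort(design_spec("exp2", sessions = 27), 2, seed = 32)
  tr <- simulate_discrimination_responses(plan, pars, seed = 33)
  dt <- build_dprime_table(tr)
  expect_equal(nrow(dt), 16)
  # compare recovered vs generating value cell by cell (1296 trials/cell)
  gen <- pars$dprime[match(paste(dt$target, dt$target_contrast,
                                 dt$nontarget_contrast),
                           paste(pars$target, pars$target_contrast,
                                 pars$nontarget_contrast))]
  expect_true(all(abs(dt$dprime - gen) < 0.3))
  # stimulus-independent responding: all cells near zero
  null_tr <- tr
  set.seed(34)
  null_tr$response_tilt <- sample(c("cw", "ccw"), nrow(tr), replace = TRUE)
  dt0 <- build_dprime_table(null_tr)
  se <- 2 / sqrt(dt0$n_trials)                  # rough d' standard error
  expect_true(all(abs(dt0$dprime) < 3.5 * se))
  # deterministic correct responder: every cell at the correction ceiling
  det <- tr
  det$response_tilt <- ifelse(det$cue == "T1", det$t1_tilt, det$t2_tilt)
  dtd <- build_dprime_table(det)
  ceiling_d <- qnorm((dtd$n_trials / 2 + 0.5) / (dtd$n_trials / 2 + 1)) -
    qnorm(0.5 / (dtd$n_trials / 2 + 1))
  expect_equal(dtd$dprime, ceiling_d, tolerance = 1e-12)
})

test_that("incomplete designs are rejected", {
  plan <- enumerate_cohort(design_spec("exp2", sessions = 1), 2, seed = 35)
  tr <- simulate_discrimination_responses(plan, seed = 36)
  broken <- tr[!(tr$participant == 2 & tr$cue == "T2" &
                   contrast_label(tr$t2_contrast) == "high"), ]
  expect_error(build_dprime_table(broken), "incomplete")
})

test_that("a flat table gives F = 0 and EMMD = 0 everywhere", {
  g <- condition_grid()[rep(1:8, 6), ]
  g$participant <- rep(1:6, each = 8)
  g$value <- rep(1:6, each = 8) * 0.3          # participant offsets only
  res <- rm_anova_2x2x2(g, value_col = "value")
  expect_equal(res$F, rep(0, 7))
  expect_equal(res$emmd[1:3], rep(0, 3))
})

test_that("the ANOVA recovers a planted target-contrast effect", {
  set.seed(37)
  g <- condition_grid()[rep(1:8, 12), ]
  g$participant <- rep(1:12, each = 8)
  g$value <- 1 + 1.0 * (g$target_contrast == "high") + rnorm(96, 0, 0.2)
  res <- rm_anova_2x2x2(g, value_col = "value")
  tc <- res[res$effect == "target_contrast", ]
  expect_true(tc$ci_lo < 1 & 1 < tc$ci_hi)
  for (eff in c("nontarget_contrast", "target")) {
    row <- res[res$effect == eff, ]
    expect_true(row$ci_lo < 0 & 0 < row$ci_hi)
  }
})

test_that("F and p match the classical repeated-measures ANOVA for random tables", {
  set.seed(38)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    g <- condition_grid()[rep(1:8, n), ]
    g$participant <- rep(seq_len(n), each = 8)
    g$value <- rnorm(8 * n, sd = runif(1, 0.5, 2))
    res <- rm_anova_2x2x2(g, value_col = "value")
    d <- g
    d$participant <- factor(d$participant)
    d$A <- factor(d$target_contrast); d$B <- factor(d$nontarget_contrast)
    d$C <- factor(d$target)
    fit <- aov(value ~ A * B * C + Error(participant / (A * B * C)), data = d)
    s <- summary(fit)
    oracle <- vapply(s[-1], function(x) {
      tab <- x[[1]]
      c(tab[["F value"]][1], tab[["Pr(>F)"]][1])
    }, numeric(2))
    strata <- c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")
    ours <- c(target_contrast = "A", nontarget_contrast = "B", target = "C",
              `target_contrast:nontarget_contrast` = "A:B",
              `target_contrast:target` = "A:C",
              `nontarget_contrast:target` = "B:C",
              `target_contrast:nontarget_contrast:target` = "A:B:C")
    idx <- match(ours[res$effect], strata)
    expect_equal(res$F, unname(oracle[1, idx]), tolerance = 1e-6)
    expect_equal(res$p, unname(oracle[2, idx]), tolerance = 1e-6)
  }
})

test_that("ANOVA restricted to one target drops the target factor", {
  set.seed(39)
  g <- condition_grid()[rep(1:8, 5), ]
  g$participant <- rep(1:5, each = 8)
  g$value <- rnorm(40)
  res <- rm_anova_2x2x2(g, value_col = "value", subset_target = "T1")
  expect_equal(nrow(res), 3)
  expect_false("target" %in% res$effect)
})

test_that("paired t-tests behave at the edges and keep nominal type-I error", {
  x <- c(1.2, 0.8, 1.5, 1.1)
  r <- paired_ttest(x, x)
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  set.seed(40)
  r2 <- paired_ttest(x + 1 + rnorm(4, 0, 1e-4), x)
  expect_lt(r2$p, 0.001)
  r3 <- paired_ttest(x + 1, x)                  # zero-variance difference
  expect_true(is.infinite(r3$t) && r3$p == 0 && r3$degenerate)
  expect_error(paired_ttest(1, numeric(0)), "equal length")
  # type-I error at alpha = 0.05 across 10000 null replicates, n = 12
  set.seed(41)
  rej <- vapply(1:10000, function(i) {
    a <- rnorm(12); b <- rnorm(12)
    paired_ttest(a, b)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.044)
  expect_lte(mean(rej), 0.056)
})
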