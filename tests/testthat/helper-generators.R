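# Shared fixtures: error-table generator and independent numeric oracles.

# Draw a mixture error table directly from the generative equation:
# target von Mises / swap von Mises / uniform guess, with random
# target/non-target separations. Independent of the observer module.
gen_mixture_errors <- function(n, alpha, beta, sigma_deg, seed) {
  set.seed(seed)
  comp <- sample(1:3, n, replace = TRUE,
                 prob = c(alpha, beta, max(0, 1 - alpha - beta)))
  delta <- circ_diff_ori(runif(n, 0, 180), runif(n, 0, 180))
  noise <- rvm_error(n, sigma_deg)
  e_t <- ifelse(comp == 1, noise,
                ifelse(comp == 2, circ_diff_ori(delta + noise, 0),
                       runif(n, -90, 90)))
  data.frame(error_target = e_t,
             error_nontarget = circ_diff_ori(e_t - delta, 0),
             delta = delta, component = comp)
}

# Independent kappa oracle: invert sd -> kappa by bisection on A1, without
# the package's Newton solver.
oracle_kappa <- function(sd_deg) {
  s <- sd_deg * 2 * pi / 180
  r_target <- exp(-s^2 / 2)
  f <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE) - r_target
  stats::uniroot(f, c(1e-8, 2e4), tol = 1e-13)$root
}

# Independent mean-zero von Mises density on the doubled-angle circle.
oracle_vm_density <- function(error_deg, sd_deg) {
  k <- oracle_kappa(sd_deg)
  theta <- 2 * error_deg * pi / 180
  exp(k * cos(theta)) / (2 * pi * besselI(k, 0))
}

# Empirical circular SD of orientation errors, in degrees.
circ_sd_deg <- function(err_deg) {
  theta <- 2 * err_deg * pi / 180
  r <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  (180 / (2 * pi)) * sqrt(-2 * log(r))
}

# Cumulative-Gaussian 2AFC observer: chance at zero tilt, ceiling at
# large tilt.
gaussian_observer <- function(mu = 3.5, sd = 1.5) {
  function(tilt) 0.5 + 0.5 * stats::pnorm(tilt, mean = mu, sd = sd)
}
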