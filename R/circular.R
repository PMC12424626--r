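#' Circular helpers for orientation data (period 180 degrees)
#'
#' Orientations live on a half-circle: 0 and 180 degrees are the same
#' stimulus. All circular arithmetic in the package therefore works on the
#' doubled-angle circle, where an orientation difference of `e` degrees maps
#' to an angle `2 * e * pi / 180` radians, and von Mises densities are
#' defined per radian of doubled angle.
#'
#' @name circular-helpers
NULL

#' Wrap orientations into [0, 180)
#'
#' @param ori numeric vector of orientations in degrees.
#' @return Orientations wrapped to `[0, 180)`.
#' @export
#' @examples
#' wrap_orientation(c(-10, 185, 90))
wrap_orientation <- function(ori) ori %% 180

#' Signed circular difference between orientations
#'
#' Returns `a - b` wrapped onto `(-90, 90]` degrees, the signed error along
#' the shorter arc of the orientation half-circle.
#'
#' @param a,b orientations in degrees (any real values; wrapped internally).
#' @return Signed differences in `(-90, 90]`.
#' @export
#' @examples
#' circ_diff_ori(175, 5)   # -10, not 170
circ_diff_ori <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}

#' Convert von Mises concentration to circular SD in orientation degrees
#'
#' The circular SD on the doubled-angle circle is
#' `sqrt(-2 * log(A1(kappa)))` radians, where `A1 = I1/I0` is the mean
#' resultant length; dividing the doubled angle by two converts back to
#' orientation degrees, giving `sd_deg = (180 / (2 * pi)) * sqrt(-2 log A1)`.
#'
#' @param kappa concentration parameter(s), `>= 0`.
#' @return Circular SD in orientation degrees.
#' @export
sd_from_kappa <- function(kappa) {
  stopifnot(all(kappa >= 0))
  r <- a1_bessel(kappa)
  (180 / (2 * pi)) * sqrt(-2 * log(r))
}

# mean resultant length A1(kappa) = I1(kappa) / I0(kappa), computed with
# exponentially scaled Bessel functions for stability at large kappa
a1_bessel <- function(kappa) {
  out <- numeric(length(kappa))
  pos <- kappa > 0
  out[pos] <- besselI(kappa[pos], 1, expon.scaled = TRUE) /
    besselI(kappa[pos], 0, expon.scaled = TRUE)
  out
}

#' Convert circular SD in orientation degrees to von Mises concentration
#'
#' Inverts [sd_from_kappa()] by solving `A1(kappa) = exp(-s^2 / 2)` with
#' `s` the SD in radians of doubled angle, using the classical series
#' approximation for the inverse of `A1` followed by Newton refinement.
#'
#' @param sd_deg circular SD in orientation degrees, `> 0`.
#' @return Concentration `kappa`. SDs too large to invert reliably (beyond
#'   the near-uniform regime, about 81 degrees) return 0 with a warning:
#'   the distribution is then indistinguishable from uniform.
#' @export
kappa_from_sd <- function(sd_deg) {
  stopifnot(length(sd_deg) == 1L, is.finite(sd_deg), sd_deg > 0)
  s <- sd_deg * 2 * pi / 180          # SD in radians of doubled angle
  r <- exp(-s^2 / 2)                  # target mean resultant length
  if (r < 1e-4) {
    warning("circular SD of ", signif(sd_deg, 4),
            " degrees is in the uniform limit; returning kappa = 0")
    return(0)
  }
  # Fisher/Best starting approximation for A1^{-1}(r)
  k <- if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
  # Newton steps on A1(k) - r = 0; A1'(k) = 1 - A1/k - A1^2
  for (i in 1:25) {
    a <- a1_bessel(k)
    deriv <- 1 - a / k - a^2
    step <- (a - r) / deriv
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-12 * max(1, k)) { k <- k_new; break }
    k <- k_new
  }
  k
}

#' von Mises density of an orientation error
#'
#' Density of a mean-zero von Mises on the doubled-angle circle, evaluated
#' at an orientation error in degrees. The density is per radian of doubled
#' angle, so it integrates to 1 over the doubled circle `(-pi, pi]`; the
#' uniform limit is `1 / (2 * pi)`.
#'
#' @param error_deg orientation error(s) in degrees, normally in `(-90, 90]`.
#' @param sigma_deg circular SD of the component in orientation degrees.
#' @return Density values per radian of doubled angle.
#' @export
#' @examples
#' vm_density(0, 12) > vm_density(30, 12)
vm_density <- function(error_deg, sigma_deg) {
  kappa <- kappa_from_sd(sigma_deg)
  vm_density_kappa(error_deg, kappa)
}

# density with kappa already known (used in optimization inner loops)
vm_density_kappa <- function(error_deg, kappa) {
  theta <- 2 * error_deg * pi / 180
  if (kappa == 0) return(rep.int(1 / (2 * pi), length(theta)))
  # exp(k cos t) / (2 pi I0(k)) written with scaled Bessel for stability
  exp(kappa * (cos(theta) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Draw von Mises orientation errors
#'
#' Samples mean-zero von Mises deviates on the doubled-angle circle
#' (Best-Fisher rejection sampler) and returns them as orientation errors
#' in degrees in `(-90, 90]`.
#'
#' @param n number of draws.
#' @param sigma_deg circular SD in orientation degrees.
#' @return Numeric vector of orientation errors in degrees.
#' @export
rvm_error <- function(n, sigma_deg) {
  kappa <- kappa_from_sd(sigma_deg)
  if (kappa < 1e-8) return(runif(n, -90, 90))
  theta <- best_fisher_vm(n, kappa)
  theta * 180 / (2 * pi)
}

# Best & Fisher (1979) von Mises sampler, mean 0, concentration kappa
best_fisher_vm <- function(n, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nk <- sum(ok)
    if (nk) {
      out[(got + 1L):(got + nk)] <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      got <- got + nk
    }
  }
  out
}
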