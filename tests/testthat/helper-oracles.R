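# Independent numerical oracles used to freeze expected values.  These stay
# deliberately naive (series sums, Riemann integration of the generative
# model) and never call the code paths they check.

# modified Bessel function of the first kind by direct series summation
bessel_i_series <- function(x, nu, terms = 80) {
  k <- 0:terms
  sum((x / 2)^(2 * k + nu) / (factorial(k) * gamma(k + nu + 1)))
}

# von Mises density on [-pi, pi)
vm_density <- function(x, mu, kappa) {
  exp(kappa * cos(x - mu)) / (2 * pi * besselI(kappa, 0))
}

# Brute-force local decision variable: ratio of the two marginal densities
# p(x, y | change at i) / p(x, y | no change at i) of the generative model
# (orientation uniform, change magnitude uniform), by 2-D Riemann sums over
# (theta, Delta).  Periodic integrand => Riemann sum is spectrally accurate.
d_oracle <- function(x, y, kx, ky, n = 512) {
  th <- seq(-pi, pi, length.out = n + 1)[1:n]
  w <- 2 * pi / n
  fx <- vm_density(x, th, kx)
  p_nc <- sum(fx * vm_density(y, th, ky)) * w / (2 * pi)
  p_c <- 0
  for (dl in th) {
    p_c <- p_c + sum(fx * vm_density(y, th + dl, ky)) * w * w / (2 * pi)^2
  }
  p_c / p_nc
}

# maximum-likelihood von Mises concentration from a sample (textbook
# estimator: solve I1/I0(kappa) = mean resultant length)
kappa_ml <- function(x) {
  r <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
  uniroot(function(k) besselI(k, 1, TRUE) / besselI(k, 0, TRUE) - r,
          c(1e-8, 1e4))$root
}

# representative generating parameters used across simulation-based tests
rep_params <- function(code) default_params(code)
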