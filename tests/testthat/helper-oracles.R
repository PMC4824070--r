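# Independent oracles used to pin expected values.

# Poisson CDF by direct pmf summation in log space (no ppois).
brute_poisson_cdf <- function(k, lambda) {
  if (k < 0) return(0)
  if (lambda == 0) return(1)
  sum(exp((0:k) * log(lambda) - lambda - lgamma((0:k) + 1)))
}

# Closed-form OLS slope.
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# One noiseless growth-series tibble (exponential OD, linear F vs OD).
toy_series <- function(mu = 0.02, od0 = 0.01, t = seq(0, 300, by = 30),
                       slope_rfp = 800, slope_gfp = 500) {
  od <- od0 * exp(mu * t)
  tibble::tibble(time_min = t, od600 = od,
                 f_rfp = slope_rfp * od, f_gfp = slope_gfp * od)
}
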