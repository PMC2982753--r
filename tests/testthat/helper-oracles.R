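# Independent oracles used across the tests. These deliberately avoid the
# package's own code paths: plain weighted sums for distribution moments and
# the full Poisson log-pmf for likelihood checks.

# discrete piecewise-Gaussian moments computed directly from the definition
oracle_gaussian_mean <- function(sigma_ccw, sigma_cw, interval_ccw = 2.5,
                                 interval_cw = 2.5, trunc_ccw = 45,
                                 trunc_cw = 45,
                                 weighting = c("density", "equal")) {
  weighting <- match.arg(weighting)
  x_ccw <- seq(0, trunc_ccw, by = interval_ccw)
  x_ccw <- x_ccw[x_ccw < 90]
  x_cw <- seq(0, trunc_cw, by = interval_cw)
  w <- function(x, s) if (s == 0) as.numeric(x == 0) else exp(-x^2 / (2 * s^2))
  w_ccw <- w(x_ccw, sigma_ccw)
  w_cw <- w(x_cw, sigma_cw)
  if (weighting == "density") {
    a <- sigma_ccw / (sigma_ccw + sigma_cw)
    b <- sigma_cw / (sigma_ccw + sigma_cw)
  } else {
    a <- b <- 0.5
  }
  m_ccw <- if (sum(w_ccw) > 0) a * w_ccw / sum(w_ccw) else w_ccw
  m_cw <- if (sum(w_cw) > 0) b * w_cw / sum(w_cw) else w_cw
  sum(-x_ccw * m_ccw) + sum(x_cw * m_cw)
}

# skewed-uniform mean from the definition: equal-mass halves, 0 excluded
oracle_uniform_mean <- function(range_ccw, range_cw, interval = 2.5) {
  x_ccw <- seq(interval, range_ccw, by = interval)
  x_cw <- seq(interval, range_cw, by = interval)
  0.5 * mean(-x_ccw) + 0.5 * mean(x_cw)
}

# full Poisson log-likelihood (no dropped terms) of counts under a
# candidate-response matrix; returns the argmax candidate index
oracle_poisson_argmax <- function(counts, response_matrix) {
  ll <- vapply(seq_len(ncol(response_matrix)), function(j) {
    sum(stats::dpois(counts, response_matrix[, j], log = TRUE))
  }, numeric(1))
  which.max(ll)
}

# candidate-response matrices mirroring the model definition, built
# independently of the package internals
oracle_point_responses <- function(t, r_max = 60, h = 22.5,
                                   rate_floor = 0.01) {
  grid <- 0:179
  d <- abs(outer(grid, grid, "-")) %% 180
  d <- pmin(d, 180 - d)
  pmax(r_max * t * exp(-(d / h)^2 * log(2)), rate_floor * t)
}

oracle_template_responses <- function(pr0, t, r_max = 60, h = 22.5,
                                      rate_floor = 0.01) {
  grid <- 0:179
  d <- abs(outer(grid, grid, "-")) %% 180
  d <- pmin(d, 180 - d)
  S <- exp(-(d / h)^2 * log(2))
  r0 <- pmax(r_max * t * as.numeric(S %*% pr0), rate_floor * t)
  vapply(grid, function(c) r0[((grid - c) %% 180) + 1], numeric(180))
}

# handy fixtures
exp1_key_dist <- function(reference = 90) {
  build_skewed_gaussian(skewed_gaussian_spec(30, 0), reference)
}
exp2_key_dist <- function(reference = 90) {
  build_skewed_gaussian(
    skewed_gaussian_spec(18, 45, interval_ccw = 2.5, interval_cw = 0.5,
                         truncation_ccw = 90, truncation_cw = 90,
                         half_weighting = "equal-mass"),
    reference)
}
exp3_key_dist <- function(reference = 90) {
  build_skewed_uniform(skewed_uniform_spec(75, 15), reference)
}
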