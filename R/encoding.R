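#' A bank of orientation-tuned neurons
#'
#' Neurons are evenly spaced on the 180-degree axial circle, each with a
#' Gaussian sensitivity profile `S = exp(-(d/h)^2 * log(2))` where `d` is the
#' axial distance to the preferred orientation and `h` the half-height
#' half-width bandwidth, so sensitivity is exactly 0.5 at distance `h`.
#' Defaults: 180 neurons at 1-degree spacing, h = 22.5 degrees, maximum mean
#' rate 60 spikes/s. `rate_floor` is a small positive rate that floors every
#' mean response, keeping downstream log-likelihoods finite.
#'
#' @param n_neurons number of evenly spaced neurons covering \[0, 180).
#' @param bandwidth half-height half-width `h` in degrees (> 0).
#' @param r_max maximum mean firing rate in spikes/s (> 0).
#' @param rate_floor minimum mean rate in spikes/s (>= 0; default 0.01).
#' @return an object of class `neuron_bank` with fields `preferred`,
#'   `bandwidth`, `r_max`, `rate_floor`, `grid` (the 1-degree stimulus grid)
#'   and `sens` (the neurons x grid sensitivity matrix).
#' @examples
#' bank <- neuron_bank()
#' tuning_sensitivity(bank, 90)[c(91, 113, 136)]  # 1, 0.5, 0.0625
#' @export
neuron_bank <- function(n_neurons = 180, bandwidth = 22.5, r_max = 60,
                        rate_floor = 0.01) {
  if (n_neurons < 2) stop("`n_neurons` must be >= 2", call. = FALSE)
  if (bandwidth <= 0) stop("`bandwidth` must be > 0", call. = FALSE)
  if (r_max <= 0) stop("`r_max` must be > 0", call. = FALSE)
  if (rate_floor < 0) stop("`rate_floor` must be >= 0", call. = FALSE)
  preferred <- seq(0, 180, length.out = n_neurons + 1)[seq_len(n_neurons)]
  grid <- 0:179
  d <- axial_distance(outer(preferred, grid, "-"), 0)
  sens <- exp(-(d / bandwidth)^2 * log(2))
  structure(
    list(preferred = preferred, bandwidth = bandwidth, r_max = r_max,
         rate_floor = rate_floor, grid = grid, sens = sens),
    class = "neuron_bank"
  )
}

#' @export
print.neuron_bank <- function(x, ...) {
  cat("neuron_bank:", length(x$preferred), "neurons,",
      "spacing", x$preferred[2] - x$preferred[1], "deg,",
      "bandwidth", x$bandwidth, "deg, r_max", x$r_max, "spikes/s\n")
  invisible(x)
}

#' Tuning sensitivities of every neuron to one orientation
#'
#' @param bank a [neuron_bank()].
#' @param theta orientation in degrees.
#' @return numeric vector of sensitivities in \[0, 1\], one per neuron;
#'   exactly 1 at distance 0 and 0.5 at the bandwidth.
#' @export
tuning_sensitivity <- function(bank, theta) {
  stopifnot(inherits(bank, "neuron_bank"))
  d <- axial_distance(bank$preferred, theta)
  exp(-(d / bank$bandwidth)^2 * log(2))
}

#' Proportions of stimulus orientations on the 1-degree grid
#'
#' For a texture stimulus, the empirical proportions of its (frame-pooled)
#' line orientations, binned to the nearest grid orientation; for a
#' distribution, its masses re-binned to the grid. The result is non-negative
#' and sums to 1.
#'
#' @param x a [texture_stimulus()] or [orientation_distribution()].
#' @return numeric vector of length 180 over the grid 0..179 degrees.
#' @export
stimulus_proportions <- function(x) {
  if (inherits(x, "texture_stimulus")) {
    theta <- pooled_orientations(x)
    if (length(theta) == 0) stop("empty stimulus", call. = FALSE)
    bins <- round(theta) %% 180
    tabulate(bins + 1L, nbins = 180L) / length(bins)
  } else if (inherits(x, "orientation_distribution")) {
    bins <- round(x$reference + x$support) %% 180
    pr <- numeric(180)
    for (i in seq_along(bins)) {
      pr[bins[i] + 1L] <- pr[bins[i] + 1L] + x$mass[i]
    }
    pr
  } else {
    stop("`x` must be a texture_stimulus or orientation_distribution",
         call. = FALSE)
  }
}

#' Mean spike counts of the bank for given stimulus proportions
#'
#' Expected spike count of neuron i over an interval of `t` seconds:
#' `R_i = r_max * t * sum_theta S_i(theta) * pr(theta)`, floored at
#' `rate_floor * t`. Linear in `t` and in the proportions; a point stimulus
#' at a neuron's preferred orientation yields `r_max * t` expected spikes.
#'
#' @param bank a [neuron_bank()].
#' @param proportions length-180 vector from [stimulus_proportions()].
#' @param t stimulus duration in seconds (> 0).
#' @param gain multiplicative gain in (0, 1] applied to `r_max` (contrast
#'   hook; default 1).
#' @return numeric vector of expected spike counts, one per neuron.
#' @export
mean_response <- function(bank, proportions, t, gain = 1) {
  stopifnot(inherits(bank, "neuron_bank"))
  if (t <= 0) stop("`t` must be > 0", call. = FALSE)
  if (gain <= 0 || gain > 1) stop("`gain` must lie in (0, 1]", call. = FALSE)
  if (length(proportions) != length(bank$grid)) {
    stop("`proportions` must match the stimulus grid", call. = FALSE)
  }
  k <- bank$r_max * gain * t
  pmax(k * as.numeric(bank$sens %*% proportions), bank$rate_floor * t)
}

#' Poisson spike counts for given mean counts
#'
#' Independent Poisson draws per neuron, using the ambient RNG stream.
#'
#' @param mean_counts non-negative expected spike counts.
#' @return integer vector of spike counts.
#' @export
sample_spikes <- function(mean_counts) {
  if (any(mean_counts < 0)) stop("`mean_counts` must be >= 0", call. = FALSE)
  stats::rpois(length(mean_counts), mean_counts)
}

#' Encode a stimulus as a population response
#'
#' Computes the mean spike counts for the whole presentation and draws one
#' set of Poisson spike counts. Dynamic stimuli are encoded frame by frame
#' with `t = frame_duration` and the per-frame means summed; by Poisson
#' additivity a single draw from the summed means is distributed identically
#' to summing per-frame draws.
#'
#' @param bank a [neuron_bank()].
#' @param stimulus a [texture_stimulus()].
#' @param gain_fun function mapping Michelson contrast to a gain in (0, 1]
#'   applied to `r_max`; default identity gain of 1 (the model specifies no
#'   contrast mechanism).
#' @return an object of class `population_response` with fields
#'   `mean_counts`, `spike_counts`, `duration`.
#' @examples
#' bank <- neuron_bank()
#' d <- build_skewed_uniform(skewed_uniform_spec(75, 15), reference = 90)
#' set.seed(1)
#' encode_stimulus(bank, sample_static_texture(d))
#' @export
encode_stimulus <- function(bank, stimulus, gain_fun = NULL) {
  stopifnot(inherits(bank, "neuron_bank"),
            inherits(stimulus, "texture_stimulus"))
  gain <- if (is.null(gain_fun)) 1 else gain_fun(stimulus$contrast)
  if (length(gain) != 1 || gain <= 0 || gain > 1) {
    stop("`gain_fun` must return a single gain in (0, 1]", call. = FALSE)
  }
  n_frames <- length(stimulus$frames)
  # frame-pooled proportions; summing per-frame means equals one mean
  # response at the pooled proportions because the encoder is linear
  pr <- stimulus_proportions(stimulus)
  mu <- mean_response(bank, pr, t = stimulus$frame_duration * n_frames,
                      gain = gain)
  population_response(mu, sample_spikes(mu),
                      duration = stimulus$frame_duration * n_frames)
}

#' Population response container
#'
#' @param mean_counts expected spike counts per neuron.
#' @param spike_counts observed (Poisson) spike counts per neuron.
#' @param duration stimulus duration in seconds.
#' @return an object of class `population_response`.
#' @export
population_response <- function(mean_counts, spike_counts, duration) {
  if (length(mean_counts) != length(spike_counts)) {
    stop("count vectors must have equal length", call. = FALSE)
  }
  if (any(mean_counts < 0) || any(spike_counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(
    list(mean_counts = as.numeric(mean_counts),
         spike_counts = as.integer(round(spike_counts)),
         duration = duration),
    class = "population_response"
  )
}

#' @export
print.population_response <- function(x, ...) {
  cat("population_response:", length(x$spike_counts), "neurons,",
      sum(x$spike_counts), "spikes in", x$duration, "s\n")
  invisible(x)
}

#' @export
as.data.frame.population_response <- function(x, ...) {
  data.frame(neuron = seq_along(x$mean_counts),
             mean_count = x$mean_counts,
             spike_count = x$spike_counts)
}
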