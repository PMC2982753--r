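#' Stimulus conditions of the three pooling experiments
#'
#' Experiment 1: piecewise Gaussians sampled at 2.5-degree intervals over a
#' 90-degree total range (45 per side), counter-clockwise SDs 15/20/25/30
#' against clockwise SDs 15/10/5/0, halves weighted in proportion to their
#' SDs (density continuous at the mode). Experiment 2: piecewise Gaussians
#' with clockwise SDs 15/25/35/45 sampled at 0.5 degrees and
#' counter-clockwise SDs 6/10/14/18 sampled at 2.5 degrees, equal-mass
#' halves (same mode and median, different mean), truncated at 90 degrees per
#' side. Experiment 3: skewed uniforms sampled at 2.5 degrees,
#' counter-clockwise ranges 45/55/65/75 against clockwise ranges 45/35/25/15,
#' equal-mass halves (the junction is the median).
#'
#' @param experiment 1, 2 or 3.
#' @return a data frame with one row per condition and a `label` column.
#' @export
experiment_conditions <- function(experiment) {
  if (!experiment %in% 1:3) {
    stop("`experiment` must be 1, 2 or 3", call. = FALSE)
  }
  switch(as.character(experiment),
    "1" = data.frame(
      sigma_ccw = c(15, 20, 25, 30), sigma_cw = c(15, 10, 5, 0),
      label = c("15/15", "20/10", "25/5", "30/0")
    ),
    "2" = data.frame(
      sigma_cw = c(15, 25, 35, 45), sigma_ccw = c(6, 10, 14, 18),
      label = c("cw15/ccw6", "cw25/ccw10", "cw35/ccw14", "cw45/ccw18")
    ),
    "3" = data.frame(
      range_ccw = c(45, 55, 65, 75), range_cw = c(45, 35, 25, 15),
      label = c("45/45", "55/35", "65/25", "75/15")
    )
  )
}

#' Build the comparison distribution for one experiment condition
#'
#' @param experiment 1, 2 or 3.
#' @param condition one row of [experiment_conditions()] (or a list with the
#'   same fields).
#' @param reference absolute reference orientation.
#' @return an [orientation_distribution()].
#' @export
condition_distribution <- function(experiment, condition, reference = 90) {
  if (experiment == 1) {
    build_skewed_gaussian(
      skewed_gaussian_spec(condition$sigma_ccw, condition$sigma_cw,
                           interval_ccw = 2.5, interval_cw = 2.5,
                           truncation_ccw = 45, truncation_cw = 45,
                           half_weighting = "density-matched"),
      reference
    )
  } else if (experiment == 2) {
    build_skewed_gaussian(
      skewed_gaussian_spec(condition$sigma_ccw, condition$sigma_cw,
                           interval_ccw = 2.5, interval_cw = 0.5,
                           truncation_ccw = 90, truncation_cw = 90,
                           half_weighting = "equal-mass"),
      reference
    )
  } else if (experiment == 3) {
    build_skewed_uniform(
      skewed_uniform_spec(condition$range_ccw, condition$range_cw,
                          interval = 2.5),
      reference
    )
  } else {
    stop("`experiment` must be 1, 2 or 3", call. = FALSE)
  }
}

# noisy-standard control distributions (orientation uncertainty added to the
# standard): symmetric Gaussian SD 30 for the Gaussian experiments, uniform
# with a 90-degree total range for the uniform experiment
.noisy_standard_distribution <- function(experiment, reference = 90) {
  if (experiment %in% c(1, 2)) {
    build_skewed_gaussian(
      skewed_gaussian_spec(30, 30, interval_ccw = 2.5, interval_cw = 2.5,
                           truncation_ccw = 90, truncation_cw = 90,
                           half_weighting = "equal-mass"),
      reference
    )
  } else {
    build_skewed_uniform(skewed_uniform_spec(45, 45, interval = 2.5),
                         reference)
  }
}

# shared engine behind the spatial and temporal sweeps
.run_pooling_experiment <- function(experiment, mode, conditions = NULL,
                                    decoders = "va", trials_per_level = 80,
                                    n_levels = 9, n_boot = 5000,
                                    bank = neuron_bank(),
                                    noisy_standard = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(conditions)) conditions <- experiment_conditions(experiment)
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, , drop = FALSE]
    cmp <- condition_distribution(experiment, cond)
    stats3 <- distribution_stats(cmp)
    std <- if (noisy_standard) {
      .noisy_standard_distribution(experiment)
    } else {
      point_mass_distribution()
    }
    for (dec in decoders) {
      task <- afc_task(cmp, standard_dist = std, decoder = dec, bank = bank,
                       mode = mode)
      data <- run_constant_stimuli(task, n_levels = n_levels,
                                   trials_per_level = trials_per_level)
      fit <- fit_logistic(data)
      if (fit$converged && n_boot > 0) {
        fit <- bootstrap_pse_ci(data, fit, n_boot = n_boot)
      }
      rows[[length(rows) + 1]] <- data.frame(
        experiment = experiment,
        condition = cond$label,
        mode = mode,
        standard = if (noisy_standard) "noisy" else "common",
        decoder = dec,
        pse_deg = fit$pse,
        pse_magnitude_deg = abs(fit$pse),
        threshold_deg = fit$threshold,
        ci_low = fit$ci_low,
        ci_high = fit$ci_high,
        converged = fit$converged,
        dist_mean = stats3[["mean"]],
        dist_median = stats3[["median"]],
        dist_mode = stats3[["mode"]],
        n_trials = sum(data$n_trials),
        seed = if (is.null(seed)) NA_integer_ else seed
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a spatial-pooling experiment sweep
#'
#' Static 500-line textures shown for 0.052 s; orientations are distributed
#' across space. Runs every condition of the chosen experiment with every
#' requested decoder and returns one row per condition x decoder with the
#' fitted PSE (signed and magnitude), discrimination threshold, bootstrap CI
#' and the comparison distribution's mean/median/mode offsets.
#'
#' @param experiment 1, 2 or 3.
#' @param decoders character vector from `"va"`, `"wta"`, `"ml"`.
#' @param conditions optional subset of [experiment_conditions()].
#' @param trials_per_level,n_levels method-of-constant-stimuli scale
#'   (defaults 80 x 9 = 720 trials).
#' @param n_boot bootstrap resamples for the PSE CI (0 to skip).
#' @param bank a [neuron_bank()].
#' @param noisy_standard run the noisy-standard control (standard
#'   orientations drawn from a symmetric distribution instead of a common
#'   orientation).
#' @param seed integer seed; recorded in the result.
#' @return a data frame, one row per condition x decoder.
#' @export
run_spatial_experiment <- function(experiment, decoders = "va",
                                   conditions = NULL, trials_per_level = 80,
                                   n_levels = 9, n_boot = 5000,
                                   bank = neuron_bank(),
                                   noisy_standard = FALSE, seed = NULL) {
  .run_pooling_experiment(experiment, "static", conditions, decoders,
                          trials_per_level, n_levels, n_boot, bank,
                          noisy_standard, seed)
}

#' Run a temporal-pooling experiment sweep
#'
#' Identical to [run_spatial_experiment()] except that the textures are
#' dynamic: 25 frames of 0.052 s (1.3 s total), each frame drawing one
#' common orientation from the distribution, so the orientations are
#' distributed over time instead of space.
#'
#' @inheritParams run_spatial_experiment
#' @return a data frame, one row per condition x decoder.
#' @export
run_temporal_experiment <- function(experiment, decoders = "va",
                                    conditions = NULL, trials_per_level = 80,
                                    n_levels = 9, n_boot = 5000,
                                    bank = neuron_bank(),
                                    noisy_standard = FALSE, seed = NULL) {
  .run_pooling_experiment(experiment, "dynamic", conditions, decoders,
                          trials_per_level, n_levels, n_boot, bank,
                          noisy_standard, seed)
}

#' The default diagnostic distribution for the duration experiments
#'
#' A 75/15 equal-mass skewed uniform whose median is placed 7.5 degrees
#' clockwise of vertical - midway between the distribution's median (which a
#' maximum-likelihood observer matched to the stimulus family recovers) and
#' its mean (which the vector average tracks, 15 degrees counter-clockwise
#' of the median). The two read-outs therefore fall on opposite sides of
#' vertical with margins of more than 5 degrees, which is the diagnostic
#' property the duration experiment requires. Chosen by a pilot search over
#' skewed-uniform placements, mirroring how such diagnostic stimuli are
#' found in practice.
#'
#' @param placement_deg clockwise rotation of the median away from vertical
#'   (default 7.5).
#' @return an [orientation_distribution()].
#' @export
diagnostic_distribution <- function(placement_deg = 7.5) {
  build_skewed_uniform(skewed_uniform_spec(75, 15, interval = 2.5),
                       reference = wrap_orientation(90 + placement_deg))
}

#' Seven log-spaced durations between 0.05 and 3.33 seconds
#' @return numeric vector of 7 durations in seconds.
#' @export
duration_grid <- function() {
  exp(seq(log(0.05), log(3.33), length.out = 7))
}

#' Run the duration experiment
#'
#' Single-interval clockwise-of-vertical judgements of a static texture drawn
#' from the diagnostic distribution, at each duration of the 7-point
#' log-spaced grid, for each requested decoder. Before running, the
#' noiseless vector-average and maximum-likelihood predictions are verified
#' to fall on opposite sides of vertical (the property that makes the
#' stimulus diagnostic); a distribution that fails this precondition is
#' rejected.
#'
#' @param dist diagnostic [orientation_distribution()]; default
#'   [diagnostic_distribution()].
#' @param decoders decoders to run (default VA and ML).
#' @param durations duration grid in seconds (default [duration_grid()]).
#' @param n_trials trials per duration x decoder (default 720).
#' @param bank a [neuron_bank()].
#' @param contrast Michelson contrast.
#' @param gain_fun optional contrast-to-gain function.
#' @param seed integer seed; recorded in the result.
#' @return a data frame with one row per duration x decoder: proportion of
#'   clockwise judgements with a 95% binomial (Wilson) CI.
#' @export
run_duration_experiment <- function(dist = diagnostic_distribution(),
                                    decoders = c("va", "ml"),
                                    durations = duration_grid(),
                                    n_trials = 720, bank = neuron_bank(),
                                    contrast = 1, gain_fun = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gain <- if (is.null(gain_fun)) 1 else gain_fun(contrast)
  check <- check_sign_divergence(dist, bank = bank, gain = gain)
  if (!check$diagnostic) {
    stop(sprintf(paste0(
      "distribution is not diagnostic: noiseless VA offset %.2f and ",
      "ML offset %.2f deg from vertical do not fall on opposite sides"),
      check$va_offset, check$ml_offset), call. = FALSE)
  }
  rows <- list()
  for (dec in decoders) {
    for (t in durations) {
      p <- simulate_vertical_judgement(dist, t, decoder = dec, bank = bank,
                                       n_trials = n_trials,
                                       contrast = contrast,
                                       gain_fun = gain_fun)
      ci <- .wilson_ci(p, n_trials)
      rows[[length(rows) + 1]] <- data.frame(
        decoder = dec, duration_s = t, contrast = contrast,
        prop_clockwise = p, ci_low = ci[1], ci_high = ci[2],
        n_trials = n_trials,
        seed = if (is.null(seed)) NA_integer_ else seed
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check the VA/ML sign-divergence precondition of a diagnostic stimulus
#'
#' @param dist an [orientation_distribution()].
#' @param t duration used for the noiseless check (default 1.3 s).
#' @param bank a [neuron_bank()].
#' @param gain gain in (0, 1].
#' @return list with `va_offset`, `ml_offset` (signed degrees from vertical)
#'   and `diagnostic` (`TRUE` when they fall on strictly opposite sides).
#' @export
check_sign_divergence <- function(dist, t = 1.3, bank = neuron_bank(),
                                  gain = 1) {
  va <- signed_offset(
    dist$reference + noiseless_estimate(bank, dist, t, "va", gain = gain), 90)
  ml <- signed_offset(
    dist$reference + noiseless_estimate(bank, dist, t, "ml", gain = gain), 90)
  list(va_offset = va, ml_offset = ml,
       diagnostic = is.finite(va) && is.finite(ml) && va * ml < 0)
}

.wilson_ci <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Run the contrast experiment
#'
#' Repeats the duration experiment at each Michelson contrast, with an
#' optional gain function scaling the maximum firing rate. With the default
#' identity gain (`g(c) = 1`) every contrast reproduces the plain duration
#' experiment exactly when run from the same seed - the model itself
#' specifies no contrast mechanism, so the gain hook is deliberately
#' uncalibrated.
#'
#' @inheritParams run_duration_experiment
#' @param contrasts Michelson contrasts (default 0.25, 0.5, 1).
#' @param gain_fun function mapping contrast to a gain in (0, 1].
#' @return a data frame over contrast x duration x decoder.
#' @export
run_contrast_experiment <- function(dist = diagnostic_distribution(),
                                    decoders = c("va", "ml"),
                                    durations = duration_grid(),
                                    contrasts = c(0.25, 0.5, 1),
                                    n_trials = 720, bank = neuron_bank(),
                                    gain_fun = NULL, seed = NULL) {
  if (!is.null(gain_fun)) {
    g <- vapply(contrasts, gain_fun, numeric(1))
    if (any(g <= 0) || any(g > 1)) {
      stop("`gain_fun` must map every contrast into (0, 1]", call. = FALSE)
    }
  }
  rows <- lapply(contrasts, function(ctr) {
    run_duration_experiment(dist, decoders, durations, n_trials, bank,
                            contrast = ctr, gain_fun = gain_fun, seed = seed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
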