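#' Psychometric data: clockwise-judgement tallies per stimulus level
#'
#' @param levels comparison offsets in degrees (>= 2 distinct values).
#' @param n_trials number of trials per level.
#' @param n_clockwise number of "comparison more clockwise" judgements per
#'   level.
#' @return an object of class `psychometric_data`.
#' @export
psychometric_data <- function(levels, n_trials, n_clockwise) {
  if (length(levels) < 2 || length(unique(levels)) < 2) {
    stop("at least two distinct levels are required", call. = FALSE)
  }
  n_trials <- rep_len(n_trials, length(levels))
  if (length(n_clockwise) != length(levels)) {
    stop("`n_clockwise` must align with `levels`", call. = FALSE)
  }
  if (any(n_clockwise < 0) || any(n_clockwise > n_trials)) {
    stop("`n_clockwise` must lie in [0, n_trials]", call. = FALSE)
  }
  ord <- order(levels)
  structure(
    list(levels = as.numeric(levels[ord]),
         n_trials = as.integer(n_trials[ord]),
         n_clockwise = as.integer(n_clockwise[ord])),
    class = "psychometric_data"
  )
}

#' @export
print.psychometric_data <- function(x, ...) {
  cat("psychometric_data:", length(x$levels), "levels,",
      sum(x$n_trials), "trials\n")
  print(data.frame(level_deg = x$levels, n_trials = x$n_trials,
                   n_clockwise = x$n_clockwise))
  invisible(x)
}

#' @export
as.data.frame.psychometric_data <- function(x, ...) {
  data.frame(level_deg = x$levels, n_trials = x$n_trials,
             n_clockwise = x$n_clockwise)
}

#' Fit the logistic psychometric function
#'
#' Fits `y = 100 / (1 + exp(-(x - pse) / threshold))` to the percentage of
#' clockwise judgements, with the sign fixed so that the curve increases
#' towards clockwise judgements and `y(pse) = 50`. The default objective is
#' binomial maximum likelihood (via [stats::glm()]), which is well defined
#' with small per-level counts; `objective = "ls"` minimises the squared
#' error of the percentages instead, for strict replication of
#' least-squares fits.
#'
#' @param data a [psychometric_data()].
#' @param objective `"ml"` (binomial likelihood) or `"ls"` (least squares on
#'   percentages).
#' @return an object of class `psychometric_fit` with fields `pse`,
#'   `threshold` (both degrees), `converged`, `ci_low`, `ci_high` (filled by
#'   [bootstrap_pse_ci()]).
#' @export
fit_logistic <- function(data, objective = c("ml", "ls")) {
  stopifnot(inherits(data, "psychometric_data"))
  objective <- match.arg(objective)
  p_hat <- data$n_clockwise / data$n_trials
  if (diff(range(p_hat)) == 0) {
    # flat data carry no information about where the curve crosses 50%
    return(.psychometric_fit(NA_real_, NA_real_, FALSE))
  }
  if (objective == "ml") {
    fit <- suppressWarnings(
      stats::glm(cbind(n_clockwise, n_trials - n_clockwise) ~ levels,
                 family = stats::binomial(), data = unclass(data))
    )
    b <- stats::coef(fit)
    ok <- fit$converged && is.finite(b[2]) && b[2] > 0 &&
      abs(b[2]) < 1e3  # separation blows the slope up
    if (!ok) return(.psychometric_fit(NA_real_, NA_real_, FALSE))
    .psychometric_fit(pse = unname(-b[1] / b[2]),
                      threshold = unname(1 / b[2]), TRUE)
  } else {
    start <- c(pse = sum(data$levels * data$n_trials) / sum(data$n_trials),
               threshold = max(diff(range(data$levels)) / 6, 0.5))
    obj <- function(par) {
      if (par[2] <= 0) return(1e12)
      y <- 100 / (1 + exp(-(data$levels - par[1]) / par[2]))
      sum((100 * p_hat - y)^2)
    }
    opt <- stats::optim(start, obj)
    ok <- is.finite(opt$value) && opt$par[2] > 0 &&
      opt$par[1] >= min(data$levels) - 90 && opt$par[1] <= max(data$levels) + 90
    if (!ok) return(.psychometric_fit(NA_real_, NA_real_, FALSE))
    .psychometric_fit(unname(opt$par[1]), unname(opt$par[2]), TRUE)
  }
}

.psychometric_fit <- function(pse, threshold, converged,
                              ci_low = NA_real_, ci_high = NA_real_,
                              ci_flagged = FALSE) {
  structure(
    list(pse = pse, threshold = threshold, converged = converged,
         ci_low = ci_low, ci_high = ci_high, ci_flagged = ci_flagged),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (!x$converged) {
    cat("psychometric_fit: not converged\n")
  } else {
    cat(sprintf("psychometric_fit: PSE %.2f deg, threshold %.2f deg",
                x$pse, x$threshold))
    if (is.finite(x$ci_low)) {
      cat(sprintf(" (95%% CI %.2f..%.2f)", x$ci_low, x$ci_high))
    }
    cat("\n")
  }
  invisible(x)
}

# Vectorised Newton-Raphson binomial-logistic fits: one (intercept, slope)
# pair per row of `k`. Shared levels x, trial counts n. Returns cbind(pse,
# threshold) with NA rows where the fit failed or the slope was <= 0.
# Used by the bootstrap, where refitting thousands of resamples through glm
# would dominate the runtime; agreement with glm is checked in the tests.
.fit_logistic_many <- function(x, n, k, max_iter = 50L, tol = 1e-8) {
  B <- nrow(k)
  L <- length(x)
  b0 <- numeric(B)
  b1 <- numeric(B)
  # moment-based init: linear regression of empirical logits
  p0 <- (k + 0.5) / matrix(n + 1, B, L, byrow = TRUE)
  lg <- log(p0 / (1 - p0))
  xc <- x - mean(x)
  b1[] <- (lg %*% xc) / sum(xc^2)
  b0[] <- rowMeans(lg) - b1 * mean(x)
  active <- rep(TRUE, B)
  nm <- matrix(n, B, L, byrow = TRUE)
  xm <- matrix(x, B, L, byrow = TRUE)
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    eta <- matrix(b0, B, L) + matrix(b1, B, L) * xm
    p <- 1 / (1 + exp(-eta))
    w <- nm * p * (1 - p)
    r <- k - nm * p
    g0 <- rowSums(r)
    g1 <- rowSums(r * xm)
    h00 <- rowSums(w)
    h01 <- rowSums(w * xm)
    h11 <- rowSums(w * xm^2)
    det <- h00 * h11 - h01^2
    bad <- !is.finite(det) | det < 1e-12
    step0 <- ifelse(bad, 0, (h11 * g0 - h01 * g1) / det)
    step1 <- ifelse(bad, 0, (h00 * g1 - h01 * g0) / det)
    # cap huge steps (quasi-separation)
    sc <- pmax(1, pmax(abs(step0), abs(step1)) / 10)
    step0 <- step0 / sc
    step1 <- step1 / sc
    upd <- active & !bad
    b0[upd] <- b0[upd] + step0[upd]
    b1[upd] <- b1[upd] + step1[upd]
    active <- active & !bad &
      (abs(step0) > tol | abs(step1) > tol)
  }
  ok <- is.finite(b0) & is.finite(b1) & b1 > 1e-6 & b1 < 1e3
  cbind(pse = ifelse(ok, -b0 / b1, NA_real_),
        threshold = ifelse(ok, 1 / b1, NA_real_))
}

#' Percentile bootstrap confidence interval for the PSE
#'
#' Nonparametric per-level binomial resampling: each resample redraws the
#' clockwise counts from Binomial(n_l, p_hat_l), refits the logistic, and the
#' 2.5/97.5 percentiles of the resampled PSEs give the 95% interval. If more
#' than 5% of resamples fail to converge the interval is computed from the
#' converged ones and flagged.
#'
#' @param data a [psychometric_data()].
#' @param fit the base [fit_logistic()] fit (must be converged).
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param conf confidence level (default 0.95).
#' @return the fit with `ci_low`, `ci_high` (and `ci_flagged`) filled in.
#' @export
bootstrap_pse_ci <- function(data, fit = fit_logistic(data), n_boot = 5000,
                             conf = 0.95) {
  stopifnot(inherits(data, "psychometric_data"),
            inherits(fit, "psychometric_fit"))
  if (!fit$converged) {
    stop("base fit did not converge; no CI available", call. = FALSE)
  }
  p_hat <- data$n_clockwise / data$n_trials
  L <- length(data$levels)
  k <- matrix(stats::rbinom(n_boot * L, rep(data$n_trials, each = n_boot),
                            rep(p_hat, each = n_boot)),
              nrow = n_boot)
  pars <- .fit_logistic_many(data$levels, data$n_trials, k)
  pse <- pars[, "pse"]
  ok <- is.finite(pse)
  if (sum(ok) < 2) {
    stop("bootstrap failed: almost no resamples converged", call. = FALSE)
  }
  flagged <- mean(!ok) > 0.05
  qs <- stats::quantile(pse[ok], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  .psychometric_fit(fit$pse, fit$threshold, TRUE,
                    ci_low = qs[1], ci_high = qs[2], ci_flagged = flagged)
}

#' Define a simulated 2AFC orientation-discrimination task
#'
#' Bundles everything one simulated trial needs: the standard and comparison
#' distributions, the decoder, the neuron bank, and the stimulus parameters.
#' In `"static"` mode each interval is a single-frame texture of
#' `n_lines` lines; in `"dynamic"` mode each interval is an `n_frames`-frame
#' sequence with one common orientation per frame.
#'
#' @param comparison_dist [orientation_distribution()] of the comparison
#'   texture (its reference is re-placed on every trial).
#' @param standard_dist [orientation_distribution()] of the standard;
#'   defaults to a common orientation (point mass). Noisy-standard controls
#'   pass a symmetric distribution here.
#' @param decoder `"va"`, `"wta"` or `"ml"`.
#' @param bank a [neuron_bank()].
#' @param mode `"static"` or `"dynamic"`.
#' @param n_lines lines per frame (default 500).
#' @param n_frames frames per dynamic interval (default 25).
#' @param frame_duration seconds per frame (default 0.052).
#' @param static_duration total duration of a static interval (default one
#'   frame, 0.052 s).
#' @param contrast Michelson contrast of both intervals.
#' @param gain_fun optional contrast-to-gain function, see
#'   [encode_stimulus()].
#' @param ml_matched_template if `TRUE` (default) the ML decoder uses the
#'   interval's own generating distribution as its candidate template (an
#'   observer who knows the stimulus family up to rotation); if `FALSE` it
#'   uses single-orientation candidates.
#' @return an object of class `afc_task`.
#' @export
afc_task <- function(comparison_dist,
                     standard_dist = point_mass_distribution(),
                     decoder = c("va", "wta", "ml"),
                     bank = neuron_bank(),
                     mode = c("static", "dynamic"),
                     n_lines = 500, n_frames = 25, frame_duration = 0.052,
                     static_duration = 0.052, contrast = 1,
                     gain_fun = NULL, ml_matched_template = TRUE) {
  stopifnot(inherits(comparison_dist, "orientation_distribution"),
            inherits(standard_dist, "orientation_distribution"),
            inherits(bank, "neuron_bank"))
  decoder <- match.arg(decoder)
  mode <- match.arg(mode)
  structure(
    list(comparison_dist = comparison_dist, standard_dist = standard_dist,
         decoder = decoder, bank = bank, mode = mode, n_lines = n_lines,
         n_frames = n_frames, frame_duration = frame_duration,
         static_duration = static_duration, contrast = contrast,
         gain_fun = gain_fun, ml_matched_template = ml_matched_template),
    class = "afc_task"
  )
}

# gain for the task's contrast
.task_gain <- function(task) {
  if (is.null(task$gain_fun)) 1 else task$gain_fun(task$contrast)
}

# interval duration implied by the task mode
.task_duration <- function(task) {
  if (task$mode == "static") task$static_duration
  else task$n_frames * task$frame_duration
}

# Sample, encode and decode one interval. Fast path used by every trial:
# works on plain vectors, no S3 containers.
.decode_interval <- function(task, dist, reference) {
  t_total <- .task_duration(task)
  gain <- .task_gain(task)
  bank <- task$bank
  if (task$mode == "static") {
    offs <- .sample_offsets(dist, task$n_lines)
  } else {
    offs <- .sample_offsets(dist, task$n_frames)  # one orientation per frame
  }
  bins <- round(reference + offs) %% 180
  pr <- tabulate(bins + 1L, nbins = 180L) / length(bins)
  mu <- pmax(bank$r_max * gain * t_total * as.numeric(bank$sens %*% pr),
             bank$rate_floor * t_total)
  counts <- stats::rpois(length(mu), mu)
  .decode_fast(task, counts, dist, t_total, gain)
}

# decode counts under the task's decoder; returns estimate or NA (degenerate)
.decode_fast <- function(task, counts, dist, t_total, gain) {
  bank <- task$bank
  if (task$decoder == "va") {
    .va_estimate(bank$preferred, counts)
  } else if (task$decoder == "wta") {
    if (diff(range(counts)) == 0) return(NA_real_)
    top <- which(counts == max(counts))
    pick <- if (length(top) == 1) top else top[sample.int(length(top), 1)]
    bank$preferred[pick]
  } else {
    template <- if (task$ml_matched_template) dist else NULL
    prof <- loglik_profile(bank, counts, t_total, template = template,
                           gain = gain)
    if (prof$flat) return(NA_real_)
    top <- which(prof$loglik >= max(prof$loglik) - 1e-9)
    pick <- if (length(top) == 1) top else top[sample.int(length(top), 1)]
    prof$candidates[pick]
  }
}

#' Simulate one 2AFC trial
#'
#' Draws a random standard reference uniformly over the 180-degree range,
#' places the comparison reference `level` degrees clockwise of it, samples
#' and encodes both intervals independently, decodes each with the task's
#' decoder, and judges the comparison "more clockwise" when the signed offset
#' of its estimate from the standard's estimate is positive. Degenerate or
#' exactly tied estimates are resolved by a fair coin, matching forced-choice
#' behaviour.
#'
#' @param task an [afc_task()].
#' @param level comparison offset in degrees (positive = clockwise of the
#'   standard).
#' @return logical: was the comparison judged more clockwise?
#' @export
simulate_2afc_trial <- function(task, level) {
  stopifnot(inherits(task, "afc_task"))
  std_ref <- stats::runif(1, 0, 180)
  cmp_ref <- wrap_orientation(std_ref + level)
  est_s <- .decode_interval(task, task$standard_dist, std_ref)
  est_c <- .decode_interval(task, task$comparison_dist, cmp_ref)
  if (is.na(est_s) || is.na(est_c)) {
    return(stats::runif(1) < 0.5)
  }
  d <- signed_offset(est_c, est_s)
  if (d == 0) stats::runif(1) < 0.5 else d > 0
}

#' Noiseless decoder prediction for a distribution
#'
#' Decodes the expected (mean) spike counts of the bank's response to the
#' distribution - no Poisson noise - and returns the signed offset of the
#' estimate from the distribution's reference. Used to anticipate PSEs when
#' placing constant-stimulus levels and to verify sign-divergence
#' preconditions.
#'
#' @param bank a [neuron_bank()].
#' @param dist an [orientation_distribution()].
#' @param t interval duration in seconds.
#' @param decoder `"va"`, `"wta"` or `"ml"`.
#' @param gain gain in (0, 1].
#' @param ml_matched_template see [afc_task()].
#' @return signed offset in degrees (positive = clockwise of the reference).
#' @export
noiseless_estimate <- function(bank, dist, t, decoder = c("va", "wta", "ml"),
                               gain = 1, ml_matched_template = TRUE) {
  stopifnot(inherits(bank, "neuron_bank"),
            inherits(dist, "orientation_distribution"))
  decoder <- match.arg(decoder)
  pr <- stimulus_proportions(dist)
  mu <- mean_response(bank, pr, t, gain = gain)
  est <- if (decoder == "va") {
    .va_estimate(bank$preferred, mu)
  } else if (decoder == "wta") {
    bank$preferred[which.max(mu)]
  } else {
    template <- if (ml_matched_template) dist else NULL
    prof <- loglik_profile(bank, mu, t, template = template, gain = gain)
    prof$candidates[which.max(prof$loglik)]
  }
  signed_offset(est, dist$reference)
}

#' Run a method-of-constant-stimuli session
#'
#' Places `n_levels` levels symmetrically about the anticipated PSE (the
#' negative of the noiseless decoder prediction for the comparison), spanning
#' plus/minus three times a pilot threshold estimated from a short pre-run,
#' then simulates `trials_per_level` 2AFC trials per level. The defaults (9
#' levels x 80 trials = 720 trials) match a standard session of 4 runs of 180
#' trials.
#'
#' @param task an [afc_task()].
#' @param n_levels number of levels (default 9).
#' @param trials_per_level trials per level (default 80).
#' @param levels optional explicit level vector, bypassing placement.
#' @param pilot_trials trials in the placement pre-run (default 50).
#' @return a [psychometric_data()].
#' @export
run_constant_stimuli <- function(task, n_levels = 9, trials_per_level = 80,
                                 levels = NULL, pilot_trials = 50) {
  stopifnot(inherits(task, "afc_task"))
  if (is.null(levels)) {
    centre <- -noiseless_estimate(task$bank, task$comparison_dist,
                                  .task_duration(task), task$decoder,
                                  gain = .task_gain(task),
                                  ml_matched_template = task$ml_matched_template)
    spread <- .pilot_threshold(task, centre, pilot_trials)
    levels <- centre + seq(-3 * spread, 3 * spread, length.out = n_levels)
  }
  n_cw <- vapply(levels, function(x) {
    sum(vapply(seq_len(trials_per_level), function(i) {
      simulate_2afc_trial(task, x)
    }, logical(1)))
  }, integer(1))
  psychometric_data(levels, trials_per_level, n_cw)
}

# crude threshold estimate from a short pre-run around the anticipated PSE
.pilot_threshold <- function(task, centre, pilot_trials = 50,
                             fallback = 4) {
  pilot_levels <- centre + c(-15, -7.5, 0, 7.5, 15)
  per <- max(1L, floor(pilot_trials / length(pilot_levels)))
  n_cw <- vapply(pilot_levels, function(x) {
    sum(vapply(seq_len(per), function(i) simulate_2afc_trial(task, x),
               logical(1)))
  }, integer(1))
  fit <- fit_logistic(psychometric_data(pilot_levels, per, n_cw))
  if (fit$converged && is.finite(fit$threshold)) {
    min(max(fit$threshold, 0.75), 12)
  } else {
    fallback
  }
}

#' Simulate single-interval clockwise-of-vertical judgements
#'
#' Each trial samples a static texture from the distribution (placed at its
#' own reference), encodes it for `duration` seconds, decodes it, and judges
#' "clockwise" when the estimate is clockwise of vertical (90 degrees).
#' Degenerate or exactly vertical estimates are a fair coin.
#'
#' @param dist an [orientation_distribution()]; its reference encodes the
#'   placement relative to vertical.
#' @param duration stimulus duration in seconds.
#' @param decoder `"va"`, `"wta"` or `"ml"`.
#' @param bank a [neuron_bank()].
#' @param n_trials number of trials.
#' @param contrast Michelson contrast.
#' @param gain_fun optional contrast-to-gain function.
#' @param n_lines lines per frame.
#' @param ml_matched_template see [afc_task()].
#' @return proportion of clockwise judgements.
#' @export
simulate_vertical_judgement <- function(dist, duration,
                                        decoder = c("va", "wta", "ml"),
                                        bank = neuron_bank(), n_trials = 720,
                                        contrast = 1, gain_fun = NULL,
                                        n_lines = 500,
                                        ml_matched_template = TRUE) {
  stopifnot(inherits(dist, "orientation_distribution"))
  decoder <- match.arg(decoder)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  task <- afc_task(dist, decoder = decoder, bank = bank, mode = "static",
                   n_lines = n_lines, static_duration = duration,
                   contrast = contrast, gain_fun = gain_fun,
                   ml_matched_template = ml_matched_template)
  cw <- vapply(seq_len(n_trials), function(i) {
    est <- .decode_interval(task, dist, dist$reference)
    if (is.na(est)) return(stats::runif(1) < 0.5)
    d <- signed_offset(est, 90)
    if (d == 0) stats::runif(1) < 0.5 else d > 0
  }, logical(1))
  mean(cw)
}
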