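test_that("experiment condition tables match the stimulus protocol", {
  c1 <- experiment_conditions(1)
  expect_equal(c1$sigma_ccw, c(15, 20, 25, 30))
  expect_equal(c1$sigma_cw, c(15, 10, 5, 0))
  c2 <- experiment_conditions(2)
  expect_equal(c2$sigma_cw, c(15, 25, 35, 45))
  expect_equal(c2$sigma_ccw, c(6, 10, 14, 18))
  c3 <- experiment_conditions(3)
  expect_equal(c3$range_ccw + c3$range_cw, rep(90, 4))
  expect_error(experiment_conditions(4), "1, 2 or 3")
})

test_that("every second-experiment condition keeps mode = median = 0", {
  c2 <- experiment_conditions(2)
  for (i in seq_len(nrow(c2))) {
    s <- distribution_stats(condition_distribution(2, c2[i, , drop = FALSE]))
    expect_equal(s[["mode"]], 0)
    expect_equal(s[["median"]], 0)
    expect_gt(s[["mean"]], 0)  # clockwise tail always heavier
  }
})

test_that("spatial sweeps return one converged row per condition x decoder", {
  res <- run_spatial_experiment(1, decoders = c("va", "wta"),
                                conditions = experiment_conditions(1)[c(1, 4), ],
                                trials_per_level = 8, n_boot = 0, seed = 5)
  expect_equal(nrow(res), 4)
  expect_setequal(res$decoder, c("va", "wta"))
  expect_equal(unique(res$mode), "static")
  expect_true(all(c("pse_deg", "pse_magnitude_deg", "threshold_deg",
                    "dist_mean", "dist_median", "dist_mode", "n_trials",
                    "seed") %in% names(res)))
  expect_equal(unique(res$seed), 5)
})

test_that("same-seed reruns are identical, different seeds agree loosely", {
  conds <- experiment_conditions(1)[4, , drop = FALSE]
  a <- run_spatial_experiment(1, conditions = conds, trials_per_level = 15,
                              n_boot = 200, seed = 42)
  b <- run_spatial_experiment(1, conditions = conds, trials_per_level = 15,
                              n_boot = 200, seed = 42)
  expect_identical(a, b)
  c <- run_spatial_experiment(1, conditions = conds, trials_per_level = 15,
                              n_boot = 200, seed = 43)
  expect_false(identical(a$pse_deg, c$pse_deg))
  expect_equal(a$pse_deg, c$pse_deg, tolerance = 0.25)  # same condition
})

test_that("temporal sweeps use dynamic stimuli and match the spatial PSE", {
  res <- run_temporal_experiment(1,
                                 conditions = experiment_conditions(1)[4, ],
                                 trials_per_level = 30, n_boot = 500,
                                 seed = 11)
  expect_equal(unique(res$mode), "dynamic")
  # VA tracks the temporally accumulated mean: ~18.3 degrees
  expect_equal(res$pse_magnitude_deg, 18.3, tolerance = 2.5)
})

test_that("VA point of equality tracks the mean across the first sweep", {
  res <- run_spatial_experiment(1, trials_per_level = 25, n_boot = 0,
                                seed = 29)
  expect_equal(nrow(res), 4)
  # magnitude grows monotonically as the clockwise SD shrinks 15 -> 0
  expect_true(all(diff(res$pse_magnitude_deg) > 0))
  expect_equal(res$pse_magnitude_deg[4], 18.3, tolerance = 2)
  expect_equal(res$pse_magnitude_deg[1], 0, tolerance = 1.5)
  # and each PSE sits near the distribution-mean prediction
  expect_lt(max(abs(res$pse_deg + res$dist_mean)), 2)
})

test_that("the duration grid spans 0.05 to 3.33 s in 7 log steps", {
  g <- duration_grid()
  expect_length(g, 7)
  expect_equal(g[1], 0.05)
  expect_equal(g[7], 3.33)
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 6), tolerance = 1e-9)
})

test_that("the diagnostic stimulus passes the sign-divergence check", {
  chk <- check_sign_divergence(diagnostic_distribution())
  expect_true(chk$diagnostic)
  expect_lt(chk$va_offset, -3)
  expect_gt(chk$ml_offset, 3)
  # the same distribution centred on vertical is not diagnostic
  flat <- check_sign_divergence(diagnostic_distribution(placement_deg = 0))
  expect_false(flat$diagnostic)
  expect_error(run_duration_experiment(diagnostic_distribution(0),
                                       n_trials = 10),
               "not diagnostic")
})

test_that("duration experiment reports per-duration judgement proportions", {
  res <- run_duration_experiment(durations = duration_grid()[c(1, 7)],
                                 n_trials = 60, seed = 6)
  expect_equal(nrow(res), 4)
  expect_true(all(res$prop_clockwise >= res$ci_low - 1e-9 &
                    res$prop_clockwise <= res$ci_high + 1e-9))
  va <- res[res$decoder == "va", ]
  ml <- res[res$decoder == "ml", ]
  expect_true(all(va$prop_clockwise < 0.5))
  expect_true(all(ml$prop_clockwise > 0.5))
})

test_that("identity gain reproduces the duration run; gains are validated", {
  durations <- duration_grid()[c(2, 6)]
  base <- run_duration_experiment(durations = durations, n_trials = 40,
                                  seed = 9)
  ctr <- run_contrast_experiment(durations = durations, n_trials = 40,
                                 seed = 9)
  expect_equal(unique(ctr$contrast), c(0.25, 0.5, 1))
  for (cc in unique(ctr$contrast)) {
    expect_equal(ctr$prop_clockwise[ctr$contrast == cc],
                 base$prop_clockwise)
  }
  expect_error(run_contrast_experiment(gain_fun = function(ctr) 2 * ctr,
                                       n_trials = 10),
               "0, 1")
})

test_that("lower contrast gain makes ML estimates more variable", {
  bank <- neuron_bank()
  d <- diagnostic_distribution()
  gain_fun <- function(ctr) ctr
  sd_at <- function(contrast) {
    task <- afc_task(d, decoder = "ml", static_duration = 0.1,
                     contrast = contrast, gain_fun = gain_fun)
    ests <- replicate(250, orientpool:::.decode_interval(task, d,
                                                         d$reference))
    stats::sd(signed_offset(ests[!is.na(ests)], d$reference))
  }
  set.seed(33)
  expect_gt(sd_at(0.25), sd_at(1))
})

test_that("distribution specs round-trip through config files", {
  spec <- skewed_gaussian_spec(18, 45, interval_ccw = 2.5, interval_cw = 0.5,
                               truncation_ccw = 90, truncation_cw = 90,
                               half_weighting = "equal-mass")
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_config(spec_to_list(spec), path)
    back <- spec_from_list(read_config(path))
    expect_equal(unclass(back), unclass(spec))
  }
  u <- skewed_uniform_spec(75, 15)
  expect_equal(unclass(spec_from_list(spec_to_list(u))), unclass(u))
  expect_error(spec_from_list(list(type = "nope")), "unknown spec type")
})
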