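test_that("the likelihood profile peaks at a point stimulus's orientation", {
  bank <- neuron_bank()
  mu <- mean_response(bank, stimulus_proportions(texture_stimulus(list(90))),
                      t = 1.3)
  prof <- loglik_profile(bank, round(mu), t = 1.3)
  expect_false(prof$flat)
  expect_equal(prof$candidates[which.max(prof$loglik)], 90)
  est <- ml_decode(prof)
  expect_equal(est$estimate, 90)
  expect_false(est$degenerate)
})

test_that("dropping Poisson constants never changes the ML argmax", {
  # oracle: full Poisson log-pmf per candidate, constants included
  bank <- neuron_bank()
  set.seed(99)
  dists <- list(exp1_key_dist(), exp3_key_dist(),
                point_mass_distribution(137))
  for (d in dists) {
    mu <- mean_response(bank, stimulus_proportions(d), t = 0.3)
    R_point <- oracle_point_responses(0.3)
    R_tmpl <- oracle_template_responses(
      stimulus_proportions(
        orientation_distribution(d$support, d$mass, reference = 0)),
      t = 0.3)
    for (i in 1:75) {
      n <- stats::rpois(180, mu)
      if (sum(n) == 0) next
      p1 <- loglik_profile(bank, n, t = 0.3)
      expect_equal(p1$candidates[which.max(p1$loglik)],
                   (oracle_poisson_argmax(n, R_point) - 1))
      p2 <- loglik_profile(bank, n, t = 0.3, template = d)
      expect_equal(p2$candidates[which.max(p2$loglik)],
                   (oracle_poisson_argmax(n, R_tmpl) - 1))
    }
  }
  # the explicit rate term shifts values but not the argmax
  n <- stats::rpois(180, mean_response(bank,
                                       stimulus_proportions(exp1_key_dist()),
                                       t = 0.3))
  a <- loglik_profile(bank, n, t = 0.3)
  b <- loglik_profile(bank, n, t = 0.3, include_rate_term = TRUE)
  expect_equal(which.max(a$loglik), which.max(b$loglik))
})

test_that("likelihood ties are broken uniformly at random", {
  bank <- neuron_bank()
  counts <- integer(180)
  counts[c(1, 91)] <- 1L  # spikes at 0 and 90: exact ties at 45 and 135
  prof <- loglik_profile(bank, counts, t = 1)
  tops <- prof$candidates[prof$loglik >= max(prof$loglik) - 1e-9]
  expect_equal(tops, c(45, 135))
  set.seed(123)
  picks <- replicate(4000, ml_decode(prof)$estimate)
  expect_equal(mean(picks == 45), 0.5, tolerance = 0.05)
})

test_that("winner-takes-all picks the most active neuron", {
  bank <- neuron_bank()
  counts <- integer(180)
  counts[121] <- 5L
  expect_equal(wta_decode(bank, counts)$estimate, 120)
  expect_true(wta_decode(bank, rep(3L, 180))$degenerate)
  expect_true(wta_decode(bank, integer(180))$degenerate)
})

test_that("vector average matches the stimulus mean and handles the seam", {
  bank <- neuron_bank()
  # counts symmetric about 90
  counts <- integer(180)
  counts[c(81, 101)] <- 10L
  expect_equal(va_decode(bank, counts)$estimate, 90)

  # noiseless response to the key skewed Gaussian: estimate within half a
  # degree of the distribution mean offset
  d <- exp1_key_dist()
  mu <- mean_response(bank, stimulus_proportions(d), t = 1.3)
  est <- va_decode(bank, mu)$estimate
  expect_equal(signed_offset(est, d$reference),
               distribution_stats(d)[["mean"]], tolerance = 0.5)

  # one-hot activity decodes to the preferred orientation on both sides of
  # the seam
  one <- integer(180); one[11] <- 4L
  expect_equal(va_decode(bank, one)$estimate, 10)
  other <- integer(180); other[171] <- 4L
  expect_equal(va_decode(bank, other)$estimate, 170)

  expect_true(va_decode(bank, rep(2L, 180))$degenerate)
  expect_true(va_decode(bank, integer(180))$degenerate)
})

test_that("all decoders are rotation equivariant", {
  bank <- neuron_bank()
  d <- exp1_key_dist()
  mu <- mean_response(bank, stimulus_proportions(d), t = 1.3)
  set.seed(17)
  counts <- stats::rpois(180, mu)
  base <- list(
    va = va_decode(bank, counts)$estimate,
    wta = wta_decode(bank, counts)$estimate,
    ml = ml_decode(loglik_profile(bank, counts, 1.3))$estimate
  )
  for (delta in c(10, 45, 90)) {
    rotated <- counts[((0:179 - delta) %% 180) + 1]
    expect_equal(va_decode(bank, rotated)$estimate,
                 wrap_orientation(base$va + delta), tolerance = 1e-6)
    expect_equal(wta_decode(bank, rotated)$estimate,
                 wrap_orientation(base$wta + delta))
    expect_equal(ml_decode(loglik_profile(bank, rotated, 1.3))$estimate,
                 wrap_orientation(base$ml + delta))
  }
})

test_that("decoders are unbiased for symmetric stimuli", {
  bank <- neuron_bank()
  d <- build_skewed_gaussian(skewed_gaussian_spec(15, 15), reference = 90)
  set.seed(21)
  n <- 400
  ests <- sapply(seq_len(n), function(i) {
    stim <- sample_static_texture(d)
    resp <- encode_stimulus(bank, stim)
    c(va = va_decode(bank, resp$spike_counts)$estimate,
      wta = wta_decode(bank, resp$spike_counts)$estimate,
      ml = ml_decode(loglik_profile(bank, resp$spike_counts, 0.052,
                                    template = d))$estimate)
  })
  for (dec in c("va", "wta", "ml")) {
    offs <- signed_offset(ests[dec, ], 90)
    sem <- stats::sd(offs) / sqrt(n)
    expect_lt(abs(mean(offs)), 3 * sem + 0.5)
  }
})

test_that("decoders separate as expected for the skewed uniform", {
  bank <- neuron_bank()
  d <- exp3_key_dist()
  set.seed(31)
  n <- 300
  ests <- sapply(seq_len(n), function(i) {
    stim <- sample_static_texture(d, frame_duration = 1.3)
    resp <- encode_stimulus(bank, stim)
    c(va = va_decode(bank, resp$spike_counts)$estimate,
      wta = wta_decode(bank, resp$spike_counts)$estimate,
      ml = ml_decode(loglik_profile(bank, resp$spike_counts, 1.3,
                                    template = d))$estimate)
  })
  va_off <- mean(signed_offset(ests["va", ], d$reference))
  ml_off <- mean(signed_offset(ests["ml", ], d$reference))
  wta_off <- mean(signed_offset(ests["wta", ], d$reference))
  # VA tracks the mean (counter-clockwise); ML, matched to the stimulus
  # family, recovers the median junction; WTA sits on the dense side
  expect_equal(va_off, -14.4, tolerance = 1.5)
  expect_equal(ml_off, 0, tolerance = 1)
  expect_gt(wta_off, va_off + 5)
  # ML and WTA both deviate from the mean toward the median/dense side
  expect_gt(ml_off, va_off)
})

test_that("degenerate inputs yield flagged estimates", {
  bank <- neuron_bank()
  prof <- loglik_profile(bank, integer(180), t = 1)
  expect_true(prof$flat)
  expect_true(ml_decode(prof)$degenerate)
  expect_error(loglik_profile(bank, rep(-1L, 180), t = 1), "non-negative")
  expect_error(decode_counts(bank, integer(179), "va"), "per neuron")
  expect_error(decode_counts(bank, integer(180), "ml"), "`t`")
})

test_that("decode_counts dispatches by decoder name", {
  bank <- neuron_bank()
  counts <- integer(180); counts[46] <- 8L
  expect_equal(decode_counts(bank, counts, "va")$estimate, 45)
  expect_equal(decode_counts(bank, counts, "wta")$estimate, 45)
  expect_equal(decode_counts(bank, counts, "ml", t = 0.5)$estimate, 45)
})
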