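test_that("simulation is deterministic and class-lateralized", {
  cfg <- sim_config(trial_duration = 4)
  a <- simulate_trial(cfg, "R", seed = 42)
  b <- simulate_trial(cfg, "R", seed = 42)
  expect_identical(a$signal, b$signal)
  expect_identical(a$true_velocity, b$true_velocity)

  # right-hand imagery attenuates the left hemisphere: C3 mu power < C4
  expect_lt(pgram_band_power(a$signal[, "C3"], 100, 8, 13),
            pgram_band_power(a$signal[, "C4"], 100, 8, 13))
  # left-hand imagery mirrors it
  l <- simulate_trial(cfg, "L", seed = 42)
  expect_lt(pgram_band_power(l$signal[, "C4"], 100, 8, 13),
            pgram_band_power(l$signal[, "C3"], 100, 8, 13))

  expect_error(simulate_trial(cfg, "X", seed = 1), "class")
})

test_that("zero intensity removes asymmetry and motion", {
  cfg <- sim_config(trial_duration = 4, intensity = 0)
  tr <- simulate_trial(cfg, "R", seed = 7)
  expect_true(all(tr$true_velocity == 0))
  # band-power ratio across many seeds stays near 1
  ratios <- vapply(1:10, function(s) {
    t2 <- simulate_trial(cfg, "R", seed = s)
    pgram_band_power(t2$signal[, "C3"], 100, 8, 13) /
      pgram_band_power(t2$signal[, "C4"], 100, 8, 13)
  }, 0)
  expect_gt(mean(ratios), 0.7)
  expect_lt(mean(ratios), 1.4)
})

test_that("ERD deepens monotonically with imagery intensity", {
  # class L attenuates the right hemisphere; mean C4 mu power over seeds
  # must be non-increasing in intensity
  mean_c4 <- vapply(c(0, 0.5, 1), function(int) {
    mean(vapply(1:20, function(s) {
      tr <- simulate_trial(sim_config(trial_duration = 2, intensity = int),
                           "L", seed = s)
      pgram_band_power(tr$signal[, "C4"], 100, 8, 13)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_c4) <= 0))
})

test_that("error-rate zero gives an ERP-free signal", {
  cfg0 <- sim_config(trial_duration = 4, error_rate = 0)
  tr0 <- simulate_trial(cfg0, "U", seed = 3)
  expect_length(tr0$error_events, 0)
  # identical to the explicit no-ERP construction
  tr0b <- simulate_trial(cfg0, "U", seed = 3)
  expect_identical(tr0$signal, tr0b$signal)
})

test_that("signal energy grows with the error-potential amplitude", {
  energies <- vapply(c(0, 5, 15), function(a) {
    tr <- simulate_trial(sim_config(trial_duration = 4, error_rate = 1,
                                    p300_amp = a), "D", seed = 11)
    sum(tr$signal^2)
  }, 0)
  expect_true(all(diff(energies) > 0))
})

test_that("error-potential injection is additive, localized and timed", {
  cfg <- sim_config(trial_duration = 4, error_rate = 0)
  base <- simulate_trial(cfg, "R", seed = 2)

  # zero amplitude is the identity
  same <- inject_error_potential(base, 1.0, amp = 0)
  expect_equal(same$signal, base$signal)

  # peak of the difference signal lands at onset + latency on FC4
  one <- inject_error_potential(base, 1.0, amp = 5, latency = 0.3)
  dif <- one$signal[, "FC4"] - base$signal[, "FC4"]
  expect_lte(abs(which.max(dif) - (1.3 * 100 + 1)), 1)
  expect_true(all(dif >= 0))
  # C1/C2 get half amplitude, untouched channels none
  expect_equal(max(one$signal[, "C1"] - base$signal[, "C1"]), max(dif) / 2,
               tolerance = 1e-12)
  expect_equal(one$signal[, "CP3"], base$signal[, "CP3"])

  # linearity: two onsets equal the sum of the single-event differences
  two <- inject_error_potential(base, c(1.0, 2.5), amp = 5)
  d_two <- two$signal - base$signal
  d_sum <- (inject_error_potential(base, 1.0, amp = 5)$signal - base$signal) +
    (inject_error_potential(base, 2.5, amp = 5)$signal - base$signal)
  expect_lt(max(abs(d_two - d_sum)), 1e-9)

  expect_error(inject_error_potential(base, 5.0, amp = 1), "onset")
})

test_that("dataset simulation is balanced, labelled and reproducible", {
  cfg <- sim_config(trial_duration = 2)
  sim <- simulate_dataset(cfg, 10, seed = 99)
  expect_length(sim$trials, 40)
  expect_equal(unname(table(sim$manifest$class)), rep(10L, 4),
               ignore_attr = TRUE)

  sim2 <- simulate_dataset(cfg, 10, seed = 99)
  for (i in c(1, 17, 40))
    expect_identical(sim$trials[[i]]$signal, sim2$trials[[i]]$signal)

  # velocity labels obey the axis convention in every trial
  for (tr in sim$trials) {
    if (tr$class_label %in% c("U", "D"))
      expect_true(all(tr$true_velocity[, 1] == 0))
    else
      expect_true(all(tr$true_velocity[, 2] == 0))
  }
})

test_that("complex trials carry piecewise-constant velocity", {
  cfg <- sim_config(trial_duration = 1)
  tr <- simulate_complex_trial(cfg, c("U", "R", "D"), seed = 4)
  expect_equal(nrow(tr$signal), 300)
  v <- tr$true_velocity
  expect_true(all(v[1:100, 1] == 0) && all(v[1:100, 2] > 0))
  expect_true(all(v[101:200, 2] == 0) && all(v[101:200, 1] > 0))
  expect_true(all(v[201:300, 2] < 0))
})
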