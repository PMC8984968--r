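test_that("fusion right-aligns streams and preserves columns exactly", {
  tr <- random_trial(1000)
  xs <- spectral_features(tr)
  xt <- temporal_features(tr)
  fused <- fuse_features(xs, xt)
  expect_equal(dim(fused$values), c(961, 20))
  expect_identical(fused$values[, 1:10], xs$values)
  expect_identical(fused$values[, 11:20],
                   xt$values[11:nrow(xt$values), , drop = FALSE])

  # a temporal stream shorter than the spectral one cannot be aligned
  short <- feature_seq(xt$values[1:960, ], 30, kind = "temporal")
  expect_error(fuse_features(xs, short), "fewer rows")
})

test_that("segmentation takes whole leading blocks", {
  mk <- function(rows) feature_seq(matrix(seq_len(rows * 2), rows, 2),
                                   40, kind = "fused")
  expect_length(segment_features(mk(961), 30), 32)
  expect_length(segment_features(mk(30), 30), 1)
  expect_warning(out <- segment_features(mk(29), 30), "fewer rows")
  expect_length(out, 0)
  # blocks are consecutive from the start
  b <- segment_features(mk(65), 30)
  expect_equal(b[[1]][, 1], 1:30)
  expect_equal(b[[2]][, 1], 31:60)
})

test_that("velocity labels are window means with the class axis rule", {
  n <- 1000
  # class U: horizontal label exactly zero whatever the stored velocity
  tru <- eeg_trial(matrix(stats::rnorm(n * 10), n, 10), 100,
                   default_channels(), "U",
                   true_velocity = cbind(stats::rnorm(n), rep(3, n)))
  blocks <- segment_features(fuse_features(spectral_features(tru),
                                           temporal_features(tru)), 30)
  for (s in velocity_samples(tru, blocks))
    expect_identical(s$label[1], 0)

  # class R at constant speed: every label is (v, 0)
  trr <- random_trial(400, class_label = "R")
  blocks <- segment_features(fuse_features(spectral_features(trr),
                                           temporal_features(trr)), 30)
  for (s in velocity_samples(trr, blocks)) {
    expect_equal(s$label, c(5, 0), ignore_attr = TRUE)
  }

  # class L with a ramp: labels equal the windowed means of the ramp
  ramp <- seq(0, 10, length.out = n)
  trl <- eeg_trial(matrix(stats::rnorm(n * 10), n, 10), 100,
                   default_channels(), "L",
                   true_velocity = cbind(-ramp, rep(0, n)))
  blocks <- segment_features(fuse_features(spectral_features(trl),
                                           temporal_features(trl)), 30)
  samples <- velocity_samples(trl, blocks)
  for (b in seq_along(samples)) {
    span <- ((b - 1) * 30 + 1):min(b * 30 + 39, n)
    expect_equal(samples[[b]]$label[1], mean(-ramp[span]))
    expect_identical(samples[[b]]$label[2], 0)
  }

  no_vel <- eeg_trial(matrix(0, 100, 2), 100, c("a", "b"), "R")
  expect_error(velocity_samples(no_vel, blocks), "velocity")
})

test_that("the end-to-end shape law holds for random trial lengths", {
  set.seed(202)
  for (n in sample(69:400, 5)) {
    tr <- random_trial(n)
    ds <- suppressWarnings(build_dataset(list(tr)))
    expect_equal(n_samples(ds), (n - 39) %/% 30)
    expect_equal(dim(ds$x)[2:3], c(30, 20))
  }
})

test_that("trial-level split is balanced, leak-free and deterministic", {
  sim <- simulate_dataset(sim_config(trial_duration = 3), 10, seed = 55)
  ds <- build_dataset(sim$trials)
  sp <- split_dataset(ds, 0.7, seed = 4)

  expect_length(unique(sp$train$trial_id), 28)
  expect_length(unique(sp$test$trial_id), 12)
  expect_equal(unname(table(sp$test$class)) / 8, rep(3, 4),
               ignore_attr = TRUE)               # 3 trials/class, 8 seg each
  expect_setequal(unique(sp$test_ud$class), c("U", "D"))
  expect_setequal(unique(sp$test_lr$class), c("L", "R"))

  # leakage guard: no trial straddles the partitions
  expect_length(intersect(sp$train$trial_id, sp$test$trial_id), 0)

  sp2 <- split_dataset(ds, 0.7, seed = 4)
  expect_identical(sp$train$trial_id, sp2$train$trial_id)

  # a class without trials is rejected
  lr_only <- subset_samples(ds, ds$class %in% c("L", "R"))
  expect_error(split_dataset(lr_only, 0.7, seed = 1), "class U")

  # label zero-structure holds for every sample after labelling
  ud <- ds$class %in% c("U", "D")
  expect_true(all(ds$y[ud, 1] == 0))
  expect_true(all(ds$y[!ud, 2] == 0))
})
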