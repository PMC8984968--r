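test_that("velocity integration is forward Euler with exact symmetry", {
  tr <- integrate_velocity(matrix(c(1, 0), 100, 2, byrow = TRUE))
  expect_equal(nrow(tr$positions), 101)
  expect_equal(unname(tr$positions[101, ]), c(100, 0))
  expect_equal(unname(tr$positions[1, ]), c(0, 0))

  still <- integrate_velocity(matrix(0, 10, 2), start = c(3, 4))
  expect_true(all(still$positions[, 1] == 3 & still$positions[, 2] == 4))

  set.seed(9)
  v <- matrix(stats::rnorm(40), 20, 2)
  back <- integrate_velocity(rbind(v, -v[rev(seq_len(20)), ]))
  expect_equal(unname(back$positions[41, ]), c(0, 0))

  # linearity of the endpoint displacement
  a <- 2.5
  expect_equal(unname(integrate_velocity(a * v)$positions[21, ]),
               a * unname(integrate_velocity(v)$positions[21, ]))

  expect_error(integrate_velocity(cbind(1, NaN)), "finite")
})

test_that("per-axis RMSE matches the direct formula", {
  set.seed(13)
  y <- matrix(stats::rnorm(60), 30, 2)
  yh <- matrix(stats::rnorm(60), 30, 2)
  expect_equal(axis_rmse(y, y, "horizontal"), 0)
  expect_equal(axis_rmse(y, sweep(y, 2, c(2, 0)), "horizontal"), 2)
  expect_equal(axis_rmse(y, yh, "vertical"),
               sqrt(mean((y[, 2] - yh[, 2])^2)), tolerance = 1e-12)
  expect_error(axis_rmse(y[0, ], yh[0, ]), "empty")
})

test_that("direction accuracy uses the signed dominant axis", {
  p <- rbind(c(0, 1), c(0, 2), c(1, 0))
  expect_equal(direction_accuracy(p, rep("U", 3)), 200 / 3)
  expect_equal(direction_accuracy(rbind(c(0, 5), c(0, 0.1)), c("U", "U")), 100)
  expect_equal(direction_accuracy(rbind(c(-3, 1)), "L"), 100)
  expect_equal(direction_accuracy(rbind(c(0, -2)), "D"), 100)
  # ties count as incorrect
  expect_equal(direction_accuracy(rbind(c(1, 1)), "U"), 0)
  # invariance under positive rescaling
  set.seed(3)
  yh <- matrix(stats::rnorm(40), 20, 2)
  cls <- sample(c("L", "R", "U", "D"), 20, replace = TRUE)
  expect_equal(direction_accuracy(yh, cls),
               direction_accuracy(7.3 * yh, cls))
  expect_error(direction_accuracy(rbind(c(1, 0)), "Z"), "class")
})

test_that("MAR divides non-imaginary RMSE by smoothed accuracy", {
  expect_equal(mar(0, 50), 0)
  expect_equal(mar(1, 0), 1e8)
  # published worked cell: 5.62 / (1e-8 + 61.40) rounds to 0.09
  expect_equal(round(mar(5.62, 61.40), 2), 0.09)
  # fraction scale is available and documented
  expect_equal(mar(5.62, 61.40, acc_scale = "fraction"),
               5.62 / (1e-8 + 0.614), tolerance = 1e-9)
  # monotone: increasing in RMSE, decreasing in ACC
  expect_gt(mar(6, 60), mar(5, 60))
  expect_gt(mar(5, 50), mar(5, 60))
  expect_error(mar(-1, 10), ">= 0")
})

test_that("gate test detects the first midline crossing", {
  start <- c(0, 0); target <- c(100, 0)
  straight <- integrate_velocity(matrix(c(10, 0), 12, 2, byrow = TRUE))
  expect_true(gate_success(straight, start, target))

  # crosses the midpoint plane at a 250 px offset: outside a 400 px gate
  offside <- integrate_velocity(matrix(c(10, 0), 12, 2, byrow = TRUE),
                                start = c(0, 250))
  expect_false(gate_success(offside, start, target))
  expect_true(gate_success(offside, start, target, gate_width = 600))

  # stops before the plane: failure by convention
  shortstop <- integrate_velocity(matrix(c(10, 0), 4, 2, byrow = TRUE))
  expect_false(gate_success(shortstop, start, target))

  expect_error(gate_success(straight, start, start), "degenerate")
})

test_that("gate outcome is invariant to rigid rotation about the start", {
  set.seed(21)
  v <- matrix(stats::rnorm(40, mean = c(5, 0)), 20, 2, byrow = FALSE)
  v[, 1] <- abs(v[, 1]) + 2
  traj <- integrate_velocity(v)
  target <- c(80, 10)
  base <- gate_success(traj, c(0, 0), target)
  for (ang in c(pi / 2, pi, 0.3, 1.234)) {
    Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    rtraj <- integrate_velocity(v %*% t(Rm))
    expect_identical(gate_success(rtraj, c(0, 0), as.numeric(Rm %*% target)),
                     base)
  }
})

test_that("the evaluation report is internally consistent", {
  sp <- tiny_split()

  # a perfect oracle predictor: zero RMSE and MAR on its view
  perfect <- structure(list(), class = "perfect_model")
  .S3method("predict", "perfect_model",
            function(object, newdata, ...) unname(newdata$y))
  rpt <- evaluate_decoder(perfect, sp$test, sp$test_ud, sp$test_lr)
  expect_equal(rpt$test_ud$rmse_horizontal, 0)
  expect_equal(rpt$test_ud$mar, 0)
  expect_equal(rpt$test_lr$rmse_vertical, 0)
  expect_equal(rpt$test$acc, 100)
  expect_equal(rpt$gate_successes, rpt$gate_trials)
  expect_equal(rpt$gate_trials, length(unique(sp$test$trial_id)))

  # a real model's report matches direct metric calls
  m <- stlstm(sp$train, lambda = 0.01, epochs = 10, hidden = 10, seed = 6)
  r2 <- evaluate_decoder(m, sp$test, sp$test_ud, sp$test_lr)
  p <- predict(m, sp$test)
  expect_equal(r2$test$rmse_horizontal, axis_rmse(sp$test$y, p, "horizontal"))
  expect_equal(r2$test$rmse_vertical, axis_rmse(sp$test$y, p, "vertical"))
  expect_equal(r2$test$acc, direction_accuracy(p, sp$test$class))
  pud <- predict(m, sp$test_ud)
  expect_equal(r2$test_ud$mar,
               mar(axis_rmse(sp$test_ud$y, pud, "horizontal"),
                   direction_accuracy(pud, sp$test_ud$class)))
  expect_length(r2$gate_by_trial, length(unique(sp$test$trial_id)))
})
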