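test_that("loss arithmetic matches the defining formulas", {
  expect_equal(loss_mse(cbind(0, 0), cbind(3, 4)), 25)
  expect_equal(loss_mse(cbind(c(0, 0), c(0, 0)), cbind(c(1, 0), c(0, 2))),
               2.5)
  expect_equal(loss_mse(cbind(1, 2), cbind(1, 2)), 0)

  expect_equal(loss_vc("R", cbind(3, 4)), 7)       # vertical^2 - horizontal^2
  expect_equal(loss_vc("U", cbind(3, 4)), -7)      # horizontal^2 - vertical^2
  expect_equal(loss_vc("D", cbind(0, 0)), 0)
  expect_error(loss_vc("Q", cbind(1, 1)), "class")

  lt <- loss_total(cbind(5, 0), cbind(3, 4), "R", lambda = 0.01)
  expect_equal(lt$mse, 20)
  expect_equal(lt$vc, 7)
  expect_equal(lt$total, 20.07)
  expect_equal(loss_total(cbind(5, 0), cbind(3, 4), "R", 0)$total, 20)
  # mse 20, vc -7, lambda 1 -> 13
  expect_equal(loss_total(cbind(0, 5), cbind(3, 4), "U",
                          1)$total, (9 + 1) + 1 * (9 - 16))
  expect_error(loss_total(cbind(0, 0), cbind(1, 1), "R", -1), "lambda")
})

test_that("loss identity and prediction gradient hold on random batches", {
  set.seed(15)
  for (rep in 1:5) {
    n <- 17
    y <- matrix(stats::rnorm(2 * n), n, 2)
    yh <- matrix(stats::rnorm(2 * n), n, 2)
    cls <- sample(c("L", "R", "U", "D"), n, replace = TRUE)
    lam <- stats::runif(1, 0, 0.1)
    lt <- loss_total(y, yh, cls, lam)
    expect_equal(lt$total, lt$mse + lam * lt$vc, tolerance = 1e-9)

    # central finite differences on each prediction coordinate
    g <- loss_gradient(y, yh, cls, lam)
    h <- 1e-5
    for (k in sample(seq_len(2 * n), 6)) {
      yp <- yh; ym <- yh
      yp[k] <- yp[k] + h; ym[k] <- ym[k] - h
      fd <- (loss_total(y, yp, cls, lam)$total -
               loss_total(y, ym, cls, lam)$total) / (2 * h)
      expect_equal(g[k], fd, tolerance = 1e-4)
    }
  }
})

test_that("network forward pass honours the shape contract", {
  sp <- tiny_split()
  m <- stlstm(sp$train, lambda = 0, epochs = 2, hidden = 8, seed = 3)
  p <- predict(m, sp$test)
  expect_equal(dim(p), c(n_samples(sp$test), 2))
  expect_true(all(is.finite(p)))
  expect_identical(colnames(p), c("horizontal", "vertical"))

  # same data twice: identical predictions
  expect_identical(p, predict(m, sp$test))

  # wrong feature count is rejected
  bad <- array(0, dim = c(4, 30, 7))
  expect_error(predict(m, bad), "dimensions")
})

test_that("initialization and training are reproducible", {
  sp <- tiny_split()
  m1 <- stlstm(sp$train, lambda = 0.01, epochs = 15, hidden = 12, seed = 8)
  m2 <- stlstm(sp$train, lambda = 0.01, epochs = 15, hidden = 12, seed = 8)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  # training reduces the objective on this well-posed problem
  expect_lt(utils::tail(m1$history$total, 1), m1$history$total[1])
  # loss identity recorded per epoch
  expect_equal(m1$history$total, m1$history$mse + 0.01 * m1$history$vc,
               tolerance = 1e-9)

  # lambda = 0 is plain MSE training
  m0 <- stlstm(sp$train, lambda = 0, epochs = 15, hidden = 12, seed = 8)
  expect_equal(m0$history$total, m0$history$mse)
})

test_that("backpropagation matches finite differences on a tiny network", {
  set.seed(44)
  n <- 3; T_ <- 4; E <- 3; H <- 3
  x <- array(stats::rnorm(n * T_ * E), dim = c(n, T_, E))
  y <- matrix(stats::rnorm(2 * n), n, 2)
  s <- c(1, -1, 1)
  lam <- 0.05
  params <- stlstm:::init_params(E, H, seed = 10)
  cube <- aperm(x, c(1, 3, 2))
  an <- stlstm:::cpp_stlstm_grad(cube, y, s, lam, params)

  h <- 1e-6
  for (branch in c("horizontal", "vertical"))
    for (nm in c("Wx", "Wh", "b", "wout", "bout")) {
      theta <- params[[branch]][[nm]]
      picks <- sample(seq_along(theta), min(4, length(theta)))
      for (k in picks) {
        pp <- params; pm <- params
        pp[[branch]][[nm]][k] <- pp[[branch]][[nm]][k] + h
        pm[[branch]][[nm]][k] <- pm[[branch]][[nm]][k] - h
        fd <- (stlstm:::cpp_stlstm_grad(cube, y, s, lam, pp)$total -
                 stlstm:::cpp_stlstm_grad(cube, y, s, lam, pm)$total) / (2 * h)
        ana <- as.numeric(an$grads[[branch]][[nm]])[k]
        expect_lt(abs(ana - fd), 1e-6 + 1e-4 * abs(fd))
      }
    }
})

test_that("model save/load round-trip reproduces predictions bitwise", {
  sp <- tiny_split()
  m <- stlstm(sp$train, lambda = 0.01, epochs = 5, hidden = 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, path)
  m2 <- readRDS(path)
  expect_identical(predict(m, sp$test), predict(m2, sp$test))
})

test_that("lambda selection minimizes held-out MSE with stable ties", {
  sp <- tiny_split()
  one <- tune_lambda(sp$train, sp$test, lambda_grid = 0.005,
                     epochs = 3, hidden = 6, seed = 1)
  expect_equal(one$lambda, 0.005)
  expect_equal(nrow(one$table), 1)

  # a huge candidate destroys the fit (or aborts) and is never selected
  two <- tune_lambda(sp$train, sp$test, lambda_grid = c(0, 1e6),
                     epochs = 25, hidden = 6, seed = 1)
  expect_equal(two$lambda, 0)
  expect_equal(nrow(two$table), 2)
  expect_true(two$table$test_mse[2] > two$table$test_mse[1] ||
                !is.finite(two$table$test_mse[2]))

  expect_error(tune_lambda(sp$train, sp$test, lambda_grid = numeric(0)),
               "empty")
  expect_length(default_lambda_grid(), 20)
})
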