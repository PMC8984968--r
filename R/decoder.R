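#' Mean squared velocity error
#'
#' Mean over the batch of the squared Euclidean distance between predicted
#' and target (horizontal, vertical) velocity pairs.
#'
#' @param y,yhat Numeric matrices, samples x 2.
#' @return Scalar loss.
#' @export
loss_mse <- function(y, yhat) {
  y <- rbind(y); yhat <- rbind(yhat)
  if (!all(dim(y) == dim(yhat))) stop("y and yhat shapes differ")
  mean(rowSums((y - yhat)^2))
}

# +1 for vertical-imagery samples (U/D: horizontal is the non-imaginary
# axis), -1 for horizontal imagery (L/R)
vc_sign <- function(class_labels) {
  if (!all(class_labels %in% c("L", "R", "U", "D")))
    stop("unknown class label(s): ",
         paste(setdiff(class_labels, c("L", "R", "U", "D")), collapse = ", "))
  ifelse(class_labels %in% c("U", "D"), 1, -1)
}

#' Velocity-constrained (VC) loss
#'
#' Per sample, the squared predicted speed on the non-imaginary axis minus
#' the squared predicted speed on the imaginary axis: for L/R samples
#' `vertical^2 - horizontal^2`, for U/D samples
#' `horizontal^2 - vertical^2`; the batch value is the mean. Minimizing it
#' rewards speed along the imagined axis while suppressing the orthogonal
#' component; it can be negative.
#'
#' @param class_labels Character vector of per-sample classes.
#' @param yhat Predicted velocity pairs, samples x 2.
#' @return Scalar loss.
#' @export
loss_vc <- function(class_labels, yhat) {
  yhat <- rbind(yhat)
  s <- vc_sign(class_labels)
  mean(s * (yhat[, 1]^2 - yhat[, 2]^2))
}

#' Total training loss: MSE + lambda * VC
#'
#' @param y Target velocity pairs, samples x 2.
#' @param yhat Predicted velocity pairs, samples x 2.
#' @param class_labels Per-sample classes.
#' @param lambda Regularization weight, `>= 0`.
#' @return List with `mse`, `vc` and `total = mse + lambda * vc`.
#' @export
loss_total <- function(y, yhat, class_labels, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  mse <- loss_mse(y, yhat)
  vc <- loss_vc(class_labels, yhat)
  list(mse = mse, vc = vc, total = mse + lambda * vc)
}

#' Analytic gradient of the total loss with respect to the predictions
#'
#' @inheritParams loss_total
#' @return Matrix samples x 2 of `d total / d yhat`.
#' @export
loss_gradient <- function(y, yhat, class_labels, lambda) {
  y <- rbind(y); yhat <- rbind(yhat)
  s <- vc_sign(class_labels)
  n <- nrow(y)
  cbind((2 * (yhat[, 1] - y[, 1]) + lambda * 2 * s * yhat[, 1]) / n,
        (2 * (yhat[, 2] - y[, 2]) - lambda * 2 * s * yhat[, 2]) / n)
}

# uniform(-1/sqrt(H), 1/sqrt(H)) initialization for every weight,
# reproducible from the seed
init_params <- function(input_size, hidden, seed) {
  set.seed(seed)
  lim <- 1 / sqrt(hidden)
  ru <- function(r, c) matrix(stats::runif(r * c, -lim, lim), r, c)
  one_branch <- function() list(
    Wx = ru(input_size, 4 * hidden),
    Wh = ru(hidden, 4 * hidden),
    b = ru(1, 4 * hidden),
    wout = as.numeric(ru(hidden, 1)),
    bout = stats::runif(1, -lim, lim))
  list(horizontal = one_branch(), vertical = one_branch())
}

# per-feature standardization statistics over all samples and time steps
fit_scaling <- function(x) {
  E <- dim(x)[3]
  ctr <- numeric(E); scl <- numeric(E)
  for (e in seq_len(E)) {
    v <- x[, , e]
    ctr[e] <- mean(v)
    s <- stats::sd(as.numeric(v))
    scl[e] <- if (is.finite(s) && s > 0) s else 1
  }
  list(center = ctr, scale = scl)
}

apply_scaling <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  for (e in seq_len(dim(x)[3]))
    x[, , e] <- (x[, , e] - scaling$center[e]) / scaling$scale[e]
  x
}

# fused_dataset array (N x T x E) -> cube (N x E x T) for the C++ core
as_input_cube <- function(x) aperm(x, c(1, 3, 2))

#' Fit the spectral-temporal recurrent velocity decoder
#'
#' Trains the two-branch recurrent regressor: each branch is one LSTM
#' layer of `hidden` units reading the fused feature sequence, whose final
#' hidden state is linearly mapped to one scalar; branch outputs are
#' concatenated as (horizontal, vertical) velocity. Training minimizes
#' `MSE + lambda * VC` by full-batch Adam for `epochs` steps. Features are
#' z-scored per feature dimension with statistics fitted on the training
#' data and stored in the model.
#'
#' @param data A `fused_dataset` (see [build_dataset()]).
#' @param lambda Velocity-constraint weight (`>= 0`).
#' @param hidden Hidden units per branch (default 100).
#' @param epochs Full-batch Adam steps (default 300).
#' @param lr Learning rate (default 1e-3).
#' @param seed Seed for weight initialization.
#' @param standardize Z-score features with training statistics
#'   (default `TRUE`).
#' @return An object of class `stlstm` with components `params`, `lambda`,
#'   `scaling`, `history` (per-epoch mse/vc/total), `dims`, plus the
#'   training predictions and targets for `fitted()`/`residuals()`.
#' @seealso [predict.stlstm()], [tune_lambda()], [evaluate_decoder()]
#' @export
stlstm <- function(data, lambda = 0.01, hidden = 100, epochs = 300,
                   lr = 1e-3, seed = 1, standardize = TRUE) {
  stopifnot(inherits(data, "fused_dataset"))
  if (lambda < 0) stop("lambda must be >= 0")
  if (n_samples(data) < 1) stop("empty training set")
  d <- dim(data$x)
  scaling <- if (standardize) fit_scaling(data$x) else NULL
  x <- apply_scaling(data$x, scaling)
  params <- init_params(input_size = d[3], hidden = hidden, seed = seed)
  fit <- cpp_stlstm_train(as_input_cube(x), data$y, vc_sign(data$class),
                          lambda, epochs, lr, params)
  history <- data.frame(epoch = seq_len(epochs),
                        mse = fit$history[, 1], vc = fit$history[, 2],
                        total = fit$history[, 3])
  yhat <- cpp_stlstm_forward(as_input_cube(x), fit$params)
  colnames(yhat) <- c("horizontal", "vertical")
  structure(list(params = fit$params, lambda = lambda, hidden = hidden,
                 epochs = epochs, lr = lr, seed = seed, scaling = scaling,
                 history = history,
                 dims = c(n = d[1], seq_len = d[2], input_size = d[3]),
                 train_fitted = yhat, train_y = data$y,
                 train_class = data$class, call = match.call()),
            class = "stlstm")
}

#' Predict velocities for new samples
#'
#' @param object A fitted [stlstm()] model.
#' @param newdata A `fused_dataset` or a samples x T x E array with the
#'   model's feature dimensions.
#' @param ... Unused.
#' @return Matrix samples x 2 (`horizontal`, `vertical`), finite values.
#' @export
predict.stlstm <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "fused_dataset")) newdata$x else newdata
  if (length(dim(x)) != 3 || dim(x)[2] != object$dims["seq_len"] ||
      dim(x)[3] != object$dims["input_size"])
    stop("newdata dimensions ", paste(dim(x), collapse = "x"),
         " do not match the model (T = ", object$dims["seq_len"],
         ", E = ", object$dims["input_size"], ")")
  x <- apply_scaling(x, object$scaling)
  out <- cpp_stlstm_forward(as_input_cube(x), object$params)
  colnames(out) <- c("horizontal", "vertical")
  out
}

#' @export
fitted.stlstm <- function(object, ...) object$train_fitted

#' @export
residuals.stlstm <- function(object, ...) object$train_y - object$train_fitted

#' @export
coef.stlstm <- function(object, ...) object$params

#' @export
print.stlstm <- function(x, ...) {
  cat(sprintf("<stlstm> %d hidden units/branch, lambda = %g, %d epochs (lr %g)\n",
              x$hidden, x$lambda, x$epochs, x$lr))
  cat(sprintf("  input: %d samples x (T = %d, E = %d)%s\n",
              x$dims["n"], x$dims["seq_len"], x$dims["input_size"],
              if (is.null(x$scaling)) "" else ", standardized"))
  h <- x$history
  cat(sprintf("  loss %g -> %g (mse %g -> %g)\n",
              h$total[1], h$total[nrow(h)], h$mse[1], h$mse[nrow(h)]))
  invisible(x)
}

#' @export
summary.stlstm <- function(object, ...) {
  res <- residuals(object)
  out <- list(model = object,
              train_rmse = sqrt(colMeans(res^2)),
              final = utils::tail(object$history, 1))
  class(out) <- "summary.stlstm"
  out
}

#' @export
print.summary.stlstm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training RMSE: horizontal %.4g, vertical %.4g\n",
              x$train_rmse[1], x$train_rmse[2]))
  cat(sprintf("  final losses: mse %.4g, vc %.4g, total %.4g\n",
              x$final$mse, x$final$vc, x$final$total))
  invisible(x)
}

#' Plot training history
#'
#' @param x A fitted [stlstm()] model.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.stlstm <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$mse, h$total), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"), xlab = "epoch",
                    ylab = "loss", ...)
  graphics::legend("topright", c("MSE", "total"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Default candidate grid for the velocity-constraint weight
#'
#' `0.0001`, `0.001` to `0.009` in steps of `0.001`, and `0.01` to `0.1`
#' in steps of `0.01`.
#'
#' @return Numeric vector of 20 candidates.
#' @export
default_lambda_grid <- function() {
  c(1e-4, seq(0.001, 0.009, by = 0.001), seq(0.01, 0.1, by = 0.01))
}

#' Select the velocity-constraint weight on a held-out set
#'
#' Trains one model per candidate (fresh initialization from the same
#' seed), evaluates the plain MSE on the test set, and returns the
#' minimizer; ties break toward the smallest candidate.
#'
#' @param train,test `fused_dataset` partitions.
#' @param lambda_grid Candidate weights (default [default_lambda_grid()]).
#' @param ... Passed to [stlstm()] (`hidden`, `epochs`, `lr`, `seed`, ...).
#' @return List with `model` (the best fit), `lambda`, and `table`
#'   (data.frame of candidate and test MSE).
#' @export
tune_lambda <- function(train, test, lambda_grid = default_lambda_grid(),
                        ...) {
  if (length(lambda_grid) == 0) stop("empty lambda grid")
  if (any(lambda_grid < 0)) stop("lambda candidates must be >= 0")
  lambda_grid <- sort(lambda_grid)
  fits <- vector("list", length(lambda_grid))
  test_mse <- numeric(length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    # a pathological candidate can abort training (runaway negative VC
    # term); record it as Inf so it can never be selected
    fits[[i]] <- tryCatch(stlstm(train, lambda = lambda_grid[i], ...),
                          error = function(e) e)
    test_mse[i] <- if (inherits(fits[[i]], "error")) Inf else
      loss_mse(test$y, predict(fits[[i]], test))
  }
  if (all(!is.finite(test_mse))) stop("every lambda candidate failed")
  best <- which.min(test_mse)    # ties -> first, i.e. the smallest lambda
  list(model = fits[[best]], lambda = lambda_grid[best],
       table = data.frame(lambda = lambda_grid, test_mse = test_mse))
}
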