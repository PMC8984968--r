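#' Integrate velocities into a cursor trajectory
#'
#' Forward-Euler integration: `position[k+1] = position[k] + velocity[k] * dt`.
#'
#' @param velocities Numeric matrix, steps x 2 (horizontal, vertical).
#' @param start Starting point, length 2 (default origin).
#' @param dt Time per step (one feature segment; default 1).
#' @return An object of class `trajectory`: list with `positions`
#'   (`steps + 1` x 2, first row = `start`), `dt`, `start`.
#' @export
integrate_velocity <- function(velocities, start = c(0, 0), dt = 1) {
  velocities <- rbind(velocities)
  if (!all(is.finite(velocities))) stop("non-finite velocities")
  pos <- rbind(start,
               sweep(apply(velocities * dt, 2, cumsum), 2, start, `+`))
  dimnames(pos) <- list(NULL, c("x", "y"))
  structure(list(positions = pos, dt = dt, start = start),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("<trajectory> %d steps, start (%g, %g) -> end (%g, %g)\n",
              n - 1, x$start[1], x$start[2],
              x$positions[n, 1], x$positions[n, 2]))
  invisible(x)
}

#' Per-axis root mean square error
#'
#' @param y,yhat Velocity matrices, samples x 2.
#' @param axis `"horizontal"` (column 1) or `"vertical"` (column 2).
#' @return Scalar RMSE.
#' @export
axis_rmse <- function(y, yhat, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  y <- rbind(y); yhat <- rbind(yhat)
  if (nrow(y) == 0) stop("empty input")
  if (!all(dim(y) == dim(yhat))) stop("shape mismatch")
  a <- if (axis == "horizontal") 1 else 2
  sqrt(mean((y[, a] - yhat[, a])^2))
}

# signed direction of a velocity pair: axis of the larger |component|;
# ties are NA (counted incorrect)
decode_direction <- function(yhat) {
  h <- yhat[, 1]; v <- yhat[, 2]
  dir <- rep(NA_character_, length(h))
  hz <- abs(h) > abs(v)
  vt <- abs(v) > abs(h)
  dir[hz] <- ifelse(h[hz] > 0, "R", "L")
  dir[vt] <- ifelse(v[vt] > 0, "U", "D")
  dir[h == 0 & v == 0] <- NA_character_
  dir
}

#' Signed direction accuracy (ACC)
#'
#' For each decoded sample the actual direction is the axis with the
#' larger absolute velocity, signed (positive horizontal = right, positive
#' vertical = up). ACC is the percentage of samples whose actual direction
#' matches the intended class; ties (`|h| == |v|`) count as incorrect.
#'
#' @param yhat Predicted velocity pairs, samples x 2.
#' @param intended Character vector of intended classes per sample.
#' @return Percentage in `[0, 100]`.
#' @export
direction_accuracy <- function(yhat, intended) {
  yhat <- rbind(yhat)
  if (nrow(yhat) == 0) stop("empty input")
  if (!all(intended %in% c("L", "R", "U", "D")))
    stop("unknown class label(s): ",
         paste(setdiff(intended, c("L", "R", "U", "D")), collapse = ", "))
  dir <- decode_direction(yhat)
  100 * mean(!is.na(dir) & dir == intended)
}

#' RMSE-accuracy ratio (MAR)
#'
#' `MAR = RMSE / (eps + ACC)` with the RMSE taken on the non-imaginary
#' axis and ACC entered on the percent scale (`acc_scale = "percent"`,
#' the default, reproduces the published worked value 5.62 / 61.40 ~ 0.09;
#' set `acc_scale = "fraction"` to divide by ACC/100 instead). Lower is
#' better.
#'
#' @param rmse_nonimaginary Non-imaginary-axis RMSE, `>= 0`.
#' @param acc Direction accuracy in percent, `>= 0`.
#' @param eps Smoothing constant avoiding division by zero (default 1e-8).
#' @param acc_scale `"percent"` or `"fraction"`.
#' @return Scalar MAR, `>= 0`.
#' @export
mar <- function(rmse_nonimaginary, acc, eps = 1e-8,
                acc_scale = c("percent", "fraction")) {
  acc_scale <- match.arg(acc_scale)
  if (rmse_nonimaginary < 0 || acc < 0) stop("rmse and acc must be >= 0")
  denom_acc <- if (acc_scale == "percent") acc else acc / 100
  rmse_nonimaginary / (eps + denom_acc)
}

#' Midline gate success test
#'
#' A gate of width `gate_width` is placed at the midpoint of the
#' start-target line, perpendicular to the start-target direction. The
#' trial succeeds iff the trajectory's first crossing of the gate plane
#' (detected by a sign change of the along-axis coordinate, with linear
#' interpolation at the crossing) lies within `gate_width / 2` of the
#' midline; a trajectory that never reaches the plane fails.
#'
#' @param traj A [integrate_velocity()] trajectory.
#' @param start,target Length-2 points, distinct.
#' @param gate_width Gate width in pixels (default 400).
#' @return Logical: `TRUE` on success.
#' @export
gate_success <- function(traj, start, target, gate_width = 400) {
  if (all(start == target)) stop("degenerate gate: start equals target")
  u <- (target - start) / sqrt(sum((target - start)^2))
  mid <- (start + target) / 2
  rel <- sweep(traj$positions, 2, mid)
  along <- as.numeric(rel %*% u)
  perp <- rel - outer(along, u)
  cross <- which(along[-1] >= 0 & along[-length(along)] < 0)
  if (length(cross) == 0) return(FALSE)
  k <- cross[1]
  w <- along[k] / (along[k] - along[k + 1])       # in [0, 1]
  p_at <- perp[k, ] + w * (perp[k + 1, ] - perp[k, ])
  sqrt(sum(p_at^2)) <= gate_width / 2
}

#' Evaluate a decoder on held-out data
#'
#' Computes per-axis RMSE on the TEST/TESTUD/TESTLR views, the signed
#' direction accuracy, the MAR on the non-imaginary axis of each filtered
#' view (horizontal on TESTUD, vertical on TESTLR), and the midline gate
#' outcome for every test trial's integrated predicted trajectory (target
#' = the endpoint of the ideal trajectory integrated from the labels).
#' Empty views yield `NA` metrics rather than zeros.
#'
#' @param model A fitted [stlstm()] model.
#' @param test A `fused_dataset` test partition.
#' @param test_ud,test_lr Optional pre-filtered U/D-only and L/R-only
#'   views; derived from `test` by class when omitted.
#' @param gate_width Gate width in pixels (default 400).
#' @param eps MAR smoothing constant.
#' @param acc_scale MAR accuracy scale, see [mar()].
#' @param dt Integration time step per segment.
#' @return An `eval_report` list: per-view RMSE/ACC/MAR, gate counts, and
#'   a per-trial table with trajectories.
#' @export
evaluate_decoder <- function(model, test, test_ud = NULL, test_lr = NULL,
                             gate_width = 400, eps = 1e-8,
                             acc_scale = "percent", dt = 1) {
  if (n_samples(test) == 0) stop("empty test set")
  if (is.null(test_ud))
    test_ud <- subset_samples(test, test$class %in% c("U", "D"), "TESTUD")
  if (is.null(test_lr))
    test_lr <- subset_samples(test, test$class %in% c("L", "R"), "TESTLR")

  view_metrics <- function(ds, nonimag_axis) {
    if (n_samples(ds) == 0)
      return(list(rmse_horizontal = NA_real_, rmse_vertical = NA_real_,
                  acc = NA_real_, mar = NA_real_))
    p <- predict(model, ds)
    rh <- axis_rmse(ds$y, p, "horizontal")
    rv <- axis_rmse(ds$y, p, "vertical")
    acc <- direction_accuracy(p, ds$class)
    m <- if (is.na(nonimag_axis)) NA_real_ else
      mar(if (nonimag_axis == "horizontal") rh else rv, acc, eps,
          acc_scale = acc_scale)
    list(rmse_horizontal = rh, rmse_vertical = rv, acc = acc, mar = m)
  }

  # per-trial gate test on integrated predicted vs ideal trajectories
  trial_ids <- unique(test$trial_id)
  gate <- logical(length(trial_ids))
  trajs <- vector("list", length(trial_ids))
  for (i in seq_along(trial_ids)) {
    sel <- test$trial_id == trial_ids[i]
    ord <- order(test$segment[sel])
    p <- predict(model, subset_samples(test, which(sel)[ord]))
    ideal_end <- colSums(test$y[sel, , drop = FALSE][ord, , drop = FALSE]) * dt
    traj <- integrate_velocity(p, start = c(0, 0), dt = dt)
    gate[i] <- if (all(ideal_end == 0)) NA else
      gate_success(traj, c(0, 0), ideal_end, gate_width)
    trajs[[i]] <- traj
  }

  rep <- list(
    test = view_metrics(test, NA),
    test_ud = view_metrics(test_ud, "horizontal"),
    test_lr = view_metrics(test_lr, "vertical"),
    gate_successes = sum(gate, na.rm = TRUE),
    gate_trials = sum(!is.na(gate)),
    gate_by_trial = stats::setNames(gate, trial_ids),
    trajectories = stats::setNames(trajs, trial_ids),
    eps = eps, acc_scale = acc_scale, gate_width = gate_width)
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  cat("<eval_report>\n")
  cat(sprintf("  TEST   : RMSE h %s / v %s, ACC %s%%\n",
              fmt(x$test$rmse_horizontal), fmt(x$test$rmse_vertical),
              fmt(x$test$acc)))
  cat(sprintf("  TESTUD : RMSE h %s / v %s, ACC %s%%, MAR %s\n",
              fmt(x$test_ud$rmse_horizontal), fmt(x$test_ud$rmse_vertical),
              fmt(x$test_ud$acc), fmt(x$test_ud$mar)))
  cat(sprintf("  TESTLR : RMSE h %s / v %s, ACC %s%%, MAR %s\n",
              fmt(x$test_lr$rmse_horizontal), fmt(x$test_lr$rmse_vertical),
              fmt(x$test_lr$acc), fmt(x$test_lr$mar)))
  cat(sprintf("  gate   : %d / %d trials within %g px\n",
              x$gate_successes, x$gate_trials, x$gate_width))
  invisible(x)
}
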