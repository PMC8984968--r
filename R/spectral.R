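#' Sliding-window Burg spectral specification
#'
#' @param window_ms Window length in milliseconds (default 400, i.e. 40
#'   samples at 100 Hz).
#' @param step_ms Window step in milliseconds (default 10, one sample at
#'   100 Hz).
#' @param order Autoregressive model order (default 16).
#' @param band Frequency band of interest in Hz (default mu, 8-13).
#' @param freq_step Evaluation-grid spacing in Hz (default 0.5; the grid is
#'   `seq(band[1], band[2], by = freq_step)`).
#' @return A list of class `spectral_spec`.
#' @export
spectral_spec <- function(window_ms = 400, step_ms = 10, order = 16,
                          band = c(8, 13), freq_step = 0.5) {
  stopifnot(window_ms > 0, step_ms > 0, order >= 1,
            length(band) == 2, band[1] < band[2], freq_step > 0)
  structure(list(window_ms = window_ms, step_ms = step_ms, order = order,
                 band = band, freq_step = freq_step),
            class = "spectral_spec")
}

#' Time-indexed feature sequence
#'
#' @param values Numeric matrix, feature steps x features.
#' @param start_offset Index of the first raw sample whose window ends at
#'   the first feature step.
#' @param step_samples Raw samples per feature step.
#' @param kind One of `"spectral"`, `"temporal"`, `"fused"`.
#' @return A list of class `feature_seq`.
#' @export
feature_seq <- function(values, start_offset, step_samples = 1L,
                        kind = c("spectral", "temporal", "fused")) {
  kind <- match.arg(kind)
  structure(list(values = as.matrix(values),
                 start_offset = as.integer(start_offset),
                 step_samples = as.integer(step_samples), kind = kind),
            class = "feature_seq")
}

#' @export
print.feature_seq <- function(x, ...) {
  cat(sprintf("<feature_seq %s> %d steps x %d features (window end offset %d, step %d)\n",
              x$kind, nrow(x$values), ncol(x$values), x$start_offset,
              x$step_samples))
  invisible(x)
}

#' @export
dim.feature_seq <- function(x) dim(x$values)

# Burg recursion vectorized over many windows at once.
# W: windows x len matrix. Returns coefficients in the prediction-error
# filter convention A(z) = 1 + sum a_k z^-k (so the fitted signal model is
# x_t = -sum a_k x_{t-k} + e_t) and the final prediction error power.
# Zero-variance windows yield all-zero coefficients and noise_var 0.
burg_multi <- function(W, order) {
  nw <- nrow(W); len <- ncol(W)
  f <- W; b <- W
  A <- matrix(0, nw, order)
  E <- rowSums(W * W) / len
  for (m in seq_len(order)) {
    fc <- f[, (m + 1L):len, drop = FALSE]
    bc <- b[, m:(len - 1L), drop = FALSE]
    den <- rowSums(fc * fc) + rowSums(bc * bc)
    k <- ifelse(den > 0, -2 * rowSums(fc * bc) / den, 0)
    if (m > 1L) {
      prev <- A[, 1:(m - 1L), drop = FALSE]
      A[, 1:(m - 1L)] <- prev + k * prev[, (m - 1L):1, drop = FALSE]
    }
    A[, m] <- k
    fnew <- fc + k * bc
    bnew <- bc + k * fc
    f[, (m + 1L):len] <- fnew
    b[, (m + 1L):len] <- bnew
    E <- E * (1 - k^2)
  }
  list(coeffs = A, noise_var = pmax(E, 0))
}

#' Fit an autoregressive model to one window by the Burg method
#'
#' Coefficients are stored in the prediction-error-filter convention, i.e.
#' the denominator of the spectral density is
#' `|1 + sum_k a_k exp(-i w k)|^2`; `noise_var` is the final (order-p)
#' prediction error power.
#'
#' @param window Numeric vector, length `> 2 * order`.
#' @param order Model order.
#' @return A list of class `ar_model` with `order`, `coeffs`, `noise_var`.
#' @export
burg_ar <- function(window, order) {
  window <- as.numeric(window)
  if (length(window) <= 2 * order)
    stop("degenerate window: need more than ", 2 * order, " samples")
  if (stats::var(window) == 0)
    stop("degenerate window: zero variance")
  fit <- burg_multi(matrix(window, 1), order)
  structure(list(order = as.integer(order), coeffs = drop(fit$coeffs),
                 noise_var = fit$noise_var), class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> order %d, innovation variance %.4g\n",
              x$order, x$noise_var))
  invisible(x)
}

#' Autoregressive power spectral density
#'
#' Evaluates the two-sided AR spectral density
#' `P(f) = sigma^2 / (fs * |1 + sum_k a_k exp(-i 2 pi f k / fs)|^2)`
#' elementwise on a frequency grid. The `1/fs` factor makes `P` a per-Hz
#' density, so the band integral of `2 * P` over `[0, fs/2]` approximates
#' the process variance.
#'
#' @param model An [burg_ar()] fit (or any list with `coeffs`, `noise_var`).
#' @param freqs Frequencies in Hz, within `[0, fs/2]`.
#' @param sample_rate Sampling rate `fs` in Hz.
#' @return Numeric vector of nonnegative densities.
#' @export
ar_psd <- function(model, freqs, sample_rate) {
  if (any(freqs < 0 | freqs > sample_rate / 2))
    stop("frequencies outside [0, Nyquist = ", sample_rate / 2, "]")
  a <- model$coeffs
  p <- length(a)
  ph <- outer(freqs, seq_len(p), function(f, k) -2 * pi * f * k / sample_rate)
  den2 <- Mod(1 + exp(1i * ph) %*% a)^2
  drop(model$noise_var / (sample_rate * den2))
}

#' Band power as the area under a sampled spectral density
#'
#' Rectangle-rule integral `sum P(f) * freq_step` over the grid points
#' falling inside `band`.
#'
#' @param psd Density values on `freqs`.
#' @param freqs Sorted frequency grid, Hz.
#' @param band Length-2 interval in Hz, within `range(freqs)`.
#' @param freq_step Grid spacing, Hz.
#' @return Scalar band power, `>= 0` for nonnegative `psd`.
#' @export
band_power <- function(psd, freqs, band = c(8, 13), freq_step = 0.5) {
  if (band[1] < min(freqs) || band[2] > max(freqs))
    stop("band [", band[1], ", ", band[2], "] outside the frequency grid")
  sel <- freqs >= band[1] & freqs <= band[2]
  sum(psd[sel]) * freq_step
}

#' Sliding-window mu-band power features
#'
#' Slides a window along each channel, fits a Burg AR model per window,
#' evaluates the AR spectral density on the band grid and integrates it:
#' one mu-power value per channel per window position. At the defaults
#' (400 ms window, 10 ms step, 100 Hz) the window is 40 samples, slides by
#' one sample, and the output has `n - 39` rows; row `t` summarizes raw
#' samples `[t, t + 39]`. Zero-variance windows inside a trial yield power
#' 0 with a warning rather than aborting.
#'
#' @param trial An [eeg_trial()] (typically preprocessed to 100 Hz).
#' @param spec A [spectral_spec()].
#' @return A [feature_seq()] of kind `"spectral"`.
#' @export
spectral_features <- function(trial, spec = spectral_spec()) {
  fs <- trial$sample_rate
  w <- spec$window_ms * fs / 1000
  s <- spec$step_ms * fs / 1000
  if (abs(w - round(w)) > 1e-9 || abs(s - round(s)) > 1e-9)
    stop("window/step must be integral multiples of the sample period")
  w <- round(w); s <- round(s)
  n <- nrow(trial$signal); m <- ncol(trial$signal)
  if (n < w) stop("trial too short: ", n, " samples < window of ", w)
  starts <- seq(1L, n - w + 1L, by = s)
  freqs <- seq(spec$band[1], spec$band[2], by = spec$freq_step)
  if (max(freqs) > fs / 2) stop("band extends beyond Nyquist")
  ph <- outer(seq_len(spec$order), freqs,
              function(k, f) -2 * pi * f * k / fs)
  Egrid <- exp(1i * ph)                                 # order x nfreq
  vals <- matrix(0, length(starts), m,
                 dimnames = list(NULL, colnames(trial$signal)))
  degenerate <- FALSE
  win_idx <- outer(starts, 0:(w - 1L), `+`)             # nw x w
  for (j in seq_len(m)) {
    W <- matrix(trial$signal[win_idx, j], nrow(win_idx), w)
    fit <- burg_multi(W, spec$order)
    den2 <- Mod(1 + fit$coeffs %*% Egrid)^2             # nw x nfreq
    P <- (fit$noise_var / fs) / den2
    if (any(fit$noise_var == 0)) degenerate <- TRUE
    vals[, j] <- rowSums(P) * spec$freq_step
  }
  if (degenerate)
    warning("degenerate (flat) window(s) encountered; mu power set to 0")
  feature_seq(vals, start_offset = w, step_samples = s, kind = "spectral")
}
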