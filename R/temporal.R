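#' Wavelet specification for error-related temporal features
#'
#' The temporal stream convolves each channel with the first derivative of
#' a Gaussian -- a transient detector whose response peaks on the rising and
#' falling flanks of an event-related deflection such as the P300.
#'
#' @param scale_l Kernel length in samples (default 30, i.e. 300 ms at
#'   100 Hz).
#' @param gauss_sigma Gaussian width in samples; defaults to `scale_l / 6`
#'   so +/- 3 sigma spans the kernel.
#' @return A list of class `wavelet_spec`.
#' @export
wavelet_spec <- function(scale_l = 30, gauss_sigma = scale_l / 6) {
  stopifnot(scale_l >= 2, gauss_sigma > 0)
  structure(list(scale_l = as.integer(scale_l), gauss_sigma = gauss_sigma),
            class = "wavelet_spec")
}

#' First-derivative-of-Gaussian kernel
#'
#' `k(u) = -(u - c) / sigma^2 * exp(-(u - c)^2 / (2 sigma^2))` for
#' `u = 1..l` with centre `c = (l + 1) / 2`, rescaled to unit peak absolute
#' value. The kernel is antisymmetric about its centre, so it sums to zero
#' and rejects constant signals exactly.
#'
#' @param spec A [wavelet_spec()].
#' @return Numeric vector of length `spec$scale_l`.
#' @export
gauss_deriv_kernel <- function(spec = wavelet_spec()) {
  l <- spec$scale_l
  u <- seq_len(l)
  ctr <- (l + 1) / 2
  k <- -(u - ctr) / spec$gauss_sigma^2 * exp(-(u - ctr)^2 / (2 * spec$gauss_sigma^2))
  k / max(abs(k))
}

#' Error-sensitive temporal features by wavelet convolution
#'
#' Computes, for every channel j and time `t = l..n`,
#' `X[t, j] = (1/l) * sum_{i=0}^{l-1} k(l - i) * signal[t - i, j]`,
#' i.e. the kernel runs over the most recent `l` samples with no padding,
#' so the output has `n - l + 1` rows (`n - 29` at the defaults) and row
#' `r` summarizes raw samples `[r, r + l - 1]`.
#'
#' @param trial An [eeg_trial()].
#' @param spec A [wavelet_spec()].
#' @return A [feature_seq()] of kind `"temporal"`.
#' @export
temporal_features <- function(trial, spec = wavelet_spec()) {
  l <- spec$scale_l
  n <- nrow(trial$signal)
  if (n < l) stop("trial too short: ", n, " samples < kernel length ", l)
  k <- gauss_deriv_kernel(spec)
  # filter() with the reversed kernel gives y[t] = sum_i k(l-i) x[t-i]
  vals <- apply(trial$signal, 2, function(x) {
    y <- stats::filter(x, rev(k), method = "convolution", sides = 1)
    as.numeric(y[l:n]) / l
  })
  feature_seq(as.matrix(vals), start_offset = l, step_samples = 1L,
              kind = "temporal")
}
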