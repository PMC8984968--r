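#' Default 10-channel sensorimotor montage
#'
#' Channel names of the 10-electrode subset over left/right motor cortex and
#' fronto-central areas used throughout the package (standard 10-20 names).
#' Odd-numbered electrodes lie over the left hemisphere, even-numbered over
#' the right.
#'
#' @return Character vector of 10 channel names.
#' @export
default_channels <- function() {
  c("C1", "C2", "C3", "C4", "C5", "C6", "FC3", "FC4", "CP3", "CP4")
}

# hemisphere grouping by electrode-number parity, valid for the default montage
left_hemisphere_channels  <- function() c("C1", "C3", "C5", "FC3", "CP3")
right_hemisphere_channels <- function() c("C2", "C4", "C6", "FC4", "CP4")

#' Construct a single-trial EEG object
#'
#' Bundles one trial's multichannel signal with its sampling rate, motor
#' imagery class label, optional ground-truth cursor velocities and optional
#' error-event onset times.
#'
#' @param signal Numeric matrix, samples x channels.
#' @param sample_rate Sampling rate in Hz.
#' @param channel_names Character vector naming the columns of `signal`.
#' @param class_label One of `"L"`, `"R"`, `"U"`, `"D"` (left hand, right
#'   hand, both hands, relax).
#' @param true_velocity Optional numeric matrix, samples x 2 (horizontal,
#'   vertical), in velocity units.
#' @param error_events Optional numeric vector of error-event onset times in
#'   seconds.
#' @param trial_id Identifier string.
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(signal, sample_rate, channel_names,
                      class_label = c("L", "R", "U", "D"),
                      true_velocity = NULL, error_events = NULL,
                      trial_id = "trial") {
  class_label <- match.arg(class_label)
  signal <- as.matrix(signal)
  if (nrow(signal) < 1L) stop("signal must have at least one sample")
  if (ncol(signal) != length(channel_names))
    stop("channel count (", ncol(signal), ") does not match channel_names (",
         length(channel_names), ")")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive")
  if (!is.null(true_velocity)) {
    true_velocity <- as.matrix(true_velocity)
    if (nrow(true_velocity) != nrow(signal) || ncol(true_velocity) != 2L)
      stop("true_velocity must be n x 2 with n matching the signal")
  }
  colnames(signal) <- channel_names
  structure(
    list(signal = signal, sample_rate = sample_rate,
         channel_names = as.character(channel_names),
         class_label = class_label, true_velocity = true_velocity,
         error_events = if (is.null(error_events)) numeric(0) else
           as.numeric(error_events),
         trial_id = as.character(trial_id)),
    class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf(
    "<eeg_trial '%s'>  %d samples x %d channels @ %g Hz, class %s\n",
    x$trial_id, nrow(x$signal), ncol(x$signal), x$sample_rate, x$class_label))
  if (!is.null(x$true_velocity))
    cat(sprintf("  ground-truth velocity present (mean |h| = %.3g, |v| = %.3g)\n",
                mean(abs(x$true_velocity[, 1])), mean(abs(x$true_velocity[, 2]))))
  if (length(x$error_events))
    cat(sprintf("  %d error event(s) at %s s\n", length(x$error_events),
                paste(signif(x$error_events, 3), collapse = ", ")))
  invisible(x)
}

#' @export
dim.eeg_trial <- function(x) dim(x$signal)

trial_duration <- function(trial) nrow(trial$signal) / trial$sample_rate

# seconds -> 1-based sample index (floor), clamped to the trial
time_to_sample <- function(t, rate, n) pmin(pmax(1L, floor(t * rate) + 1L), n)
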