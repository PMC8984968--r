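#' Configuration for the synthetic EEG generator
#'
#' The generator emulates the statistical structure the decoder relies on:
#' a 10 Hz mu rhythm with slow amplitude modulation whose lateralized
#' attenuation (ERD) deepens with motor-imagery intensity, broadband
#' 1/f^alpha + white background noise, and positive error-locked deflections
#' about 300 ms after observed trajectory deviations. Ground-truth cursor
#' speed is proportional to imagery intensity.
#'
#' @param sample_rate Sampling rate in Hz (default 100).
#' @param trial_duration Trial length in seconds.
#' @param mu_freq Mu-rhythm frequency in Hz.
#' @param mu_base_amp Baseline mu amplitude (signal units, microvolt-like).
#' @param erd_depth Fraction of mu amplitude removed at intensity 1 on the
#'   attenuated hemisphere; `erd_depth * intensity` is clipped at 1 so the
#'   amplitude never goes negative.
#' @param intensity Dimensionless imagery intensity (>= 0); scales both ERD
#'   depth and ground-truth speed.
#' @param noise_sd Standard deviation of each background-noise component
#'   (white and pink each contribute this sd).
#' @param pink_noise_exponent Spectral slope alpha of the 1/f^alpha noise.
#' @param p300_amp Peak amplitude of the error-locked deflection.
#' @param p300_latency Deflection latency after the error event, seconds.
#' @param p300_width Gaussian width (sd) of the deflection, seconds.
#' @param error_rate Error events per second (Poisson rate, >= 0).
#' @param speed_gain Ground-truth speed per unit intensity ("pixels per
#'   feature step"; velocity units are arbitrary).
#' @param channel_names Montage; defaults to [default_channels()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sample_rate = 100, trial_duration = 10, mu_freq = 10,
                       mu_base_amp = 10, erd_depth = 0.5, intensity = 1,
                       noise_sd = 2, pink_noise_exponent = 1,
                       p300_amp = 5, p300_latency = 0.3, p300_width = 0.1,
                       error_rate = 0.2, speed_gain = 10,
                       channel_names = default_channels()) {
  stopifnot(sample_rate > 0, trial_duration > 0, p300_latency > 0,
            p300_width > 0, error_rate >= 0, intensity >= 0,
            erd_depth >= 0, erd_depth <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %g s @ %g Hz, %d ch | mu %g Hz amp %g, ERD depth %g x intensity %g\n",
    x$trial_duration, x$sample_rate, length(x$channel_names),
    x$mu_freq, x$mu_base_amp, x$erd_depth, x$intensity))
  cat(sprintf("  noise sd %g (1/f^%g + white) | P300 amp %g @ %g ms | error rate %g /s\n",
              x$noise_sd, x$pink_noise_exponent, x$p300_amp,
              1000 * x$p300_latency, x$error_rate))
  invisible(x)
}

# 1/f^alpha noise by spectral shaping of white noise, rescaled to unit sd
pink_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  k <- seq_len(n) - 1L
  k2 <- pmin(k, n - k)          # symmetric frequency index, 0..n/2
  scale <- c(0, k2[-1]^(-alpha / 2))
  x <- Re(stats::fft(sp * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# slow random amplitude modulation: Ornstein-Uhlenbeck envelope around 1
ou_envelope <- function(n, dt, theta = 1, sigma = 0.3) {
  e <- numeric(n)
  e[1] <- 1
  z <- stats::rnorm(n - 1L)
  sq <- sigma * sqrt(dt)
  for (k in seq_len(n - 1L)) e[k + 1L] <- e[k] + theta * (1 - e[k]) * dt + sq * z[k]
  pmax(e, 0)
}

# per-channel mu amplitude multiplier for a class:
# L attenuates the right hemisphere, R the left, U (both hands) both,
# D (relax) boosts both (ERS) so all four classes separate in band power
erd_gain <- function(class_label, channel_names, erd_depth, intensity) {
  att <- min(erd_depth * intensity, 1)
  g <- rep(1, length(channel_names))
  left  <- channel_names %in% left_hemisphere_channels()
  right <- channel_names %in% right_hemisphere_channels()
  switch(class_label,
    L = g[right] <- 1 - att,
    R = g[left]  <- 1 - att,
    U = g[left | right] <- 1 - att,
    D = g[left | right] <- 1 + att)
  g
}

class_velocity <- function(class_label, speed) {
  switch(class_label,
    R = c(speed, 0), L = c(-speed, 0), U = c(0, speed), D = c(0, -speed),
    stop("unknown class label '", class_label, "'"))
}

#' Simulate one synthetic EEG trial
#'
#' Builds mu rhythm (amplitude-modulated sinusoid) with class-dependent
#' lateralized ERD, adds pink + white background noise, draws error events
#' as a Poisson process and injects a positive P300-like deflection
#' `p300_latency` after each, and attaches the constant ground-truth
#' velocity along the class axis (zero on the orthogonal axis).
#'
#' @param config A [sim_config()].
#' @param class_label One of `"L"`, `"R"`, `"U"`, `"D"`.
#' @param seed Integer seed; identical `(config, class_label, seed)` give
#'   bit-identical trials.
#' @param trial_id Identifier for the trial.
#' @return An [eeg_trial()].
#' @export
simulate_trial <- function(config, class_label, seed, trial_id = NULL) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (!is.character(class_label) || !(class_label %in% c("L", "R", "U", "D")))
    stop("unknown class label '", paste(class_label, collapse = ","), "'")
  set.seed(seed)
  fs <- config$sample_rate
  n <- round(config$trial_duration * fs)
  chn <- config$channel_names
  m <- length(chn)
  tt <- (seq_len(n) - 1L) / fs
  gain <- erd_gain(class_label, chn, config$erd_depth, config$intensity)

  sig <- matrix(0, n, m)
  for (j in seq_len(m)) {
    phase <- stats::runif(1, 0, 2 * pi)
    env <- ou_envelope(n, 1 / fs)
    mu <- config$mu_base_amp * gain[j] * env * sin(2 * pi * config$mu_freq * tt + phase)
    noise <- config$noise_sd * (pink_noise(n, config$pink_noise_exponent) +
                                  stats::rnorm(n))
    sig[, j] <- mu + noise
  }

  speed <- config$speed_gain * config$intensity
  vel <- matrix(rep(class_velocity(class_label, speed), each = n), n, 2)

  trial <- eeg_trial(sig, fs, chn, class_label, true_velocity = vel,
                     trial_id = trial_id %||%
                       sprintf("sim_%s_seed%d", class_label, seed))

  # events drawn last so the error_rate = 0 signal is bitwise identical to
  # the no-ERP construction
  n_ev <- stats::rpois(1, config$error_rate * config$trial_duration)
  if (n_ev > 0) {
    onsets <- sort(stats::runif(n_ev, 0, config$trial_duration))
    trial <- inject_error_potential(trial, onsets, config$p300_amp,
                                    config$p300_latency, config$p300_width)
  }
  trial
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add error-locked P300-like deflections to a trial
#'
#' Adds a positive Gaussian bump peaking `latency` seconds after each onset
#' on the fronto-central channels FC3/FC4 (full amplitude) and C1/C2 (half
#' amplitude). The operation is exactly additive, so injecting two onset
#' sets sequentially equals injecting their union.
#'
#' @param trial An [eeg_trial()].
#' @param onsets Error-event onset times in seconds, within `[0, duration)`.
#' @param amp Peak amplitude (signal units).
#' @param latency Peak delay after onset, seconds.
#' @param width Gaussian sd, seconds.
#' @return A copy of `trial` with the deflections added and `error_events`
#'   extended by `onsets`.
#' @export
inject_error_potential <- function(trial, onsets, amp, latency = 0.3,
                                   width = 0.1) {
  stopifnot(inherits(trial, "eeg_trial"), width > 0)
  dur <- trial_duration(trial)
  if (any(onsets < 0 | onsets >= dur))
    stop("error-event onset outside the trial [0, ", dur, ")")
  tt <- (seq_len(nrow(trial$signal)) - 1L) / trial$sample_rate
  full <- trial$channel_names %in% c("FC3", "FC4")
  half <- trial$channel_names %in% c("C1", "C2")
  bump <- numeric(length(tt))
  for (on in onsets)
    bump <- bump + amp * exp(-(tt - (on + latency))^2 / (2 * width^2))
  trial$signal[, full] <- trial$signal[, full] + bump
  trial$signal[, half] <- trial$signal[, half] + bump / 2
  trial$error_events <- c(trial$error_events, onsets)
  trial
}

#' Simulate a balanced multi-trial dataset
#'
#' Generates `trials_per_class` trials for each of the four imagery classes.
#' Per-trial seeds are derived deterministically from `seed`, and per-trial
#' imagery intensity is drawn uniformly from
#' `config$intensity * intensity_jitter` so ground-truth speeds span a range
#' (set `intensity_jitter = c(1, 1)` for constant intensity).
#'
#' @param config A [sim_config()].
#' @param trials_per_class Number of trials per class (>= 1).
#' @param seed Master seed.
#' @param intensity_jitter Length-2 range of the per-trial intensity
#'   multiplier.
#' @return A list with `trials` (list of [eeg_trial()]) and `manifest`
#'   (data.frame: trial_id, class, seed, intensity).
#' @export
simulate_dataset <- function(config, trials_per_class, seed,
                             intensity_jitter = c(0.5, 1.5)) {
  stopifnot(trials_per_class >= 1, length(intensity_jitter) == 2)
  classes <- rep(c("L", "R", "U", "D"), each = trials_per_class)
  n_tr <- length(classes)
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_tr)
  intens <- config$intensity *
    stats::runif(n_tr, intensity_jitter[1], intensity_jitter[2])
  trials <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    cfg_i <- config
    cfg_i$intensity <- intens[i]
    trials[[i]] <- simulate_trial(cfg_i, classes[i], trial_seeds[i],
                                  trial_id = sprintf("sim%03d_%s", i, classes[i]))
  }
  manifest <- data.frame(trial_id = vapply(trials, `[[`, "", "trial_id"),
                         class = classes, seed = trial_seeds,
                         intensity = intens, stringsAsFactors = FALSE)
  list(trials = trials, manifest = manifest)
}

#' Simulate a trial with a piecewise-constant imagery sequence
#'
#' Concatenates per-class segments into one long trial whose ground-truth
#' velocity is piecewise constant -- an analogue of complex path-tracking
#' runs (e.g. up, right, down, right, up).
#'
#' @param config A [sim_config()]; `trial_duration` is used per segment.
#' @param classes Character vector of segment classes.
#' @param seed Master seed (one sub-seed per segment).
#' @return An [eeg_trial()] whose `class_label` is the first segment's class.
#' @export
simulate_complex_trial <- function(config, classes, seed) {
  stopifnot(length(classes) >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(classes))
  parts <- mapply(simulate_trial, class_label = classes, seed = seeds,
                  MoreArgs = list(config = config), SIMPLIFY = FALSE)
  sig <- do.call(rbind, lapply(parts, `[[`, "signal"))
  vel <- do.call(rbind, lapply(parts, `[[`, "true_velocity"))
  offs <- cumsum(c(0, vapply(parts, trial_duration, 0)))
  ev <- unlist(mapply(function(p, o) p$error_events + o, parts,
                      offs[seq_along(parts)], SIMPLIFY = FALSE))
  eeg_trial(sig, config$sample_rate, config$channel_names,
            class_label = classes[1], true_velocity = vel,
            error_events = ev,
            trial_id = sprintf("sim_complex_%s", paste(classes, collapse = "")))
}
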