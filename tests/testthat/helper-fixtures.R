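# shared fixtures and small oracles, all built in code

# periodogram band integral (independent of the Burg path)
pgram_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / (n * fs)
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f >= lo & f <= hi]) * fs / n
}

# small fused dataset for decoder/eval tests, built once per session
.fixture_env <- new.env(parent = emptyenv())

tiny_split <- function() {
  if (is.null(.fixture_env$split)) {
    sim <- simulate_dataset(sim_config(trial_duration = 3), 2, seed = 5)
    ds <- build_dataset(sim$trials)
    .fixture_env$split <- split_dataset(ds, 0.7, seed = 9)
  }
  .fixture_env$split
}

# random trial with known velocity, for shape-law property tests
random_trial <- function(n, m = 10, class_label = "R", seed = 1) {
  set.seed(seed)
  eeg_trial(matrix(stats::rnorm(n * m), n, m), 100,
            paste0("ch", seq_len(m)), class_label,
            true_velocity = cbind(rep(5, n), rep(0, n)))
}

# flatten branch parameters for finite-difference gradient checks
flatten_params <- function(p) {
  unlist(lapply(p, function(br) lapply(br, as.numeric)))
}
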