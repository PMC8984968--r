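#' Preprocessing specification
#'
#' Standard preprocessing for raw multichannel EEG before feature
#' extraction: channel selection, optional mains notch, down-sampling with
#' anti-aliasing, and a zero-phase band-pass. Stages run in the fixed order
#' channel-select, notch (if set), resample, band-pass, so the band-pass
#' operates at the target rate.
#'
#' @param target_rate Output sampling rate, Hz.
#' @param bandpass_low,bandpass_high Band edges in Hz,
#'   `0 < low < high < target_rate / 2`.
#' @param notch_freq Mains notch frequency in Hz, or `NULL` to skip.
#' @param channel_subset Ordered channel names to keep.
#' @return A list of class `preprocess_spec`.
#' @export
preprocess_spec <- function(target_rate = 100, bandpass_low = 0.1,
                            bandpass_high = 30, notch_freq = NULL,
                            channel_subset = default_channels()) {
  stopifnot(bandpass_low > 0, bandpass_low < bandpass_high,
            bandpass_high < target_rate / 2,
            length(channel_subset) >= 1,
            !anyDuplicated(channel_subset))
  structure(list(target_rate = target_rate, bandpass_low = bandpass_low,
                 bandpass_high = bandpass_high, notch_freq = notch_freq,
                 channel_subset = as.character(channel_subset)),
            class = "preprocess_spec")
}

#' Select and reorder channels
#'
#' @param trial An [eeg_trial()].
#' @param channels Ordered channel names to keep; all must be present.
#' @return The trial restricted to `channels`, in the requested order.
#' @export
select_channels <- function(trial, channels) {
  missing <- setdiff(channels, trial$channel_names)
  if (length(missing))
    stop("channel(s) not present in trial: ", paste(missing, collapse = ", "))
  idx <- match(channels, trial$channel_names)
  trial$signal <- trial$signal[, idx, drop = FALSE]
  trial$channel_names <- as.character(channels)
  trial
}

# zero-phase Butterworth helper
zp_filter <- function(x, filt) signal::filtfilt(filt, x)

#' Zero-phase band-pass filter
#'
#' Cascade of a 2nd-order Butterworth high-pass and a 4th-order low-pass,
#' each applied forward-backward (`signal::filtfilt`), so the passband is
#' flat, the effective roll-off doubles and peak latencies are preserved --
#' the temporal features downstream are latency-sensitive. Length is
#' preserved.
#'
#' @param trial An [eeg_trial()].
#' @param low,high Band edges in Hz, `0 < low < high < ` Nyquist.
#' @return Filtered trial.
#' @export
bandpass_trial <- function(trial, low, high) {
  fs <- trial$sample_rate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band [", low, ", ", high, "] Hz outside (0, Nyquist = ", fs / 2, ")")
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  # demean first: the mean is stop-band anyway and removing it avoids the
  # long edge transient of the near-DC high-pass
  trial$signal <- apply(trial$signal, 2, function(x)
    zp_filter(zp_filter(x - mean(x), hp), lp))
  trial
}

#' Zero-phase mains notch filter
#'
#' @param trial An [eeg_trial()].
#' @param freq Notch centre frequency, Hz.
#' @param bw Stop-band full width, Hz (default 2).
#' @return Filtered trial.
#' @export
notch_trial <- function(trial, freq, bw = 2) {
  fs <- trial$sample_rate
  if (freq + bw / 2 >= fs / 2) stop("notch frequency above Nyquist")
  bs <- signal::butter(2, c(freq - bw / 2, freq + bw / 2) / (fs / 2), type = "stop")
  trial$signal <- apply(trial$signal, 2, zp_filter, filt = bs)
  trial
}

#' Down-sample a trial with anti-aliasing
#'
#' Integer decimation factors use a 4th-order zero-phase Butterworth
#' anti-alias filter at 80% of the new Nyquist followed by sample picking;
#' non-integer ratios fall back to polyphase resampling
#' (`signal::resample`). Ground-truth velocities are resampled to match.
#' Upsampling is not supported.
#'
#' @param trial An [eeg_trial()].
#' @param target_rate New rate in Hz, `<= trial$sample_rate`.
#' @return Resampled trial with `floor(n * target_rate / input_rate)` samples.
#' @export
resample_trial <- function(trial, target_rate) {
  fs <- trial$sample_rate
  if (target_rate > fs)
    stop("upsampling unsupported: target ", target_rate, " Hz > input ", fs, " Hz")
  if (target_rate == fs) return(trial)
  n <- nrow(trial$signal)
  n_out <- floor(n * target_rate / fs)
  q <- fs / target_rate
  if (abs(q - round(q)) < 1e-9) {          # integer decimation
    q <- round(q)
    aa <- signal::butter(4, 0.8 * (target_rate / 2) / (fs / 2), type = "low")
    idx <- seq(1L, by = q, length.out = n_out)
    trial$signal <- apply(trial$signal, 2,
                          function(x) zp_filter(x, aa)[idx])
    if (!is.null(trial$true_velocity))
      trial$true_velocity <- trial$true_velocity[idx, , drop = FALSE]
  } else {                                  # rational ratio: polyphase
    frac <- gcd_ratio(target_rate, fs)
    trial$signal <- apply(trial$signal, 2, function(x)
      signal::resample(x, frac[1], frac[2])[seq_len(n_out)])
    if (!is.null(trial$true_velocity)) {
      t_old <- (seq_len(n) - 1) / fs
      t_new <- (seq_len(n_out) - 1) / target_rate
      trial$true_velocity <- apply(trial$true_velocity, 2, function(v)
        stats::approx(t_old, v, xout = t_new, rule = 2)$y)
    }
  }
  trial$sample_rate <- target_rate
  trial
}

gcd_ratio <- function(p, q) {
  # integer p/q in lowest terms, assuming rates are rational with small terms
  scale <- 1
  while (abs(p * scale - round(p * scale)) > 1e-9 ||
         abs(q * scale - round(q * scale)) > 1e-9) scale <- scale * 10
  a <- round(p * scale); b <- round(q * scale)
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  d <- g(a, b)
  c(a / d, b / d)
}

#' Apply the full preprocessing pipeline
#'
#' Channel-select, optional notch, anti-aliased down-sampling, then
#' zero-phase band-pass at the target rate. The output rate always equals
#' `spec$target_rate`.
#'
#' @param trial An [eeg_trial()].
#' @param spec A [preprocess_spec()].
#' @return Preprocessed trial.
#' @export
preprocess <- function(trial, spec = preprocess_spec()) {
  stopifnot(inherits(spec, "preprocess_spec"))
  trial <- select_channels(trial, spec$channel_subset)
  if (!is.null(spec$notch_freq)) trial <- notch_trial(trial, spec$notch_freq)
  trial <- resample_trial(trial, spec$target_rate)
  bandpass_trial(trial, spec$bandpass_low, spec$bandpass_high)
}

## ---------------------------------------------------------------- EDF IO

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x) formatC(signif(x, 6), format = "g", digits = 6)

#' Write a trial to an EDF file
#'
#' Minimal European Data Format writer: one data record holding the whole
#' trial, 16-bit samples scaled channel-wise between the physical min/max
#' actually printed in the header (so a round trip is exact up to the
#' 16-bit quantization step). The class label and trial id are stored in
#' the recording-identification field as `class=<L> id=<trial_id>`.
#'
#' @param trial An [eeg_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(trial, path) {
  stopifnot(inherits(trial, "eeg_trial"))
  sig <- trial$signal
  phys_min <- apply(sig, 2, min)
  phys_max <- apply(sig, 2, max)
  flat <- phys_max - phys_min <= 0
  phys_max[flat] <- phys_min[flat] + 1
  # scale with the header-printed (6 significant digit) bounds so the
  # reader reconstructs on exactly the writer's quantization grid
  pmin_s <- edf_num(phys_min); pmax_s <- edf_num(phys_max)
  phys_min <- as.numeric(pmin_s); phys_max <- as.numeric(pmax_s)
  bad <- phys_max <= phys_min
  phys_max[bad] <- phys_min[bad] + 1
  pmax_s[bad] <- edf_num(phys_max[bad])
  write_edf_impl(trial, path, pmin_s, pmax_s, phys_min, phys_max,
                 -32768, 32767)
  invisible(path)
}

write_edf_impl <- function(trial, path, pmin_s, pmax_s, phys_min, phys_max,
                           dig_min, dig_max) {
  sig <- trial$signal
  n <- nrow(sig); m <- ncol(sig); fs <- trial$sample_rate
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad_field(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr(sprintf("class=%s id=%s", trial$class_label, trial$trial_id), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256 * (1 + m)), 8)
  wr("", 44)
  wr("1", 8)
  wr(edf_num(n / fs), 8)
  wr(as.character(m), 4)
  wfield <- function(vals, w) for (v in vals) wr(v, w)
  wfield(trial$channel_names, 16)
  wfield(rep("", m), 80)
  wfield(rep("uV", m), 8)
  wfield(pmin_s, 8)
  wfield(pmax_s, 8)
  wfield(rep(dig_min, m), 8)
  wfield(rep(dig_max, m), 8)
  wfield(rep("", m), 80)
  wfield(rep(n, m), 8)
  wfield(rep("", m), 32)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (j in seq_len(m)) {
    d <- round((sig[, j] - phys_min[j]) / scale[j]) + dig_min
    d <- pmin(pmax(d, dig_min), dig_max)
    writeBin(as.integer(d), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a trial from an EDF file
#'
#' Reads a (possibly multi-record) 16-bit EDF file. All signals must share
#' one sampling rate. Class label and trial id are recovered from the
#' recording-identification field when written by [write_edf()], and can be
#' overridden.
#'
#' @param path EDF file path.
#' @param class_label Optional class label overriding the header.
#' @param true_velocity Optional n x 2 ground-truth velocity matrix.
#' @param channels Optional ordered channel subset to keep.
#' @return An [eeg_trial()].
#' @export
read_edf <- function(path, class_label = NULL, true_velocity = NULL,
                     channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8)
  if (!identical(ver, "0")) stop("malformed EDF file (version field '", ver, "')")
  rd(80)
  recording <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  m <- as.integer(rd(4))
  if (is.na(m) || m < 1) stop("malformed EDF file (signal count)")
  rdf <- function(w) vapply(seq_len(m), function(j) rd(w), "")
  labels <- rdf(16); rdf(80); rdf(8)
  phys_min <- as.numeric(rdf(8)); phys_max <- as.numeric(rdf(8))
  dig_min <- as.numeric(rdf(8)); dig_max <- as.numeric(rdf(8))
  rdf(80)
  spr <- as.integer(rdf(8))
  rdf(32)
  if (length(unique(spr)) != 1)
    stop("EDF signals with heterogeneous sampling rates are unsupported")
  fs <- spr[1] / rec_dur
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec <- matrix(NA_real_, spr[1], m)
    for (j in seq_len(m)) {
      d <- readBin(con, integer(), n = spr[j], size = 2, endian = "little",
                   signed = TRUE)
      scale <- (phys_max[j] - phys_min[j]) / (dig_max[j] - dig_min[j])
      rec[, j] <- (d - dig_min[j]) * scale + phys_min[j]
    }
    chunks[[r]] <- rec
  }
  sig <- do.call(rbind, chunks)
  cls <- class_label
  tid <- sub("\\.edf$", "", basename(path))
  if (grepl("class=([LRUD]) id=(.*)", recording)) {
    if (is.null(cls)) cls <- sub(".*class=([LRUD]).*", "\\1", recording)
    tid <- sub(".*id=(\\S+).*", "\\1", recording)
  }
  if (is.null(cls)) stop("class label neither in EDF header nor supplied")
  trial <- eeg_trial(sig, fs, labels, cls, true_velocity = true_velocity,
                     trial_id = tid)
  if (!is.null(channels)) trial <- select_channels(trial, channels)
  trial
}

## ---------------------------------------------------------- delimited IO

#' Read a trial from a delimited text file
#'
#' Comma-separated, one row per sample, header row of channel names. The
#' sampling rate is not stored in the file and must be supplied.
#'
#' @param path CSV file path.
#' @param sample_rate Sampling rate in Hz.
#' @param class_label Class label (`"L"`, `"R"`, `"U"`, `"D"`).
#' @param true_velocity Optional n x 2 velocity matrix.
#' @param channels Optional ordered channel subset/reordering.
#' @param trial_id Identifier; defaults to the file stem.
#' @return An [eeg_trial()].
#' @export
read_trial_csv <- function(path, sample_rate, class_label,
                           true_velocity = NULL, channels = NULL,
                           trial_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  trial <- eeg_trial(as.matrix(df), sample_rate, colnames(df), class_label,
                     true_velocity = true_velocity,
                     trial_id = trial_id %||% sub("\\.[^.]*$", "", basename(path)))
  if (!is.null(channels)) trial <- select_channels(trial, channels)
  trial
}

# full-precision numeric text (17 significant digits round-trips doubles)
full_precision_csv <- function(mat, path, col_names) {
  lines <- c(paste(col_names, collapse = ","),
             apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")))
  writeLines(lines, path)
}

#' Write a trial to a delimited text file
#'
#' Values are printed with 17 significant digits, so reading the file back
#' reproduces the doubles exactly.
#'
#' @param trial An [eeg_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  full_precision_csv(trial$signal, path, trial$channel_names)
  invisible(path)
}

## ------------------------------------------------- trial-set container

#' Write a set of trials as a directory container
#'
#' A hierarchical plain-text container: a `manifest.csv` indexing the
#' trials plus, per trial, a full-precision signal CSV, a JSON attribute
#' file (rate, channels, class, error events) and, when present, a
#' velocity CSV. [read_trials()] inverts it exactly (bit-identical doubles).
#'
#' @param trials List of [eeg_trial()] sharing one channel set.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (length(trials)) {
    chsets <- unique(lapply(trials, `[[`, "channel_names"))
    if (length(chsets) != 1)
      stop("trials have heterogeneous channel sets; container requires one")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(seq_along(trials), function(i) sprintf("trial%04d", i), "")
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    full_precision_csv(tr$signal, file.path(path, paste0(ids[i], "_signal.csv")),
                       tr$channel_names)
    if (!is.null(tr$true_velocity))
      full_precision_csv(tr$true_velocity,
                         file.path(path, paste0(ids[i], "_velocity.csv")),
                         c("horizontal", "vertical"))
    meta <- list(trial_id = tr$trial_id, sample_rate = tr$sample_rate,
                 channel_names = tr$channel_names, class_label = tr$class_label,
                 error_events = tr$error_events,
                 has_velocity = !is.null(tr$true_velocity))
    jsonlite::write_json(meta, file.path(path, paste0(ids[i], "_meta.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- data.frame(
    key = ids,
    trial_id = vapply(trials, `[[`, "", "trial_id"),
    class = vapply(trials, `[[`, "", "class_label"),
    n_samples = vapply(trials, function(t) nrow(t$signal), 0L),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a trial-set container written by [write_trials()]
#'
#' @param path Container directory.
#' @return List of [eeg_trial()].
#' @export
read_trials <- function(path) {
  mf <- utils::read.csv(file.path(path, "manifest.csv"),
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(mf)), function(i) {
    key <- mf$key[i]
    meta <- jsonlite::read_json(file.path(path, paste0(key, "_meta.json")),
                                simplifyVector = TRUE)
    sig <- utils::read.csv(file.path(path, paste0(key, "_signal.csv")),
                           check.names = FALSE)
    vel <- NULL
    if (isTRUE(meta$has_velocity))
      vel <- as.matrix(utils::read.csv(file.path(path,
                                                 paste0(key, "_velocity.csv"))))
    eeg_trial(as.matrix(sig), meta$sample_rate, meta$channel_names,
              meta$class_label, true_velocity = vel,
              error_events = as.numeric(meta$error_events),
              trial_id = meta$trial_id)
  })
}
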