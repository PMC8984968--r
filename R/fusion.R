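#' Right-align and concatenate spectral and temporal feature streams
#'
#' The temporal stream starts earlier than the spectral stream (shorter
#' window), so its leading rows have no spectral counterpart. The streams
#' are right-aligned along time by dropping the first
#' `nrow(xt) - nrow(xs)` rows of the temporal stream (10 at the defaults),
#' then concatenated column-wise, spectral first.
#'
#' @param xs Spectral [feature_seq()].
#' @param xt Temporal [feature_seq()] with at least as many rows as `xs`.
#' @return A fused [feature_seq()] with `nrow(xs)` rows and
#'   `ncol(xs) + ncol(xt)` columns.
#' @export
fuse_features <- function(xs, xt) {
  stopifnot(inherits(xs, "feature_seq"), inherits(xt, "feature_seq"))
  extra <- nrow(xt$values) - nrow(xs$values)
  if (extra < 0)
    stop("temporal stream has fewer rows (", nrow(xt$values),
         ") than spectral (", nrow(xs$values), "); cannot right-align")
  vt <- xt$values[(extra + 1L):nrow(xt$values), , drop = FALSE]
  feature_seq(cbind(xs$values, vt), start_offset = xs$start_offset,
              step_samples = xs$step_samples, kind = "fused")
}

#' Segment a feature sequence into fixed-length blocks
#'
#' Takes `floor(rows / seg_len)` non-overlapping consecutive blocks of
#' `seg_len` rows from the start; trailing remainder rows are discarded.
#'
#' @param fused A [feature_seq()].
#' @param seg_len Rows per block (default 30).
#' @return List of `seg_len x features` matrices (possibly empty, with a
#'   warning, when there are fewer than `seg_len` rows).
#' @export
segment_features <- function(fused, seg_len = 30L) {
  v <- fused$values
  nb <- nrow(v) %/% seg_len
  if (nb == 0L) {
    warning("fewer rows (", nrow(v), ") than segment length (", seg_len,
            "); no samples produced")
    return(list())
  }
  lapply(seq_len(nb), function(b)
    v[((b - 1L) * seg_len + 1L):(b * seg_len), , drop = FALSE])
}

# zero the non-class axis: horizontal for U/D, vertical for L/R
zero_non_class_axis <- function(label, class_label) {
  if (class_label %in% c("U", "D")) label[1] <- 0 else label[2] <- 0
  label
}

#' Attach velocity labels to segmented feature blocks
#'
#' Each block's label is the mean ground-truth velocity over the raw-sample
#' span the block covers (block b of a fused stream whose windows end at
#' `start_offset` covers raw samples
#' `[(b-1) seg_len + 1, b seg_len + start_offset - 1]`), with the
#' non-class axis then forced to zero: horizontal for U/D trials, vertical
#' for L/R trials.
#'
#' @param trial The source [eeg_trial()]; must carry `true_velocity`.
#' @param blocks List of feature blocks from [segment_features()].
#' @param start_offset Window-end offset of the fused stream (40 at the
#'   defaults).
#' @return List of `velocity_sample` objects (fields: `features`, `label`,
#'   `class_label`, `trial_id`, `segment_index`).
#' @export
velocity_samples <- function(trial, blocks, start_offset = 40L) {
  if (is.null(trial$true_velocity))
    stop("trial '", trial$trial_id, "' carries no ground-truth velocity")
  n <- nrow(trial$signal)
  lapply(seq_along(blocks), function(b) {
    seg_len <- nrow(blocks[[b]])
    from <- (b - 1L) * seg_len + 1L
    to <- min(b * seg_len + start_offset - 1L, n)
    lab <- colMeans(trial$true_velocity[from:to, , drop = FALSE])
    lab <- zero_non_class_axis(lab, trial$class_label)
    structure(list(features = blocks[[b]], label = lab,
                   class_label = trial$class_label, trial_id = trial$trial_id,
                   segment_index = b), class = "velocity_sample")
  })
}

#' Build a fused, segmented, labelled dataset from trials
#'
#' Runs the full feature pipeline on each trial (spectral sliding-window
#' band power, temporal wavelet features, right-align + concatenate,
#' segment, label) and stacks the samples.
#'
#' @param trials List of [eeg_trial()].
#' @param sspec A [spectral_spec()].
#' @param wspec A [wavelet_spec()].
#' @param seg_len Sequence length per sample (default 30).
#' @return A `fused_dataset`: list with `x` (array samples x seg_len x
#'   features), `y` (samples x 2 velocity labels), `class`, `trial_id`,
#'   `segment`, `split_tag`.
#' @export
build_dataset <- function(trials, sspec = spectral_spec(),
                          wspec = wavelet_spec(), seg_len = 30L) {
  samples <- list()
  for (tr in trials) {
    xs <- spectral_features(tr, sspec)
    xt <- temporal_features(tr, wspec)
    fused <- fuse_features(xs, xt)
    blocks <- segment_features(fused, seg_len)
    samples <- c(samples,
                 velocity_samples(tr, blocks, start_offset = fused$start_offset))
  }
  as_fused_dataset(samples)
}

#' Assemble velocity samples into a fused dataset
#'
#' @param samples List of `velocity_sample` objects with identical
#'   dimensions.
#' @param split_tag Optional tag (`"TRAIN"`, `"TEST"`, `"TESTUD"`,
#'   `"TESTLR"`, `"none"`).
#' @return A `fused_dataset`.
#' @export
as_fused_dataset <- function(samples, split_tag = "none") {
  n <- length(samples)
  if (n == 0L) stop("no samples")
  dims <- dim(samples[[1]]$features)
  x <- array(0, dim = c(n, dims[1], dims[2]))
  y <- matrix(0, n, 2, dimnames = list(NULL, c("horizontal", "vertical")))
  for (i in seq_len(n)) {
    if (!all(dim(samples[[i]]$features) == dims))
      stop("samples with inconsistent feature dimensions")
    x[i, , ] <- samples[[i]]$features
    y[i, ] <- samples[[i]]$label
  }
  structure(list(
    x = x, y = y,
    class = vapply(samples, `[[`, "", "class_label"),
    trial_id = vapply(samples, `[[`, "", "trial_id"),
    segment = vapply(samples, `[[`, 0L, "segment_index"),
    split_tag = split_tag), class = "fused_dataset")
}

#' @export
print.fused_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<fused_dataset %s> %d samples x (T = %d, E = %d), %d trial(s)\n",
              x$split_tag, d[1], d[2], d[3], length(unique(x$trial_id))))
  print(table(class = x$class))
  invisible(x)
}

#' Number of samples in a fused dataset
#' @param ds A `fused_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(ds) dim(ds$x)[1]

#' Subset a fused dataset by sample index
#' @param ds A `fused_dataset`.
#' @param idx Integer or logical index over samples.
#' @param split_tag Tag for the result.
#' @return A `fused_dataset`.
#' @export
subset_samples <- function(ds, idx, split_tag = ds$split_tag) {
  structure(list(x = ds$x[idx, , , drop = FALSE],
                 y = ds$y[idx, , drop = FALSE],
                 class = ds$class[idx], trial_id = ds$trial_id[idx],
                 segment = ds$segment[idx], split_tag = split_tag),
            class = "fused_dataset")
}

#' Class-balanced trial-level train/test split
#'
#' Splits at trial granularity (no trial's samples straddle the
#' partitions) with the train fraction applied within every class, then
#' derives the class-filtered test views: TESTUD (U/D trials only) and
#' TESTLR (L/R only). Deterministic given `seed`.
#'
#' @param ds A `fused_dataset`.
#' @param ratio Train fraction (default 0.7).
#' @param seed Integer seed for the trial shuffle.
#' @return List with `train`, `test`, `test_ud`, `test_lr` fused datasets.
#' @export
split_dataset <- function(ds, ratio = 0.7, seed = 1) {
  set.seed(seed)
  train_trials <- character(0)
  for (cl in c("L", "R", "U", "D")) {
    tr_ids <- unique(ds$trial_id[ds$class == cl])
    if (length(tr_ids) == 0L) stop("class ", cl, " has no trials")
    n_train <- max(1L, min(length(tr_ids) - 1L, round(ratio * length(tr_ids))))
    if (length(tr_ids) == 1L) n_train <- 1L
    train_trials <- c(train_trials, sample(tr_ids)[seq_len(n_train)])
  }
  in_train <- ds$trial_id %in% train_trials
  test <- subset_samples(ds, !in_train, "TEST")
  list(train = subset_samples(ds, in_train, "TRAIN"),
       test = test,
       test_ud = subset_samples(test, test$class %in% c("U", "D"), "TESTUD"),
       test_lr = subset_samples(test, test$class %in% c("L", "R"), "TESTLR"))
}
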