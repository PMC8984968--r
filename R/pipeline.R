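#' Pipeline run configuration
#'
#' One configuration object driving every stage. A master seed fans out to
#' per-stage seeds deterministically (`stage_seed = master * 8 + k`, kept
#' below 2^31), so a rerun from the echoed configuration reproduces every
#' artifact bit-for-bit.
#'
#' @param sim A [sim_config()].
#' @param trials_per_class Trials per class for the simulate stage.
#' @param preprocess A [preprocess_spec()] or `NULL` to skip filtering
#'   (simulated data is already at the target rate).
#' @param spectral A [spectral_spec()].
#' @param wavelet A [wavelet_spec()].
#' @param seg_len Sequence length per decoded sample.
#' @param split_ratio Train fraction of trials per class.
#' @param lambda Velocity-constraint weight.
#' @param hidden,epochs,lr Decoder size and training settings.
#' @param gate_width Gate width for evaluation, pixels.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), trials_per_class = 10,
                       preprocess = NULL, spectral = spectral_spec(),
                       wavelet = wavelet_spec(), seg_len = 30,
                       split_ratio = 0.7, lambda = 0.01, hidden = 100,
                       epochs = 300, lr = 1e-3, gate_width = 400, seed = 1) {
  stopifnot(seed == round(seed), abs(seed) * 8 + 4 < 2^31)
  structure(as.list(environment()), class = "run_config")
}

stage_seed <- function(config, k) as.integer(abs(config$seed) * 8 + k)

config_as_plain_list <- function(config) {
  rapply(unclass(config), function(x) x, how = "replace")
}

#' Write a configuration echo
#'
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_as_plain_list(config), path)
  invisible(path)
}

#' Read a configuration echo written by [write_config()]
#'
#' @param path YAML path.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(
    sim = do.call(sim_config, raw$sim[names(raw$sim) != "n_channels"]),
    trials_per_class = raw$trials_per_class,
    preprocess = if (is.null(raw$preprocess)) NULL else
      do.call(preprocess_spec, raw$preprocess),
    spectral = do.call(spectral_spec, raw$spectral),
    wavelet = do.call(wavelet_spec, raw$wavelet),
    seg_len = raw$seg_len, split_ratio = raw$split_ratio,
    lambda = raw$lambda, hidden = raw$hidden, epochs = raw$epochs,
    lr = raw$lr, gate_width = raw$gate_width, seed = raw$seed)
  cfg
}

write_report_json <- function(report, path) {
  out <- list(
    test = report$test, test_ud = report$test_ud, test_lr = report$test_lr,
    gate_successes = report$gate_successes,
    gate_trials = report$gate_trials,
    gate_by_trial = as.list(report$gate_by_trial),
    eps = report$eps, acc_scale = report$acc_scale,
    gate_width = report$gate_width)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Stages (in order): `simulate` writes a trial container and manifest;
#' `preprocess` filters it (skipped when `config$preprocess` is `NULL`);
#' `featurize` builds the fused dataset and the train/test split; `train`
#' fits the decoder; `evaluate` writes a JSON report and per-trial
#' trajectory CSVs. Later stages read the artifacts of earlier ones from
#' `out_dir`, so a subset of stages can be rerun. Every run writes a
#' `config.yaml` echo sufficient to reproduce it exactly.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of
#'   `c("simulate", "preprocess", "featurize", "train", "evaluate")`.
#' @param verbose Print stage logs.
#' @return Invisibly, a list with the paths of the produced artifacts and
#'   (when computed) the evaluation report.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "featurize", "train",
                                    "evaluate"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  known <- c("simulate", "preprocess", "featurize", "train", "evaluate")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- known[known %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  paths <- list(
    config = file.path(out_dir, "config.yaml"),
    container = file.path(out_dir, "trials"),
    dataset = file.path(out_dir, "dataset.rds"),
    model = file.path(out_dir, "model.rds"),
    report = file.path(out_dir, "report.json"),
    traj_dir = file.path(out_dir, "trajectories"))
  write_config(config, paths$config)
  report <- NULL

  if ("simulate" %in% stages) {
    sim <- simulate_dataset(config$sim, config$trials_per_class,
                            seed = stage_seed(config, 1))
    write_trials(sim$trials, paths$container)
    utils::write.csv(sim$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    say("simulate: %d trials x %d samples x %d channels",
        length(sim$trials), nrow(sim$trials[[1]]$signal),
        ncol(sim$trials[[1]]$signal))
  }

  if ("preprocess" %in% stages) {
    if (!dir.exists(paths$container))
      stop("preprocess: missing input container ", paths$container)
    trials <- lapply(read_trials(paths$container), preprocess,
                     spec = config$preprocess %||% preprocess_spec())
    write_trials(trials, paths$container)
    say("preprocess: %d trials -> %g Hz", length(trials),
        trials[[1]]$sample_rate)
  }

  if ("featurize" %in% stages) {
    if (!dir.exists(paths$container))
      stop("featurize: missing input container ", paths$container)
    trials <- read_trials(paths$container)
    ds <- build_dataset(trials, config$spectral, config$wavelet,
                        config$seg_len)
    split <- split_dataset(ds, config$split_ratio,
                           seed = stage_seed(config, 2))
    saveRDS(split, paths$dataset)
    say("featurize: %d samples (T = %d, E = %d); train %d / test %d",
        n_samples(ds), dim(ds$x)[2], dim(ds$x)[3],
        n_samples(split$train), n_samples(split$test))
  }

  if ("train" %in% stages) {
    if (!file.exists(paths$dataset))
      stop("train: missing dataset ", paths$dataset)
    split <- readRDS(paths$dataset)
    model <- stlstm(split$train, lambda = config$lambda,
                    hidden = config$hidden, epochs = config$epochs,
                    lr = config$lr, seed = stage_seed(config, 3))
    saveRDS(model, paths$model)
    say("train: final total loss %.4g",
        utils::tail(model$history$total, 1))
  }

  if ("evaluate" %in% stages) {
    if (!file.exists(paths$model)) stop("evaluate: missing model ", paths$model)
    if (!file.exists(paths$dataset))
      stop("evaluate: missing dataset ", paths$dataset)
    model <- readRDS(paths$model)
    split <- readRDS(paths$dataset)
    report <- evaluate_decoder(model, split$test, split$test_ud,
                               split$test_lr, gate_width = config$gate_width)
    write_report_json(report, paths$report)
    dir.create(paths$traj_dir, showWarnings = FALSE)
    for (id in names(report$trajectories)) {
      pos <- report$trajectories[[id]]$positions
      utils::write.csv(data.frame(step = seq_len(nrow(pos)) - 1L,
                                  x = pos[, 1], y = pos[, 2]),
                       file.path(paths$traj_dir, paste0(id, ".csv")),
                       row.names = FALSE)
    }
    say("evaluate: gate %d/%d", report$gate_successes, report$gate_trials)
  }

  invisible(list(paths = paths, report = report))
}
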