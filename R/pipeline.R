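# End-to-end orchestration: config handling, stage commands with run
# manifests, and the channel-ablation harness.

#' Default pipeline configuration
#'
#' One nested list covering every stage; [cmd_simulate()] and friends take
#' this structure (or a YAML file deep-merged onto it via
#' [read_run_config()]).
#'
#' @param seed master seed recorded in every manifest and used by all stages.
#' @param outdir output directory for stage artifacts.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1, outdir = "nmfdecode_run") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    montage = list(set = "set1"),
    synth = list(n_channels = 60, fs = 1000,
                 classes = c("KG", "PG", "WE", "WF"),
                 trials_per_class = 20, trial_s = 5, rest_s = 5,
                 snr = 4, erd = FALSE, drift = 0, shift = 0),
    preprocess = list(low = 1, high = 40, order = 4, zero_phase = TRUE,
                      n_train = 16, n_test = 4,
                      block_ms = 100, hop_ms = 50, segment_ms = 20,
                      normalizer_all_blocks = FALSE),
    nmf = list(r = 2, max_iter = 200, tol = 1e-5, eps = 1e-9),
    encoder = list(latent_dim = 32, stage_channels = c(32, 64, 128),
                   stage_strides = c(1, 2, 2), blocks_per_stage = c(1, 1, 1),
                   kernel = 3, padding = 1),
    training = list(lr = 1e-3, pretrain_epochs = 50, joint_epochs = 50,
                    batch_size = 64, M = 8, lambda_contrastive = 0),
    ablation = list(no_nmf = FALSE, no_joint_refinement = FALSE)
  )
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default, so partial configs are valid.
#'
#' @param path YAML file.
#' @param seed optional seed overriding both file and default.
#' @return configuration list.
#' @export
read_run_config <- function(path = NULL, seed = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
    cfg <- deep_merge(cfg, yaml::read_yaml(path))
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  bad <- character()
  chk <- function(cond, field) if (!cond) bad <<- c(bad, field)
  chk(is_scalar_number(cfg$seed), "seed")
  chk(cfg$montage$set %in% paste0("set", 1:6), "montage$set")
  chk(cfg$synth$snr >= 0, "synth$snr")
  chk(cfg$preprocess$low < cfg$preprocess$high, "preprocess$low/high")
  chk(cfg$nmf$r >= 1, "nmf$r")
  chk(cfg$training$lr > 0, "training$lr")
  if (length(bad))
    abort_argument(sprintf("invalid configuration fields: %s",
                           paste(bad, collapse = ", ")))
  invisible(cfg)
}

write_manifest <- function(cfg, stage, outdir, extra = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(list(stage = stage, seed = cfg$seed,
                     package = "nmfdecode",
                     version = as.character(utils::packageVersion("nmfdecode")),
                     config = cfg), extra)
  path <- file.path(outdir, sprintf("%s_manifest.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Pipeline stage commands
#'
#' File-based stages mirroring a decoding study: `cmd_simulate` writes a
#' synthetic recording, `cmd_extract` turns it into standardized block
#' features, `cmd_train` fits the two-stage model, `cmd_evaluate` scores the
#' held-out blocks, and `cmd_ablate_channels` repeats the whole chain for
#' each of the six channel sets. Every stage writes a JSON manifest capturing
#' the full configuration and seed, so a rerun with the same config
#' reproduces identical outputs.
#'
#' @param config configuration list (see [default_config()]).
#' @return `cmd_simulate` the recording path; `cmd_extract` the feature
#'   file path; `cmd_train` the checkpoint path; `cmd_evaluate` a
#'   `metrics_report`; `cmd_ablate_channels` a data.frame with one row per
#'   channel set.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(config = default_config()) {
  validate_config(config)
  outdir <- file.path(config$outdir, "data")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sp <- config$synth
  spec <- synthetic_spec(n_channels = sp$n_channels, fs = sp$fs,
                         classes = sp$classes,
                         trials_per_class = sp$trials_per_class,
                         trial_s = sp$trial_s, rest_s = sp$rest_s,
                         snr = sp$snr, channels = sp$channels,
                         pattern_focus = sp$pattern_focus,
                         erd = isTRUE(sp$erd), drift = sp$drift,
                         shift = sp$shift, seed = config$seed)
  rec <- generate_dataset(spec)
  path <- file.path(outdir, "recording.tsv")
  write_recording(rec, path)
  write_manifest(config, "simulate", outdir,
                 list(recording = path, n_annotations = nrow(rec$annotations)))
  invisible(path)
}

# Shared in-memory chain: recording -> standardized train/test features.
prepare_features <- function(rec, config) {
  pp <- config$preprocess
  if (!identical(config$montage$set, "set1") ||
      length(rec$channel_labels) != length(get_channel_set(config$montage$set)$labels))
    rec <- subset_channels(rec, get_channel_set(config$montage$set))
  rec <- bandpass_filter(rec, pp$low, pp$high, pp$order,
                         zero_phase = isTRUE(pp$zero_phase))
  ts <- epoch_trials(rec)
  sp <- split_trials(ts, pp$n_train, pp$n_test,
                     seed = derive_seed(config$seed, 11L))
  mk <- function(t) blocks_from_trials(t, pp$block_ms, pp$hop_ms, pp$segment_ms)
  if (isTRUE(config$ablation$no_nmf)) {
    tr <- extract_raw_features(mk(sp$train))
    te <- extract_raw_features(mk(sp$test))
  } else {
    ncfg <- nmf_config(config$nmf$r, config$nmf$max_iter, config$nmf$tol,
                       config$nmf$eps, seed = derive_seed(config$seed, 13L))
    tr <- extract_features(mk(sp$train), ncfg)
    te <- extract_features(mk(sp$test), ncfg)
  }
  if (isTRUE(pp$normalizer_all_blocks)) {
    all_fd <- tr
    all_fd$features <- c(tr$features, te$features)
    all_fd$labels <- c(tr$labels, te$labels)
    ns <- fit_normalizer(all_fd)
  } else {
    ns <- fit_normalizer(tr)
  }
  list(train = apply_normalizer(tr, ns), test = apply_normalizer(te, ns),
       norm_stats = ns, channel_labels = rec$channel_labels)
}

#' @rdname pipeline-commands
#' @export
cmd_extract <- function(config = default_config()) {
  validate_config(config)
  rec_path <- file.path(config$outdir, "data", "recording.tsv")
  if (!file.exists(rec_path))
    abort_io(sprintf("no recording at %s; run cmd_simulate first", rec_path))
  rec <- load_recording(rec_path)
  fs <- prepare_features(rec, config)
  outdir <- file.path(config$outdir, "features")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(outdir, "features.rds")
  saveRDS(fs, path)
  write_manifest(config, "extract", outdir,
                 list(features = path,
                      n_train = length(fs$train$features),
                      n_test = length(fs$test$features),
                      feature_shape = dim(fs$train$features[[1]]),
                      nmf = !isTRUE(config$ablation$no_nmf)))
  invisible(path)
}

# Shared in-memory training: standardized features -> fitted model.
fit_model <- function(train_fd, config) {
  d <- dim(train_fd$features[[1]])
  tc <- config$training
  ec <- encoder_config(in_channels = d[1],
                       n_classes = length(unique(train_fd$labels)),
                       stage_channels = config$encoder$stage_channels,
                       stage_strides = config$encoder$stage_strides,
                       blocks_per_stage = config$encoder$blocks_per_stage,
                       kernel = config$encoder$kernel,
                       padding = config$encoder$padding,
                       latent_dim = config$encoder$latent_dim,
                       input_length = d[2])
  model <- build_encoder(ec, seed = derive_seed(config$seed, 17L))
  cfg <- train_config(lr = tc$lr, pretrain_epochs = tc$pretrain_epochs,
                      joint_epochs = tc$joint_epochs,
                      batch_size = tc$batch_size, M = tc$M,
                      lambda_contrastive = tc$lambda_contrastive,
                      master_seed = derive_seed(config$seed, 19L))
  pre_hist <- pretrain_contrastive(model, train_fd, cfg)
  joint_hist <- if (isTRUE(config$ablation$no_joint_refinement)) {
    train_head_only(model, train_fd, cfg)
  } else {
    joint_train(model, train_fd, cfg)
  }
  list(model = model, pretrain_history = pre_hist,
       joint_history = joint_hist)
}

#' @rdname pipeline-commands
#' @export
cmd_train <- function(config = default_config()) {
  validate_config(config)
  feat_path <- file.path(config$outdir, "features", "features.rds")
  if (!file.exists(feat_path))
    abort_io(sprintf("no features at %s; run cmd_extract first", feat_path))
  fs <- readRDS(feat_path)
  fit <- fit_model(fs$train, config)
  outdir <- file.path(config$outdir, "model")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ckpt <- file.path(outdir, "encoder.rds")
  save_encoder(fit$model, ckpt)
  if (nrow(fit$pretrain_history))
    data.table::fwrite(fit$pretrain_history,
                       file.path(outdir, "pretrain_log.csv"))
  if (nrow(fit$joint_history))
    data.table::fwrite(fit$joint_history, file.path(outdir, "joint_log.csv"))
  write_manifest(config, "train", outdir,
                 list(checkpoint = ckpt,
                      variant = if (isTRUE(config$ablation$no_nmf))
                        "no-nmf" else if (isTRUE(config$ablation$no_joint_refinement))
                          "no-joint-refinement" else "full",
                      pretrain_epochs_run = nrow(fit$pretrain_history),
                      joint_epochs_run = nrow(fit$joint_history)))
  invisible(ckpt)
}

#' @rdname pipeline-commands
#' @export
cmd_evaluate <- function(config = default_config()) {
  validate_config(config)
  feat_path <- file.path(config$outdir, "features", "features.rds")
  ckpt <- file.path(config$outdir, "model", "encoder.rds")
  if (!file.exists(feat_path) || !file.exists(ckpt))
    abort_io("missing features or checkpoint; run earlier stages first")
  fs <- readRDS(feat_path)
  model <- load_encoder(ckpt)
  pred <- predict_labels(model, fs$test)
  rep <- confusion_and_metrics(fs$test$labels, pred, model$classes)
  trial_rep <- majority_vote_metrics(fs$test$labels, pred, fs$test$trial,
                                     model$classes)
  outdir <- file.path(config$outdir, "metrics")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(accuracy = rep$accuracy, macro_f1 = rep$macro_f1,
         kappa = rep$kappa, n_blocks = rep$n_blocks,
         trial_accuracy = trial_rep$accuracy,
         trial_macro_f1 = trial_rep$macro_f1),
    file.path(outdir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(as.data.frame.matrix(rep$confusion),
                     file.path(outdir, "confusion.csv"), row.names = TRUE)
  write_manifest(config, "evaluate", outdir)
  rep
}

#' @rdname pipeline-commands
#' @export
cmd_ablate_channels <- function(config = default_config()) {
  validate_config(config)
  rec_path <- file.path(config$outdir, "data", "recording.tsv")
  if (!file.exists(rec_path))
    abort_io(sprintf("no recording at %s; run cmd_simulate first", rec_path))
  rec <- load_recording(rec_path)
  rows <- lapply(paste0("set", 1:6), function(s) {
    cfg <- config
    cfg$montage$set <- s
    fs <- prepare_features(rec, cfg)
    fit <- fit_model(fs$train, cfg)
    pred <- predict_labels(fit$model, fs$test)
    rep <- confusion_and_metrics(fs$test$labels, pred, fit$model$classes)
    data.frame(set = s,
               n_channels = length(get_channel_set(s)$labels),
               accuracy = rep$accuracy, macro_f1 = rep$macro_f1,
               kappa = rep$kappa, n_blocks = rep$n_blocks)
  })
  tab <- do.call(rbind, rows)
  outdir <- file.path(config$outdir, "ablation")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(tab, file.path(outdir, "channel_ablation.csv"))
  write_manifest(config, "ablate_channels", outdir)
  tab
}

#' Run the full decoding pipeline in memory
#'
#' Generate (or accept) a recording, prepare features, fit the two-stage
#' model and score held-out blocks, without touching the filesystem. This is
#' the programmatic equivalent of simulate + extract + train + evaluate.
#'
#' @param config configuration list.
#' @param rec optional pre-made [raw_recording()]; generated from
#'   `config$synth` when missing.
#' @return list with `metrics` (a `metrics_report`), `trial_metrics`,
#'   `model`, `features`, and the training histories.
#' @export
run_pipeline <- function(config = default_config(), rec = NULL) {
  validate_config(config)
  if (is.null(rec)) {
    sp <- config$synth
    spec <- synthetic_spec(n_channels = sp$n_channels, fs = sp$fs,
                           classes = sp$classes,
                           trials_per_class = sp$trials_per_class,
                           trial_s = sp$trial_s, rest_s = sp$rest_s,
                           snr = sp$snr, channels = sp$channels,
                           pattern_focus = sp$pattern_focus,
                           erd = isTRUE(sp$erd), drift = sp$drift,
                           shift = sp$shift, seed = config$seed)
    rec <- generate_dataset(spec)
  }
  fs <- prepare_features(rec, config)
  fit <- fit_model(fs$train, config)
  pred <- predict_labels(fit$model, fs$test)
  rep <- confusion_and_metrics(fs$test$labels, pred, fit$model$classes)
  trial_rep <- majority_vote_metrics(fs$test$labels, pred, fs$test$trial,
                                     fit$model$classes)
  list(metrics = rep, trial_metrics = trial_rep, model = fit$model,
       features = fs, pretrain_history = fit$pretrain_history,
       joint_history = fit$joint_history)
}
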