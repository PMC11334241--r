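#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end pipeline, with every default
#' explicit.  Unknown keys in an override are rejected.
#'
#' @param overrides Named nested list (or path to a YAML file) overriding
#'   defaults section-by-section.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(overrides = NULL) {
  defaults <- list(
    seed = 1L,
    out_dir = "siamquality_run",
    stages = c("simulate", "preprocess", "pair", "pretrain", "finetune",
               "evaluate"),
    simulate = list(n_patients = 4, recording_minutes = 10, fs = 240,
                    hr_range = c(50, 130), bursts_per_10min = 8,
                    drift_level = 0.1),
    preprocess = list(segment_seconds = 30, target_fs = 40,
                      labels = "truth"),
    pair = list(window_seconds = 300, low_quality_threshold = 0.2,
                anchor_threshold = 0),
    model = list(encoder_variant = "tiny_1d", projection_dim = 32),
    pretrain = list(epochs = 3, batch_size = 8, learning_rate = 0.05,
                    curriculum_mode = "staged_buckets"),
    finetune = list(strategy = "fine_tune_all", epochs = 20, batch_size = 16,
                    learning_rate = 0.01, test_fraction = 0.2),
    evaluate = list(thresholds = seq(0, 1, by = 0.1)))
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (is.null(overrides)) overrides <- list()
  check_keys <- function(defs, ovr, path = "") {
    unknown <- setdiff(names(ovr), names(defs))
    if (length(unknown))
      stopf("unknown config key(s): %s",
            paste0(path, unknown, collapse = ", "))
    for (nm in names(ovr))
      if (is.list(defs[[nm]]) && is.list(ovr[[nm]]))
        check_keys(defs[[nm]], ovr[[nm]], paste0(path, nm, "."))
  }
  check_keys(defaults, overrides)
  cfg <- modifyList(defaults, overrides)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

log_event <- function(log_path, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the end-to-end pipeline
#'
#' Executes the selected stages -- simulate, preprocess, pair, pretrain,
#' finetune (a heart-rate regression on the generator heart rates),
#' evaluate (AT-curve of the regression error against segment artifact
#' fraction) -- writing each stage's artifacts plus a JSON-lines log with
#' the seed and a config hash to the output directory.  Any stage can be
#' re-run standalone from a directory holding the upstream artifacts.
#'
#' @param config A \code{\link{run_config}} (or overrides acceptable to it).
#' @return Invisibly, a list of stage results (paths and key metrics).
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  hash <- config_hash(config)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
  log_event(log_path, "start", seed = config$seed, config_hash = hash)
  results <- list(config_hash = hash)

  store_dir <- file.path(config$out_dir, "segments")
  pairs_path <- file.path(config$out_dir, "pairs.csv")
  ckpt_path <- file.path(config$out_dir, "pretrained.rds")

  if ("simulate" %in% config$stages) {
    sc <- config$simulate
    corpus <- make_corpus(sc$n_patients, sc$recording_minutes, sc$fs,
                          sc$hr_range,
                          artifact_schedule(bursts_per_10min = sc$bursts_per_10min,
                                            drift_level = sc$drift_level),
                          seed = config$seed)
    rec_dir <- file.path(config$out_dir, "recordings")
    dir.create(rec_dir, showWarnings = FALSE)
    for (rec in corpus)
      write_recording(rec, file.path(rec_dir, paste0(rec$patient_id, ".csv")))
    results$recordings <- rec_dir
    log_event(log_path, "simulate", n_patients = length(corpus),
              config_hash = hash)
  }

  if ("preprocess" %in% config$stages) {
    rec_dir <- file.path(config$out_dir, "recordings")
    if (!dir.exists(rec_dir))
      stopf("preprocess: missing upstream recordings at %s", rec_dir)
    files <- list.files(rec_dir, pattern = "\\.csv$", full.names = TRUE)
    corpus <- lapply(files, read_recording)
    pc <- config$preprocess
    segments <- preprocess_corpus(corpus, pc$segment_seconds, pc$target_fs,
                                  labels = pc$labels)
    write_segment_store(segments, store_dir)
    results$segments <- store_dir
    log_event(log_path, "preprocess", n_segments = length(segments),
              config_hash = hash)
  }

  if ("pair" %in% config$stages) {
    if (!dir.exists(store_dir))
      stopf("pair: missing upstream segment store at %s", store_dir)
    segments <- read_segment_store(store_dir)
    pcfg <- pairing_config(config$pair$window_seconds,
                           config$pair$low_quality_threshold,
                           config$pair$anchor_threshold)
    pairs <- find_pairs(segments, pcfg)
    write_pairs(pairs, pairs_path)
    results$pairs <- pairs_path
    results$n_pairs <- nrow(pairs)
    log_event(log_path, "pair", n_pairs = nrow(pairs), config_hash = hash)
  }

  if ("pretrain" %in% config$stages) {
    if (!file.exists(pairs_path))
      stopf("pretrain: missing upstream pairs manifest at %s", pairs_path)
    segments <- read_segment_store(store_dir)
    pairs <- read_pairs(pairs_path)
    mc <- model_config(encoder_variant = config$model$encoder_variant,
                       input_length = length(segments[[1]]$samples),
                       projection_dim = config$model$projection_dim)
    model <- siam_model(mc, seed = config$seed)
    ptc <- pretrain_config(epochs = config$pretrain$epochs,
                           batch_size = config$pretrain$batch_size,
                           learning_rate = config$pretrain$learning_rate,
                           curriculum_mode = config$pretrain$curriculum_mode,
                           seed = config$seed)
    fit <- pretrain(segments, pairs, model, ptc)
    save_checkpoint(fit$model, ckpt_path)
    trace_df <- fit$trace$steps
    for (i in seq_len(nrow(trace_df)))
      log_event(log_path, "pretrain_step", step = trace_df$step[i],
                loss = trace_df$loss[i], mean_c = trace_df$mean_c[i])
    results$pretrain_loss <- fit$trace$epoch_loss
    results$dispersion <- tail(fit$trace$epoch_dispersion, 1)
    log_event(log_path, "pretrain",
              final_loss = tail(fit$trace$epoch_loss, 1),
              dispersion = results$dispersion, config_hash = hash)
  }

  if ("finetune" %in% config$stages) {
    if (!file.exists(ckpt_path))
      stopf("finetune: missing upstream checkpoint at %s", ckpt_path)
    segments <- read_segment_store(store_dir)
    model <- load_checkpoint(ckpt_path)
    hr <- vapply(segments, function(s) s$meta$hr_bpm %||% NA_real_, 0)
    if (anyNA(hr)) stopf("finetune: segments lack generator heart rates")
    pids <- unique(vapply(segments, `[[`, "", "patient_id"))
    n_test <- max(1L, round(config$finetune$test_fraction * length(pids)))
    test_pids <- tail(pids, n_test)
    is_test <- vapply(segments, function(s) s$patient_id %in% test_pids, TRUE)
    fc <- finetune_config(strategy = config$finetune$strategy,
                          epochs = config$finetune$epochs,
                          batch_size = config$finetune$batch_size,
                          learning_rate = config$finetune$learning_rate,
                          seed = config$seed)
    ft <- finetune(model, segments[!is_test], hr[!is_test], fc)
    saveRDS(ft, file.path(config$out_dir, "finetuned.rds"))
    test_segs <- segments[is_test]
    preds <- predict(ft, test_segs)
    test_mae <- mae(hr[is_test], preds)
    pred_df <- data.frame(segment_id = vapply(test_segs, `[[`, "", "segment_id"),
                          y = vapply(test_segs, `[[`, 0, "y"),
                          hr_true = hr[is_test], hr_pred = preds)
    write.csv(pred_df, file.path(config$out_dir, "predictions.csv"),
              row.names = FALSE)
    results$test_mae <- test_mae
    log_event(log_path, "finetune", test_mae = test_mae, config_hash = hash)
  }

  if ("evaluate" %in% config$stages) {
    pred_path <- file.path(config$out_dir, "predictions.csv")
    if (!file.exists(pred_path))
      stopf("evaluate: missing upstream predictions at %s", pred_path)
    pred_df <- read.csv(pred_path)
    curve <- at_curve(pred_df$y, pred_df$hr_true, pred_df$hr_pred, "mae",
                      config$evaluate$thresholds)
    write.csv(as.data.frame(curve), file.path(config$out_dir, "at_curve.csv"),
              row.names = FALSE)
    results$at_curve <- curve
    log_event(log_path, "evaluate",
              overall_mae = curve$metric[nrow(curve)], config_hash = hash)
  }

  log_event(log_path, "done", config_hash = hash)
  invisible(results)
}
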