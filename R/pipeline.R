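#' Default run configuration
#'
#' A fully serializable description of one end-to-end run: data source (a
#' directory-per-class tree, or the synthetic generator when `root` is `NULL`),
#' preprocessing, backbone candidates, fusion hyperparameters and the training
#' recipe. A run can be replayed exactly from its persisted config and seed.
#'
#' The desk-scale defaults (small images, 64-d stub features, P = 64) keep a
#' full run inside a couple of minutes on one CPU; the reference-scale settings
#' (224 x 224 inputs, 768-d features, P = 256, r = 32) are reached by changing
#' the corresponding fields.
#'
#' @param seed Global integer seed; all stage seeds are spawned from it.
#' @param out_dir Output directory for run artifacts.
#' @param data,preprocessing,backbones,fusion,train Optional lists overriding
#'   individual fields of the corresponding config blocks.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, out_dir = tempfile("qfuse_run_"),
                               data = list(), preprocessing = list(),
                               backbones = list(), fusion = list(), train = list()) {
  base <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    data = list(root = NULL, n_per_class = 200, image_size = 32, n_classes = 5,
                signal_strength = 1, interaction_only = FALSE, noise_sd = 10),
    preprocessing = list(test_fraction = 0.2, val_fraction_of_train = 0.1,
                         stratified = TRUE, stats_from = "all"),
    backbones = list(candidates = c("tiny_pool_a", "tiny_pool_b", "tiny_tanh",
                                    "tiny_edge", "tiny_freq", "tiny_raw"),
                     feature_dim = 64),
    fusion = list(P = 64, r = 16, n_heads = 4, hidden_dim = 128,
                  dropout_rate = 0.3, eps = 1e-6, pooling = "mean"),
    train = list(epochs = 10, batch_size = 32, lr = 1e-4, weight_decay = 1e-2,
                 patience = 3)
  )
  base$data <- utils::modifyList(base$data, data)
  base$preprocessing <- utils::modifyList(base$preprocessing, preprocessing)
  base$backbones <- utils::modifyList(base$backbones, backbones)
  base$fusion <- utils::modifyList(base$fusion, fusion)
  base$train <- utils::modifyList(base$train, train)
  structure(base, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` invisibly returns `cfg`; `read_run_config`
#'   returns the restored `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(cfg)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_run_config, c(
    list(seed = cfg$seed, out_dir = cfg$out_dir),
    cfg[intersect(names(cfg), c("data", "preprocessing", "backbones", "fusion", "train"))]
  ))
}

train_config_from <- function(cfg, seed) {
  train_config(epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
               lr = cfg$train$lr, weight_decay = cfg$train$weight_decay,
               patience = cfg$train$patience, seed = seed)
}

load_run_images <- function(cfg) {
  if (is.null(cfg$data$root)) {
    spec <- synthetic_spec(
      n_per_class = cfg$data$n_per_class, image_size = cfg$data$image_size,
      n_classes = cfg$data$n_classes, signal_strength = cfg$data$signal_strength,
      interaction_only = cfg$data$interaction_only, noise_sd = cfg$data$noise_sd,
      seed = spawn_seed(cfg$seed, "data")
    )
    generate_images(spec)
  } else {
    resize_images(read_image_dataset(cfg$data$root), cfg$data$image_size)
  }
}

#' Run the full pipeline
#'
#' Executes every stage in order: load or generate images, compute channel
#' statistics and normalize, split, fine-tune and score all backbone
#' candidates, select the top two by weighted F1, extract their features,
#' train the QFM + MHA fusion model plus a concat+MLP baseline and the two
#' single-backbone heads, and evaluate everything on the held-out test split.
#' All artifacts needed for exact replay (resolved config, label map, channel
#' stats, split spec, candidate scores, train log, checkpoint manifest, metric
#' tables, confusion matrix) are written under `cfg$out_dir`.
#'
#' @param cfg A [default_run_config()].
#' @return A list of class `run_result`: `comparison` (Table-style tibble of
#'   test metrics per model), `per_class` (per-class metrics of the fusion
#'   model), `confusion` (its test confusion matrix), `selected` (the two
#'   backbone names), `candidate_scores`, `fit` (the fusion fit), and `cfg`.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))

  images <- load_run_images(cfg)
  jsonlite::write_json(
    list(class_names = images$class_names, index = seq_along(images$class_names) - 1L),
    file.path(cfg$out_dir, "label_map.json"), auto_unbox = FALSE
  )
  split <- make_splits(images$labels, cfg$preprocessing$test_fraction,
                       cfg$preprocessing$val_fraction_of_train,
                       cfg$preprocessing$stratified, spawn_seed(cfg$seed, "split"))
  stats_input <- if (identical(cfg$preprocessing$stats_from, "train")) {
    subset_images(images, split$train_idx)
  } else {
    images
  }
  stats <- compute_channel_stats(stats_input)
  write_sidecar(stats, file.path(cfg$out_dir, "channel_stats.json"))
  write_sidecar(split, file.path(cfg$out_dir, "split_spec.json"))
  images <- normalize_images(images, stats)
  labels <- images$labels
  K <- length(images$class_names)

  # --- candidate fine-tuning and selection -----------------------------------
  tc <- train_config_from(cfg, spawn_seed(cfg$seed, "candidates"))
  fd <- cfg$backbones$feature_dim
  cand_feats <- lapply(cfg$backbones$candidates, function(nm) {
    extract_features(tiny_backbone(nm, fd), images)
  })
  names(cand_feats) <- cfg$backbones$candidates
  cand_rows <- list(); cand_test <- list()
  for (nm in cfg$backbones$candidates) {
    fit <- train_mlp_baseline(cand_feats[[nm]], labels, split, K,
                              hidden_dim = cfg$fusion$hidden_dim,
                              dropout_rate = cfg$fusion$dropout_rate, config = tc)
    val_rep <- metrics_from_cm(confusion_matrix(
      labels[split$val_idx],
      predict(fit, cand_feats[[nm]][split$val_idx, , drop = FALSE], type = "class"), K,
      images$class_names))
    test_rep <- metrics_from_cm(confusion_matrix(
      labels[split$test_idx],
      predict(fit, cand_feats[[nm]][split$test_idx, , drop = FALSE], type = "class"), K,
      images$class_names))
    cand_rows[[nm]] <- tibble::tibble(name = nm, f1 = val_rep$weighted_f1,
                                      accuracy = val_rep$accuracy,
                                      precision = val_rep$weighted_precision,
                                      recall = val_rep$weighted_recall)
    cand_test[[nm]] <- glance(test_rep) |> dplyr::mutate(model = nm, .before = 1)
  }
  candidate_scores <- dplyr::bind_rows(cand_rows)
  utils::write.csv(candidate_scores, file.path(cfg$out_dir, "candidate_scores.csv"),
                   row.names = FALSE)
  top2 <- select_top_two(candidate_scores)
  jsonlite::write_json(list(backbone_a = top2$name[1], backbone_b = top2$name[2]),
                       file.path(cfg$out_dir, "selected_backbones.json"), auto_unbox = TRUE)

  # --- fusion training -------------------------------------------------------
  # backbone A reads view a; backbone B reads view b when paired views exist
  ZA <- extract_features(tiny_backbone(top2$name[1], fd), images, view = "a")
  ZB <- extract_features(tiny_backbone(top2$name[2], fd), images, view = "b")
  model <- fusion_model(fd, fd, P = cfg$fusion$P, r = cfg$fusion$r,
                        n_heads = cfg$fusion$n_heads, hidden_dim = cfg$fusion$hidden_dim,
                        dropout_rate = cfg$fusion$dropout_rate, n_classes = K,
                        eps = cfg$fusion$eps, pooling = cfg$fusion$pooling,
                        seed = spawn_seed(cfg$seed, "fusion_init"))
  fit <- train_fusion(ZA, ZB, labels, split, model,
                      train_config_from(cfg, spawn_seed(cfg$seed, "fusion")))
  utils::write.csv(fit$log, file.path(cfg$out_dir, "train_log.csv"), row.names = FALSE)
  write_fusion_checkpoint(fit, file.path(cfg$out_dir, "checkpoint.json"))

  # --- baselines and evaluation ---------------------------------------------
  tcb <- train_config_from(cfg, spawn_seed(cfg$seed, "baseline"))
  concat_fit <- train_mlp_baseline(cbind(ZA, ZB), labels, split, K,
                                   hidden_dim = cfg$fusion$hidden_dim,
                                   dropout_rate = cfg$fusion$dropout_rate, config = tcb)
  te <- split$test_idx
  eval_rep <- function(pred) metrics_from_cm(confusion_matrix(labels[te], pred, K, images$class_names))
  fusion_pred <- predict(fit, ZA[te, , drop = FALSE], ZB[te, , drop = FALSE], type = "class")
  fusion_rep <- eval_rep(fusion_pred)
  concat_rep <- eval_rep(predict(concat_fit, cbind(ZA, ZB)[te, , drop = FALSE], type = "class"))
  comparison <- dplyr::bind_rows(
    dplyr::bind_rows(cand_test),
    glance(concat_rep) |>
      dplyr::mutate(model = sprintf("concat_mlp(%s+%s)", top2$name[1], top2$name[2]), .before = 1),
    glance(fusion_rep) |> dplyr::mutate(model = "qfm_fusion", .before = 1)
  )
  utils::write.csv(comparison, file.path(cfg$out_dir, "comparison.csv"), row.names = FALSE)
  utils::write.csv(tidy(fusion_rep), file.path(cfg$out_dir, "per_class_metrics.csv"),
                   row.names = FALSE)
  cm <- confusion_matrix(labels[te], fusion_pred, K, images$class_names)
  jsonlite::write_json(list(counts = cm$counts, class_names = cm$class_names),
                       file.path(cfg$out_dir, "confusion.json"))
  structure(
    list(comparison = comparison, per_class = tidy(fusion_rep), confusion = cm,
         selected = top2$name, candidate_scores = candidate_scores, fit = fit,
         cfg = cfg),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> backbones: %s + %s\n", x$selected[1], x$selected[2]))
  print(as.data.frame(x$comparison))
  invisible(x)
}

#' Persist / restore a fusion checkpoint as JSON
#'
#' The checkpoint is a flat parameter archive plus a hyperparameter manifest,
#' all in one JSON file (text-only, replayable).
#'
#' @param fit A `fusion_fit`.
#' @param path JSON file path.
#' @return `write_fusion_checkpoint` invisibly returns `fit`;
#'   `read_fusion_checkpoint` returns a `fusion_fit` with the restored model.
#' @export
write_fusion_checkpoint <- function(fit, path) {
  m <- fit$model
  leaves <- trainable_leaves(m)
  manifest <- list(dA = m$dA, dB = m$dB, P = m$P, r = m$r,
                   n_heads = m$mha$n_heads, hidden_dim = m$head$hidden_dim,
                   dropout_rate = m$head$dropout_rate, n_classes = m$n_classes,
                   eps = m$qfm_a$eps, pooling = m$head$pooling,
                   h1_reading = m$qfm_a$h1_reading,
                   best_epoch = fit$best_epoch, best_val_macro_f1 = fit$best_val_macro_f1)
  jsonlite::write_json(list(manifest = manifest, params = leaves), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' @rdname write_fusion_checkpoint
#' @export
read_fusion_checkpoint <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mf <- o$manifest
  model <- fusion_model(mf$dA, mf$dB, P = mf$P, r = mf$r, n_heads = mf$n_heads,
                        hidden_dim = mf$hidden_dim, dropout_rate = mf$dropout_rate,
                        n_classes = mf$n_classes, eps = mf$eps, pooling = mf$pooling,
                        h1_reading = mf$h1_reading)
  leaves <- lapply(o$params, function(blk) lapply(blk, function(x) {
    if (is.matrix(x)) x else as.numeric(x)
  }))
  model <- set_trainable_leaves(model, leaves)
  structure(list(model = model, log = NULL, best_epoch = mf$best_epoch,
                 best_val_macro_f1 = mf$best_val_macro_f1, config = NULL),
            class = "fusion_fit")
}
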