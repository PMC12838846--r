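#' Average cross-entropy loss
#'
#' `L = -(1/Nb) * sum(log p[n, y_n])`, the mean negative log-probability of the
#' true class. Probabilities at the true label are clamped below at `clamp`
#' before the log for numerical safety.
#'
#' @param probs An `n x K` matrix of class probabilities (rows sum to 1), or a
#'   single probability vector.
#' @param labels 0-based true class indices.
#' @param clamp Lower clamp applied inside the log (default 1e-12).
#' @return A single non-negative number.
#' @export
#' @examples
#' cross_entropy_loss(matrix(0.2, 2, 5), c(0, 3))  # log(5)
cross_entropy_loss <- function(probs, labels, clamp = 1e-12) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1)
  labels <- as_label_int(labels, ncol(probs))
  if (length(labels) != nrow(probs)) abort_bad_arg("`labels` length must match rows of `probs`.")
  p_true <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  -mean(log(pmax(p_true, clamp)))
}

#' Cosine annealing learning rate
#'
#' `lr(step) = lr0 * (1 + cos(pi * step / total_steps)) / 2`: starts at `lr0`,
#' decays monotonically to 0 at `total_steps`. Applied per optimisation step
#' (no warm restarts).
#'
#' @param step Current step in `[0, total_steps]`.
#' @param total_steps Total number of steps (> 0).
#' @param lr0 Initial learning rate.
#' @return The learning rate at `step`.
#' @export
cosine_lr <- function(step, total_steps, lr0) {
  check_number(total_steps, "total_steps", min = 1, integerish = TRUE)
  check_number(step, "step", min = 0, max = total_steps)
  lr0 * 0.5 * (1 + cos(pi * step / total_steps))
}

#' Training configuration
#'
#' Defaults follow the reference recipe: 10 epochs, mini-batches of 32,
#' learning rate 1e-4 under a per-step cosine annealing schedule, decoupled
#' weight decay (AdamW-style, applied to weight matrices, not biases), and
#' early stopping on validation macro F1.
#'
#' @param epochs Number of epochs (default 10).
#' @param batch_size Mini-batch size Nb (default 32).
#' @param lr Initial learning rate (default 1e-4).
#' @param weight_decay Decoupled weight decay coefficient (default 1e-2).
#' @param schedule Learning-rate schedule; only `"cosine"` is implemented.
#' @param early_stop_metric Metric watched for early stopping (`"macro_f1"`).
#' @param patience Epochs without improvement before stopping (default 3).
#' @param seed Integer seed for shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 10, batch_size = 32, lr = 1e-4, weight_decay = 1e-2,
                         schedule = "cosine", early_stop_metric = "macro_f1",
                         patience = 3, seed = 1) {
  check_number(epochs, "epochs", min = 1, integerish = TRUE)
  check_number(batch_size, "batch_size", min = 1, integerish = TRUE)
  if (!is.numeric(lr) || lr <= 0) abort_bad_arg("`lr` must be > 0.")
  check_number(weight_decay, "weight_decay", min = 0)
  check_number(patience, "patience", min = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, schedule = schedule,
                 early_stop_metric = early_stop_metric, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- AdamW over nested parameter lists --------------------------------------

adamw_init <- function(leaves) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(leaves), v = zero_like(leaves), t = 0L)
}

# One decoupled-weight-decay Adam step on nested leaves given matching grads.
adamw_step <- function(leaves, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- Map(walk, w, g, m, v)
      list(w = lapply(out, `[[`, "w"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      upd <- (m2 / bc1) / (sqrt(v2 / bc2) + adam_eps)
      decay <- if (!is.null(dim(w))) weight_decay * w else 0  # no decay on biases
      list(w = w - lr * (upd + decay), m = m2, v = v2)
    }
  }
  res <- walk(leaves, grads, state$m, state$v)
  list(leaves = res$w, state = list(m = res$m, v = res$v, t = state$t))
}

# Internal macro-F1 on label vectors (0-based), used during training.
macro_f1_score <- function(true, pred, n_classes) {
  f1 <- numeric(n_classes)
  for (k in seq_len(n_classes) - 1L) {
    tp <- sum(true == k & pred == k)
    fp <- sum(true != k & pred == k)
    fn <- sum(true == k & pred != k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k + 1L] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  mean(f1)
}

one_hot <- function(labels, K) {
  Y <- matrix(0, length(labels), K)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

#' Train the fusion model on labelled feature pairs
#'
#' Trains the QFM + MHA + MLP fusion head with cross-entropy, AdamW-style
#' decoupled weight decay and a per-step cosine annealing schedule, watching
#' validation macro F1 for early stopping. Backbone features are inputs here,
#' so the backbones themselves stay frozen by construction. The returned fit
#' carries the checkpoint of the epoch with the highest validation macro F1.
#'
#' @param features_a,features_b `n x dA` / `n x dB` feature matrices.
#' @param labels 0-based class labels of length `n`.
#' @param split A [make_splits()] result (indices into the rows).
#' @param model A [fusion_model()]; its `dA`/`dB`/`n_classes` must match.
#' @param config A [train_config()].
#' @return An object of class `fusion_fit`: `model` (best checkpoint), `log`
#'   (a tibble with epoch, loss, val_macro_f1, lr), `best_epoch`, `config`.
#' @export
train_fusion <- function(features_a, features_b, labels, split, model,
                         config = train_config()) {
  stopifnot(inherits(model, "fusion_model"), inherits(config, "train_config"))
  labels <- as_label_int(labels, model$n_classes)
  tr <- split$train_idx; va <- split$val_idx
  if (length(tr) == 0 || length(va) == 0) abort_bad_arg("train and validation splits must be non-empty.")
  ZA <- as.matrix(features_a); ZB <- as.matrix(features_b)
  set.seed(spawn_seed(config$seed, "train_fusion"))
  leaves <- trainable_leaves(model)
  state <- adamw_init(leaves)
  steps_per_epoch <- ceiling(length(tr) / config$batch_size)
  total_steps <- config$epochs * steps_per_epoch
  gstep <- 0L
  log <- vector("list", config$epochs)
  best <- list(metric = -Inf, leaves = leaves, epoch = 0L)
  stale <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- tr[sample.int(length(tr))]
    losses <- numeric(steps_per_epoch)
    lr_now <- config$lr
    for (s in seq_len(steps_per_epoch)) {
      idx <- ord[((s - 1L) * config$batch_size + 1L):min(s * config$batch_size, length(ord))]
      model <- set_trainable_leaves(model, leaves)
      fw <- fusion_fwd(model, ZA[idx, , drop = FALSE], ZB[idx, , drop = FALSE],
                       training = TRUE, keep_cache = TRUE)
      losses[s] <- cross_entropy_loss(fw$probs, labels[idx])
      dlogits <- (fw$probs - one_hot(labels[idx], model$n_classes)) / length(idx)
      grads <- fusion_bwd(model, dlogits, fw$cache)
      lr_now <- cosine_lr(gstep, total_steps, config$lr)
      upd <- adamw_step(leaves, grads, state, lr_now, config$weight_decay)
      leaves <- upd$leaves; state <- upd$state
      gstep <- gstep + 1L
    }
    model <- set_trainable_leaves(model, leaves)
    val_probs <- fusion_fwd(model, ZA[va, , drop = FALSE], ZB[va, , drop = FALSE])
    val_pred <- max.col(val_probs, ties.method = "first") - 1L
    vf1 <- macro_f1_score(labels[va], val_pred, model$n_classes)
    log[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                val_macro_f1 = vf1, lr = lr_now)
    if (vf1 > best$metric) {
      best <- list(metric = vf1, leaves = leaves, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model <- set_trainable_leaves(model, best$leaves)
  structure(
    list(model = model, log = dplyr::bind_rows(log), best_epoch = best$epoch,
         best_val_macro_f1 = best$metric, config = config),
    class = "fusion_fit"
  )
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf("<fusion_fit> best epoch %d, val macro F1 %.4f (%d epochs run)\n",
              x$best_epoch, x$best_val_macro_f1, nrow(x$log)))
  invisible(x)
}

#' Predict from a fusion fit
#' @param object A `fusion_fit`.
#' @param features_a,features_b Feature matrices.
#' @param type `"prob"` for probabilities, `"class"` for 0-based labels.
#' @param ... Unused.
#' @return An `n x K` probability matrix or an integer label vector.
#' @export
predict.fusion_fit <- function(object, features_a, features_b,
                               type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- fusion_forward(object$model, as.matrix(features_a), as.matrix(features_b))
  if (is.null(dim(probs))) probs <- matrix(probs, 1)
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' Train a plain MLP classifier on a single feature matrix
#'
#' One hidden layer with ReLU, dropout, and a softmax output — the same head
#' and training recipe as the fusion model but without QFM/MHA. Used as the
#' per-candidate fine-tuning head during backbone selection, as the single-view
#' baseline, and (on concatenated features) as the concat+MLP baseline.
#'
#' @param features `n x d` feature matrix.
#' @param labels 0-based class labels.
#' @param split A [make_splits()] result.
#' @param n_classes Number of classes.
#' @param hidden_dim Hidden width (default 256).
#' @param dropout_rate Dropout probability (default 0.3).
#' @param config A [train_config()].
#' @return An object of class `mlp_fit` with `params`, `log`, `best_epoch`.
#' @export
train_mlp_baseline <- function(features, labels, split, n_classes,
                               hidden_dim = 256, dropout_rate = 0.3,
                               config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  X <- as.matrix(features)
  labels <- as_label_int(labels, n_classes)
  tr <- split$train_idx; va <- split$val_idx
  set.seed(spawn_seed(config$seed, "train_mlp"))
  d <- ncol(X)
  leaves <- list(W1 = init_matrix(hidden_dim, d), b1 = numeric(hidden_dim),
                 W2 = init_matrix(n_classes, hidden_dim), b2 = numeric(n_classes))
  state <- adamw_init(leaves)
  steps_per_epoch <- ceiling(length(tr) / config$batch_size)
  total_steps <- config$epochs * steps_per_epoch
  gstep <- 0L
  fwd <- function(lv, X, training = FALSE) {
    Hpre <- X %*% t(lv$W1) + matrix(lv$b1, nrow(X), hidden_dim, byrow = TRUE)
    Hact <- relu(Hpre)
    mask <- NULL
    if (training && dropout_rate > 0) {
      keep <- 1 - dropout_rate
      mask <- matrix(stats::rbinom(length(Hact), 1, keep), nrow(Hact)) / keep
      Hact <- Hact * mask
    }
    logits <- Hact %*% t(lv$W2) + matrix(lv$b2, nrow(X), n_classes, byrow = TRUE)
    list(probs = softmax_rows(logits), Hpre = Hpre, Hact = Hact, mask = mask, X = X)
  }
  log <- vector("list", config$epochs)
  best <- list(metric = -Inf, leaves = leaves, epoch = 0L)
  stale <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- tr[sample.int(length(tr))]
    losses <- numeric(steps_per_epoch)
    lr_now <- config$lr
    for (s in seq_len(steps_per_epoch)) {
      idx <- ord[((s - 1L) * config$batch_size + 1L):min(s * config$batch_size, length(ord))]
      fw <- fwd(leaves, X[idx, , drop = FALSE], training = TRUE)
      losses[s] <- cross_entropy_loss(fw$probs, labels[idx])
      dlogits <- (fw$probs - one_hot(labels[idx], n_classes)) / length(idx)
      dW2 <- t(dlogits) %*% fw$Hact; db2 <- colSums(dlogits)
      dH <- dlogits %*% leaves$W2
      if (!is.null(fw$mask)) dH <- dH * fw$mask
      dH <- dH * (fw$Hpre > 0)
      dW1 <- t(dH) %*% fw$X; db1 <- colSums(dH)
      grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
      lr_now <- cosine_lr(gstep, total_steps, config$lr)
      upd <- adamw_step(leaves, grads, state, lr_now, config$weight_decay)
      leaves <- upd$leaves; state <- upd$state
      gstep <- gstep + 1L
    }
    vp <- fwd(leaves, X[va, , drop = FALSE])$probs
    vf1 <- macro_f1_score(labels[va], max.col(vp, ties.method = "first") - 1L, n_classes)
    log[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses), val_macro_f1 = vf1, lr = lr_now)
    if (vf1 > best$metric) {
      best <- list(metric = vf1, leaves = leaves, epoch = ep); stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  structure(list(params = best$leaves, log = dplyr::bind_rows(log),
                 best_epoch = best$epoch, best_val_macro_f1 = best$metric,
                 n_classes = n_classes, hidden_dim = hidden_dim,
                 dropout_rate = dropout_rate, config = config),
            class = "mlp_fit")
}

#' @export
predict.mlp_fit <- function(object, features, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(features)
  lv <- object$params
  H <- relu(X %*% t(lv$W1) + matrix(lv$b1, nrow(X), length(lv$b1), byrow = TRUE))
  probs <- softmax_rows(H %*% t(lv$W2) + matrix(lv$b2, nrow(X), object$n_classes, byrow = TRUE))
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' Tidy the per-epoch training log
#' @param x A `fusion_fit` or `mlp_fit`.
#' @param ... Unused.
#' @return The training-log tibble (epoch, loss, val_macro_f1, lr).
#' @export
tidy.fusion_fit <- function(x, ...) x$log

#' @rdname tidy.fusion_fit
#' @export
tidy.mlp_fit <- function(x, ...) x$log

#' One-row summary of a fit
#' @param x A `fusion_fit` or `mlp_fit`.
#' @param ... Unused.
#' @return A one-row tibble with best epoch and best validation macro F1.
#' @export
glance.fusion_fit <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch, best_val_macro_f1 = x$best_val_macro_f1,
                 epochs_run = nrow(x$log))
}

#' @rdname glance.fusion_fit
#' @export
glance.mlp_fit <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch, best_val_macro_f1 = x$best_val_macro_f1,
                 epochs_run = nrow(x$log))
}
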