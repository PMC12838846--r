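#' Backbone feature-extractor handle
#'
#' A uniform contract over pluggable feature extractors: a handle has a name,
#' a fixed output dimension, a frozen flag, and an extractor function mapping a
#' normalized image batch to an `n x feature_dim` matrix. The published
#' pretrained architectures require weight downloads and are not bundled; the
#' built-in registry provides tiny deterministic extractors with the same
#' contract (default `feature_dim` 768, mirroring the reference backbones).
#'
#' @param name Identifier.
#' @param feature_dim Output dimension d (>= 1).
#' @param extractor `function(x)` taking an `n x H x W x 3` array and returning
#'   an `n x feature_dim` matrix.
#' @param frozen Logical; frozen handles are never updated by training.
#' @param weights_source One of `"pretrained"`, `"random"`, `"tiny-test"`.
#' @return An object of class `backbone_handle`.
#' @export
backbone_handle <- function(name, feature_dim, extractor, frozen = TRUE,
                            weights_source = c("tiny-test", "random", "pretrained")) {
  check_number(feature_dim, "feature_dim", min = 1, integerish = TRUE)
  stopifnot(is.function(extractor))
  structure(
    list(name = name, feature_dim = as.integer(feature_dim), extractor = extractor,
         frozen = isTRUE(frozen), weights_source = match.arg(weights_source)),
    class = "backbone_handle"
  )
}

#' @export
print.backbone_handle <- function(x, ...) {
  cat(sprintf("<backbone_handle> %s: d=%d, %s%s\n", x$name, x$feature_dim,
              x$weights_source, if (x$frozen) ", frozen" else ""))
  invisible(x)
}

# 4x4 block means per channel: n x 48 summary that preserves coarse
# block-brightness structure (the signal carrier of the synthetic generator).
block_pool <- function(x, grid = 4L) {
  d <- dim(x)
  ih <- pmin(ceiling(seq_len(d[2]) / (d[2] / grid)), grid)
  iw <- pmin(ceiling(seq_len(d[3]) / (d[3] / grid)), grid)
  out <- matrix(0, d[1], grid * grid * d[4])
  for (ch in seq_len(d[4])) {
    for (a in seq_len(grid)) for (b in seq_len(grid)) {
      sel_h <- which(ih == a); sel_w <- which(iw == b)
      block <- x[, sel_h, sel_w, ch, drop = FALSE]
      out[, (ch - 1L) * grid * grid + (a - 1L) * grid + b] <-
        apply(block, 1L, mean)
    }
  }
  out
}

# Oriented-gradient energies pooled on the block grid (texture-sensitive).
grad_pool <- function(x, grid = 4L) {
  d <- dim(x)
  gx <- x[, -1, , , drop = FALSE] - x[, -d[2], , , drop = FALSE]
  gy <- x[, , -1, , drop = FALSE] - x[, , -d[3], , drop = FALSE]
  block_pool(abs(gx[, , -d[3], , drop = FALSE]) + abs(gy[, -d[2], , , drop = FALSE]), grid)
}

# Low-frequency 2-D cosine-basis energies per channel (frequency-sensitive).
freq_pool <- function(x, n_freq = 4L) {
  d <- dim(x)
  h <- seq_len(d[2]) / d[2]; w <- seq_len(d[3]) / d[3]
  out <- matrix(0, d[1], n_freq * n_freq * d[4])
  col <- 0L
  for (ch in seq_len(d[4])) for (fa in seq_len(n_freq)) for (fb in seq_len(n_freq)) {
    basis <- outer(cos(2 * pi * fa * h), cos(2 * pi * fb * w))
    col <- col + 1L
    out[, col] <- apply(x[, , , ch, drop = FALSE], 1L, function(m) mean(as.vector(m) * as.vector(basis)))
  }
  out
}

# Deterministic projection matrix keyed by (name, d_in, d_out).
stub_projection <- function(name, d_in, d_out) {
  set.seed(spawn_seed(spawn_seed(1L, name), "stub_proj"))
  matrix(rnorm(d_in * d_out, 0, 1 / sqrt(d_in)), d_in, d_out)
}

#' Built-in tiny test backbones
#'
#' Deterministic, dependency-free feature extractors meant for desk-scale
#' pipelines and tests. Each pools the image into a small descriptor and
#' applies a fixed seeded projection to `feature_dim`; no parameters are
#' learnable, so they behave like frozen pretrained extractors. Variants:
#' `tiny_pool_a` / `tiny_pool_b` (block-brightness means with distinct
#' projections — two different "views" of the same image), `tiny_tanh`
#' (block means through a tanh nonlinearity), `tiny_edge` (pooled gradient
#' magnitudes), `tiny_freq` (cosine-basis texture energies), and `tiny_raw`
#' (subsampled pixels).
#'
#' @param name One of the registry names, see [backbone_registry()].
#' @param feature_dim Output dimension (default 768).
#' @return A [backbone_handle()].
#' @export
tiny_backbone <- function(name, feature_dim = 768) {
  builders <- backbone_registry()
  if (!name %in% names(builders)) {
    abort_bad_arg(sprintf("unknown backbone `%s`; known: %s.",
                          name, paste(names(builders), collapse = ", ")))
  }
  builders[[name]](feature_dim)
}

#' Registry of available backbone constructors
#'
#' @return A named list of constructor functions `function(feature_dim)`
#'   returning [backbone_handle()]s.
#' @export
backbone_registry <- function() {
  make <- function(name, pool_fn) {
    force(name); force(pool_fn)
    function(feature_dim = 768) {
      proj <- NULL
      extractor <- function(x) {
        desc <- pool_fn(x)
        if (is.null(proj)) proj <<- stub_projection(name, ncol(desc), feature_dim)
        desc %*% proj
      }
      backbone_handle(name, feature_dim, extractor, frozen = TRUE,
                      weights_source = "tiny-test")
    }
  }
  list(
    tiny_pool_a = make("tiny_pool_a", block_pool),
    tiny_pool_b = make("tiny_pool_b", block_pool),
    tiny_tanh = make("tiny_tanh", function(x) tanh(block_pool(x))),
    tiny_edge = make("tiny_edge", grad_pool),
    tiny_freq = make("tiny_freq", freq_pool),
    tiny_raw = make("tiny_raw", function(x) {
      d <- dim(x)
      sh <- unique(pmax(1L, round(seq(1, d[2], length.out = 8))))
      sw <- unique(pmax(1L, round(seq(1, d[3], length.out = 8))))
      sub <- x[, sh, sw, , drop = FALSE]
      matrix(sub, d[1], length(sh) * length(sw) * d[4])
    })
  )
}

#' Extract backbone features from a normalized image batch
#'
#' Deterministic in evaluation mode: the same batch always yields the same
#' features, and frozen handles are never modified.
#'
#' @param handle A [backbone_handle()].
#' @param images An `image_set` or an `n x H x W x 3` array (already
#'   normalized).
#' @param view For paired-view image sets, which view to read (`"a"` or
#'   `"b"`); ignored otherwise.
#' @return An `n x feature_dim` matrix.
#' @export
extract_features <- function(handle, images, view = c("a", "b")) {
  stopifnot(inherits(handle, "backbone_handle"))
  view <- match.arg(view)
  x <- if (inherits(images, "image_set")) {
    if (view == "b" && !is.null(images$x_b)) images$x_b else images$x
  } else {
    images
  }
  if (!is.array(x) || length(dim(x)) != 4L) abort_bad_arg("`images` must be a 4-d array or image_set.")
  out <- handle$extractor(x)
  if (!is.matrix(out) || ncol(out) != handle$feature_dim || nrow(out) != dim(x)[1]) {
    abort_bad_arg("extractor returned a matrix inconsistent with the handle's contract.")
  }
  unname(out)
}

#' Select the two best backbone candidates by F1
#'
#' Orders candidates by weighted F1 (the primary selection criterion), breaking
#' ties by higher accuracy, then lexicographically by name, and returns the two
#' best — best first (Backbone A). The result is invariant to the input order.
#'
#' @param scores A data frame with columns `name`, `f1`, and optionally
#'   `accuracy` (percent scales).
#' @return A two-row tibble, best candidate first.
#' @export
#' @examples
#' scores <- tibble::tibble(
#'   name = c("ViTB32", "EfficientNetB0", "ResNet50",
#'            "DenseNet121", "ConvNeXtTiny", "ViTB16"),
#'   f1 = c(68.30, 89.65, 96.28, 96.32, 96.33, 96.35)
#' )
#' select_top_two(scores)$name
select_top_two <- function(scores) {
  scores <- tibble::as_tibble(scores)
  if (!all(c("name", "f1") %in% names(scores))) {
    abort_bad_arg("`scores` needs columns `name` and `f1`.")
  }
  if (nrow(scores) < 2) abort_bad_arg("need at least 2 candidates to select from.")
  if (!"accuracy" %in% names(scores)) scores$accuracy <- 0
  ord <- order(-scores$f1, -scores$accuracy, scores$name)
  scores[ord[1:2], , drop = FALSE]
}

#' Fine-tune and score backbone candidates
#'
#' For each candidate, extracts features from the training images, trains an
#' MLP classification head with the standard recipe (the backbone itself stays
#' frozen), and scores weighted F1 / accuracy / precision / recall (percent) on
#' the evaluation split — the validation split by default.
#'
#' @param images A normalized `image_set`.
#' @param split A [make_splits()] result.
#' @param candidates Character vector of registry names (see
#'   [backbone_registry()]).
#' @param feature_dim Backbone output dimension (default 768).
#' @param n_classes Number of classes.
#' @param config A [train_config()].
#' @param eval_on `"val"` (default) or `"test"`.
#' @return A tibble with columns `name`, `f1`, `accuracy`, `precision`,
#'   `recall` — one row per candidate, in input order.
#' @export
score_candidates <- function(images, split, candidates, feature_dim = 768,
                             n_classes = 5, config = train_config(),
                             eval_on = c("val", "test")) {
  eval_on <- match.arg(eval_on)
  eval_idx <- if (eval_on == "val") split$val_idx else split$test_idx
  labels <- images$labels
  rows <- purrr::map(candidates, function(nm) {
    handle <- tiny_backbone(nm, feature_dim)
    feats <- extract_features(handle, images)
    fit <- train_mlp_baseline(feats, labels, split, n_classes, config = config)
    pred <- predict(fit, feats[eval_idx, , drop = FALSE], type = "class")
    rep <- metrics_from_cm(confusion_matrix(labels[eval_idx], pred, n_classes))
    tibble::tibble(name = nm, f1 = rep$weighted_f1, accuracy = rep$accuracy,
                   precision = rep$weighted_precision, recall = rep$weighted_recall)
  })
  dplyr::bind_rows(rows)
}
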