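#' Per-channel image statistics
#'
#' Computes the channel-wise mean and *population* standard deviation over an
#' entire image set: both moments pool every pixel of every image, i.e. the
#' divisor is `N * H * W` (not `N*H*W - 1`).
#'
#' By default the statistics are computed from all data before splitting,
#' matching the normalization protocol the model was described with. Computing
#' them from all data leaks test-set pixel moments into preprocessing; pass the
#' training subset explicitly (e.g. `subset_images(images, split$train_idx)`)
#' if that leakage matters for your use.
#'
#' @param images An `image_set` or an `n x H x W x 3` array.
#' @return An object of class `channel_stats` with fields `mu`, `sigma`
#'   (length-3 numerics), `n_images`, `height`, `width`.
#' @export
#' @examples
#' imgs <- generate_images(synthetic_spec(2, image_size = 16, seed = 1))
#' compute_channel_stats(imgs)
compute_channel_stats <- function(images) {
  x <- if (inherits(images, "image_set")) images$x else images
  if (!is.array(x) || length(dim(x)) != 4L || dim(x)[4] != 3L) {
    abort_bad_arg("`images` must be an n x H x W x 3 array or image_set.")
  }
  if (dim(x)[1] == 0L) abort_bad_arg("image set is empty.")
  mu <- apply(x, 4L, mean)
  sigma <- sqrt(apply(x, 4L, function(ch) mean((ch - mean(ch))^2)))
  structure(
    list(mu = mu, sigma = sigma, n_images = dim(x)[1],
         height = dim(x)[2], width = dim(x)[3]),
    class = "channel_stats"
  )
}

#' @export
print.channel_stats <- function(x, ...) {
  cat(sprintf("<channel_stats> N=%d %dx%d\n  mu    = %s\n  sigma = %s\n",
              x$n_images, x$height, x$width,
              paste(signif(x$mu, 6), collapse = ", "),
              paste(signif(x$sigma, 6), collapse = ", ")))
  invisible(x)
}

#' Normalize an image set channel-wise
#'
#' Standardizes every pixel as `(x - mu_c) / sigma_c` using precomputed
#' [compute_channel_stats()]. A channel with zero variance is divided by
#' `sigma_c + eps_norm` instead, to keep the transform finite on constant
#' channels.
#'
#' @param images An `image_set` or `n x H x W x 3` array (dimensions must match
#'   those the stats were computed on).
#' @param stats A `channel_stats`.
#' @param eps_norm Divisor guard for zero-variance channels. Default `1e-8`.
#' @return Same container as the input, normalized.
#' @export
normalize_images <- function(images, stats, eps_norm = 1e-8) {
  stopifnot(inherits(stats, "channel_stats"))
  is_set <- inherits(images, "image_set")
  x <- if (is_set) images$x else images
  if (!is.array(x) || length(dim(x)) != 4L) abort_bad_arg("`images` must be a 4-d array or image_set.")
  if (dim(x)[2] != stats$height || dim(x)[3] != stats$width) {
    abort_bad_arg("image dimensions do not match the dimensions `stats` was computed on.")
  }
  div <- ifelse(stats$sigma == 0, stats$sigma + eps_norm, stats$sigma)
  for (ch in 1:3) x[, , , ch] <- (x[, , , ch] - stats$mu[ch]) / div[ch]
  if (is_set) {
    images$x <- x
    if (!is.null(images$x_b)) {
      for (ch in 1:3) images$x_b[, , , ch] <- (images$x_b[, , , ch] - stats$mu[ch]) / div[ch]
    }
    images
  } else {
    x
  }
}

#' Bilinearly resize an image set to a square side
#'
#' @param images An `image_set` or 4-d array.
#' @param size Target side in pixels (default 224, the input size of the
#'   standard pretrained backbones).
#' @return Same container, resized.
#' @export
resize_images <- function(images, size = 224) {
  check_number(size, "size", min = 1, integerish = TRUE)
  is_set <- inherits(images, "image_set")
  x <- if (is_set) images$x else images
  d <- dim(x)
  if (d[2] == size && d[3] == size) return(images)
  out <- array(0, dim = c(d[1], size, size, d[4]))
  for (i in seq_len(d[1])) {
    out[i, , , ] <- EBImage::resize(x[i, , , ], w = size, h = size, filter = "bilinear")
  }
  if (is_set) { images$x <- out; images } else out
}

#' Subset an image set by index
#' @param images An `image_set`.
#' @param idx Integer indices (1-based).
#' @return The subset `image_set`.
#' @export
subset_images <- function(images, idx) {
  stopifnot(inherits(images, "image_set"))
  out <- images
  out$x <- images$x[idx, , , , drop = FALSE]
  if (!is.null(images$x_b)) out$x_b <- images$x_b[idx, , , , drop = FALSE]
  out$labels <- images$labels[idx]
  out
}

# Largest-remainder apportionment of `total` across quotas.
apportion <- function(quota, total) {
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Train/validation/test partition
#'
#' Splits sample indices into disjoint train / validation / test sets,
#' stratified per class by default. The test share is taken per class by
#' ceiling (`ceiling(test_fraction * n_k)` per class k), so every class is
#' represented in the test set even when small; the validation share is
#' `val_fraction_of_train` of the remaining training pool, sized to
#' round-half-up of the pool total and apportioned across classes by largest
#' remainder. Unstratified splits use round-half-up on the totals.
#'
#' @param labels 0-based integer class labels (or a factor).
#' @param test_fraction Fraction held out for test (default 0.20).
#' @param val_fraction_of_train Fraction of the training pool used for
#'   validation (default 0.10).
#' @param stratified Stratify per class (default `TRUE`).
#' @param seed Integer seed.
#' @return An object of class `split_spec` with `train_idx`, `val_idx`,
#'   `test_idx` (1-based, pairwise disjoint, covering all samples) and the
#'   parameters used.
#' @export
#' @examples
#' sp <- make_splits(rep(0:4, each = 20), seed = 1)
#' lengths(sp[c("train_idx", "val_idx", "test_idx")])
make_splits <- function(labels, test_fraction = 0.20, val_fraction_of_train = 0.10,
                        stratified = TRUE, seed = 1) {
  labels <- as_label_int(labels)
  if (test_fraction <= 0 || test_fraction >= 1) abort_bad_arg("`test_fraction` must be in (0,1).")
  if (val_fraction_of_train <= 0 || val_fraction_of_train >= 1) {
    abort_bad_arg("`val_fraction_of_train` must be in (0,1).")
  }
  check_number(seed, "seed", integerish = TRUE)
  n <- length(labels)
  set.seed(spawn_seed(seed, "splits"))
  if (stratified) {
    classes <- sort(unique(labels))
    test_idx <- integer(0); pool_by_class <- list()
    for (k in classes) {
      idx <- which(labels == k)
      if (length(idx) < 1L) abort_bad_arg("every class needs at least one sample when stratified.")
      idx <- idx[sample.int(length(idx))]
      n_test <- min(ceiling(test_fraction * length(idx)), length(idx))
      test_idx <- c(test_idx, idx[seq_len(n_test)])
      pool_by_class[[as.character(k)]] <- idx[-seq_len(n_test)]
    }
    pool_sizes <- lengths(pool_by_class)
    n_val_total <- as.integer(round_half_up(val_fraction_of_train * sum(pool_sizes)))
    val_per_class <- apportion(val_fraction_of_train * pool_sizes, n_val_total)
    val_per_class <- pmin(val_per_class, pool_sizes)
    val_idx <- integer(0); train_idx <- integer(0)
    for (j in seq_along(pool_by_class)) {
      p <- pool_by_class[[j]]
      if (val_per_class[j] > 0) {
        val_idx <- c(val_idx, p[seq_len(val_per_class[j])])
        train_idx <- c(train_idx, p[-seq_len(val_per_class[j])])
      } else {
        train_idx <- c(train_idx, p)
      }
    }
  } else {
    perm <- sample.int(n)
    n_test <- as.integer(round_half_up(test_fraction * n))
    test_idx <- perm[seq_len(n_test)]
    pool <- perm[-seq_len(n_test)]
    n_val <- as.integer(round_half_up(val_fraction_of_train * length(pool)))
    val_idx <- pool[seq_len(n_val)]
    train_idx <- pool[-seq_len(n_val)]
  }
  structure(
    list(train_idx = sort(train_idx), val_idx = sort(val_idx), test_idx = sort(test_idx),
         test_fraction = test_fraction, val_fraction_of_train = val_fraction_of_train,
         stratified = stratified, seed = as.integer(seed), n = n),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> n=%d: train=%d val=%d test=%d (stratified=%s, seed=%d)\n",
              x$n, length(x$train_idx), length(x$val_idx), length(x$test_idx),
              x$stratified, x$seed))
  invisible(x)
}

#' Persist / restore preprocessing sidecars as JSON
#'
#' `channel_stats` and `split_spec` objects round-trip through JSON so a run
#' can be replayed exactly.
#'
#' @param x A `channel_stats` or `split_spec`.
#' @param path JSON file path.
#' @return `write_sidecar` invisibly returns `x`; `read_channel_stats` /
#'   `read_split_spec` return the restored object.
#' @export
write_sidecar <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' @rdname write_sidecar
#' @export
read_channel_stats <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(o[c("mu", "sigma", "n_images", "height", "width")], class = "channel_stats")
}

#' @rdname write_sidecar
#' @export
read_split_spec <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  o$train_idx <- as.integer(o$train_idx); o$val_idx <- as.integer(o$val_idx)
  o$test_idx <- as.integer(o$test_idx)
  structure(o, class = "split_spec")
}
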