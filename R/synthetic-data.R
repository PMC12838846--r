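#' Specification for a synthetic labelled image dataset
#'
#' Describes a five-class (by default) synthetic image collection whose classes
#' differ by controllable structural signals: a class-specific grating
#' frequency, a class-specific count of bright blobs, and (optionally) a
#' class-specific sign pattern over a coarse block grid. `signal_strength`
#' scales every class-dependent component, so at `signal_strength = 0` the
#' class-conditional image distributions are identical pure-noise fields.
#'
#' With `interaction_only = TRUE` the generator emits two image views per
#' sample. View A carries a random block-brightness field `g`; view B carries
#' the same field multiplied block-wise by a class-specific sign pattern.
#' Each view's marginal distribution is then identical across classes (a sign
#' flip of a symmetric field is distribution-preserving), so class identity is
#' decodable only from the joint statistics of the two views — the regime the
#' Hadamard interaction token is designed for.
#'
#' @param n_per_class Images per class (>= 1).
#' @param image_size Square image side in pixels (>= 8). Default 224, the
#'   input size expected by the pretrained architectures the model targets.
#' @param n_classes Number of classes. Default 5.
#' @param signal_strength Real in `[0, 1]` scaling class separability.
#' @param interaction_only If `TRUE`, emit paired views with interaction-only
#'   class signal (see Details).
#' @param noise_sd Pixel noise standard deviation on the 8-bit scale (>= 0).
#' @param seed Integer seed; identical spec + seed gives a bit-identical dataset.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_per_class = 4, image_size = 32, seed = 1)
#' imgs <- generate_images(spec)
#' table(imgs$labels)
synthetic_spec <- function(n_per_class,
                           image_size = 224,
                           n_classes = 5,
                           signal_strength = 1,
                           interaction_only = FALSE,
                           noise_sd = 10,
                           seed = 1) {
  check_number(n_per_class, "n_per_class", min = 1, integerish = TRUE)
  check_number(image_size, "image_size", min = 8, integerish = TRUE)
  check_number(n_classes, "n_classes", min = 2, integerish = TRUE)
  check_number(signal_strength, "signal_strength", min = 0, max = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(
      n_per_class = as.integer(n_per_class),
      image_size = as.integer(image_size),
      n_classes = as.integer(n_classes),
      signal_strength = signal_strength,
      interaction_only = isTRUE(interaction_only),
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Default class names
#'
#' For the five-class task the fixed label order is (localized complicated,
#' normal, rare, advanced complicated, simple); other class counts fall back
#' to `class_0 ... class_{K-1}`. The position in this vector is the 0-based
#' class index used everywhere in the package.
#'
#' @param n_classes Number of classes.
#' @return Character vector of class names in fixed index order.
#' @export
default_class_names <- function(n_classes = 5) {
  if (n_classes == 5) {
    c("localized_complicated", "normal", "rare", "advanced_complicated", "simple")
  } else {
    paste0("class_", seq_len(n_classes) - 1L)
  }
}

# Class-specific block sign patterns on a b x b grid, mutually distinct.
block_sign_patterns <- function(n_classes, n_blocks) {
  patterns <- matrix(0, n_classes, n_blocks)
  for (k in seq_len(n_classes)) {
    repeat {
      p <- sample(c(-1, 1), n_blocks, replace = TRUE)
      dup <- k > 1 && any(apply(patterns[seq_len(k - 1), , drop = FALSE], 1L,
                                function(q) all(q == p) || all(q == -p)))
      if (!dup) break
    }
    patterns[k, ] <- p
  }
  patterns
}

# One noise-plus-signal image as an H x W x 3 array on [0, 255].
render_image <- function(size, class_idx, strength, noise_sd, block_field = NULL) {
  h <- seq_len(size) / size
  w <- seq_len(size) / size
  base <- matrix(127.5, size, size)
  img <- array(0, dim = c(size, size, 3))
  if (strength > 0) {
    freq <- 2 + 2 * class_idx  # class-specific grating frequency
    grating <- outer(sin(2 * pi * freq * h), cos(2 * pi * freq * w))
    n_blobs <- class_idx + 1L  # class-specific blob count
    blobs <- matrix(0, size, size)
    for (b in seq_len(n_blobs)) {
      cx <- runif(1, 0.15, 0.85); cy <- runif(1, 0.15, 0.85)
      s2 <- (0.06 + 0.04 * runif(1))^2
      blobs <- blobs + exp(-(outer((h - cx)^2, (w - cy)^2, `+`)) / (2 * s2))
    }
    signal <- strength * (25 * grating + 35 * pmin(blobs, 1))
  } else {
    signal <- matrix(0, size, size)
  }
  if (!is.null(block_field)) {
    b <- nrow(block_field$values)
    idx_h <- pmin(ceiling(seq_len(size) / (size / b)), b)
    idx_w <- pmin(ceiling(seq_len(size) / (size / b)), b)
    signal <- signal + block_field$amp * block_field$values[idx_h, idx_w]
  }
  mix <- c(1, 0.8, 0.6)  # channel mixing keeps the three channels correlated but distinct
  for (ch in 1:3) {
    img[, , ch] <- base + mix[ch] * signal + matrix(rnorm(size^2, 0, noise_sd), size, size)
  }
  pmin(pmax(img, 0), 255)
}

#' Generate a labelled synthetic image set
#'
#' Draws `n_per_class` images for each class according to a [synthetic_spec()].
#' Images are 3-channel arrays on `[0, 255]` (8-bit range before any
#' normalization). Generation is fully deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `image_set` with elements `x` (an
#'   `n x size x size x 3` array), `labels` (0-based integer class indices,
#'   exactly `n_per_class` of each), `class_names`, and — when the spec sets
#'   `interaction_only` — a second view `x_b` of identical shape.
#' @export
generate_images <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) abort_bad_arg("`spec` must be a `synthetic_spec`.")
  set.seed(spawn_seed(spec$seed, "images"))
  n <- spec$n_per_class * spec$n_classes
  size <- spec$image_size
  labels <- rep(seq_len(spec$n_classes) - 1L, each = spec$n_per_class)
  x <- array(0, dim = c(n, size, size, 3))
  xb <- if (spec$interaction_only) array(0, dim = c(n, size, size, 3)) else NULL
  n_grid <- 4L
  patterns <- if (spec$interaction_only) {
    block_sign_patterns(spec$n_classes, n_grid^2)
  } else NULL
  amp <- 30 * spec$signal_strength
  for (i in seq_len(n)) {
    k <- labels[i]
    if (spec$interaction_only) {
      g <- matrix(rnorm(n_grid^2), n_grid, n_grid)
      field_a <- list(values = g, amp = amp)
      sgn <- matrix(patterns[k + 1L, ], n_grid, n_grid)
      field_b <- list(values = g * sgn, amp = amp)
      # interaction-only: structural signal off, class lives in the joint block field
      x[i, , , ] <- render_image(size, k, 0, spec$noise_sd, field_a)
      xb[i, , , ] <- render_image(size, k, 0, spec$noise_sd, field_b)
    } else {
      x[i, , , ] <- render_image(size, k, spec$signal_strength, spec$noise_sd)
    }
  }
  out <- list(x = x, labels = labels, class_names = default_class_names(spec$n_classes))
  if (spec$interaction_only) out$x_b <- xb
  structure(out, class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<image_set> %d images, %dx%dx%d%s\n", d[1], d[2], d[3], d[4],
              if (!is.null(x$x_b)) " (paired views)" else ""))
  print(table(class = x$class_names[x$labels + 1L]))
  invisible(x)
}

#' Write an image set as a directory-per-class PNG tree
#'
#' Lays out `<root>/<class_name>/<idx>.png` so that synthetic and real data go
#' through the same reader. Paired views are written under `<root>/view_a` and
#' `<root>/view_b`. A `manifest.csv` (file, class, label) is written at the
#' root.
#'
#' @param images An `image_set` from [generate_images()].
#' @param root Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_image_dataset <- function(images, root) {
  stopifnot(inherits(images, "image_set"))
  views <- if (is.null(images$x_b)) list(`.` = images$x) else list(view_a = images$x, view_b = images$x_b)
  rows <- list()
  for (vname in names(views)) {
    vroot <- if (vname == ".") root else file.path(root, vname)
    arr <- views[[vname]]
    for (i in seq_len(dim(arr)[1])) {
      cls <- images$class_names[images$labels[i] + 1L]
      dir.create(file.path(vroot, cls), recursive = TRUE, showWarnings = FALSE)
      path <- file.path(vroot, cls, sprintf("%05d.png", i))
      png::writePNG(arr[i, , , ] / 255, path)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        file = path, view = vname, class = cls, label = images$labels[i]
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a directory-per-class PNG/JPEG tree into an image set
#'
#' @param root Directory whose sub-directories are class names containing PNG
#'   images. Class index order follows [default_class_names()] when the names
#'   match, otherwise sorted directory order.
#' @return An `image_set` (values on `[0, 255]`).
#' @export
read_image_dataset <- function(root) {
  if (!dir.exists(root)) abort_bad_arg(sprintf("data root `%s` does not exist.", root))
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  dirs <- setdiff(dirs, c("view_a", "view_b"))
  if (length(dirs) == 0) abort_bad_arg(sprintf("no class directories under `%s`.", root))
  canonical <- default_class_names(length(dirs))
  class_names <- if (setequal(dirs, canonical)) canonical else sort(dirs)
  xs <- list(); labels <- integer(0)
  for (k in seq_along(class_names)) {
    files <- sort(list.files(file.path(root, class_names[k]), pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
      xs[[length(xs) + 1L]] <- a[, , 1:3] * 255
      labels <- c(labels, k - 1L)
    }
  }
  if (length(xs) == 0) abort_bad_arg("no PNG images found.")
  d <- dim(xs[[1]])
  if (!all(vapply(xs, function(a) identical(dim(a), d), logical(1)))) {
    abort_bad_arg("images have mixed sizes; resize before ingest.")
  }
  x <- array(0, dim = c(length(xs), d))
  for (i in seq_along(xs)) x[i, , , ] <- xs[[i]]
  structure(list(x = x, labels = labels, class_names = class_names), class = "image_set")
}

#' Generate a labelled feature-vector fixture
#'
#' Produces two feature matrices (one per backbone branch) and labels, for
#' unit-testing the fusion head without images. In the default regime each
#' class is a Gaussian cluster whose centroid lies at distance proportional to
#' `separation` from the origin along a class-specific random unit direction
#' (split across the two views). In the `interaction_only` regime, view A
#' carries a standard normal field `g`, view B carries `c * sign_k * g`
#' plus independent noise with `c = separation / (1 + separation)`; each view
#' is marginally class-free while the elementwise product has class-dependent
#' mean `c * sign_k`.
#'
#' @param n Total number of samples (>= `n_classes`), allocated round-robin.
#' @param dA,dB Feature dimensions of views A and B (>= 1).
#' @param n_classes Number of classes.
#' @param separation Non-negative real controlling class separability;
#'   0 means no class signal anywhere.
#' @param seed Integer seed.
#' @param interaction_only Use the interaction-only regime (requires dA == dB).
#' @return A list of class `feature_fixture` with `features_a` (n x dA),
#'   `features_b` (n x dB) and `labels` (0-based integers).
#' @export
#' @examples
#' fx <- generate_feature_fixture(100, 16, 16, n_classes = 5, separation = 10, seed = 3)
#' dim(fx$features_a)
generate_feature_fixture <- function(n, dA, dB, n_classes = 5, separation = 1,
                                     seed = 1, interaction_only = FALSE) {
  check_number(n, "n", min = 1, integerish = TRUE)
  check_number(dA, "dA", min = 1, integerish = TRUE)
  check_number(dB, "dB", min = 1, integerish = TRUE)
  check_number(n_classes, "n_classes", min = 2, integerish = TRUE)
  check_number(separation, "separation", min = 0)
  if (n < n_classes) abort_bad_arg("`n` must be at least `n_classes`.")
  if (interaction_only && dA != dB) abort_bad_arg("interaction_only requires dA == dB.")
  set.seed(spawn_seed(seed, "feature_fixture"))
  labels <- sort(rep_len(seq_len(n_classes) - 1L, n))
  fa <- matrix(rnorm(n * dA), n, dA)
  fb <- matrix(rnorm(n * dB), n, dB)
  if (interaction_only) {
    signs <- block_sign_patterns(n_classes, dA)
    cc <- separation / (1 + separation)
    g <- matrix(rnorm(n * dA), n, dA)
    fa <- g + fa                      # view A: field plus unit noise, class-free
    fb <- cc * signs[labels + 1L, , drop = FALSE] * g + sqrt(1 - cc^2) * fb
  } else {
    ua <- matrix(rnorm(n_classes * dA), n_classes, dA)
    ua <- ua / sqrt(rowSums(ua^2))
    ub <- matrix(rnorm(n_classes * dB), n_classes, dB)
    ub <- ub / sqrt(rowSums(ub^2))
    fa <- fa + separation * ua[labels + 1L, , drop = FALSE]
    fb <- fb + separation * ub[labels + 1L, , drop = FALSE]
  }
  structure(list(features_a = fa, features_b = fb, labels = labels),
            class = "feature_fixture")
}

#' @export
print.feature_fixture <- function(x, ...) {
  cat(sprintf("<feature_fixture> n=%d, dA=%d, dB=%d, %d classes\n",
              nrow(x$features_a), ncol(x$features_a), ncol(x$features_b),
              length(unique(x$labels))))
  invisible(x)
}

#' Tidy a feature fixture into one long-format tibble
#'
#' @param x A `feature_fixture`.
#' @param ... Unused.
#' @return A tibble with columns `label`, `view`, `feature`, `value`.
#' @export
tidy.feature_fixture <- function(x, ...) {
  one <- function(m, view) {
    colnames(m) <- paste0("f", seq_len(ncol(m)) - 1L)
    tibble::as_tibble(m) |>
      dplyr::mutate(label = x$labels, view = view, .before = 1) |>
      tidyr::pivot_longer(-c("label", "view"), names_to = "feature", values_to = "value")
  }
  dplyr::bind_rows(one(x$features_a, "a"), one(x$features_b, "b"))
}

#' Write / read a feature fixture as CSV
#'
#' One CSV per view with header `label,f0,f1,...`.
#'
#' @param fixture A `feature_fixture`.
#' @param path_a,path_b Output CSV paths for the two views.
#' @return Invisibly, the fixture.
#' @export
write_feature_fixture <- function(fixture, path_a, path_b) {
  one <- function(m, path) {
    df <- data.frame(label = fixture$labels, m)
    names(df) <- c("label", paste0("f", seq_len(ncol(m)) - 1L))
    utils::write.csv(df, path, row.names = FALSE)
  }
  one(fixture$features_a, path_a)
  one(fixture$features_b, path_b)
  invisible(fixture)
}

#' @rdname write_feature_fixture
#' @export
read_feature_fixture <- function(path_a, path_b) {
  one <- function(path) utils::read.csv(path)
  da <- one(path_a); db <- one(path_b)
  if (!identical(da$label, db$label)) abort_bad_arg("view CSVs disagree on labels.")
  structure(list(
    features_a = as.matrix(da[, -1, drop = FALSE]),
    features_b = as.matrix(db[, -1, drop = FALSE]),
    labels = as.integer(da$label)
  ), class = "feature_fixture")
}
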