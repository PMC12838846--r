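as_batch <- function(...) {
  mats <- list(...)
  n <- length(mats)
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  x <- array(0, dim = c(n, h, w, 3))
  for (i in seq_len(n)) for (ch in 1:3) x[i, , , ch] <- mats[[i]]
  x
}

test_that("channel statistics match hand computations with the population divisor", {
  # two 1x1 images with values {0, 2}: mean 1, population sd 1
  x <- as_batch(matrix(0, 1, 1), matrix(2, 1, 1))
  st <- compute_channel_stats(x)
  expect_equal(st$mu, rep(1, 3))
  expect_equal(st$sigma, rep(1, 3))

  # single 2x2 image {1,2,3,4}: brute-force loop oracle
  m <- matrix(1:4, 2, 2)
  x2 <- as_batch(m)
  st2 <- compute_channel_stats(x2)
  vals <- as.numeric(m)
  mu_oracle <- sum(vals) / 4
  sd_oracle <- sqrt(sum((vals - mu_oracle)^2) / 4)
  expect_equal(st2$mu, rep(mu_oracle, 3))
  expect_equal(st2$sigma, rep(sd_oracle, 3))
  expect_equal(st2$mu[1], 2.5)
  expect_equal(st2$sigma[1], sqrt(1.25))

  # constant set has zero variance
  st3 <- compute_channel_stats(as_batch(matrix(7, 3, 3)))
  expect_equal(st3$sigma, rep(0, 3))

  # recomputation is exact
  expect_identical(compute_channel_stats(x), st)
})

test_that("channel statistics validate their input", {
  expect_error(compute_channel_stats(array(0, dim = c(0, 4, 4, 3))),
               class = "qfuse_validation_error")
  expect_error(compute_channel_stats(matrix(1, 2, 2)), class = "qfuse_validation_error")
  # mixed sizes are rejected at ingest
  root <- withr::local_tempdir()
  dir.create(file.path(root, "class_0"))
  png::writePNG(array(0.5, dim = c(8, 8, 3)), file.path(root, "class_0", "a.png"))
  png::writePNG(array(0.5, dim = c(16, 16, 3)), file.path(root, "class_0", "b.png"))
  expect_error(read_image_dataset(root), class = "qfuse_validation_error")
})

test_that("normalization standardizes, is idempotent at (0,1), and guards zero variance", {
  spec <- synthetic_spec(n_per_class = 3, image_size = 12, seed = 2)
  imgs <- generate_images(spec)
  st <- compute_channel_stats(imgs)
  norm <- normalize_images(imgs, st)
  for (ch in 1:3) {
    v <- as.numeric(norm$x[, , , ch])
    expect_lt(abs(mean(v)), 1e-5)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-5)
  }
  # stats (0, 1) act as the identity
  id_stats <- structure(list(mu = rep(0, 3), sigma = rep(1, 3), n_images = 3,
                             height = 12, width = 12), class = "channel_stats")
  expect_equal(normalize_images(norm, id_stats), norm)
  # scalar case x=5, mu=1, sigma=2 -> 2
  one <- array(5, dim = c(1, 1, 1, 3))
  st512 <- structure(list(mu = rep(1, 3), sigma = rep(2, 3), n_images = 1,
                          height = 1, width = 1), class = "channel_stats")
  expect_equal(as.numeric(normalize_images(one, st512)), rep(2, 3))
  # zero-variance channel stays finite
  cst <- compute_channel_stats(as_batch(matrix(7, 2, 2)))
  out <- normalize_images(as_batch(matrix(7, 2, 2)), cst)
  expect_true(all(is.finite(out)))
  # shape mismatch
  expect_error(normalize_images(array(0, dim = c(1, 6, 6, 3)), st),
               class = "qfuse_validation_error")
})

test_that("stats are permutation-invariant and normalization is equivariant", {
  spec <- synthetic_spec(n_per_class = 2, image_size = 10, seed = 4)
  imgs <- generate_images(spec)
  perm <- c(3, 1, 4, 2, 5, 7, 10, 6, 9, 8)
  shuffled <- subset_images(imgs, perm)
  expect_equal(compute_channel_stats(shuffled), compute_channel_stats(imgs))
  st <- compute_channel_stats(imgs)
  expect_equal(normalize_images(shuffled, st)$x,
               normalize_images(imgs, st)$x[perm, , , , drop = FALSE])
})

test_that("splits reproduce the declared arithmetic", {
  labels <- rep(0:4, each = 20)
  sp <- make_splits(labels, seed = 1)
  expect_length(sp$test_idx, 20)
  expect_length(sp$val_idx, 8)
  expect_length(sp$train_idx, 72)
  # a 3176-image cohort under per-class ceiling yields a 636-image test set
  sizes <- c(855, 390, 310, 675, 946)
  expect_equal(sum(sizes), 3176)
  big <- rep(0:4, times = sizes)
  spb <- make_splits(big, seed = 2)
  expect_length(spb$test_idx, 636)
  # determinism
  expect_identical(make_splits(labels, seed = 9), make_splits(labels, seed = 9))
  expect_error(make_splits(labels, test_fraction = 1.2), class = "qfuse_validation_error")
})

test_that("splits are disjoint and cover the dataset across seeds and label draws", {
  for (seed in 1:100) {
    set.seed(seed)
    labels <- sample(0:4, 40 + seed %% 17, replace = TRUE)
    # stratification requires every class present
    labels <- c(labels, 0:4)
    sp <- make_splits(labels, seed = seed)
    all_idx <- c(sp$train_idx, sp$val_idx, sp$test_idx)
    expect_equal(sort(all_idx), seq_along(labels))
    expect_equal(anyDuplicated(all_idx), 0L)
    # every class appears in the test set under stratification
    expect_setequal(unique(labels[sp$test_idx]), 0:4)
  }
})

test_that("sidecar JSON files reproduce stats and splits exactly", {
  spec <- synthetic_spec(n_per_class = 2, image_size = 8, seed = 6)
  st <- compute_channel_stats(generate_images(spec))
  f <- withr::local_tempfile(fileext = ".json")
  write_sidecar(st, f)
  expect_equal(read_channel_stats(f), st)
  sp <- make_splits(rep(0:4, each = 10), seed = 3)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_sidecar(sp, f2)
  back <- read_split_spec(f2)
  expect_equal(back$train_idx, sp$train_idx)
  expect_equal(back$test_idx, sp$test_idx)
})

test_that("bilinear resize preserves constant images and output shape", {
  x <- array(3, dim = c(2, 16, 16, 3))
  out <- resize_images(x, 8)
  expect_equal(dim(out), c(2, 8, 8, 3))
  expect_equal(as.numeric(out), rep(3, length(out)))
})
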