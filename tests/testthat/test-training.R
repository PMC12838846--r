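test_that("cross-entropy reproduces closed forms and hand computations", {
  # perfect predictions: zero loss
  perfect <- diag(3)[c(1, 2, 3), ]
  expect_equal(cross_entropy_loss(perfect, c(0, 1, 2)), 0)
  # uniform over K = 5: ln 5
  expect_equal(cross_entropy_loss(matrix(0.2, 4, 5), c(0, 1, 2, 3)), log(5))
  expect_equal(log(5), 1.60944, tolerance = 1e-5)
  # batch of 2 with p_true = (0.5, 0.25)
  probs <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(cross_entropy_loss(probs, c(0, 0)), -(log(0.5) + log(0.25)) / 2)
  expect_equal(cross_entropy_loss(probs, c(0, 0)), 1.03972, tolerance = 1e-5)
  # zero probability at the true label is clamped, not infinite
  expect_true(is.finite(cross_entropy_loss(rbind(c(0, 1)), 0L)))
  expect_error(cross_entropy_loss(probs, c(0, 5)), class = "qfuse_validation_error")
})

test_that("cosine annealing hits its endpoints and decays monotonically", {
  expect_equal(cosine_lr(0, 100, 1e-4), 1e-4)
  expect_equal(cosine_lr(100, 100, 1e-4), 0)
  expect_equal(cosine_lr(50, 100, 1e-4), 5e-5)
  lrs <- sapply(0:50, cosine_lr, total_steps = 50, lr0 = 3e-3)
  expect_true(all(diff(lrs) <= 0))
  expect_error(cosine_lr(1, 0, 1e-4), class = "qfuse_validation_error")
})

test_that("training is reproducible and the log follows the cosine schedule", {
  fx <- generate_feature_fixture(200, 8, 8, n_classes = 5, separation = 5, seed = 2)
  sp <- make_splits(fx$labels, seed = 1)
  m <- fusion_model(8, 8, P = 8, r = 4, n_heads = 2, hidden_dim = 16,
                    n_classes = 5, seed = 1)
  cfg <- train_config(epochs = 4, seed = 7)
  f1 <- train_fusion(fx$features_a, fx$features_b, fx$labels, sp, m, cfg)
  f2 <- train_fusion(fx$features_a, fx$features_b, fx$labels, sp, m, cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(qfuse:::trainable_leaves(f1$model), qfuse:::trainable_leaves(f2$model))
  # logged lr equals the analytic schedule at the last step of each epoch
  steps_per_epoch <- ceiling(length(sp$train_idx) / cfg$batch_size)
  total <- cfg$epochs * steps_per_epoch
  expected_lr <- sapply(seq_len(nrow(f1$log)), function(ep) {
    cosine_lr(ep * steps_per_epoch - 1, total, cfg$lr)
  })
  expect_equal(f1$log$lr, expected_lr)
})

test_that("early stopping returns the epoch with maximal validation macro F1", {
  fx <- generate_feature_fixture(300, 8, 8, n_classes = 5, separation = 8, seed = 4)
  sp <- make_splits(fx$labels, seed = 2)
  m <- fusion_model(8, 8, P = 8, r = 4, n_heads = 2, hidden_dim = 16,
                    n_classes = 5, seed = 2)
  fit <- train_fusion(fx$features_a, fx$features_b, fx$labels, sp, m,
                      train_config(epochs = 6, lr = 1e-3, seed = 3))
  expect_equal(fit$best_epoch, which.max(fit$log$val_macro_f1))
  expect_equal(fit$best_val_macro_f1, max(fit$log$val_macro_f1))
  # the returned checkpoint reproduces the best epoch's validation score
  pred <- predict(fit, fx$features_a[sp$val_idx, ], fx$features_b[sp$val_idx, ],
                  type = "class")
  expect_equal(qfuse:::macro_f1_score(fx$labels[sp$val_idx], pred, 5),
               fit$best_val_macro_f1)
})

test_that("loss decreases over the first epochs on separable data", {
  fx <- generate_feature_fixture(500, 8, 8, n_classes = 5, separation = 8, seed = 6)
  sp <- make_splits(fx$labels, seed = 1)
  m <- fusion_model(8, 8, P = 16, r = 4, n_heads = 2, hidden_dim = 32,
                    n_classes = 5, seed = 1)
  fit <- train_fusion(fx$features_a, fx$features_b, fx$labels, sp, m,
                      train_config(epochs = 5, lr = 1e-3, seed = 1))
  expect_lt(fit$log$loss[5], fit$log$loss[1])
})

test_that("no-signal fixtures train to chance-level validation accuracy", {
  accs <- sapply(1:5, function(seed) {
    fx <- generate_feature_fixture(300, 8, 8, n_classes = 5, separation = 0, seed = seed)
    sp <- make_splits(fx$labels, seed = seed)
    m <- fusion_model(8, 8, P = 8, r = 4, n_heads = 2, hidden_dim = 16,
                      n_classes = 5, seed = seed)
    fit <- train_fusion(fx$features_a, fx$features_b, fx$labels, sp, m,
                        train_config(epochs = 3, seed = seed))
    pred <- predict(fit, fx$features_a[sp$val_idx, ], fx$features_b[sp$val_idx, ],
                    type = "class")
    mean(pred == fx$labels[sp$val_idx])
  })
  expect_lt(abs(mean(accs) - 0.20), 0.05)
})

test_that("the MLP baseline trains, predicts, and validates its inputs", {
  fx <- generate_feature_fixture(1000, 8, 8, n_classes = 5, separation = 8, seed = 3)
  sp <- make_splits(fx$labels, seed = 1)
  fit <- train_mlp_baseline(fx$features_a, fx$labels, sp, 5, hidden_dim = 32,
                            config = train_config(epochs = 10, lr = 1e-3, seed = 1))
  pred <- predict(fit, fx$features_a[sp$test_idx, ], type = "class")
  expect_gt(mean(pred == fx$labels[sp$test_idx]), 0.9)
  probs <- predict(fit, fx$features_a[sp$test_idx, ], type = "prob")
  expect_equal(rowSums(probs), rep(1, length(sp$test_idx)), tolerance = 1e-6)
  expect_error(train_fusion(fx$features_a, fx$features_b, fx$labels,
                            list(train_idx = integer(0), val_idx = 1:5),
                            fusion_model(8, 8, P = 8, r = 4, n_heads = 2,
                                         hidden_dim = 8, n_classes = 5)),
               class = "qfuse_validation_error")
})

test_that("fit tidiers expose the per-epoch log and a one-row summary", {
  fx <- generate_feature_fixture(100, 4, 4, n_classes = 5, separation = 5, seed = 1)
  sp <- make_splits(fx$labels, seed = 1)
  m <- fusion_model(4, 4, P = 4, r = 2, n_heads = 2, hidden_dim = 8,
                    n_classes = 5, seed = 1)
  fit <- train_fusion(fx$features_a, fx$features_b, fx$labels, sp, m,
                      train_config(epochs = 2, seed = 1))
  td <- tidy(fit)
  expect_named(td, c("epoch", "loss", "val_macro_f1", "lr"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$best_epoch, fit$best_epoch)
})
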