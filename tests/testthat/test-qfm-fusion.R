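test_that("hadamard interaction truncates to the common dimension and multiplies", {
  expect_equal(hadamard_interaction(c(1, 2, 3), c(4, 5)), c(4, 10))
  z <- rnorm(6)
  expect_equal(hadamard_interaction(rep(1, 6), z), z)
  # symmetric when dA == dB
  a <- rnorm(4); b <- rnorm(4)
  expect_equal(hadamard_interaction(a, b), hadamard_interaction(b, a))
  # dA = dB = 768 keeps the full 768 dimensions
  za <- rnorm(768); zb <- rnorm(768)
  expect_length(hadamard_interaction(za, zb), 768)
  expect_error(hadamard_interaction(numeric(0), 1:3), class = "qfuse_validation_error")
})

test_that("qfm zero-parameter cases follow from cos(0)=1 and sin(0)=0", {
  p <- qfm_params(4, P = 6, r = 3, seed = 1)
  p$W[] <- 0; p$b[] <- 0; p$U[] <- 0
  z <- rnorm(4)
  # theta = 0: c all ones, s all zeros, and U = 0 kills the interaction term,
  # so f reduces to W0 [1; 0; 0] + b0
  f_expected <- drop(p$W0 %*% c(rep(1, 6), rep(0, 6), rep(0, 3))) + p$b0
  psi <- qfm_forward(z, p)
  expect_equal(psi, f_expected / (sqrt(sum(f_expected^2)) + p$eps))
  # f = 0 gives psi = 0 exactly
  p0 <- p; p0$W0[] <- 0; p0$b0[] <- 0
  expect_equal(qfm_forward(z, p0), rep(0, 6))
  expect_error(qfm_params(4, P = 6, r = 3, eps = 0), class = "qfuse_validation_error")
  expect_error(qfm_forward(rnorm(5), p), class = "qfuse_validation_error")
})

test_that("qfm matches the scalar-loop oracle under both low-rank readings", {
  for (reading in c("cos_then_project", "project_then_cos")) {
    for (trial in 1:20) {
      set.seed(trial)
      p <- rand_qfm_params(5, 8, 3, seed = trial, reading = reading)
      z <- rnorm(5)
      expect_equal(qfm_forward(z, p), oracle_qfm(z, p), tolerance = 1e-6)
    }
  }
})

test_that("qfm output norm is strictly below one and saturates in the large-norm limit", {
  set.seed(42)
  p <- rand_qfm_params(6, 10, 4, seed = 9)
  for (trial in 1:50) {
    psi <- qfm_forward(rnorm(6, sd = 3), p)
    expect_lt(sqrt(sum(psi^2)), 1)
  }
  # ||psi|| = ||f|| / (||f|| + eps), within 1e-4 of 1 once ||f|| >= 1e4 * eps
  p_big <- p
  p_big$W0 <- p_big$W0 * 1e4
  psi <- qfm_forward(rnorm(6), p_big)
  nf <- sqrt(sum(psi^2))
  expect_gt(nf, 1 - 1e-4)
  expect_lt(nf, 1)
})

test_that("qfm embedding is 2*pi-periodic in the phase bias", {
  p <- rand_qfm_params(4, 6, 3, seed = 2)
  z <- rnorm(4)
  base <- qfm_forward(z, p)
  for (i in c(1, 4, 6)) {
    p2 <- p
    p2$b[i] <- p2$b[i] + 2 * pi
    # the phase-domain terms are trigonometric; only sin(z'V) is phase-free
    expect_equal(qfm_forward(z, p2), base, tolerance = 1e-9)
  }
})

test_that("token sequences stack the three QFM outputs in order", {
  t1 <- c(1, 0); t2 <- c(0, 1); t3 <- c(1, 1)
  Tm <- build_token_sequence(t1, t2, t3)
  expect_equal(unname(Tm), rbind(c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(rownames(Tm), c("t_A", "t_B", "t_H"))
  # permuting inputs permutes rows only
  Tm2 <- build_token_sequence(t3, t1, t2)
  expect_equal(unname(Tm2), unname(Tm[c(3, 1, 2), ]))
  expect_error(build_token_sequence(t1, t2, c(1, 2, 3)), class = "qfuse_validation_error")
  # the reference configuration yields a 3 x 256 sequence
  p <- qfm_params(768, P = 256, r = 32, seed = 1)
  psi <- qfm_forward(rnorm(768), p)
  expect_equal(dim(build_token_sequence(psi, psi, psi)), c(3, 256))
})

test_that("attention is uniform under zero query/key maps and rows are stochastic", {
  p <- mha_params(8, n_heads = 2, seed = 3)
  p$Wq[] <- 0; p$Wk[] <- 0
  Tm <- matrix(rnorm(24), 3, 8)
  out <- mha_forward(Tm, p, return_weights = TRUE)
  for (h in 1:2) {
    expect_equal(out$weights[, , h], matrix(1 / 3, 3, 3), tolerance = 1e-12)
  }
  # uniform attention averages the V rows before the output projection:
  # all three output rows coincide
  expect_equal(out$attended[1, ], out$attended[2, ], tolerance = 1e-12)
  expect_equal(out$attended[1, ], out$attended[3, ], tolerance = 1e-12)
  # random parameters: every attention row sums to 1
  p2 <- mha_params(8, n_heads = 4, seed = 5)
  w <- mha_forward(Tm, p2, return_weights = TRUE)$weights
  expect_equal(apply(w, c(1, 3), sum), matrix(1, 3, 4), tolerance = 1e-6)
  expect_error(mha_params(10, n_heads = 4), class = "qfuse_validation_error")
})

test_that("mha matches the scalar-loop attention oracle", {
  set.seed(7)
  for (trial in 1:20) {
    heads <- sample(c(1, 2, 4), 1)
    p <- mha_params(4 * heads, n_heads = heads, seed = trial)
    Tm <- matrix(rnorm(12 * heads), 3, 4 * heads)
    expect_equal(unname(mha_forward(Tm, p)), oracle_mha(Tm, p), tolerance = 1e-6)
  }
})

test_that("the classifier head produces valid probabilities and matches hand computation", {
  head <- classifier_head(4, hidden_dim = 3, dropout_rate = 0, n_classes = 3, seed = 1)
  head$W1[] <- 0; head$b1[] <- 0; head$W2[] <- 0; head$b2[] <- 0
  att <- matrix(rnorm(12), 3, 4)
  expect_equal(classify(att, head), rep(1 / 3, 3))
  # uniform for K = 5 as well
  h5 <- classifier_head(4, hidden_dim = 3, n_classes = 5, seed = 1)
  h5$W1[] <- 0; h5$W2[] <- 0
  expect_equal(classify(att, h5), rep(0.2, 5))
  # fixed tiny weights against the scalar oracle
  set.seed(3)
  h2 <- classifier_head(4, hidden_dim = 5, dropout_rate = 0, n_classes = 3, seed = 3)
  probs <- classify(att, h2)
  expect_equal(probs, oracle_classify(att, h2), tolerance = 1e-9)
  expect_equal(sum(probs), 1, tolerance = 1e-6)
  expect_true(all(probs >= 0))
  expect_error(classifier_head(4, n_classes = 1), class = "qfuse_validation_error")
})

test_that("the composed fusion forward matches the composed stage oracles", {
  for (trial in 1:20) {
    m <- fusion_model(6, 5, P = 8, r = 3, n_heads = 2, hidden_dim = 7,
                      n_classes = 5, dropout_rate = 0.3, seed = trial)
    set.seed(trial + 500)
    zA <- rnorm(6); zB <- rnorm(5)
    expect_equal(fusion_forward(m, zA, zB), oracle_fusion(m, zA, zB), tolerance = 1e-5)
  }
  # deterministic at inference
  m <- fusion_model(6, 5, P = 8, r = 3, n_heads = 2, hidden_dim = 7, n_classes = 5, seed = 1)
  zA <- rnorm(6); zB <- rnorm(5)
  expect_identical(fusion_forward(m, zA, zB), fusion_forward(m, zA, zB))
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(11)
  m <- fusion_model(5, 4, P = 6, r = 3, n_heads = 2, hidden_dim = 7,
                    n_classes = 3, dropout_rate = 0, seed = 3)
  n <- 4
  ZA <- matrix(rnorm(n * 5), n); ZB <- matrix(rnorm(n * 4), n)
  y <- c(0L, 1L, 2L, 1L)
  fw <- qfuse:::fusion_fwd(m, ZA, ZB, keep_cache = TRUE)
  dlogits <- (fw$probs - qfuse:::one_hot(y, 3)) / n
  gr <- qfuse:::fusion_bwd(m, dlogits, fw$cache)
  loss_at <- function(model) cross_entropy_loss(qfuse:::fusion_fwd(model, ZA, ZB), y)
  eps <- 1e-6
  for (blk in names(gr)) {
    for (nm in names(gr[[blk]])) {
      w <- m[[blk]][[nm]]
      idx <- sample(length(w), min(4, length(w)))
      for (i in idx) {
        mp <- m; mp[[blk]][[nm]][i] <- w[i] + eps
        mm <- m; mm[[blk]][[nm]][i] <- w[i] - eps
        num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
        expect_equal(gr[[blk]][[nm]][i], num, tolerance = 1e-4)
      }
    }
  }
})
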