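#' Hadamard interaction vector between two backbone embeddings
#'
#' Aligns the two embeddings to the common dimension `dH = min(dA, dB)` by
#' keeping each vector's first `dH` components, then multiplies them
#' elementwise. This interaction vector becomes the model's third token.
#'
#' @param zA,zB Numeric vectors, or matrices with one sample per row.
#' @return A vector (or matrix) of dimension `dH = min(dA, dB)`.
#' @export
#' @examples
#' hadamard_interaction(c(1, 2, 3), c(4, 5))  # -> c(4, 10)
hadamard_interaction <- function(zA, zB) {
  vec <- is.null(dim(zA)) && is.null(dim(zB))
  A <- if (is.null(dim(zA))) matrix(zA, 1) else as.matrix(zA)
  B <- if (is.null(dim(zB))) matrix(zB, 1) else as.matrix(zB)
  if (ncol(A) == 0 || ncol(B) == 0) abort_bad_arg("feature vectors must be non-empty.")
  if (nrow(A) != nrow(B)) abort_bad_arg("`zA` and `zB` must have the same number of rows.")
  dH <- min(ncol(A), ncol(B))
  out <- A[, seq_len(dH), drop = FALSE] * B[, seq_len(dH), drop = FALSE]
  if (vec) drop(out) else out
}

#' Quantum Feature Map parameters
#'
#' Creates the learnable parameters of one Quantum Feature Map branch: a phase
#' projection `W` (P x d) with bias `b`, low-rank interaction maps `U` (P x r,
#' phase domain) and `V` (d x r, input domain), an output projection `W0`
#' (P x (2P + r)) with bias `b0`, and the norm-scaling constant `eps`.
#' Projection matrices use variance-scaled uniform initialisation; biases start
#' at zero.
#'
#' The low-rank term admits two parenthesisations. The default,
#' `"cos_then_project"`, computes `h1` as the elementwise cosine of the phase
#' vector projected by `U`, and `h2` as the elementwise sine of `z` projected
#' by `V` (trig after projection on the input side). The alternative
#' `"project_then_cos"` applies the cosine after projecting the phase vector
#' too; both give length-`r` vectors.
#'
#' @param d Input feature dimension.
#' @param P Phase embedding dimension (default 256).
#' @param r Low-rank interaction dimension (default 32).
#' @param eps Positive norm-scaling constant (default 1e-6).
#' @param seed Integer seed for initialisation.
#' @param h1_reading Parenthesisation of the low-rank term (see Details).
#' @return An object of class `qfm_params`.
#' @export
qfm_params <- function(d, P = 256, r = 32, eps = 1e-6, seed = 1,
                       h1_reading = c("cos_then_project", "project_then_cos")) {
  check_number(d, "d", min = 1, integerish = TRUE)
  check_number(P, "P", min = 1, integerish = TRUE)
  check_number(r, "r", min = 1, integerish = TRUE)
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0) abort_bad_arg("`eps` must be > 0.")
  h1_reading <- match.arg(h1_reading)
  set.seed(spawn_seed(seed, "qfm"))
  structure(
    list(W = init_matrix(P, d), b = numeric(P),
         U = init_matrix(P, r),
         V = init_matrix(d, r),
         W0 = init_matrix(P, 2 * P + r), b0 = numeric(P),
         d = as.integer(d), P = as.integer(P), r = as.integer(r),
         eps = eps, h1_reading = h1_reading),
    class = "qfm_params"
  )
}

# Batch QFM forward. Z: n x d. Returns psi (n x P) and, optionally, the cache
# needed for the analytic backward pass.
qfm_fwd <- function(Z, p, keep_cache = FALSE) {
  if (ncol(Z) != p$d) abort_bad_arg(sprintf("input dim %d != params dim %d.", ncol(Z), p$d))
  theta <- Z %*% t(p$W) + matrix(p$b, nrow(Z), p$P, byrow = TRUE)
  C <- cos(theta); S <- sin(theta)
  if (p$h1_reading == "cos_then_project") {
    H1 <- C %*% p$U
    thU <- NULL
  } else {
    thU <- theta %*% p$U
    H1 <- cos(thU)
  }
  M <- Z %*% p$V
  H2 <- sin(M)
  H <- H1 * H2
  Ftil <- cbind(C, S, H)
  Fo <- Ftil %*% t(p$W0) + matrix(p$b0, nrow(Z), p$P, byrow = TRUE)
  nrm <- sqrt(rowSums(Fo^2))
  Psi <- Fo / (nrm + p$eps)
  if (!keep_cache) return(Psi)
  list(psi = Psi, cache = list(Z = Z, theta = theta, C = C, S = S, thU = thU,
                               H1 = H1, M = M, H2 = H2, Ftil = Ftil, F = Fo, nrm = nrm))
}

# Backward through one QFM branch. Returns parameter grads and dZ.
qfm_bwd <- function(dPsi, p, cache) {
  g <- cache$nrm + p$eps
  rs <- rowSums(dPsi * cache$F)
  coef <- ifelse(cache$nrm > 0, rs / (g^2 * cache$nrm), 0)
  dF <- dPsi / g - cache$F * coef
  dW0 <- t(dF) %*% cache$Ftil
  db0 <- colSums(dF)
  dFtil <- dF %*% p$W0
  P <- p$P; r <- p$r
  dC1 <- dFtil[, seq_len(P), drop = FALSE]
  dS <- dFtil[, P + seq_len(P), drop = FALSE]
  dH <- dFtil[, 2 * P + seq_len(r), drop = FALSE]
  dH1 <- dH * cache$H2
  dH2 <- dH * cache$H1
  if (p$h1_reading == "cos_then_project") {
    dC2 <- dH1 %*% t(p$U)
    dU <- t(cache$C) %*% dH1
    dtheta_h1 <- 0
  } else {
    dthU <- -dH1 * sin(cache$thU)
    dU <- t(cache$theta) %*% dthU
    dC2 <- 0
    dtheta_h1 <- dthU %*% t(p$U)
  }
  dM <- dH2 * cos(cache$M)
  dV <- t(cache$Z) %*% dM
  dC <- dC1 + dC2
  dtheta <- -dC * cache$S + dS * cache$C + dtheta_h1
  dW <- t(dtheta) %*% cache$Z
  db <- colSums(dtheta)
  dZ <- dtheta %*% p$W + dM %*% t(p$V)
  list(grads = list(W = dW, b = db, U = dU, V = dV, W0 = dW0, b0 = db0), dZ = dZ)
}

#' Apply a Quantum Feature Map
#'
#' Maps a feature vector `z` to its norm-scaled embedding `psi`:
#' phase vector `theta = W z + b`, trigonometric embedding `c = cos(theta)`,
#' `s = sin(theta)`, low-rank interaction `h = h1 * h2` with
#' `h1` the `U`-projection of the cosine embedding and `h2 = sin(V' z)`,
#' extended representation `[c; s; h]`, output projection
#' `f = W0 [c; s; h] + b0`, and finally `psi = f / (||f||_2 + eps)`.
#' The Euclidean norm of `psi` is always strictly below 1 and approaches 1 as
#' `||f||` grows — the norm-preservation property motivated by unit-norm
#' quantum states.
#'
#' @param z A length-`d` feature vector, or an `n x d` matrix of rows.
#' @param params A [qfm_params()] built for dimension `d`.
#' @return A length-`P` vector (or `n x P` matrix) `psi`.
#' @export
qfm_forward <- function(z, params) {
  stopifnot(inherits(params, "qfm_params"))
  vec <- is.null(dim(z))
  Z <- if (vec) matrix(z, 1) else as.matrix(z)
  out <- qfm_fwd(Z, params)
  if (vec) drop(out) else out
}

#' Stack the three QFM tokens into a sequence
#'
#' @param psiA,psiB,psiH Length-`P` QFM outputs for branch A, branch B, and the
#'   Hadamard interaction branch.
#' @return A `3 x P` matrix with rows `t_A`, `t_B`, `t_H`.
#' @export
build_token_sequence <- function(psiA, psiB, psiH) {
  if (length(psiA) != length(psiB) || length(psiB) != length(psiH)) {
    abort_bad_arg("all three tokens must have the same dimension P.")
  }
  out <- rbind(t_A = as.numeric(psiA), t_B = as.numeric(psiB), t_H = as.numeric(psiH))
  out
}

#' Multi-head attention parameters
#'
#' Query/key/value projections `Wq`, `Wk`, `Wv` (each P x P, partitioned
#' column-wise into `n_heads` blocks of width `dk = P / n_heads`) and the
#' output projection `WO` (P x P).
#'
#' @param P Token dimension; must be divisible by `n_heads`.
#' @param n_heads Number of attention heads (default 4).
#' @param seed Integer seed for initialisation.
#' @return An object of class `mha_params`.
#' @export
mha_params <- function(P, n_heads = 4, seed = 1) {
  check_number(P, "P", min = 1, integerish = TRUE)
  check_number(n_heads, "n_heads", min = 1, integerish = TRUE)
  if (P %% n_heads != 0) abort_bad_arg("`P` must be divisible by `n_heads`.")
  set.seed(spawn_seed(seed, "mha"))
  structure(
    list(Wq = init_matrix(P, P), Wk = init_matrix(P, P), Wv = init_matrix(P, P),
         WO = init_matrix(P, P), P = as.integer(P), n_heads = as.integer(n_heads),
         dk = as.integer(P / n_heads)),
    class = "mha_params"
  )
}

# Batch MHA forward over 3-token sequences. tokens: list of 3 (n x P) matrices.
# Returns attended list of 3 (n x P) matrices plus cache (incl. attention
# weights, an n x 3 x 3 x n_heads array).
mha_fwd <- function(tokens, p, keep_cache = FALSE) {
  n <- nrow(tokens[[1]])
  hs <- p$n_heads; dk <- p$dk
  attw <- array(0, dim = c(n, 3, 3, hs))
  O <- lapply(1:3, function(a) matrix(0, n, p$P))
  cache_h <- vector("list", hs)
  for (h in seq_len(hs)) {
    cols <- (h - 1L) * dk + seq_len(dk)
    Q <- lapply(tokens, function(t) t %*% p$Wq[, cols, drop = FALSE])
    K <- lapply(tokens, function(t) t %*% p$Wk[, cols, drop = FALSE])
    V <- lapply(tokens, function(t) t %*% p$Wv[, cols, drop = FALSE])
    A <- array(0, dim = c(n, 3, 3))
    for (a in 1:3) {
      sc <- sapply(1:3, function(b) rowSums(Q[[a]] * K[[b]])) / sqrt(dk)
      if (n == 1L) sc <- matrix(sc, 1)
      A[, a, ] <- softmax_rows(sc)
    }
    for (a in 1:3) {
      Oa <- A[, a, 1] * V[[1]] + A[, a, 2] * V[[2]] + A[, a, 3] * V[[3]]
      O[[a]][, cols] <- Oa
    }
    attw[, , , h] <- A
    if (keep_cache) cache_h[[h]] <- list(Q = Q, K = K, V = V, A = A, cols = cols)
  }
  att <- lapply(O, function(o) o %*% p$WO)
  if (!keep_cache) return(list(att = att, weights = attw))
  list(att = att, weights = attw, cache = list(heads = cache_h, O = O, tokens = tokens))
}

# Backward through MHA. datt: list of 3 (n x P). Returns grads + dtokens.
mha_bwd <- function(datt, p, cache) {
  n <- nrow(datt[[1]])
  dWO <- matrix(0, p$P, p$P)
  dO <- vector("list", 3)
  for (a in 1:3) {
    dWO <- dWO + t(cache$O[[a]]) %*% datt[[a]]
    dO[[a]] <- datt[[a]] %*% t(p$WO)
  }
  dWq <- matrix(0, p$P, p$P); dWk <- matrix(0, p$P, p$P); dWv <- matrix(0, p$P, p$P)
  dtok <- lapply(1:3, function(a) matrix(0, n, p$P))
  for (h in seq_len(p$n_heads)) {
    ch <- cache$heads[[h]]; cols <- ch$cols; dk <- p$dk
    dQ <- lapply(1:3, function(a) matrix(0, n, dk))
    dK <- lapply(1:3, function(a) matrix(0, n, dk))
    dV <- lapply(1:3, function(a) matrix(0, n, dk))
    for (a in 1:3) {
      dOa <- dO[[a]][, cols, drop = FALSE]
      dA <- sapply(1:3, function(b) rowSums(dOa * ch$V[[b]]))   # n x 3
      if (n == 1L) dA <- matrix(dA, 1)
      Aa <- ch$A[, a, , drop = TRUE]
      if (n == 1L) Aa <- matrix(Aa, 1)
      for (b in 1:3) dV[[b]] <- dV[[b]] + Aa[, b] * dOa
      dot <- rowSums(Aa * dA)
      dS <- Aa * (dA - dot) / sqrt(dk)                           # softmax backward, scaled
      for (b in 1:3) {
        dQ[[a]] <- dQ[[a]] + dS[, b] * ch$K[[b]]
        dK[[b]] <- dK[[b]] + dS[, b] * ch$Q[[a]]
      }
    }
    for (a in 1:3) {
      dWq[, cols] <- dWq[, cols] + t(cache$tokens[[a]]) %*% dQ[[a]]
      dWk[, cols] <- dWk[, cols] + t(cache$tokens[[a]]) %*% dK[[a]]
      dWv[, cols] <- dWv[, cols] + t(cache$tokens[[a]]) %*% dV[[a]]
      dtok[[a]] <- dtok[[a]] + dQ[[a]] %*% t(p$Wq[, cols, drop = FALSE]) +
        dK[[a]] %*% t(p$Wk[, cols, drop = FALSE]) +
        dV[[a]] %*% t(p$Wv[, cols, drop = FALSE])
    }
  }
  list(grads = list(Wq = dWq, Wk = dWk, Wv = dWv, WO = dWO), dtokens = dtok)
}

#' Multi-head self-attention over a token sequence
#'
#' Scaled dot-product attention per head — `softmax(Q K' / sqrt(dk)) V` —
#' computed in parallel over `n_heads` subspaces, concatenated, and projected
#' by `WO`. Attention weights form a row-stochastic 3 x 3 matrix per head.
#'
#' @param tokens A `3 x P` token sequence from [build_token_sequence()].
#' @param params An [mha_params()].
#' @param return_weights Also return the attention weights.
#' @return The attended `3 x P` matrix; if `return_weights`, a list with
#'   elements `attended` and `weights` (3 x 3 x n_heads).
#' @export
mha_forward <- function(tokens, params, return_weights = FALSE) {
  stopifnot(inherits(params, "mha_params"))
  if (!is.matrix(tokens) || nrow(tokens) != 3L) abort_bad_arg("`tokens` must be a 3 x P matrix.")
  if (ncol(tokens) != params$P) abort_bad_arg("token dimension does not match `params$P`.")
  toks <- lapply(1:3, function(a) matrix(tokens[a, ], 1))
  out <- mha_fwd(toks, params)
  attended <- do.call(rbind, lapply(out$att, drop))
  rownames(attended) <- rownames(tokens)
  if (return_weights) {
    w <- array(out$weights[1, , , ], dim = c(3, 3, params$n_heads))
    list(attended = attended, weights = w)
  } else {
    attended
  }
}

#' MLP classification head parameters
#'
#' The attended 3-token sequence is pooled (mean over tokens by default, or
#' flattened), passed through one hidden layer with ReLU, dropout (active only
#' during training), and a softmax output layer over `n_classes`.
#'
#' @param P Token dimension.
#' @param hidden_dim Hidden layer width (default 256).
#' @param dropout_rate Dropout probability in `[0, 1)` (default 0.3).
#' @param n_classes Number of classes K (default 5, must be >= 2).
#' @param pooling `"mean"` (default) or `"flatten"`.
#' @param seed Integer seed for initialisation.
#' @return An object of class `classifier_head`.
#' @export
classifier_head <- function(P, hidden_dim = 256, dropout_rate = 0.3, n_classes = 5,
                            pooling = c("mean", "flatten"), seed = 1) {
  check_number(P, "P", min = 1, integerish = TRUE)
  check_number(hidden_dim, "hidden_dim", min = 1, integerish = TRUE)
  check_number(dropout_rate, "dropout_rate", min = 0, max = 1 - 1e-12)
  check_number(n_classes, "n_classes", min = 2, integerish = TRUE)
  pooling <- match.arg(pooling)
  set.seed(spawn_seed(seed, "head"))
  d_in <- if (pooling == "mean") P else 3L * P
  structure(
    list(W1 = init_matrix(hidden_dim, d_in), b1 = numeric(hidden_dim),
         W2 = init_matrix(n_classes, hidden_dim), b2 = numeric(n_classes),
         P = as.integer(P), hidden_dim = as.integer(hidden_dim),
         dropout_rate = dropout_rate, n_classes = as.integer(n_classes),
         pooling = pooling),
    class = "classifier_head"
  )
}

# Batch classifier forward. att: list of 3 (n x P). Returns probs + cache.
head_fwd <- function(att, p, training = FALSE, keep_cache = FALSE) {
  X <- if (p$pooling == "mean") (att[[1]] + att[[2]] + att[[3]]) / 3 else do.call(cbind, att)
  Hpre <- X %*% t(p$W1) + matrix(p$b1, nrow(X), p$hidden_dim, byrow = TRUE)
  Hact <- relu(Hpre)
  mask <- NULL
  if (training && p$dropout_rate > 0) {
    keep <- 1 - p$dropout_rate
    mask <- matrix(stats::rbinom(length(Hact), 1, keep), nrow(Hact)) / keep
    Hact <- Hact * mask
  }
  logits <- Hact %*% t(p$W2) + matrix(p$b2, nrow(X), p$n_classes, byrow = TRUE)
  probs <- softmax_rows(logits)
  if (!keep_cache) return(probs)
  list(probs = probs, cache = list(X = X, Hpre = Hpre, Hact = Hact, mask = mask))
}

# Backward through the head given dlogits. Returns grads + datt (list of 3).
head_bwd <- function(dlogits, p, cache) {
  dW2 <- t(dlogits) %*% cache$Hact
  db2 <- colSums(dlogits)
  dHact <- dlogits %*% p$W2
  if (!is.null(cache$mask)) dHact <- dHact * cache$mask
  dHpre <- dHact * (cache$Hpre > 0)
  dW1 <- t(dHpre) %*% cache$X
  db1 <- colSums(dHpre)
  dX <- dHpre %*% p$W1
  datt <- if (p$pooling == "mean") {
    lapply(1:3, function(a) dX / 3)
  } else {
    P <- p$P
    lapply(1:3, function(a) dX[, (a - 1L) * P + seq_len(P), drop = FALSE])
  }
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), datt = datt)
}

#' Classify an attended token sequence
#'
#' @param attended A `3 x P` matrix from [mha_forward()].
#' @param head A [classifier_head()].
#' @return A length-`K` probability vector (non-negative, summing to 1).
#'   Dropout is inactive at inference.
#' @export
classify <- function(attended, head) {
  stopifnot(inherits(head, "classifier_head"))
  if (!is.matrix(attended) || nrow(attended) != 3L) abort_bad_arg("`attended` must be 3 x P.")
  if (ncol(attended) != head$P) abort_bad_arg("dimension mismatch with head's P.")
  att <- lapply(1:3, function(a) matrix(attended[a, ], 1))
  drop(head_fwd(att, head))
}

#' Build the full fusion model
#'
#' Assembles three QFM branches (backbone A, backbone B, Hadamard interaction —
#' separate parameter sets, since input dimensions can differ), one multi-head
#' attention layer (no residual connection or layer norm), and the MLP head.
#'
#' @param dA,dB Backbone feature dimensions.
#' @param P Phase embedding dimension (default 256).
#' @param r Low-rank interaction dimension (default 32).
#' @param n_heads Attention heads (default 4).
#' @param hidden_dim MLP hidden width (default 256).
#' @param dropout_rate Dropout probability (default 0.3).
#' @param n_classes Number of classes (default 5).
#' @param eps QFM norm-scaling constant (default 1e-6).
#' @param pooling Token pooling before the MLP (`"mean"` or `"flatten"`).
#' @param h1_reading QFM low-rank parenthesisation, see [qfm_params()].
#' @param seed Integer seed for all initialisations.
#' @return An object of class `fusion_model`.
#' @export
fusion_model <- function(dA, dB, P = 256, r = 32, n_heads = 4, hidden_dim = 256,
                         dropout_rate = 0.3, n_classes = 5, eps = 1e-6,
                         pooling = "mean",
                         h1_reading = "cos_then_project", seed = 1) {
  dH <- min(dA, dB)
  structure(
    list(
      qfm_a = qfm_params(dA, P, r, eps, spawn_seed(seed, "qfm_a"), h1_reading),
      qfm_b = qfm_params(dB, P, r, eps, spawn_seed(seed, "qfm_b"), h1_reading),
      qfm_h = qfm_params(dH, P, r, eps, spawn_seed(seed, "qfm_h"), h1_reading),
      mha = mha_params(P, n_heads, spawn_seed(seed, "mha")),
      head = classifier_head(P, hidden_dim, dropout_rate, n_classes,
                             pooling = pooling, seed = spawn_seed(seed, "head")),
      dA = as.integer(dA), dB = as.integer(dB), dH = as.integer(dH),
      P = as.integer(P), r = as.integer(r), n_classes = as.integer(n_classes)
    ),
    class = "fusion_model"
  )
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf(paste0("<fusion_model> dA=%d dB=%d dH=%d | P=%d r=%d heads=%d ",
                     "hidden=%d K=%d\n"),
              x$dA, x$dB, x$dH, x$P, x$r, x$mha$n_heads, x$head$hidden_dim, x$n_classes))
  invisible(x)
}

# Batch forward through the whole fusion model.
fusion_fwd <- function(model, ZA, ZB, training = FALSE, keep_cache = FALSE) {
  ZH <- hadamard_interaction(ZA, ZB)
  qa <- qfm_fwd(ZA, model$qfm_a, keep_cache)
  qb <- qfm_fwd(ZB, model$qfm_b, keep_cache)
  qh <- qfm_fwd(ZH, model$qfm_h, keep_cache)
  if (keep_cache) {
    tokens <- list(qa$psi, qb$psi, qh$psi)
  } else {
    tokens <- list(qa, qb, qh)
  }
  m <- mha_fwd(tokens, model$mha, keep_cache)
  hd <- head_fwd(m$att, model$head, training = training, keep_cache = keep_cache)
  if (!keep_cache) return(hd)
  list(probs = hd$probs,
       cache = list(qa = qa$cache, qb = qb$cache, qh = qh$cache,
                    mha = m$cache, head = hd$cache))
}

# Full backward pass from dlogits. Returns nested gradient list mirroring the
# model's parameter structure.
fusion_bwd <- function(model, dlogits, cache) {
  hb <- head_bwd(dlogits, model$head, cache$head)
  mb <- mha_bwd(hb$datt, model$mha, cache$mha)
  ga <- qfm_bwd(mb$dtokens[[1]], model$qfm_a, cache$qa)
  gb <- qfm_bwd(mb$dtokens[[2]], model$qfm_b, cache$qb)
  gh <- qfm_bwd(mb$dtokens[[3]], model$qfm_h, cache$qh)
  list(qfm_a = ga$grads, qfm_b = gb$grads, qfm_h = gh$grads,
       mha = mb$grads, head = hb$grads)
}

#' End-to-end fusion forward pass
#'
#' Composes Hadamard interaction, three QFM branches, token stacking,
#' multi-head attention, and the MLP head. Deterministic at inference
#' (dropout inactive).
#'
#' @param model A [fusion_model()].
#' @param zA,zB Feature vectors, or matrices with one sample per row.
#' @return A length-`K` probability vector, or an `n x K` matrix for
#'   matrix input.
#' @export
fusion_forward <- function(model, zA, zB) {
  stopifnot(inherits(model, "fusion_model"))
  vec <- is.null(dim(zA))
  ZA <- if (is.null(dim(zA))) matrix(zA, 1) else as.matrix(zA)
  ZB <- if (is.null(dim(zB))) matrix(zB, 1) else as.matrix(zB)
  if (ncol(ZA) != model$dA || ncol(ZB) != model$dB) {
    abort_bad_arg("feature dimensions do not match the model's dA/dB.")
  }
  out <- fusion_fwd(model, ZA, ZB)
  if (vec) drop(out) else out
}

# Leaves of a model that are trainable (matrices/vectors of weights).
trainable_leaves <- function(model) {
  list(
    qfm_a = model$qfm_a[c("W", "b", "U", "V", "W0", "b0")],
    qfm_b = model$qfm_b[c("W", "b", "U", "V", "W0", "b0")],
    qfm_h = model$qfm_h[c("W", "b", "U", "V", "W0", "b0")],
    mha = model$mha[c("Wq", "Wk", "Wv", "WO")],
    head = model$head[c("W1", "b1", "W2", "b2")]
  )
}

set_trainable_leaves <- function(model, leaves) {
  for (blk in names(leaves)) {
    for (nm in names(leaves[[blk]])) model[[blk]][[nm]] <- leaves[[blk]][[nm]]
  }
  model
}
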