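# Independent scalar-loop re-implementations of every model stage, written
# against the mathematical definitions directly (no shared code with R/).
# They are deliberately slow and explicit.

oracle_qfm <- function(z, p) {
  P <- p$P; r <- p$r; d <- p$d
  theta <- numeric(P)
  for (i in seq_len(P)) {
    acc <- p$b[i]
    for (j in seq_len(d)) acc <- acc + p$W[i, j] * z[j]
    theta[i] <- acc
  }
  cvec <- cos(theta); svec <- sin(theta)
  h1 <- numeric(r)
  if (p$h1_reading == "cos_then_project") {
    for (k in seq_len(r)) {
      acc <- 0
      for (i in seq_len(P)) acc <- acc + cvec[i] * p$U[i, k]
      h1[k] <- acc
    }
  } else {
    for (k in seq_len(r)) {
      acc <- 0
      for (i in seq_len(P)) acc <- acc + theta[i] * p$U[i, k]
      h1[k] <- cos(acc)
    }
  }
  h2 <- numeric(r)
  for (k in seq_len(r)) {
    acc <- 0
    for (j in seq_len(d)) acc <- acc + z[j] * p$V[j, k]
    h2[k] <- sin(acc)
  }
  h <- h1 * h2
  ftil <- c(cvec, svec, h)
  f <- numeric(P)
  for (i in seq_len(P)) {
    acc <- p$b0[i]
    for (j in seq_along(ftil)) acc <- acc + p$W0[i, j] * ftil[j]
    f[i] <- acc
  }
  nrm <- sqrt(sum(f^2))
  f / (nrm + p$eps)
}

oracle_softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

oracle_mha <- function(Tmat, p) {
  P <- p$P; hs <- p$n_heads; dk <- p$dk
  concat <- matrix(0, 3, P)
  for (h in seq_len(hs)) {
    cols <- (h - 1) * dk + seq_len(dk)
    Q <- Tmat %*% p$Wq[, cols]
    K <- Tmat %*% p$Wk[, cols]
    V <- Tmat %*% p$Wv[, cols]
    for (a in 1:3) {
      scores <- numeric(3)
      for (b in 1:3) scores[b] <- sum(Q[a, ] * K[b, ]) / sqrt(dk)
      w <- oracle_softmax(scores)
      out <- numeric(dk)
      for (b in 1:3) out <- out + w[b] * V[b, ]
      concat[a, cols] <- out
    }
  }
  concat %*% p$WO
}

oracle_classify <- function(att, head) {
  x <- if (head$pooling == "mean") colMeans(att) else as.numeric(t(att))
  hidden <- numeric(head$hidden_dim)
  for (i in seq_len(head$hidden_dim)) {
    acc <- head$b1[i]
    for (j in seq_along(x)) acc <- acc + head$W1[i, j] * x[j]
    hidden[i] <- max(acc, 0)
  }
  logits <- numeric(head$n_classes)
  for (k in seq_len(head$n_classes)) {
    acc <- head$b2[k]
    for (i in seq_len(head$hidden_dim)) acc <- acc + head$W2[k, i] * hidden[i]
    logits[k] <- acc
  }
  oracle_softmax(logits)
}

oracle_fusion <- function(model, zA, zB) {
  dH <- min(length(zA), length(zB))
  zH <- zA[seq_len(dH)] * zB[seq_len(dH)]
  Tmat <- rbind(oracle_qfm(zA, model$qfm_a),
                oracle_qfm(zB, model$qfm_b),
                oracle_qfm(zH, model$qfm_h))
  oracle_classify(oracle_mha(Tmat, model$mha), model$head)
}

# Per-class metrics straight from a count matrix, all in explicit loops.
oracle_metrics <- function(counts) {
  K <- nrow(counts)
  total <- sum(counts)
  prec <- rec <- f1 <- sup <- numeric(K)
  for (k in seq_len(K)) {
    tp <- counts[k, k]
    fp <- sum(counts[, k]) - tp
    fn <- sum(counts[k, ]) - tp
    sup[k] <- sum(counts[k, ])
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  acc <- sum(diag(counts)) / total
  w <- sup / total
  list(precision = prec, recall = rec, f1 = f1, accuracy = acc,
       macro_f1 = mean(f1), weighted_f1 = sum(w * f1),
       weighted_precision = sum(w * prec), weighted_recall = sum(w * rec))
}

rand_qfm_params <- function(d, P, r, seed, reading = "cos_then_project") {
  p <- qfm_params(d, P, r, eps = 1e-6, seed = seed, h1_reading = reading)
  set.seed(seed + 1000)
  p$b <- rnorm(P)
  p$b0 <- rnorm(P)
  p
}
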