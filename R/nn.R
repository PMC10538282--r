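# Internal neural-network engine for the methylation classifier.
#
# Tensors are carried as (B*T) x C matrices in "sample-fastest" row order:
# the row for sample b at sequence position t is b + (t-1)*B. Position-wise
# layers (projections, layer norm, feed-forward) then reduce to plain matrix
# ops; a time shift by `off` positions is a contiguous row-block shift by
# `off*B`, which keeps the dilated convolutions BLAS-friendly, and only
# self-attention needs the per-sample T x C view.

.row_scale <- function(m, v) m * rep(v, each = nrow(m))   # (i,j) -> m[i,j]*v[j]
.add_bias <- function(m, b) m + rep(b, each = nrow(m))

.softmax_rows <- function(z) {
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z)
  e / rowSums(e)
}

# Y[t_out rows, ] += X[t_out + off rows, ] %*% W  (zeros outside the range);
# on the (B*T) x D layout this is a row-block shift by off*B.
.conv_tap_fwd <- function(Z, Xmat, W, off, B) {
  n <- nrow(Xmat)
  s <- off * B
  if (s >= 0) { o1 <- 1L; o2 <- n - s; i1 <- s + 1L; i2 <- n }
  else        { o1 <- 1L - s; o2 <- n; i1 <- 1L; i2 <- n + s }
  if (o2 < o1) return(Z)
  Z[o1:o2, ] <- Z[o1:o2, ] + Xmat[i1:i2, , drop = FALSE] %*% W
  Z
}

# dW for the same tap: t(shifted X) %*% dZ, computed on the shared sub-block
.conv_tap_dW <- function(Xmat, dZ, off, B) {
  n <- nrow(Xmat)
  s <- off * B
  if (s >= 0) { o1 <- 1L; o2 <- n - s; i1 <- s + 1L; i2 <- n }
  else        { o1 <- 1L - s; o2 <- n; i1 <- 1L; i2 <- n + s }
  if (o2 < o1) return(matrix(0, ncol(Xmat), ncol(dZ)))
  crossprod(Xmat[i1:i2, , drop = FALSE], dZ[o1:o2, , drop = FALSE])
}

# sinusoidal positional encoding, T x M (positions 0-based)
.positional_encoding <- function(Tn, M) {
  P <- matrix(0, Tn, M)
  pos <- 0:(Tn - 1)
  for (i in seq_len(ceiling(M / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / M)
    P[, 2L * i - 1L] <- sin(pos * freq)
    if (2L * i <= M) P[, 2L * i] <- cos(pos * freq)
  }
  P
}

.ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = .add_bias(.row_scale(xhat, g), b), xhat = xhat, inv = inv)
}

.ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- .row_scale(dy, g)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                     xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

.init_params <- function(cfg) {
  Tn <- cfg$inputLen; D <- cfg$inputDim
  Fc <- cfg$convFilters; K <- cfg$kernelSize
  M <- 3L * Fc; Ff <- cfg$ffnDim
  p <- list()
  gl <- function(fin, fout) {
    matrix(rnorm(fin * fout, sd = sqrt(2 / (fin + fout))), fin, fout)
  }
  he <- function(fin, fout) {
    matrix(rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout)
  }
  for (br in 1:3) {
    for (j in seq_len(K)) p[[sprintf("conv%d.W%d", br, j)]] <- he(D, Fc)
    p[[sprintf("conv%d.b", br)]] <- numeric(Fc)
  }
  for (l in seq_len(cfg$nEncoderLayers)) {
    pre <- sprintf("enc%d.", l)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, nm)]] <- gl(M, M)
    for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- numeric(M)
    p[[paste0(pre, "ln1.g")]] <- rep(1, M)
    p[[paste0(pre, "ln1.b")]] <- numeric(M)
    p[[paste0(pre, "ffn.W1")]] <- he(M, Ff)
    p[[paste0(pre, "ffn.b1")]] <- numeric(Ff)
    p[[paste0(pre, "ffn.W2")]] <- gl(Ff, M)
    p[[paste0(pre, "ffn.b2")]] <- numeric(M)
    p[[paste0(pre, "ln2.g")]] <- rep(1, M)
    p[[paste0(pre, "ln2.b")]] <- numeric(M)
  }
  poolDim <- if (cfg$pooling == "flatten") Tn * M else M
  dims <- c(poolDim, cfg$fcDims)
  for (l in seq_along(cfg$fcDims)) {
    p[[sprintf("fc.W%d", l)]] <- he(dims[l], dims[l + 1])
    p[[sprintf("fc.b%d", l)]] <- numeric(dims[l + 1])
  }
  p[["fc.Wout"]] <- gl(tail(dims, 1), 2L)
  p[["fc.bout"]] <- numeric(2L)
  p
}

.conv_offsets <- function(K, rate) (seq_len(K) - (K + 1L) %/% 2L) * rate

# per-head view: (B*T) x M matrix -> T x dk x B array for head h
.head_view <- function(m, B, Tn, cols) {
  a <- m[, cols, drop = FALSE]
  dim(a) <- c(B, Tn, length(cols))
  aperm(a, c(2L, 3L, 1L))
}

# Full forward pass. X: (B, T, D) array. Returns probs (+ cache for backprop).
.nn_forward <- function(params, cfg, X, training = FALSE, keepCache = training) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  Fc <- cfg$convFilters; K <- cfg$kernelSize
  M <- 3L * Fc
  cache <- list(B = B)
  Xmat <- X
  dim(Xmat) <- c(B * Tn, dim(X)[3])
  if (keepCache) cache$Xmat <- Xmat

  # --- three parallel dilated convolution branches, ReLU, concat ---
  H <- matrix(0, B * Tn, M)
  if (keepCache) cache$convZ <- vector("list", 3L)
  for (br in 1:3) {
    offs <- .conv_offsets(K, cfg$dilationRates[br])
    Z <- matrix(rep(params[[sprintf("conv%d.b", br)]], each = B * Tn),
                B * Tn, Fc)
    for (j in seq_len(K)) {
      Z <- .conv_tap_fwd(Z, Xmat, params[[sprintf("conv%d.W%d", br, j)]],
                         offs[j], B)
    }
    if (keepCache) cache$convZ[[br]] <- Z
    H[, ((br - 1L) * Fc + 1L):(br * Fc)] <- pmax(Z, 0)
  }

  # --- additive sinusoidal positional encoding ---
  if (isTRUE(cfg$positional)) {
    P <- .positional_encoding(Tn, M)
    H <- H + P[rep(seq_len(Tn), each = B), ]
  }

  # --- Transformer encoder layers ---
  if (keepCache) cache$enc <- vector("list", cfg$nEncoderLayers)
  nh <- cfg$nHeads
  dk <- M / nh
  scale <- 1 / sqrt(dk)
  for (l in seq_len(cfg$nEncoderLayers)) {
    pre <- sprintf("enc%d.", l)
    Q <- .add_bias(H %*% params[[paste0(pre, "Wq")]], params[[paste0(pre, "bq")]])
    Km <- .add_bias(H %*% params[[paste0(pre, "Wk")]], params[[paste0(pre, "bk")]])
    V <- .add_bias(H %*% params[[paste0(pre, "Wv")]], params[[paste0(pre, "bv")]])
    O <- matrix(0, B * Tn, M)
    Alist <- if (keepCache) vector("list", nh) else NULL
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Qa <- .head_view(Q, B, Tn, cols)
      Ka <- .head_view(Km, B, Tn, cols)
      Va <- .head_view(V, B, Tn, cols)
      Oa <- array(0, c(Tn, dk, B))
      Ah <- if (keepCache) vector("list", B) else NULL
      for (b in seq_len(B)) {
        A <- .softmax_rows(tcrossprod(Qa[, , b], Ka[, , b]) * scale)
        Oa[, , b] <- A %*% Va[, , b]
        if (keepCache) Ah[[b]] <- A
      }
      O[, cols] <- matrix(aperm(Oa, c(3L, 1L, 2L)), B * Tn, dk)
      if (keepCache) Alist[[h]] <- Ah
    }
    attnOut <- .add_bias(O %*% params[[paste0(pre, "Wo")]],
                         params[[paste0(pre, "bo")]])
    R1 <- H + attnOut
    ln1 <- .ln_fwd(R1, params[[paste0(pre, "ln1.g")]],
                   params[[paste0(pre, "ln1.b")]])
    Z1 <- .add_bias(ln1$y %*% params[[paste0(pre, "ffn.W1")]],
                    params[[paste0(pre, "ffn.b1")]])
    F1 <- pmax(Z1, 0)
    F2 <- .add_bias(F1 %*% params[[paste0(pre, "ffn.W2")]],
                    params[[paste0(pre, "ffn.b2")]])
    R2 <- ln1$y + F2
    ln2 <- .ln_fwd(R2, params[[paste0(pre, "ln2.g")]],
                   params[[paste0(pre, "ln2.b")]])
    if (keepCache) {
      cache$enc[[l]] <- list(Hin = H, Q = Q, K = Km, V = V, O = O,
                             Alist = Alist, ln1 = ln1, Z1 = Z1, F1 = F1,
                             ln2 = ln2)
    }
    H <- ln2$y
  }

  # --- pooling over sequence positions ---
  if (cfg$pooling == "mean") {
    pool <- rowsum(H, group = rep_len(seq_len(B), B * Tn)) / Tn
  } else {
    pool <- H
    dim(pool) <- c(B, Tn * M)
  }
  if (keepCache) cache$pool <- pool

  # --- dense head with dropout ---
  act <- pool
  nFc <- length(cfg$fcDims)
  if (keepCache) {
    cache$fcZ <- vector("list", nFc)
    cache$fcA <- vector("list", nFc + 1L)
    cache$mask <- vector("list", nFc)
    cache$fcA[[1L]] <- act
  }
  for (l in seq_len(nFc)) {
    Z <- .add_bias(act %*% params[[sprintf("fc.W%d", l)]],
                   params[[sprintf("fc.b%d", l)]])
    act <- pmax(Z, 0)
    if (training && cfg$dropoutRate > 0) {
      mask <- (matrix(runif(length(act)), nrow(act)) >= cfg$dropoutRate) /
        (1 - cfg$dropoutRate)
      act <- act * mask
      if (keepCache) cache$mask[[l]] <- mask
    }
    if (keepCache) {
      cache$fcZ[[l]] <- Z
      cache$fcA[[l + 1L]] <- act
    }
  }
  logits <- .add_bias(act %*% params[["fc.Wout"]], params[["fc.bout"]])
  probs <- .softmax_rows(logits)
  list(probs = probs, cache = if (keepCache) cache else NULL)
}

# categorical cross-entropy on 2-class one-hot targets; y in {0,1};
# w: per-sample weights (normalized internally)
.nn_loss <- function(probs, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  p <- probs[cbind(seq_along(y), y + 1L)]
  sum(w * -log(pmax(p, 1e-12))) / sum(w)
}

.nn_backward <- function(params, cfg, cache, probs, y, w = NULL) {
  B <- cache$B
  Tn <- cfg$inputLen
  Fc <- cfg$convFilters; K <- cfg$kernelSize
  M <- 3L * Fc
  nh <- cfg$nHeads; dk <- M / nh; scale <- 1 / sqrt(dk)
  if (is.null(w)) w <- rep(1, length(y))
  grads <- list()

  Y <- matrix(0, length(y), 2L)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  dlogits <- (probs - Y) * (w / sum(w))

  nFc <- length(cfg$fcDims)
  act <- cache$fcA[[nFc + 1L]]
  grads[["fc.Wout"]] <- crossprod(act, dlogits)
  grads[["fc.bout"]] <- colSums(dlogits)
  dact <- tcrossprod(dlogits, params[["fc.Wout"]])
  for (l in rev(seq_len(nFc))) {
    if (!is.null(cache$mask[[l]])) dact <- dact * cache$mask[[l]]
    dZ <- dact * (cache$fcZ[[l]] > 0)
    grads[[sprintf("fc.W%d", l)]] <- crossprod(cache$fcA[[l]], dZ)
    grads[[sprintf("fc.b%d", l)]] <- colSums(dZ)
    dact <- tcrossprod(dZ, params[[sprintf("fc.W%d", l)]])
  }
  dpool <- dact

  if (cfg$pooling == "mean") {
    dH <- dpool[rep_len(seq_len(B), B * Tn), , drop = FALSE] / Tn
  } else {
    dH <- dpool
    dim(dH) <- c(B * Tn, M)
  }

  for (l in rev(seq_len(cfg$nEncoderLayers))) {
    pre <- sprintf("enc%d.", l)
    ec <- cache$enc[[l]]
    b2 <- .ln_bwd(dH, ec$ln2, params[[paste0(pre, "ln2.g")]])
    grads[[paste0(pre, "ln2.g")]] <- b2$dg
    grads[[paste0(pre, "ln2.b")]] <- b2$db
    dR2 <- b2$dx
    # FFN
    grads[[paste0(pre, "ffn.W2")]] <- crossprod(ec$F1, dR2)
    grads[[paste0(pre, "ffn.b2")]] <- colSums(dR2)
    dF1 <- tcrossprod(dR2, params[[paste0(pre, "ffn.W2")]])
    dZ1 <- dF1 * (ec$Z1 > 0)
    grads[[paste0(pre, "ffn.W1")]] <- crossprod(ec$ln1$y, dZ1)
    grads[[paste0(pre, "ffn.b1")]] <- colSums(dZ1)
    dN1 <- dR2 + tcrossprod(dZ1, params[[paste0(pre, "ffn.W1")]])
    b1 <- .ln_bwd(dN1, ec$ln1, params[[paste0(pre, "ln1.g")]])
    grads[[paste0(pre, "ln1.g")]] <- b1$dg
    grads[[paste0(pre, "ln1.b")]] <- b1$db
    dR1 <- b1$dx
    # attention output projection
    grads[[paste0(pre, "Wo")]] <- crossprod(ec$O, dR1)
    grads[[paste0(pre, "bo")]] <- colSums(dR1)
    dO <- tcrossprod(dR1, params[[paste0(pre, "Wo")]])
    dQ <- matrix(0, B * Tn, M)
    dK <- matrix(0, B * Tn, M)
    dV <- matrix(0, B * Tn, M)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      dOa <- .head_view(dO, B, Tn, cols)
      Qa <- .head_view(ec$Q, B, Tn, cols)
      Ka <- .head_view(ec$K, B, Tn, cols)
      Va <- .head_view(ec$V, B, Tn, cols)
      dQa <- array(0, c(Tn, dk, B))
      dKa <- dQa; dVa <- dQa
      Ah <- ec$Alist[[h]]
      for (b in seq_len(B)) {
        A <- Ah[[b]]
        dOb <- dOa[, , b]
        dVa[, , b] <- crossprod(A, dOb)
        dA <- tcrossprod(dOb, Va[, , b])
        dS <- A * (dA - rowSums(dA * A))
        dQa[, , b] <- (dS %*% Ka[, , b]) * scale
        dKa[, , b] <- crossprod(dS, Qa[, , b]) * scale
      }
      dQ[, cols] <- matrix(aperm(dQa, c(3L, 1L, 2L)), B * Tn, dk)
      dK[, cols] <- matrix(aperm(dKa, c(3L, 1L, 2L)), B * Tn, dk)
      dV[, cols] <- matrix(aperm(dVa, c(3L, 1L, 2L)), B * Tn, dk)
    }
    Hin <- ec$Hin
    grads[[paste0(pre, "Wq")]] <- crossprod(Hin, dQ)
    grads[[paste0(pre, "bq")]] <- colSums(dQ)
    grads[[paste0(pre, "Wk")]] <- crossprod(Hin, dK)
    grads[[paste0(pre, "bk")]] <- colSums(dK)
    grads[[paste0(pre, "Wv")]] <- crossprod(Hin, dV)
    grads[[paste0(pre, "bv")]] <- colSums(dV)
    dH <- dR1 +
      tcrossprod(dQ, params[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, params[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, params[[paste0(pre, "Wv")]])
  }

  # positional encoding is additive: gradient passes through unchanged
  for (br in 1:3) {
    cols <- ((br - 1L) * Fc + 1L):(br * Fc)
    dZ <- dH[, cols, drop = FALSE] * (cache$convZ[[br]] > 0)
    offs <- .conv_offsets(K, cfg$dilationRates[br])
    for (j in seq_len(K)) {
      grads[[sprintf("conv%d.W%d", br, j)]] <-
        .conv_tap_dW(cache$Xmat, dZ, offs[j], B)
    }
    grads[[sprintf("conv%d.b", br)]] <- colSums(dZ)
  }
  grads
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

.adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}
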