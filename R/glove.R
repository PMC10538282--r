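#' Build the global k-mer co-occurrence matrix
#'
#' For every ordered in-window pair within one document — token at position p
#' followed by token at position p+s, 1 <= s <= window — a directed count is
#' accumulated. The matrix is then symmetrized by mirroring: X\[i,j\] =
#' X\[j,i\] = (forward count of i before j) + (forward count of j before i),
#' so the upper triangle is computed and copied to the lower. With
#' `distanceWeight = TRUE` each pair contributes 1/s instead of 1.
#'
#' @param corpus a [TokenizedCorpus-class].
#' @param window context window in tokens (default 1: immediate neighbor).
#' @param distanceWeight logical; weight pairs by inverse distance.
#' @return A [CooccurrenceMatrix-class].
#' @export
buildCooccurrence <- function(corpus, window = 1L, distanceWeight = FALSE) {
  stopifnot(is(corpus, "TokenizedCorpus"))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (!length(corpus@docs)) stop("empty corpus")
  n <- length(corpus@vocab@tokens)
  D <- matrix(0, n, n)   # directed counts: D[i, j] = j appears after i
  for (doc in corpus@docs) {
    L <- length(doc)
    if (L < 2L) next
    for (s in seq_len(min(window, L - 1L))) {
      i <- doc[seq_len(L - s)]
      j <- doc[seq.int(s + 1L, L)]
      w <- if (distanceWeight) 1 / s else 1
      # accumulate via sparse tabulation of (i,j) pairs
      key <- (i - 1L) * n + j
      tab <- tapply(rep(w, length(key)), key, sum)
      idx <- as.integer(names(tab))
      D[cbind(((idx - 1L) %/% n) + 1L, ((idx - 1L) %% n) + 1L)] <-
        D[cbind(((idx - 1L) %/% n) + 1L, ((idx - 1L) %% n) + 1L)] + as.numeric(tab)
    }
  }
  new("CooccurrenceMatrix", X = D + t(D), vocab = corpus@vocab,
      window = window)
}

#' GloVe least-squares weighting function
#'
#' `f(x) = (x / tX)^alpha` for `x < tX`, and 1 otherwise. The truncation
#' parameter tX caps the influence of very frequent pairs; the exponent
#' alpha (0.75 by convention) damps rare, noisy co-occurrences. f is
#' non-decreasing, continuous at tX, and f(0) = 0 so zero-count pairs drop
#' out of the objective entirely.
#'
#' @param x nonnegative co-occurrence count(s).
#' @param tX truncation parameter (> 0), default 100.
#' @param alpha exponent in (0, 1], default 0.75.
#' @return weight(s) in \[0, 1\].
#' @export
gloveWeight <- function(x, tX = 100, alpha = 0.75) {
  if (any(x < 0)) stop("co-occurrence counts must be nonnegative")
  if (tX <= 0) stop("tX must be > 0")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  ifelse(x < tX, (x / tX)^alpha, 1)
}

.glove_pairs <- function(X) {
  nz <- which(X > 0, arr.ind = TRUE)
  list(i = nz[, 1], j = nz[, 2], x = X[nz])
}

#' Weighted least-squares GloVe objective
#'
#' `J = sum over nonzero X_ij of f(X_ij) * (V_i . Vt_j + b_i + bt_j -
#' log X_ij)^2`. The sum is restricted to nonzero entries: f(0) = 0 and
#' log(0) is undefined, so zero pairs contribute nothing.
#'
#' @param params list with elements `V`, `Vtilde` (N x d matrices), `b`,
#'   `btilde` (length-N vectors) — or a [GloveEmbedding-class].
#' @param cooc a [CooccurrenceMatrix-class] (or plain symmetric matrix).
#' @param tX,alpha weighting parameters, see [gloveWeight()].
#' @return nonnegative scalar J.
#' @export
gloveLoss <- function(params, cooc, tX = 100, alpha = 0.75) {
  X <- if (is(cooc, "CooccurrenceMatrix")) cooc@X else cooc
  if (is(params, "GloveEmbedding")) {
    params <- list(V = params@V, Vtilde = params@Vtilde,
                   b = params@b, btilde = params@btilde)
  }
  N <- nrow(X)
  if (nrow(params$V) != N || nrow(params$Vtilde) != N ||
      length(params$b) != N || length(params$btilde) != N) {
    stop("parameter shapes do not match the vocabulary size ", N)
  }
  p <- .glove_pairs(X)
  if (!length(p$x)) return(0)
  pred <- rowSums(params$V[p$i, , drop = FALSE] *
                  params$Vtilde[p$j, , drop = FALSE]) +
    params$b[p$i] + params$btilde[p$j]
  sum(gloveWeight(p$x, tX, alpha) * (pred - log(p$x))^2)
}

#' Analytic gradient of the GloVe objective
#'
#' Returns the exact gradient of [gloveLoss()] with respect to every
#' parameter block; used by the fitter's full-batch mode and verified
#' against central finite differences in the test suite.
#'
#' @inheritParams gloveLoss
#' @return list with gradients `V`, `Vtilde`, `b`, `btilde`.
#' @export
gloveGradient <- function(params, cooc, tX = 100, alpha = 0.75) {
  X <- if (is(cooc, "CooccurrenceMatrix")) cooc@X else cooc
  p <- .glove_pairs(X)
  N <- nrow(X); d <- ncol(params$V)
  gV <- matrix(0, N, d); gVt <- matrix(0, N, d)
  gb <- numeric(N); gbt <- numeric(N)
  if (length(p$x)) {
    pred <- rowSums(params$V[p$i, , drop = FALSE] *
                    params$Vtilde[p$j, , drop = FALSE]) +
      params$b[p$i] + params$btilde[p$j]
    r <- 2 * gloveWeight(p$x, tX, alpha) * (pred - log(p$x))
    for (t in seq_along(p$x)) {   # vocabularies are small (<= 4^k)
      i <- p$i[t]; j <- p$j[t]
      gV[i, ] <- gV[i, ] + r[t] * params$Vtilde[j, ]
      gVt[j, ] <- gVt[j, ] + r[t] * params$V[i, ]
      gb[i] <- gb[i] + r[t]
      gbt[j] <- gbt[j] + r[t]
    }
  }
  list(V = gV, Vtilde = gVt, b = gb, btilde = gbt)
}

#' Fit GloVe k-mer vectors by stochastic AdaGrad
#'
#' Minimizes the weighted least-squares objective over all nonzero cells of
#' the co-occurrence matrix with per-parameter adaptive gradient descent:
#' each epoch visits every nonzero (i, j) cell in a seeded random order and
#' applies an AdaGrad update to V_i, Vt_j and both biases. Initialization is
#' uniform in (-0.5/d, 0.5/d). The full objective is recorded after every
#' epoch; a run is bit-reproducible for a fixed seed.
#'
#' @param cooc a [CooccurrenceMatrix-class].
#' @param d embedding dimension (default 300).
#' @param tX,alpha weighting parameters, see [gloveWeight()].
#' @param lr initial AdaGrad learning rate (default 0.05).
#' @param epochs number of passes over the nonzero cells (default 50).
#' @param seed RNG seed controlling initialization and visit order.
#' @param export which per-token vector the embedding exposes: the main
#'   vectors `"V"` (default) or the common `"sum"` variant V + V-tilde.
#' @param center subtract the mean token vector from the exported embedding
#'   (default `TRUE`). On small corpora the fitted vectors share a large
#'   common-mode direction (the biases and the mean vector absorb the
#'   near-uniform part of the co-occurrence structure); removing it is the
#'   standard word-vector postprocessing and leaves the discriminative
#'   between-token geometry, which is what the classifier consumes.
#' @return A [GloveEmbedding-class] with the loss trajectory in
#'   `lossHistory()`.
#' @export
fitGlove <- function(cooc, d = 300L, tX = 100, alpha = 0.75, lr = 0.05,
                     epochs = 50L, seed = 1L, export = c("V", "sum"),
                     center = TRUE) {
  stopifnot(is(cooc, "CooccurrenceMatrix"))
  export <- match.arg(export)
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1")
  X <- cooc@X
  N <- nrow(X)
  p <- .glove_pairs(X)
  if (!length(p$x)) stop("co-occurrence matrix has no nonzero entries")
  logx <- log(p$x)
  fw <- gloveWeight(p$x, tX, alpha)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  V <- matrix(runif(N * d, -0.5 / d, 0.5 / d), N, d)
  Vt <- matrix(runif(N * d, -0.5 / d, 0.5 / d), N, d)
  b <- runif(N, -0.5 / d, 0.5 / d)
  bt <- runif(N, -0.5 / d, 0.5 / d)
  # AdaGrad accumulators (start at 1 so early steps are bounded by lr)
  hV <- matrix(1, N, d); hVt <- matrix(1, N, d)
  hb <- rep(1, N); hbt <- rep(1, N)

  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    for (t in sample.int(length(p$x))) {
      i <- p$i[t]; j <- p$j[t]
      diff <- sum(V[i, ] * Vt[j, ]) + b[i] + bt[j] - logx[t]
      g <- fw[t] * diff             # d(J_t)/d(pred) / 2
      if (!is.finite(g)) {
        stop("non-finite loss during GloVe training at epoch ", ep)
      }
      gVi <- g * Vt[j, ]; gVtj <- g * V[i, ]
      V[i, ] <- V[i, ] - lr * gVi / sqrt(hV[i, ])
      Vt[j, ] <- Vt[j, ] - lr * gVtj / sqrt(hVt[j, ])
      b[i] <- b[i] - lr * g / sqrt(hb[i])
      bt[j] <- bt[j] - lr * g / sqrt(hbt[j])
      hV[i, ] <- hV[i, ] + gVi^2
      hVt[j, ] <- hVt[j, ] + gVtj^2
      hb[i] <- hb[i] + g^2
      hbt[j] <- hbt[j] + g^2
    }
    pred <- rowSums(V[p$i, , drop = FALSE] * Vt[p$j, , drop = FALSE]) +
      b[p$i] + bt[p$j]
    history[ep] <- sum(fw * (pred - logx)^2)
    if (!is.finite(history[ep])) {
      stop("non-finite loss during GloVe training at epoch ", ep)
    }
  }
  new("GloveEmbedding", V = V, Vtilde = Vt, b = b, btilde = bt,
      tokens = cooc@vocab@tokens, d = d, history = history,
      config = list(tX = tX, alpha = alpha, lr = lr, epochs = epochs,
                    seed = as.integer(seed), export = export,
                    center = isTRUE(center), window = cooc@window))
}

#' Dump a co-occurrence matrix as a sparse three-column TSV
#'
#' One row per nonzero cell: token_i, token_j, count. Both triangles are
#' written (the matrix is symmetric).
#'
#' @param x a [CooccurrenceMatrix-class]
#' @param path output file
#' @return `path`, invisibly.
#' @export
writeCooccurrence <- function(x, path) {
  p <- .glove_pairs(x@X)
  df <- data.frame(i = x@vocab@tokens[p$i], j = x@vocab@tokens[p$j],
                   count = p$x, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load an embedding in GloVe text format
#'
#' One line per token: `token v1 v2 ... vd`, space-separated, '.' decimal.
#' `loadEmbedding(saveEmbedding(x, p))` reproduces the exported matrix to
#' 1e-6 per component.
#'
#' @param x a [GloveEmbedding-class] (its exported matrix is written).
#' @param path file path.
#' @return `saveEmbedding`: `path` invisibly. `loadEmbedding`: a
#'   [GloveEmbedding-class] whose V slot holds the file's vectors (context
#'   vectors and biases are zero — a loaded embedding encodes, it cannot
#'   resume training).
#' @export
saveEmbedding <- function(x, path) {
  m <- embeddingMatrix(x)
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.8g", m[i, ])), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname saveEmbedding
#' @export
loadEmbedding <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty embedding file: ", path)
  parts <- strsplit(lines, " ", fixed = TRUE)
  d <- length(parts[[1]]) - 1L
  if (d < 1L) stop("malformed embedding file at line 1: no vector components")
  bad <- which(vapply(parts, length, integer(1)) != d + 1L)
  if (length(bad)) {
    stop("inconsistent vector length at line ", bad[1], " of ", path)
  }
  tokens <- vapply(parts, `[[`, character(1), 1L)
  V <- t(vapply(parts, function(pp) as.numeric(pp[-1]), numeric(d)))
  if (anyNA(V)) stop("non-numeric vector component in ", path)
  new("GloveEmbedding", V = V, Vtilde = matrix(0, nrow(V), d),
      b = numeric(nrow(V)), btilde = numeric(nrow(V)), tokens = tokens,
      d = d, history = numeric(0),
      config = list(export = "V", source = path))
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
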