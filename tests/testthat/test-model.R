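tiny_cfg <- function(dropoutRate = 0, ...) {
  modelConfig(inputLen = 7L, inputDim = 5L, convFilters = 4L, nHeads = 2L,
              ffnDim = 10L, fcDims = c(6L, 5L, 4L),
              dropoutRate = dropoutRate, seed = 42L, ...)
}

tiny_batch <- function(B, Tn = 7, D = 5, seed = 9) {
  set.seed(seed)
  array(rnorm(B * Tn * D), c(B, Tn, D))
}

test_that("configuration contracts are enforced", {
  expect_error(modelConfig(convFilters = 10, nHeads = 4), "divisible")
  expect_error(modelConfig(kernelSize = 2), "odd")
  expect_error(modelConfig(dropoutRate = 1), "dropoutRate")
  cfg <- modelConfig(convFilters = 64)
  expect_identical(cfg$ffnDim, 4L * 192L)  # defaults to 4x model width
  expect_identical(cfg$fcDims, c(128L, 64L, 32L))
  expect_identical(cfg$dilationRates, c(1L, 2L, 3L))
})

test_that("softmax outputs are normalized probabilities of the right shape", {
  cfg <- tiny_cfg()
  m <- buildModel(cfg)
  out <- methylGlove:::.nn_forward(m@params, cfg, tiny_batch(5))$probs
  expect_identical(dim(out), c(5L, 2L))
  expect_true(all(abs(rowSums(out) - 1) < 1e-6))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("concatenated convolution width is 3 x filters", {
  cfg <- tiny_cfg()
  m <- buildModel(cfg)
  expect_identical(dim(m@params[["enc1.Wq"]]), c(12L, 12L))  # 3 * 4 filters
  expect_identical(dim(m@params[["conv2.W1"]]), c(5L, 4L))
})

test_that("analytic gradients match finite differences through every block", {
  cfg <- modelConfig(inputLen = 7L, inputDim = 5L, convFilters = 4L,
                     nHeads = 2L, nEncoderLayers = 2L, ffnDim = 10L,
                     fcDims = c(6L, 5L, 4L), dropoutRate = 0, seed = 42L)
  m <- buildModel(cfg)
  X <- tiny_batch(3)
  y <- c(0L, 1L, 1L)
  w <- c(1, 2, 0.5)
  fw <- methylGlove:::.nn_forward(m@params, cfg, X, training = TRUE)
  g <- methylGlove:::.nn_backward(m@params, cfg, fw$cache, fw$probs, y, w)
  expect_setequal(names(g), names(m@params))
  lossAt <- function(p) {
    methylGlove:::.nn_loss(
      methylGlove:::.nn_forward(p, cfg, X, training = FALSE)$probs, y, w)
  }
  set.seed(77)
  eps <- 1e-5
  for (nm in names(m@params)) {
    idx <- if (length(m@params[[nm]]) <= 4) seq_along(m@params[[nm]])
           else sample(length(m@params[[nm]]), 4)
    for (i in idx) {
      up <- m@params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- m@params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(1e-6, abs(num), abs(g[[nm]][i])),
                1e-5)
    }
  }
})

test_that("positional encoding is what breaks permutation symmetry", {
  # with a position-wise front end (kernel 1) and mean pooling, the encoder
  # stack is permutation equivariant, so pooled outputs are permutation
  # invariant exactly when the positional encoding is off
  base <- list(inputLen = 7L, inputDim = 5L, convFilters = 4L, nHeads = 2L,
               ffnDim = 10L, fcDims = c(6L, 5L, 4L), dropoutRate = 0,
               kernelSize = 1L, seed = 4L)
  cfgOff <- do.call(modelConfig, c(base, list(positional = FALSE)))
  cfgOn <- do.call(modelConfig, c(base, list(positional = TRUE)))
  X <- tiny_batch(2)
  set.seed(31)
  perm <- sample(7)
  Xp <- X[, perm, , drop = FALSE]
  mOff <- buildModel(cfgOff)
  pOff <- predictProb(mOff, X)
  pOffPerm <- predictProb(mOff, Xp)
  expect_equal(pOff, pOffPerm, tolerance = 1e-10)
  mOn <- buildModel(cfgOn)
  expect_gt(max(abs(predictProb(mOn, X) - predictProb(mOn, Xp))), 1e-6)
})

test_that("forward pass stays finite on many random inputs", {
  cfg <- tiny_cfg()
  m <- buildModel(cfg)
  probs <- predictProb(m, tiny_batch(1000, seed = 55))
  expect_true(all(is.finite(probs)))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("batch prediction equals concatenated per-sample prediction", {
  cfg <- tiny_cfg()
  m <- buildModel(cfg)
  X <- tiny_batch(6)
  whole <- predictProb(m, X)
  single <- vapply(1:6, function(i) {
    predictProb(m, X[i, , , drop = FALSE])
  }, numeric(1))
  expect_equal(whole, single, tolerance = 1e-12)
})

test_that("training is deterministic per seed and rejects bad inputs", {
  cfg <- tiny_cfg(dropoutRate = 0.2)
  m <- buildModel(cfg)
  X <- tiny_batch(40)
  y <- rep(0:1, 20)
  tr <- list(x = X, y = y)
  va <- list(x = tiny_batch(12, seed = 10), y = rep(0:1, 6))
  h1 <- lossHistory(trainModel(m, tr, va, maxEpochs = 3, seed = 5))
  h2 <- lossHistory(trainModel(m, tr, va, maxEpochs = 3, seed = 5))
  expect_identical(h1, h2)
  expect_named(h1, c("epoch", "train_loss", "val_loss", "train_acc",
                     "val_acc"))

  expect_error(trainModel(m, list(x = X, y = rep(1L, 40)), va, maxEpochs = 1),
               "single class")
  expect_error(trainModel(m, list(x = tiny_batch(4, Tn = 9), y = rep(0:1, 2)),
                          va, maxEpochs = 1), "shape")
})

test_that("parameter count is independent of dataset size", {
  cfg <- tiny_cfg()
  tr1 <- list(x = tiny_batch(20), y = rep(0:1, 10))
  tr2 <- list(x = tiny_batch(40, seed = 3), y = rep(0:1, 20))
  va <- list(x = tiny_batch(8, seed = 2), y = rep(0:1, 4))
  m1 <- trainModel(buildModel(cfg), tr1, va, maxEpochs = 1, batchSize = 5)
  m2 <- trainModel(buildModel(cfg), tr2, va, maxEpochs = 1, batchSize = 16)
  expect_identical(nParams(m1), nParams(m2))
})

test_that("a small-capacity model still learns the easy planted-motif task", {
  ds <- syntheticFragments(nPos = 400, nNeg = 400, plantingProb = 1,
                           seed = 19)
  sp <- stratifiedSplit(ds, 0.25, seed = 20)
  vocab <- buildVocab(sp$train)
  emb <- fitGlove(buildCooccurrence(tokenizeFragments(sp$train, vocab)),
                  d = 30, epochs = 20, seed = 21)
  encTr <- encodeFragments(sp$train, "glove", embedding = emb)
  encVa <- encodeFragments(sp$test, "glove", embedding = emb)
  cfg <- modelConfig(inputLen = 39, inputDim = 30, convFilters = 8,
                     seed = 22)
  mdl <- trainModel(buildModel(cfg), encTr, encVa, maxEpochs = 8, lr = 3e-3,
                    earlyStopPatience = 8, seed = 23)
  auc <- rocAuc(encodedLabels(encVa), predictProb(mdl, encVa))$auc
  expect_gte(auc, 0.9)
})

test_that("checkpoints restore an identical predictor", {
  cfg <- tiny_cfg()
  tr <- list(x = tiny_batch(20), y = rep(0:1, 10))
  va <- list(x = tiny_batch(8, seed = 2), y = rep(0:1, 4))
  mdl <- trainModel(buildModel(cfg), tr, va, maxEpochs = 2, batchSize = 5)
  path <- withr::local_tempfile(fileext = ".txt")
  saveModel(mdl, path)
  back <- loadModel(path)
  X <- tiny_batch(10, seed = 33)
  expect_equal(predictProb(back, X), predictProb(mdl, X), tolerance = 1e-8)
  expect_equal(lossHistory(back)$val_loss, lossHistory(mdl)$val_loss,
               tolerance = 1e-6)
})
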