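#' Architecture configuration for the methylation classifier
#'
#' The network is three parallel 1D convolutions along the token axis with
#' same-length padding and dilation rates 1/2/3, channel concatenation,
#' additive sinusoidal positional encoding, `nEncoderLayers` Transformer
#' encoder blocks (multi-head self-attention -> Add & Norm -> position-wise
#' feed-forward -> Add & Norm), pooling over positions, and a dense head
#' 128 -> 64 -> 32 with dropout after each layer, ending in a 2-unit softmax.
#'
#' @param inputLen tokens per fragment (39 for 41-bp fragments at k = 3).
#' @param inputDim feature dimension per token (embedding d, or vocabulary
#'   size for one-hot).
#' @param convFilters filters per convolution branch; the model width after
#'   concatenation is `3 * convFilters` and must be divisible by `nHeads`.
#' @param kernelSize convolution kernel length (odd; default 3).
#' @param dilationRates dilation rate of each of the three branches.
#' @param nHeads attention heads.
#' @param nEncoderLayers encoder blocks.
#' @param ffnDim feed-forward inner width; default 4x the model width.
#' @param fcDims dense-head layer sizes (default 128, 64, 32).
#' @param dropoutRate dropout probability in the dense head.
#' @param pooling `"mean"` over positions (default) or `"flatten"`.
#' @param positional include the sinusoidal positional encoding.
#' @param seed RNG seed for weight initialization.
#' @return list of validated settings for [buildModel()].
#' @export
modelConfig <- function(inputLen = 39L, inputDim = 300L, convFilters = 64L,
                        kernelSize = 3L, dilationRates = c(1L, 2L, 3L),
                        nHeads = 4L, nEncoderLayers = 1L, ffnDim = NULL,
                        fcDims = c(128L, 64L, 32L), dropoutRate = 0.2,
                        pooling = c("mean", "flatten"), positional = TRUE,
                        seed = 1L) {
  pooling <- match.arg(pooling)
  cfg <- list(inputLen = as.integer(inputLen), inputDim = as.integer(inputDim),
              convFilters = as.integer(convFilters),
              kernelSize = as.integer(kernelSize),
              dilationRates = as.integer(dilationRates),
              nHeads = as.integer(nHeads),
              nEncoderLayers = as.integer(nEncoderLayers),
              ffnDim = if (is.null(ffnDim)) 4L * 3L * as.integer(convFilters)
                       else as.integer(ffnDim),
              fcDims = as.integer(fcDims), dropoutRate = dropoutRate,
              pooling = pooling, positional = isTRUE(positional),
              seed = as.integer(seed))
  if (length(cfg$dilationRates) != 3L) {
    stop("dilationRates must name three branch rates")
  }
  if (cfg$kernelSize %% 2L == 0L) stop("kernelSize must be odd")
  M <- 3L * cfg$convFilters
  if (M %% cfg$nHeads != 0L) {
    stop("model width ", M, " (3 * convFilters) is not divisible by nHeads = ",
         cfg$nHeads)
  }
  if (cfg$dropoutRate < 0 || cfg$dropoutRate >= 1) {
    stop("dropoutRate must lie in [0, 1)")
  }
  cfg
}

#' Build an untrained classifier
#'
#' @param config from [modelConfig()].
#' @return A [MethylModel-class] with seeded random initial weights.
#' @export
buildModel <- function(config = modelConfig()) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  new("MethylModel", params = .init_params(config), config = config,
      history = data.frame())
}

#' Number of trainable parameters
#'
#' @param model a [MethylModel-class]
#' @export
nParams <- function(model) {
  sum(vapply(model@params, length, numeric(1)))
}

.coerce_xy <- function(data, cfg, what) {
  if (is(data, "EncodedBatch")) {
    x <- data@data
    y <- data@labels
  } else if (is.list(data) && !is.null(data$x)) {
    x <- data$x
    y <- data$y
  } else {
    stop(what, " must be an EncodedBatch or list(x = array, y = labels)")
  }
  if (length(dim(x)) != 3L) stop(what, ": x must be a 3D array")
  if (dim(x)[2] != cfg$inputLen || dim(x)[3] != cfg$inputDim) {
    stop(what, ": sample shape ", dim(x)[2], " x ", dim(x)[3],
         " does not match the model's ", cfg$inputLen, " x ", cfg$inputDim)
  }
  list(x = x, y = as.integer(y))
}

#' Train the classifier
#'
#' Minimizes categorical cross-entropy on 2-class one-hot targets with Adam
#' over shuffled minibatches, recording per-epoch train/validation loss and
#' accuracy. Early stopping monitors validation loss; the weights of the
#' best epoch are restored. Reproducible for a fixed seed.
#'
#' @param model a [MethylModel-class] from [buildModel()].
#' @param train,val labeled [EncodedBatch-class]es (or `list(x =, y =)`);
#'   the training set must contain both classes.
#' @param batchSize minibatch size (default 32).
#' @param maxEpochs epoch budget (default 30).
#' @param lr Adam learning rate (default 1e-3).
#' @param earlyStopPatience epochs without validation-loss improvement
#'   before stopping (default 5; `Inf` disables).
#' @param classWeighting `"off"` (train on the natural imbalance, the
#'   default) or `"balanced"` (weights inversely proportional to class
#'   frequency).
#' @param seed RNG seed for shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return the trained [MethylModel-class]; `lossHistory()` gives the
#'   epoch/loss/accuracy table.
#' @export
trainModel <- function(model, train, val, batchSize = 32L, maxEpochs = 30L,
                       lr = 1e-3, earlyStopPatience = 5L,
                       classWeighting = c("off", "balanced"), seed = 1L,
                       verbose = FALSE) {
  stopifnot(is(model, "MethylModel"))
  classWeighting <- match.arg(classWeighting)
  cfg <- model@config
  tr <- .coerce_xy(train, cfg, "train")
  va <- .coerce_xy(val, cfg, "val")
  n <- length(tr$y)
  if (n == 0L || length(va$y) == 0L) stop("datasets must be nonempty")
  if (anyNA(tr$y) || anyNA(va$y)) stop("all samples must be labeled")
  if (length(unique(tr$y)) < 2L) {
    stop("training set contains a single class; both classes are required")
  }
  wClass <- if (classWeighting == "balanced") {
    n / (2 * c(sum(tr$y == 0L), sum(tr$y == 1L)))
  } else c(1, 1)
  wTrain <- wClass[tr$y + 1L]

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  params <- model@params
  state <- .adam_init(params)
  hist <- data.frame()
  bestLoss <- Inf; bestParams <- params; wait <- 0L
  for (ep in seq_len(maxEpochs)) {
    ord <- sample.int(n)
    epLoss <- 0; epCorrect <- 0
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      xb <- tr$x[idx, , , drop = FALSE]
      yb <- tr$y[idx]
      fw <- .nn_forward(params, cfg, xb, training = TRUE)
      lossB <- .nn_loss(fw$probs, yb, wTrain[idx])
      if (!is.finite(lossB)) {
        stop("non-finite training loss at epoch ", ep)
      }
      grads <- .nn_backward(params, cfg, fw$cache, fw$probs, yb, wTrain[idx])
      upd <- .adam_step(params, grads, state, lr)
      params <- upd$params; state <- upd$state
      epLoss <- epLoss + lossB * length(idx)
      epCorrect <- epCorrect + sum((fw$probs[, 2L] >= 0.5) == (yb == 1L))
    }
    vl <- .evaluate_pass(params, cfg, va$x, va$y,
                         wClass[va$y + 1L])
    hist <- rbind(hist, data.frame(
      epoch = ep, train_loss = epLoss / n, val_loss = vl$loss,
      train_acc = epCorrect / n, val_acc = vl$acc))
    if (verbose) {
      message(sprintf("epoch %d: train loss %.4f acc %.4f | val loss %.4f acc %.4f",
                      ep, epLoss / n, epCorrect / n, vl$loss, vl$acc))
    }
    if (!is.finite(vl$loss)) stop("non-finite validation loss at epoch ", ep)
    if (vl$loss < bestLoss - 1e-6) {
      bestLoss <- vl$loss; bestParams <- params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= earlyStopPatience) break
    }
  }
  new("MethylModel", params = bestParams, config = cfg, history = hist)
}

.evaluate_pass <- function(params, cfg, x, y, w = NULL, chunk = 512L) {
  n <- dim(x)[1]
  probs <- matrix(0, n, 2L)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    probs[idx, ] <- .nn_forward(params, cfg, x[idx, , , drop = FALSE],
                                training = FALSE)$probs
  }
  list(loss = .nn_loss(probs, y, w),
       acc = mean((probs[, 2L] >= 0.5) == (y == 1L)),
       probs = probs)
}

#' Predict positive-class probabilities
#'
#' @param model a trained [MethylModel-class].
#' @param x an [EncodedBatch-class] or samples x positions x features array
#'   matching the model's input shape.
#' @param chunk samples per forward pass.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predictProb <- function(model, x, chunk = 512L) {
  cfg <- model@config
  if (is(x, "EncodedBatch")) x <- x@data
  if (length(dim(x)) != 3L) stop("x must be a 3D array")
  if (dim(x)[2] != cfg$inputLen || dim(x)[3] != cfg$inputDim) {
    stop("sample shape ", dim(x)[2], " x ", dim(x)[3],
         " does not match the model's ", cfg$inputLen, " x ", cfg$inputDim)
  }
  n <- dim(x)[1]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx] <- .nn_forward(model@params, cfg, x[idx, , , drop = FALSE],
                            training = FALSE)$probs[, 2L]
  }
  out
}

#' Binary calls from probabilities
#'
#' Call = 1 iff probability >= threshold (a probability exactly at the
#' threshold is called positive).
#'
#' @inheritParams predictProb
#' @param threshold decision threshold in (0, 1), default 0.5.
#' @export
predictCalls <- function(model, x, threshold = 0.5, chunk = 512L) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  as.integer(predictProb(model, x, chunk = chunk) >= threshold)
}

#' Save / load a model checkpoint
#'
#' Plain-text checkpoint: a JSON header with the architecture config and the
#' training history, followed by one line per parameter tensor
#' (`name dim1,dim2 v1 v2 ...`).
#'
#' @param model a [MethylModel-class]
#' @param path file path
#' @return `saveModel`: `path` invisibly; `loadModel`: a
#'   [MethylModel-class].
#' @export
saveModel <- function(model, path) {
  header <- jsonlite::toJSON(list(config = model@config,
                                  history = model@history),
                             auto_unbox = TRUE, digits = NA)
  lines <- c(as.character(header),
             vapply(names(model@params), function(nm) {
               p <- model@params[[nm]]
               d <- if (is.matrix(p)) dim(p) else length(p)
               paste(c(nm, paste(d, collapse = ","),
                       sprintf("%.10g", as.numeric(p))), collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  cfg <- header$config
  for (nm in c("inputLen", "inputDim", "convFilters", "kernelSize",
               "dilationRates", "nHeads", "nEncoderLayers", "ffnDim",
               "fcDims", "seed")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  params <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
    nm <- parts[1]
    d <- as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    vals <- as.numeric(parts[-(1:2)])
    if (length(vals) != prod(d)) stop("corrupt checkpoint line for ", nm)
    params[[nm]] <- if (length(d) == 2L) matrix(vals, d[1], d[2]) else vals
  }
  hist <- as.data.frame(header$history)
  new("MethylModel", params = params, config = cfg, history = hist)
}
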