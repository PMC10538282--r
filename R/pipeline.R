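.default_config <- function() {
  list(
    seed = 1L,
    outDir = "methylglove_run",
    simulate = list(nPos = 2000L, nNeg = NULL, ratio = 1, delta = 20L,
                    centerBase = "C", motif = "ACGTACGT", plantingProb = 1,
                    mutationRate = 0, testFraction = 0.2),
    window = list(fasta = NULL, delta = 20L, centerBase = "C"),
    kmer = list(k = 3L),
    glove = list(d = 50L, window = 1L, tX = 100, alpha = 0.75, lr = 0.05,
                 epochs = 25L, export = "V"),
    encode = list(encoding = "glove", unknown = "error"),
    model = list(convFilters = 16L, kernelSize = 3L,
                 dilationRates = c(1L, 2L, 3L), nHeads = 4L,
                 nEncoderLayers = 1L, ffnDim = NULL,
                 fcDims = c(128L, 64L, 32L), dropoutRate = 0.2,
                 pooling = "mean", positional = TRUE),
    train = list(batchSize = 32L, maxEpochs = 15L, lr = 1e-3,
                 earlyStopPatience = 5L, classWeighting = "off",
                 threshold = 0.5),
    predict = list(input = NULL)
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Starts from the package defaults and merges the caller's overrides
#' section by section. Unknown sections or keys are rejected outright so a
#' typo cannot silently fall back to a default.
#'
#' @param ... named overrides, e.g. `seed = 7`,
#'   `simulate = list(nPos = 500, ratio = 12)`,
#'   `glove = list(d = 100)`.
#' @return nested configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(...) {
  cfg <- .default_config()
  over <- list(...)
  if (length(over) && is.null(names(over))) stop("overrides must be named")
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) stop("unknown config section/key: ", sec)
    if (is.list(cfg[[sec]])) {
      if (!is.list(over[[sec]])) stop("section '", sec, "' must be a list")
      bad <- setdiff(names(over[[sec]]), names(cfg[[sec]]))
      if (length(bad)) {
        stop("unknown key(s) in section '", sec, "': ",
             paste(bad, collapse = ", "))
      }
      cfg[[sec]][names(over[[sec]])] <- over[[sec]]
    } else {
      cfg[[sec]] <- over[[sec]]
    }
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror [pipelineConfig()]'s
#'   sections.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.stage_order <- c("simulate", "window", "embed", "encode", "train",
                  "evaluate", "predict")

#' Run the methylation-prediction pipeline
#'
#' Executes the requested stages in canonical order (simulate/window ->
#' embed -> encode -> train -> evaluate -> predict), writing each stage's
#' interface files under `outDir` together with the fully resolved config
#' (`config.yaml`) and a manifest (`manifest.json`: artifact paths, md5
#' hashes, seed). A stage whose upstream artifacts are missing fails with an
#' error naming the stage; reruns with the same config and seed reproduce
#' identical artifacts.
#'
#' @param config from [pipelineConfig()] / [readPipelineConfig()].
#' @param stages subset of simulate, window, embed, encode, train, evaluate,
#'   predict.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the manifest and (when computed) the final
#'   [MetricsReport-class].
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("simulate", "embed", "encode", "train",
                                   "evaluate"),
                        quiet = FALSE) {
  bad <- setdiff(stages, .stage_order)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .stage_order[.stage_order %in% stages]
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- character(0)
  art <- function(nm) file.path(outDir, nm)
  need <- function(nm, stage) {
    p <- art(nm)
    if (!file.exists(p)) {
      stop("stage '", stage, "' requires artifact '", nm,
           "' produced by an earlier stage")
    }
    p
  }
  report <- NULL
  for (stage in stages) {
    t0 <- Sys.time()
    switch(stage,
      simulate = {
        sc <- config$simulate
        ds <- syntheticFragments(
          nPos = sc$nPos, nNeg = sc$nNeg, ratio = sc$ratio, delta = sc$delta,
          centerBase = sc$centerBase, motif = sc$motif,
          plantingProb = sc$plantingProb, mutationRate = sc$mutationRate,
          seed = config$seed)
        sp <- stratifiedSplit(ds, testFraction = sc$testFraction,
                              seed = config$seed + 1L)
        writeFragments(sp$train, art("train.tsv"))
        writeFragments(sp$test, art("test.tsv"))
        artifacts <- c(artifacts, "train.tsv", "test.tsv")
      },
      window = {
        wc <- config$window
        if (is.null(wc$fasta)) stop("stage 'window' requires window$fasta")
        ss <- Biostrings::readDNAStringSet(wc$fasta)
        parts <- lapply(seq_along(ss), function(i) {
          extractWindows(as.character(ss[[i]]), delta = wc$delta,
                         centerBase = wc$centerBase,
                         id = sub("\\s.*$", "", names(ss)[i]))
        })
        ds <- FragmentDataset(
          seqs = unlist(lapply(parts, fragmentSeqs)),
          ids = unlist(lapply(parts, fragmentIds)),
          delta = wc$delta, provenance = paste0("window:", wc$fasta))
        writeFragments(ds, art("windows.tsv"))
        artifacts <- c(artifacts, "windows.tsv")
      },
      embed = {
        train <- readFragments(need("train.tsv", "embed"))
        vocab <- buildVocab(train, k = config$kmer$k)
        corpus <- tokenizeFragments(train, vocab)
        cooc <- buildCooccurrence(corpus, window = config$glove$window)
        emb <- fitGlove(cooc, d = config$glove$d, tX = config$glove$tX,
                        alpha = config$glove$alpha, lr = config$glove$lr,
                        epochs = config$glove$epochs,
                        seed = config$seed + 2L,
                        export = config$glove$export)
        saveVocab(vocab, art("vocab.txt"))
        saveEmbedding(emb, art("embedding.txt"))
        artifacts <- c(artifacts, "vocab.txt", "embedding.txt")
      },
      encode = {
        ec <- config$encode
        train <- readFragments(need("train.tsv", "encode"))
        test <- readFragments(need("test.tsv", "encode"))
        if (ec$encoding == "glove") {
          emb <- loadEmbedding(need("embedding.txt", "encode"))
          encTrain <- encodeFragments(train, "glove", embedding = emb,
                                      unknown = ec$unknown)
          encTest <- encodeFragments(test, "glove", embedding = emb,
                                     unknown = ec$unknown)
        } else {
          vocab <- loadVocab(need("vocab.txt", "encode"))
          encTrain <- encodeFragments(train, "onehot", vocab = vocab)
          encTest <- encodeFragments(test, "onehot", vocab = vocab)
        }
        saveRDS(encTrain, art("encoded_train.rds"))
        saveRDS(encTest, art("encoded_test.rds"))
        artifacts <- c(artifacts, "encoded_train.rds", "encoded_test.rds")
      },
      train = {
        encTrain <- readRDS(need("encoded_train.rds", "train"))
        encTest <- readRDS(need("encoded_test.rds", "train"))
        mc <- config$model
        d <- dim(encTrain@data)
        cfg <- modelConfig(inputLen = d[2], inputDim = d[3],
                           convFilters = mc$convFilters,
                           kernelSize = mc$kernelSize,
                           dilationRates = mc$dilationRates,
                           nHeads = mc$nHeads,
                           nEncoderLayers = mc$nEncoderLayers,
                           ffnDim = mc$ffnDim, fcDims = mc$fcDims,
                           dropoutRate = mc$dropoutRate,
                           pooling = mc$pooling, positional = mc$positional,
                           seed = config$seed + 3L)
        tc <- config$train
        model <- trainModel(buildModel(cfg), encTrain, encTest,
                            batchSize = tc$batchSize,
                            maxEpochs = tc$maxEpochs, lr = tc$lr,
                            earlyStopPatience = tc$earlyStopPatience,
                            classWeighting = tc$classWeighting,
                            seed = config$seed + 4L, verbose = !quiet)
        saveModel(model, art("model.txt"))
        utils::write.csv(lossHistory(model), art("history.csv"),
                         row.names = FALSE)
        artifacts <- c(artifacts, "model.txt", "history.csv")
      },
      evaluate = {
        model <- loadModel(need("model.txt", "evaluate"))
        encTest <- readRDS(need("encoded_test.rds", "evaluate"))
        probs <- predictProb(model, encTest)
        test <- readFragments(need("test.tsv", "evaluate"))
        writePredictions(test, probs, path = art("predictions.tsv"),
                         threshold = config$train$threshold)
        report <- evaluatePredictions(encTest@labels, probs,
                                      threshold = config$train$threshold)
        writeMetrics(report, art("metrics.json"))
        roc <- rocAuc(encTest@labels, probs)$roc
        utils::write.csv(roc, art("roc.csv"), row.names = FALSE)
        artifacts <- c(artifacts, "predictions.tsv", "metrics.json", "roc.csv")
      },
      predict = {
        model <- loadModel(need("model.txt", "predict"))
        input <- config$predict$input
        if (is.null(input)) input <- need("windows.tsv", "predict")
        ds <- readFragments(input)
        emb <- loadEmbedding(need("embedding.txt", "predict"))
        enc <- encodeFragments(ds, "glove", embedding = emb,
                               unknown = config$encode$unknown)
        probs <- predictProb(model, enc)
        writePredictions(ds, probs, path = art("new_predictions.tsv"),
                         threshold = config$train$threshold)
        artifacts <- c(artifacts, "new_predictions.tsv")
      }
    )
    say("stage %-8s done in %.1f s", stage,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  manifest <- list(
    seed = config$seed,
    stages = stages,
    artifacts = lapply(setNames(nm = unique(artifacts)), function(nm) {
      list(path = art(nm), md5 = unname(tools::md5sum(art(nm))))
    })
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, metrics = report))
}
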