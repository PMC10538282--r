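#' Construct a FragmentDataset
#'
#' @param ids character vector of unique record identifiers; generated as
#'   `frag_1..frag_n` when `NULL`.
#' @param seqs character vector of DNA fragments, all of length `2*delta+1`.
#' @param labels integer/numeric vector of 0/1 labels, or `NA`; recycled from
#'   `NA` when omitted.
#' @param delta flank length; fragment length is `2*delta+1`.
#' @param provenance free-text tag recording where the records came from.
#' @return A [FragmentDataset-class].
#' @examples
#' fd <- FragmentDataset(seqs = paste0(strrep("A", 20), "C", strrep("G", 20)),
#'                       delta = 20)
#' length(fd)
#' @export
FragmentDataset <- function(seqs, ids = NULL, labels = NULL, delta = 20L,
                            provenance = "user") {
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  if (is.null(ids)) ids <- if (n) paste0("frag_", seq_len(n)) else character(0)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  labels <- suppressWarnings(as.integer(labels))
  new("FragmentDataset", ids = as.character(ids), seqs = seqs,
      labels = labels, delta = as.integer(delta),
      provenance = as.character(provenance))
}

#' @describeIn FragmentDataset number of records
#' @param x a FragmentDataset
#' @export
setMethod("length", "FragmentDataset", function(x) length(x@ids))

#' Accessors for FragmentDataset
#'
#' `fragmentIds`, `fragmentSeqs` and `fragmentLabels` return the per-record
#' fields; `flankLength` returns delta (so fragments have `2*delta+1` bases).
#'
#' @param x a [FragmentDataset-class]
#' @return character, character, integer and integer vectors respectively.
#' @name fragment-accessors
NULL

#' @rdname fragment-accessors
#' @export
fragmentIds <- function(x) x@ids

#' @rdname fragment-accessors
#' @export
fragmentSeqs <- function(x) x@seqs

#' @rdname fragment-accessors
#' @export
fragmentLabels <- function(x) x@labels

#' @rdname fragment-accessors
#' @export
flankLength <- function(x) x@delta

#' @export
setMethod("[", "FragmentDataset", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("FragmentDataset", ids = x@ids[i], seqs = x@seqs[i],
      labels = x@labels[i], delta = x@delta, provenance = x@provenance)
})

setMethod("show", "FragmentDataset", function(object) {
  n <- length(object@ids)
  nl <- sum(!is.na(object@labels))
  cat(sprintf("FragmentDataset: %d fragment%s of %d bp (delta = %d)\n",
              n, if (n == 1) "" else "s", 2L * object@delta + 1L, object@delta))
  if (nl) {
    cat(sprintf("  labels: %d positive / %d negative (%d unlabeled)\n",
                sum(object@labels == 1L, na.rm = TRUE),
                sum(object@labels == 0L, na.rm = TRUE), n - nl))
  }
  cat(sprintf("  provenance: %s\n", object@provenance))
  if (n) cat(sprintf("  first: %s  %s\n", object@ids[1], object@seqs[1]))
})

#' Accessors for KmerVocabulary
#'
#' @param x a [KmerVocabulary-class]
#' @return `vocabTokens` gives the ordered token vector, `vocabSize` its
#'   length and `kmerLength` the token length k.
#' @name vocab-accessors
NULL

#' @rdname vocab-accessors
#' @export
vocabTokens <- function(x) x@tokens

#' @rdname vocab-accessors
#' @export
vocabSize <- function(x) length(x@tokens)

#' @rdname vocab-accessors
#' @export
kmerLength <- function(x) x@k

setMethod("show", "KmerVocabulary", function(object) {
  cat(sprintf("KmerVocabulary: %d of %d possible %d-mers\n",
              length(object@tokens), 4^object@k, object@k))
})

setMethod("show", "TokenizedCorpus", function(object) {
  cat(sprintf("TokenizedCorpus: %d documents over %d tokens (k = %d)\n",
              length(object@docs), length(object@vocab@tokens), object@vocab@k))
})

#' Accessors for CooccurrenceMatrix
#'
#' @param x a [CooccurrenceMatrix-class]
#' @return `coocMatrix` returns the symmetric count matrix with token
#'   dimnames; `coocVocab` the underlying vocabulary.
#' @name cooc-accessors
NULL

#' @rdname cooc-accessors
#' @export
coocMatrix <- function(x) {
  m <- x@X
  dimnames(m) <- list(x@vocab@tokens, x@vocab@tokens)
  m
}

#' @rdname cooc-accessors
#' @export
coocVocab <- function(x) x@vocab

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf("CooccurrenceMatrix: %d x %d, window = %d, %d nonzero entries\n",
              nrow(object@X), ncol(object@X), object@window,
              sum(object@X > 0)))
})

#' Exported embedding matrix of a GloVe fit
#'
#' Returns the per-token vectors used for downstream encoding: the main word
#' vectors V by default, or V + V-tilde when the fit was configured with
#' `export = "sum"`.
#'
#' @param x a [GloveEmbedding-class]
#' @return numeric matrix, one row per token (rownames = tokens).
#' @export
embeddingMatrix <- function(x) {
  m <- if (identical(x@config$export, "sum")) x@V + x@Vtilde else x@V
  if (isTRUE(x@config$center)) m <- m - rep(colMeans(m), each = nrow(m))
  rownames(m) <- x@tokens
  m
}

#' @rdname embeddingMatrix
#' @export
embeddingDim <- function(x) x@d

#' @rdname embeddingMatrix
#' @export
embeddingTokens <- function(x) x@tokens

#' Loss trajectory of a fit
#'
#' For a [GloveEmbedding-class]: numeric vector of the full objective J after
#' each epoch. For a [MethylModel-class]: data.frame with columns epoch,
#' train_loss, val_loss, train_acc, val_acc.
#'
#' @param x a fitted object
#' @export
lossHistory <- function(x) x@history

setMethod("show", "GloveEmbedding", function(object) {
  cat(sprintf("GloveEmbedding: %d tokens x %d dims (%d epochs, final J = %.4g)\n",
              length(object@tokens), object@d,
              length(object@history),
              if (length(object@history)) tail(object@history, 1) else NA_real_))
})

setMethod("show", "EncodedBatch", function(object) {
  d <- dim(object@data)
  cat(sprintf("EncodedBatch (%s): %d samples x %d positions x %d features\n",
              object@encoding, d[1], d[2], d[3]))
})

#' @rdname encodeFragments
#' @export
encodedTensor <- function(x) x@data

#' @rdname encodeFragments
#' @export
encodedLabels <- function(x) x@labels

#' @rdname encodeFragments
#' @export
encodedIds <- function(x) x@ids

setMethod("show", "MethylModel", function(object) {
  np <- sum(vapply(object@params, length, numeric(1)))
  cfg <- object@config
  cat(sprintf(paste0(
    "MethylModel: %d params | conv %d filters x dil (%s) | width %d | ",
    "%d head(s) x %d layer(s) | fc (%s)\n"),
    np, cfg$convFilters, paste(cfg$dilationRates, collapse = ","),
    3L * cfg$convFilters, cfg$nHeads, cfg$nEncoderLayers,
    paste(cfg$fcDims, collapse = ",")))
  if (nrow(object@history)) {
    cat(sprintf("  trained %d epochs; final val loss %.4f, val acc %.4f\n",
                nrow(object@history),
                tail(object@history$val_loss, 1),
                tail(object@history$val_acc, 1)))
  }
})

#' Convert a MetricsReport to a named list
#'
#' @param x a [MetricsReport-class]
#' @return list with keys tp, tn, fp, fn, sen, spe, acc, mcc, auc.
#' @export
metricsAsList <- function(x) {
  list(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn,
       sen = x@sen, spe = x@spe, acc = x@acc, mcc = x@mcc, auc = x@auc)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: TP=%d TN=%d FP=%d FN=%d\n",
              object@tp, object@tn, object@fp, object@fn))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("  Sen=%s Spe=%s Acc=%s Mcc=%s Auc=%s\n",
              fmt(object@sen), fmt(object@spe), fmt(object@acc),
              fmt(object@mcc), fmt(object@auc)))
  if (length(object@undefined)) {
    cat("  undefined (zero denominator): ",
        paste(object@undefined, collapse = ", "), "\n")
  }
})
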