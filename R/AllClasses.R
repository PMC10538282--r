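#' @import methods
#' @importFrom stats runif rnorm setNames
#' @importFrom utils head tail read.delim write.table
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' FragmentDataset: fixed-length DNA fragments with optional binary labels
#'
#' An ordered collection of DNA fragments of identical length \eqn{2\delta+1},
#' each centered on a candidate modification site (the cytosine for 5mC).
#' Labels, when present, are 1 for a methylated (positive) site and 0 for an
#' unmethylated one; `NA` marks unlabeled records awaiting prediction.
#'
#' @slot ids character, unique record identifiers.
#' @slot seqs character, fragment sequences over \{A,C,G,T\}.
#' @slot labels integer, 0/1 or `NA` per record.
#' @slot delta integer(1), flank length on each side of the center.
#' @slot provenance character(1), free-text origin tag.
#'
#' @export
setClass("FragmentDataset",
  representation(
    ids = "character",
    seqs = "character",
    labels = "integer",
    delta = "integer",
    provenance = "character"
  )
)

setValidity("FragmentDataset", function(object) {
  msgs <- character(0)
  n <- length(object@ids)
  if (length(object@seqs) != n || length(object@labels) != n) {
    msgs <- c(msgs, "ids, seqs and labels must have equal length")
  }
  if (length(object@delta) != 1L || is.na(object@delta) || object@delta < 1L) {
    msgs <- c(msgs, "delta must be a single positive integer")
  }
  if (anyDuplicated(object@ids)) {
    dup <- unique(object@ids[duplicated(object@ids)])
    msgs <- c(msgs, paste0("duplicate record ids: ",
                           paste(head(dup, 5L), collapse = ", ")))
  }
  if (n > 0 && length(object@delta) == 1L && !is.na(object@delta)) {
    want <- 2L * object@delta + 1L
    bad <- which(nchar(object@seqs) != want)
    if (length(bad)) {
      msgs <- c(msgs, paste0("records not of length 2*delta+1 = ", want, ": ",
                             paste(head(object@ids[bad], 5L), collapse = ", ")))
    }
    badchr <- which(!grepl("^[ACGT]*$", object@seqs))
    if (length(badchr)) {
      msgs <- c(msgs, paste0("records with characters outside {A,C,G,T}: ",
                             paste(head(object@ids[badchr], 5L), collapse = ", ")))
    }
  }
  badlab <- which(!(is.na(object@labels) | object@labels %in% c(0L, 1L)))
  if (length(badlab)) {
    msgs <- c(msgs, paste0("labels must be 0, 1 or NA; offending ids: ",
                           paste(head(object@ids[badlab], 5L), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' KmerVocabulary: ordered set of distinct k-mer tokens
#'
#' @slot k integer(1), token length (>= 3 so every base has left and right
#'   context within some token).
#' @slot tokens character, distinct length-k strings in first-occurrence
#'   order; a token's vocabulary index is its position in this vector.
#'
#' @export
setClass("KmerVocabulary",
  representation(k = "integer", tokens = "character")
)

setValidity("KmerVocabulary", function(object) {
  msgs <- character(0)
  if (length(object@k) != 1L || object@k < 3L) {
    msgs <- c(msgs, "k must be a single integer >= 3")
  }
  if (anyDuplicated(object@tokens)) msgs <- c(msgs, "tokens must be distinct")
  if (length(object@tokens) > 4^object@k) {
    msgs <- c(msgs, "more tokens than 4^k possible k-mers")
  }
  if (length(object@tokens) &&
      any(nchar(object@tokens) != object@k)) {
    msgs <- c(msgs, "all tokens must have length k")
  }
  if (length(msgs)) msgs else TRUE
})

#' TokenizedCorpus: fragments as sequences of vocabulary token ids
#'
#' @slot docs list of integer vectors; each vector holds the 1-based
#'   vocabulary indices of one fragment's overlapping k-mers in 5'->3' order.
#' @slot ids character, one id per document.
#' @slot vocab the [KmerVocabulary-class] the indices refer to.
#'
#' @export
setClass("TokenizedCorpus",
  representation(docs = "list", ids = "character", vocab = "KmerVocabulary")
)

setValidity("TokenizedCorpus", function(object) {
  msgs <- character(0)
  if (length(object@docs) != length(object@ids)) {
    msgs <- c(msgs, "docs and ids must have equal length")
  }
  nv <- length(object@vocab@tokens)
  ok <- vapply(object@docs, function(d) {
    is.integer(d) && !anyNA(d) && all(d >= 1L) && all(d <= nv)
  }, logical(1))
  if (!all(ok)) msgs <- c(msgs, "documents must contain valid vocabulary indices")
  if (length(msgs)) msgs else TRUE
})

#' CooccurrenceMatrix: global k-mer co-occurrence counts
#'
#' Symmetric nonnegative matrix over the vocabulary; entry \eqn{X_{ij}} counts
#' how often token j occurs within the context window of token i across the
#' corpus (directed in-window counts mirrored onto both triangles).
#'
#' @slot X square numeric matrix, side = vocabulary size.
#' @slot vocab the [KmerVocabulary-class] indexing the rows/columns.
#' @slot window integer(1), context window width in tokens.
#'
#' @export
setClass("CooccurrenceMatrix",
  representation(X = "matrix", vocab = "KmerVocabulary", window = "integer")
)

setValidity("CooccurrenceMatrix", function(object) {
  msgs <- character(0)
  n <- length(object@vocab@tokens)
  if (!all(dim(object@X) == c(n, n))) {
    msgs <- c(msgs, "X must be square with side = vocabulary size")
  }
  if (any(object@X < 0)) msgs <- c(msgs, "co-occurrence counts must be >= 0")
  if (nrow(object@X) && !isTRUE(all.equal(object@X, t(object@X)))) {
    msgs <- c(msgs, "X must be symmetric")
  }
  if (length(object@window) != 1L || object@window < 1L) {
    msgs <- c(msgs, "window must be a single positive integer")
  }
  if (length(msgs)) msgs else TRUE
})

#' GloveEmbedding: fitted GloVe word vectors over a k-mer vocabulary
#'
#' Holds the main word vectors V, the separate context vectors V-tilde, both
#' bias vectors, and the per-epoch loss trajectory of the fit. The exported
#' per-token embedding (used for sequence encoding) is V by default.
#'
#' @slot V numeric matrix N x d, main word vectors.
#' @slot Vtilde numeric matrix N x d, context vectors.
#' @slot b numeric(N), main biases.
#' @slot btilde numeric(N), context biases.
#' @slot tokens character(N), tokens in vocabulary order.
#' @slot d integer(1), embedding dimension.
#' @slot history numeric, full-objective value after each epoch.
#' @slot config list, fit configuration (tX, alpha, lr, epochs, seed, export).
#'
#' @export
setClass("GloveEmbedding",
  representation(
    V = "matrix", Vtilde = "matrix", b = "numeric", btilde = "numeric",
    tokens = "character", d = "integer", history = "numeric", config = "list"
  )
)

setValidity("GloveEmbedding", function(object) {
  msgs <- character(0)
  n <- length(object@tokens)
  d <- object@d
  if (!all(dim(object@V) == c(n, d)) || !all(dim(object@Vtilde) == c(n, d))) {
    msgs <- c(msgs, "V and Vtilde must be N x d")
  }
  if (length(object@b) != n || length(object@btilde) != n) {
    msgs <- c(msgs, "biases must have length N")
  }
  if (!all(is.finite(object@V)) || !all(is.finite(object@Vtilde)) ||
      !all(is.finite(object@b)) || !all(is.finite(object@btilde))) {
    msgs <- c(msgs, "all parameters must be finite")
  }
  if (d < 1L) msgs <- c(msgs, "d must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' EncodedBatch: numeric tensor for a batch of encoded fragments
#'
#' @slot data numeric 3D array, samples x tokens-per-fragment x feature dim
#'   (39 x 300 per sample at the 41-bp / k=3 / d=300 defaults).
#' @slot ids character, one per sample.
#' @slot labels integer 0/1/NA, one per sample.
#' @slot encoding character(1), "glove" or "onehot".
#'
#' @export
setClass("EncodedBatch",
  representation(
    data = "array", ids = "character", labels = "integer", encoding = "character"
  )
)

setValidity("EncodedBatch", function(object) {
  msgs <- character(0)
  if (length(dim(object@data)) != 3L) {
    msgs <- c(msgs, "data must be a 3D array (samples x positions x features)")
  } else if (dim(object@data)[1] != length(object@ids) ||
             dim(object@data)[1] != length(object@labels)) {
    msgs <- c(msgs, "first array dimension must match ids/labels length")
  }
  if (!object@encoding %in% c("glove", "onehot")) {
    msgs <- c(msgs, "encoding must be 'glove' or 'onehot'")
  }
  if (length(msgs)) msgs else TRUE
})

#' MethylModel: the dilated-convolution + Transformer-encoder classifier
#'
#' @slot params named list of numeric arrays (all trainable weights).
#' @slot config list, architecture configuration (see [modelConfig()]).
#' @slot history data.frame, per-epoch train/val loss and accuracy (empty
#'   before training).
#'
#' @export
setClass("MethylModel",
  representation(params = "list", config = "list", history = "data.frame")
)

#' MetricsReport: confusion counts and derived classification metrics
#'
#' Metrics with a zero denominator are reported as `NA` and listed in the
#' `undefined` slot rather than silently coerced to 0 — with strong class
#' imbalance an empty predicted-positive set is a real possibility.
#'
#' @slot tp,tn,fp,fn integer(1) confusion counts.
#' @slot sen,spe,acc,mcc,auc numeric(1), `NA` when undefined/not computed.
#' @slot undefined character, names of metrics with zero denominators.
#'
#' @export
setClass("MetricsReport",
  representation(
    tp = "integer", tn = "integer", fp = "integer", fn = "integer",
    sen = "numeric", spe = "numeric", acc = "numeric", mcc = "numeric",
    auc = "numeric", undefined = "character"
  )
)

setValidity("MetricsReport", function(object) {
  msgs <- character(0)
  cnt <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(cnt < 0L)) msgs <- c(msgs, "confusion counts must be nonnegative")
  if (sum(cnt) < 1L) msgs <- c(msgs, "at least one sample required")
  if (!is.na(object@mcc) && abs(object@mcc) > 1 + 1e-12) {
    msgs <- c(msgs, "mcc must lie in [-1, 1]")
  }
  for (nm in c("sen", "spe", "acc", "auc")) {
    v <- slot(object, nm)
    if (!is.na(v) && (v < -1e-12 || v > 1 + 1e-12)) {
      msgs <- c(msgs, paste0(nm, " must lie in [0, 1]"))
    }
  }
  if (length(msgs)) msgs else TRUE
})
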