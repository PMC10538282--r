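#' Encode one tokenized fragment with GloVe vectors
#'
#' Row t of the result is the embedding vector of token t, order preserved,
#' giving an `(L - k + 1) x d` matrix (39 x 300 at the 41-bp / k = 3 /
#' d = 300 defaults).
#'
#' @param tokens character vector of k-mers (from [tokenize()]).
#' @param embedding a [GloveEmbedding-class].
#' @param unknown policy for tokens absent from the embedding: `"error"`
#'   (default — silent substitution would corrupt evaluation) or `"zero"`,
#'   which maps them to the zero vector and reports the count in a message.
#' @return numeric matrix, `length(tokens)` x `embeddingDim(embedding)`.
#' @export
encodeGlove <- function(tokens, embedding, unknown = c("error", "zero")) {
  unknown <- match.arg(unknown)
  m <- embeddingMatrix(embedding)
  idx <- match(tokens, rownames(m))
  if (anyNA(idx)) {
    missing <- unique(tokens[is.na(idx)])
    if (unknown == "error") {
      stop("token(s) absent from embedding: ",
           paste(head(missing, 5L), collapse = ", "))
    }
    message(sum(is.na(idx)), " unknown token(s) mapped to the zero vector")
  }
  out <- matrix(0, length(tokens), ncol(m))
  ok <- !is.na(idx)
  out[ok, ] <- m[idx[ok], , drop = FALSE]
  out
}

#' Encode one tokenized fragment as k-mer one-hot indicators
#'
#' Row t is the unit basis vector of token t's vocabulary index, so the
#' shape is `(L - k + 1) x |vocab|` (39 x 64 over the full 3-mer
#' vocabulary). One-hot here is defined at the k-mer level, not the base
#' level, so both encodings feed the downstream model the same sequence
#' length and differ only in feature dimension.
#'
#' @param tokens character vector of k-mers.
#' @param vocab a [KmerVocabulary-class] covering all tokens.
#' @return numeric 0/1 matrix with one 1 per row.
#' @export
encodeOnehot <- function(tokens, vocab) {
  idx <- match(tokens, vocab@tokens)
  if (anyNA(idx)) {
    stop("token(s) absent from vocabulary: ",
         paste(unique(tokens[is.na(idx)]), collapse = ", "))
  }
  out <- matrix(0, length(tokens), length(vocab@tokens))
  out[cbind(seq_along(tokens), idx)] <- 1
  out
}

#' Encode a whole FragmentDataset into a batch tensor
#'
#' Applies [encodeGlove()] or [encodeOnehot()] to every record, preserving
#' record order and count, and stacks the per-fragment matrices into a
#' samples x positions x features array ready for the classifier.
#'
#' @param x a [FragmentDataset-class].
#' @param encoding `"glove"` or `"onehot"`.
#' @param embedding a [GloveEmbedding-class] (required for glove).
#' @param vocab a [KmerVocabulary-class] (required for onehot).
#' @param k token length (must match the embedding/vocab).
#' @param unknown unknown-token policy, see [encodeGlove()].
#' @return An [EncodedBatch-class].
#' @export
encodeFragments <- function(x, encoding = c("glove", "onehot"),
                            embedding = NULL, vocab = NULL, k = 3L,
                            unknown = "error") {
  stopifnot(is(x, "FragmentDataset"))
  encoding <- match.arg(encoding)
  n <- length(x@ids)
  if (encoding == "glove") {
    if (is.null(embedding)) stop("glove encoding requires an embedding")
    featdim <- embedding@d
    if (length(embedding@tokens)) k <- nchar(embedding@tokens[1])
  } else {
    if (is.null(vocab)) stop("onehot encoding requires a vocabulary")
    featdim <- length(vocab@tokens)
    k <- vocab@k
  }
  tlen <- 2L * x@delta + 1L - as.integer(k) + 1L
  data <- array(0, dim = c(n, tlen, featdim))
  for (s in seq_len(n)) {
    toks <- tokenize(x@seqs[s], k = k)
    data[s, , ] <- if (encoding == "glove") {
      encodeGlove(toks, embedding, unknown = unknown)
    } else {
      encodeOnehot(toks, vocab)
    }
  }
  new("EncodedBatch", data = data, ids = x@ids, labels = x@labels,
      encoding = encoding)
}
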