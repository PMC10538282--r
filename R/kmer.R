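#' Tokenize a DNA string into overlapping k-mers
#'
#' A k-bp window slides over the sequence with stride 1, producing the
#' `L - k + 1` overlapping substrings in 5'->3' order; a 41-bp fragment gives
#' 39 tokens at k = 3. k must be at least 3 so that every interior base is
#' seen together with both its neighbors in some token.
#'
#' @param seq a single DNA string.
#' @param k token length (3, 5 or 7 are the usual choices; default 3).
#' @return character vector of `nchar(seq) - k + 1` tokens.
#' @examples
#' tokenize("ATCGT", 3)  # "ATC" "TCG" "CGT"
#' @export
tokenize <- function(seq, k = 3L) {
  stopifnot(length(seq) == 1L)
  k <- as.integer(k)
  if (k < 3L) stop("k must be >= 3 (each base needs left and right context)")
  L <- nchar(seq)
  if (L < k) stop("sequence of length ", L, " is shorter than k = ", k)
  substring(seq, seq_len(L - k + 1L), seq.int(k, L))
}

#' Build a k-mer vocabulary from a fragment corpus
#'
#' Tokens enter the vocabulary in first-occurrence order over the corpus
#' (records in order, positions 5'->3' within each record), so the result is
#' deterministic for a fixed corpus order. Only observed k-mers are included,
#' not the full 4^k set; unseen tokens at encoding time are handled by
#' [encodeGlove()]'s `unknown` policy.
#'
#' @param x a [FragmentDataset-class] or character vector of sequences.
#' @param k token length.
#' @return A [KmerVocabulary-class].
#' @export
buildVocab <- function(x, k = 3L) {
  seqs <- if (is(x, "FragmentDataset")) x@seqs else as.character(x)
  if (!length(seqs)) stop("cannot build a vocabulary from an empty corpus")
  toks <- unlist(lapply(seqs, tokenize, k = k), use.names = FALSE)
  new("KmerVocabulary", k = as.integer(k), tokens = unique(toks))
}

#' Enumerate the complete vocabulary of all 4^k k-mers
#'
#' Lexicographic A < C < G < T order. Useful for one-hot encoding with a
#' fixed 64-column layout at k = 3.
#'
#' @param k token length.
#' @return A [KmerVocabulary-class] of size `4^k`.
#' @export
fullVocab <- function(k = 3L) {
  k <- as.integer(k)
  if (k < 3L) stop("k must be >= 3")
  toks <- do.call(paste0, expand.grid(rep(list(VALID_BASES), k),
                                      stringsAsFactors = FALSE)[, k:1])
  new("KmerVocabulary", k = k, tokens = sort(toks))
}

#' Tokenize every fragment of a dataset against a vocabulary
#'
#' @param x a [FragmentDataset-class].
#' @param vocab a [KmerVocabulary-class]; built from `x` itself when `NULL`.
#' @param k token length, used only when `vocab` is `NULL`.
#' @return A [TokenizedCorpus-class]; every document from a length-L fragment
#'   has exactly `L - k + 1` token ids.
#' @export
tokenizeFragments <- function(x, vocab = NULL, k = 3L) {
  stopifnot(is(x, "FragmentDataset"))
  if (is.null(vocab)) vocab <- buildVocab(x, k = k)
  docs <- lapply(x@seqs, function(s) {
    toks <- tokenize(s, k = vocab@k)
    idx <- match(toks, vocab@tokens)
    if (anyNA(idx)) {
      stop("tokens absent from vocabulary: ",
           paste(unique(toks[is.na(idx)]), collapse = ", "))
    }
    idx
  })
  new("TokenizedCorpus", docs = docs, ids = x@ids, vocab = vocab)
}

#' Write / read a vocabulary as one token per line
#'
#' Line number = vocabulary index.
#'
#' @param x a [KmerVocabulary-class]
#' @param path file path
#' @return `saveVocab`: `path` invisibly; `loadVocab`: a
#'   [KmerVocabulary-class].
#' @export
saveVocab <- function(x, path) {
  writeLines(x@tokens, path)
  invisible(path)
}

#' @rdname saveVocab
#' @export
loadVocab <- function(path) {
  toks <- readLines(path)
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty vocabulary file: ", path)
  new("KmerVocabulary", k = nchar(toks[1]), tokens = toks)
}
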