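# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (exhaustive scans, O(n^2) counting, finite
# differences) and never call the code paths they check.

# exhaustive position-by-position window scan
oracle_windows <- function(seq, delta, center) {
  chars <- strsplit(seq, "")[[1]]
  out <- character(0)
  for (p in seq_along(chars)) {
    if (chars[p] != center) next
    if (p - delta < 1 || p + delta > length(chars)) next
    w <- paste(chars[(p - delta):(p + delta)], collapse = "")
    if (!grepl("N", w, fixed = TRUE)) out <- c(out, w)
  }
  out
}

# exhaustive enumeration of all ordered in-window token pairs
oracle_cooccurrence <- function(docs, nTokens, window) {
  D <- matrix(0, nTokens, nTokens)
  for (doc in docs) {
    for (p in seq_along(doc)) {
      for (s in seq_len(window)) {
        q <- p + s
        if (q <= length(doc)) D[doc[p], doc[q]] <- D[doc[p], doc[q]] + 1
      }
    }
  }
  D + t(D)
}

# O(n^2) concordant-pair AUC with half credit for ties
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct scalar evaluation of the confusion-matrix formulas
oracle_metrics <- function(tp, tn, fp, fn) {
  list(
    sen = tp / (tp + fn),
    spe = tn / (tn + fp),
    acc = (tp + tn) / (tp + tn + fp + fn),
    mcc = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a corpus of synthetic token-id documents over an artificial vocabulary
random_token_corpus <- function(nDocs, docLen, nTokens, k = 3L) {
  toks <- vocabTokens(fullVocab(k))[seq_len(nTokens)]
  vocab <- new("KmerVocabulary", k = k, tokens = toks)
  docs <- lapply(seq_len(nDocs), function(i) {
    sample.int(nTokens, docLen, replace = TRUE)
  })
  new("TokenizedCorpus", docs = docs, ids = paste0("doc", seq_len(nDocs)),
      vocab = vocab)
}

# random GloVe parameter set for gradient checks
random_glove_params <- function(n, d) {
  list(V = matrix(rnorm(n * d, sd = 0.3), n, d),
       Vtilde = matrix(rnorm(n * d, sd = 0.3), n, d),
       b = rnorm(n, sd = 0.3), btilde = rnorm(n, sd = 0.3))
}

# central finite differences of f over every coordinate of a params list
finite_diff <- function(f, params, eps = 1e-6) {
  lapply(setNames(nm = names(params)), function(blk) {
    g <- params[[blk]] * 0
    for (i in seq_along(params[[blk]])) {
      up <- params; up[[blk]][i] <- up[[blk]][i] + eps
      dn <- params; dn[[blk]][i] <- dn[[blk]][i] - eps
      g[i] <- (f(up) - f(dn)) / (2 * eps)
    }
    g
  })
}

# small trained-free embedding with known vectors, for encode tests
fixed_embedding <- function(tokens, d, seed = 1) {
  set.seed(seed)
  new("GloveEmbedding",
      V = matrix(rnorm(length(tokens) * d), length(tokens), d),
      Vtilde = matrix(0, length(tokens), d),
      b = numeric(length(tokens)), btilde = numeric(length(tokens)),
      tokens = tokens, d = as.integer(d), history = numeric(0),
      config = list(export = "V", center = FALSE))
}
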