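#' Generate labeled synthetic fragments with a planted motif signal
#'
#' Emulates the structure of a real 5mC fragment set: fixed-length
#' `2*delta+1` bp records with the candidate base at the center and a
#' configurable negative:positive ratio. Background bases are drawn i.i.d.
#' from `baseComposition`; each positive additionally carries the `motif`
#' planted at a uniformly drawn allowed offset with probability
#' `plantingProb` (optionally corrupted base-by-base at `mutationRate`),
#' while negatives are pure background. The center base is forced back to
#' `centerBase` after planting, so every record honors the center contract.
#' Deterministic for a fixed seed.
#'
#' @param nPos number of positive (label 1) fragments.
#' @param nNeg number of negatives; computed as `round(nPos * ratio)` when
#'   `ratio` is given instead (1:10 / 1:12 / 1:15 are the usual imbalance
#'   presets, 1:12 being the common benchmark ratio).
#' @param ratio negatives per positive; ignored when `nNeg` is given.
#' @param delta flank length (default 20: 41-bp fragments).
#' @param centerBase base at index delta (0-based), `"C"` for 5mC.
#' @param motif planted positive-class motif (default the 8-mer
#'   "ACGTACGT").
#' @param motifOffsets allowed 0-based start positions of the motif within
#'   the fragment. Default: every position where the motif fits without
#'   covering the center, so the planted signal is never clipped by the
#'   center-base restore.
#' @param plantingProb probability a positive actually receives the motif
#'   (1 = every positive; 0 makes the classes exchangeable, a useful null).
#' @param mutationRate per-base probability that a planted motif base is
#'   substituted by a random different base (0 = exact motif).
#' @param baseComposition background probabilities for A, C, G, T.
#' @param seed RNG seed.
#' @return A [FragmentDataset-class] with positives first
#'   (`pos_1..pos_nPos`, then `neg_1..neg_nNeg`).
#' @export
syntheticFragments <- function(nPos, nNeg = NULL, ratio = NULL, delta = 20L,
                               centerBase = "C", motif = "ACGTACGT",
                               motifOffsets = NULL, plantingProb = 1,
                               mutationRate = 0,
                               baseComposition = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25),
                               seed = 1L) {
  stopifnot(nPos >= 1)
  if (is.null(nNeg)) {
    if (is.null(ratio)) stop("give either nNeg or ratio")
    nNeg <- round(nPos * ratio)
  }
  delta <- as.integer(delta)
  L <- 2L * delta + 1L
  centerBase <- toupper(centerBase)
  motif <- toupper(motif)
  mlen <- nchar(motif)
  if (mlen > L) stop("motif (", mlen, " bp) longer than the fragment (", L, " bp)")
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over {A,C,G,T}")
  if (plantingProb < 0 || plantingProb > 1) {
    stop("plantingProb must lie in [0, 1]")
  }
  center0 <- delta                       # 0-based center index
  if (is.null(motifOffsets)) {
    all0 <- 0:(L - mlen)
    motifOffsets <- all0[all0 + mlen - 1L < center0 | all0 > center0]
    if (!length(motifOffsets)) {
      stop("motif cannot be placed without covering the center; ",
           "pass motifOffsets explicitly")
    }
  } else {
    motifOffsets <- as.integer(motifOffsets)
    if (any(motifOffsets < 0L) || any(motifOffsets + mlen > L)) {
      stop("motifOffsets place the motif outside the fragment")
    }
  }
  stopifnot(length(baseComposition) == 4, all(baseComposition >= 0))
  baseComposition <- baseComposition / sum(baseComposition)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- nPos + nNeg
  mat <- matrix(sample(VALID_BASES, n * L, replace = TRUE,
                       prob = baseComposition), nrow = n, ncol = L)
  mchars <- strsplit(motif, "")[[1]]
  planted <- runif(nPos) <= plantingProb
  offs <- motifOffsets[sample.int(length(motifOffsets), nPos, replace = TRUE)]
  for (s in which(planted)) {
    idx <- offs[s] + seq_len(mlen)       # 1-based columns
    bases <- mchars
    if (mutationRate > 0) {
      mut <- runif(mlen) < mutationRate
      if (any(mut)) {
        bases[mut] <- vapply(bases[mut], function(bb) {
          sample(setdiff(VALID_BASES, bb), 1L)
        }, character(1))
      }
    }
    mat[s, idx] <- bases
  }
  mat[, center0 + 1L] <- centerBase      # restore the center contract
  seqs <- do.call(paste0, lapply(seq_len(L), function(j) mat[, j]))
  ids <- c(if (nPos) paste0("pos_", seq_len(nPos)),
           if (nNeg) paste0("neg_", seq_len(nNeg)))
  labels <- c(rep(1L, nPos), rep(0L, nNeg))
  FragmentDataset(seqs = seqs, ids = ids, labels = labels, delta = delta,
                  provenance = sprintf("synthetic(seed=%d)", as.integer(seed)))
}

#' Stratified train/test split
#'
#' Per class, `round(count * testFraction)` records go to the test fold
#' (random without replacement, seeded); the folds are disjoint and
#' exhaustive. With 69,750 positives and testFraction 0.2 the test fold
#' holds exactly 13,950 positives.
#'
#' @param x a labeled [FragmentDataset-class] with both classes present.
#' @param testFraction fraction per class assigned to the test fold.
#' @param seed RNG seed.
#' @return list with elements `train` and `test`, both FragmentDatasets.
#' @export
stratifiedSplit <- function(x, testFraction = 0.2, seed = 1L) {
  stopifnot(is(x, "FragmentDataset"))
  if (testFraction <= 0 || testFraction >= 1) {
    stop("testFraction must lie strictly inside (0, 1)")
  }
  lab <- x@labels
  if (anyNA(lab)) stop("all records must be labeled for a stratified split")
  for (cl in c(0L, 1L)) {
    if (sum(lab == cl) < 2L) {
      stop("class ", cl, " has fewer than 2 members")
    }
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  testIdx <- integer(0)
  for (cl in c(0L, 1L)) {
    idx <- which(lab == cl)
    nTest <- round(length(idx) * testFraction)
    if (nTest > 0) testIdx <- c(testIdx, sample(idx, nTest))
  }
  testIdx <- sort(testIdx)
  trainIdx <- setdiff(seq_along(lab), testIdx)
  list(train = x[trainIdx], test = x[testIdx])
}
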