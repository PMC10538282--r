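#' Read labeled or unlabeled fragments from FASTA or TSV
#'
#' TSV input must carry a header with columns `id`, `sequence` and (optional
#' in practice, required for training) `label`; FASTA records become
#' unlabeled fragments named by their header line. All records are validated
#' against the fragment contract: equal length `2*delta+1`, alphabet
#' \{A,C,G,T\}, labels in \{0,1\}.
#'
#' @param path input file.
#' @param format `"fasta"`, `"tsv"`, or `"auto"` (by file extension;
#'   `.fa/.fasta/.fna` are FASTA, anything else TSV).
#' @param delta expected flank length; `NULL` infers it from the first
#'   record's length (which must be odd).
#' @return A [FragmentDataset-class] preserving file order.
#' @export
readFragments <- function(path, format = c("auto", "fasta", "tsv"),
                          delta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- toupper(as.character(ss))
    labels <- rep(NA_integer_, length(seqs))
  } else {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     colClasses = "character", check.names = FALSE)
    need <- c("id", "sequence")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("TSV is missing required column(s): ", paste(miss, collapse = ", "))
    }
    ids <- df$id
    seqs <- toupper(df$sequence)
    if ("label" %in% names(df)) {
      raw <- df$label
      ok <- is.na(raw) | raw %in% c("0", "1") | raw == ""
      if (!all(ok)) {
        stop("labels must be 0 or 1; offending ids: ",
             paste(head(ids[!ok], 5L), collapse = ", "))
      }
      labels <- ifelse(raw == "" | is.na(raw), NA_integer_, as.integer(raw))
    } else {
      labels <- rep(NA_integer_, length(ids))
    }
  }
  if (is.null(delta)) {
    if (!length(seqs)) stop("cannot infer delta from an empty file")
    len1 <- nchar(seqs[1])
    if (len1 %% 2L == 0L) {
      stop("first record has even length ", len1,
           "; fragments must have length 2*delta+1")
    }
    delta <- (len1 - 1L) %/% 2L
  }
  FragmentDataset(seqs = seqs, ids = ids, labels = labels, delta = delta,
                  provenance = paste0(format, ":", basename(path)))
}

#' Write fragments to the standard tab-separated format
#'
#' Columns `id`, `sequence`, `label` (empty for `NA`), UTF-8, '.' decimal;
#' `readFragments` on the result reproduces ids, sequences and labels exactly.
#'
#' @param x a [FragmentDataset-class]
#' @param path output file
#' @return `path`, invisibly.
#' @export
writeFragments <- function(x, path) {
  df <- data.frame(
    id = x@ids, sequence = x@seqs,
    label = ifelse(is.na(x@labels), "", as.character(x@labels)),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract all fixed-length windows centered on a given base
#'
#' Scans a DNA string and emits one `2*delta+1`-bp fragment for every
#' occurrence of `centerBase` far enough from both ends for the full window
#' to fit (0-based positions `p` with `delta <= p <= nchar(seq)-1-delta`).
#' Windows containing `N` are dropped with a message giving the count;
#' the k-mer vocabulary downstream is defined over \{A,C,G,T\} only.
#'
#' @param seq a single DNA string (A/C/G/T/N).
#' @param delta flank length on each side of the center (default 20, i.e.
#'   41-bp fragments, the resolution bisulfite pipelines report).
#' @param centerBase the candidate-site base, `"C"` for 5mC.
#' @param id prefix for record ids; ids encode the 1-based source position
#'   as `<id>:<pos>`.
#' @return A [FragmentDataset-class] (possibly empty).
#' @export
extractWindows <- function(seq, delta = 20L, centerBase = "C",
                           id = "seq") {
  stopifnot(length(seq) == 1L, delta >= 1L)
  centerBase <- toupper(centerBase)
  if (!centerBase %in% VALID_BASES) {
    stop("centerBase must be one of A, C, G, T")
  }
  seq <- toupper(seq)
  if (!nchar(seq)) {
    return(FragmentDataset(seqs = character(0), delta = delta,
                           provenance = "extractWindows"))
  }
  if (!grepl("^[ACGTN]*$", seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  delta <- as.integer(delta)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos0 <- which(chars == centerBase) - 1L        # 0-based site positions
  pos0 <- pos0[pos0 >= delta & pos0 <= length(chars) - 1L - delta]
  if (!length(pos0)) {
    return(FragmentDataset(seqs = character(0), delta = delta,
                           provenance = "extractWindows"))
  }
  windows <- substring(seq, pos0 - delta + 1L, pos0 + delta + 1L)
  hasN <- grepl("N", windows, fixed = TRUE)
  if (any(hasN)) {
    message(sum(hasN), " window(s) containing N dropped")
    windows <- windows[!hasN]
    pos0 <- pos0[!hasN]
    if (!length(pos0)) {
      return(FragmentDataset(seqs = character(0), delta = delta,
                             provenance = "extractWindows"))
    }
  }
  FragmentDataset(seqs = windows, ids = paste0(id, ":", pos0 + 1L),
                  delta = delta, provenance = "extractWindows")
}

#' Write per-fragment methylation predictions
#'
#' @param x a [FragmentDataset-class]
#' @param probs positive-class probability per record, in \[0,1\].
#' @param calls binary call per record; derived from `probs` at `threshold`
#'   (call = 1 iff prob >= threshold) when omitted.
#' @param path output TSV (columns id, sequence, prob_positive, call).
#' @param threshold decision threshold used when `calls` is `NULL`.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(x, probs, calls = NULL, path, threshold = 0.5) {
  n <- length(x@ids)
  if (length(probs) != n) {
    stop("probs (", length(probs), ") must align 1:1 with records (", n, ")")
  }
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probs must be finite and within [0, 1]")
  }
  if (is.null(calls)) calls <- as.integer(probs >= threshold)
  if (length(calls) != n) stop("calls must align 1:1 with records")
  if (!all(calls %in% c(0L, 1L))) stop("calls must be 0 or 1")
  df <- data.frame(id = x@ids, sequence = x@seqs,
                   prob_positive = sprintf("%.6f", probs),
                   call = as.integer(calls), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
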