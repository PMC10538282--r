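frag41 <- function(n, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    s <- strsplit(random_dna(41), "")[[1]]
    s[21] <- "C"
    paste(s, collapse = "")
  }, character(1))
}

test_that("TSV fragments round-trip exactly through write/read", {
  ds <- FragmentDataset(seqs = frag41(3), ids = c("a", "b", "c"),
                        labels = c(1, 0, NA), delta = 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFragments(ds, path)
  back <- readFragments(path, format = "tsv")
  expect_identical(fragmentIds(back), fragmentIds(ds))
  expect_identical(fragmentSeqs(back), fragmentSeqs(ds))
  expect_identical(fragmentLabels(back), fragmentLabels(ds))
  expect_identical(flankLength(back), 20L)
})

test_that("FASTA fragments are read with inferred delta", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1 description", frag41(1, seed = 5),
               ">r2", frag41(1, seed = 6)), path)
  ds <- readFragments(path)
  expect_identical(fragmentIds(ds), c("r1", "r2"))
  expect_identical(flankLength(ds), 20L)
  expect_true(all(is.na(fragmentLabels(ds))))
})

test_that("malformed records are rejected with informative errors", {
  # wrong length vs the declared delta
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">short", substr(frag41(1), 1, 40)), path)
  expect_error(readFragments(path, delta = 20), "2\\*delta\\+1")
  # label outside {0,1}
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsequence\tlabel",
               paste("x1", frag41(1), "2", sep = "\t")), path2)
  expect_error(readFragments(path2), "label")
  # illegal character names the offending id
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsequence\tlabel",
               paste("bad1", sub("A", "X", frag41(1)), "0", sep = "\t")),
             path3)
  expect_error(readFragments(path3), "bad1")
  # missing required column
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tseq", "a\tACGT"), path4)
  expect_error(readFragments(path4), "missing required column")
})

test_that("extractWindows matches the exhaustive scan oracle", {
  ds <- extractWindows("AACGT", delta = 1, centerBase = "C")
  expect_identical(fragmentSeqs(ds), "ACG")
  expect_identical(fragmentIds(ds), "seq:3")

  # center too close to the 5' end yields nothing
  expect_length(extractWindows("CAAAA", delta = 1, centerBase = "C"), 0L)
  # empty input is an empty dataset, not an error
  expect_length(extractWindows("", delta = 3), 0L)

  set.seed(42)
  for (rep in 1:20) {
    seq <- random_dna(sample(50:400, 1))
    delta <- sample(1:6, 1)
    center <- sample(c("A", "C", "G", "T"), 1)
    got <- extractWindows(seq, delta = delta, centerBase = center)
    want <- oracle_windows(seq, delta, center)
    expect_identical(fragmentSeqs(got), want)
    if (length(got)) {
      expect_true(all(substr(fragmentSeqs(got), delta + 1, delta + 1)
                      == center))
      expect_true(all(nchar(fragmentSeqs(got)) == 2 * delta + 1))
    }
  }
})

test_that("windows at delta = 20 have exactly 41 sites", {
  set.seed(7)
  ds <- extractWindows(random_dna(500), delta = 20, centerBase = "C")
  expect_gt(length(ds), 0L)
  expect_true(all(nchar(fragmentSeqs(ds)) == 41L))
})

test_that("windows containing N are dropped with a reported count", {
  seq <- paste0(strrep("A", 30), "N", strrep("A", 9), "C", strrep("G", 40))
  expect_message(ds <- extractWindows(seq, delta = 20), "dropped")
  expect_length(ds, 0L)
})

test_that("prediction files are validated and thresholded correctly", {
  ds <- FragmentDataset(seqs = frag41(2), ids = c("a", "b"), delta = 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePredictions(ds, probs = c(0.9, 0.1), path = path)
  back <- read.delim(path)
  expect_identical(back$call, c(1L, 0L))
  expect_equal(back$prob_positive, c(0.9, 0.1), tolerance = 1e-6)

  # a probability exactly at the threshold is called positive
  writePredictions(ds, probs = c(0.5, 0.1), path = path)
  expect_identical(read.delim(path)$call, c(1L, 0L))

  # empty dataset -> header-only file
  empty <- FragmentDataset(seqs = character(0), delta = 20)
  writePredictions(empty, probs = numeric(0), path = path)
  expect_identical(readLines(path), "id\tsequence\tprob_positive\tcall")

  expect_error(writePredictions(ds, probs = c(1.2, 0.1), path = path),
               "\\[0, 1\\]")
  expect_error(writePredictions(ds, probs = 0.5, path = path), "align")
})
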