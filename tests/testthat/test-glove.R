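make_corpus <- function(docs, tokens, k = 3L) {
  vocab <- new("KmerVocabulary", k = k, tokens = tokens)
  new("TokenizedCorpus", docs = lapply(docs, as.integer),
      ids = paste0("d", seq_along(docs)), vocab = vocab)
}

test_that("direct-precedence counts land symmetrically in the matrix", {
  # 'CGG' immediately precedes 'ATC' twice across the corpus
  toks <- c("CGG", "ATC", "TAC", "GGC")
  corp <- make_corpus(list(c(1, 2, 3), c(4, 1, 2), c(3, 4)), toks)
  X <- coocMatrix(buildCooccurrence(corp, window = 1))
  expect_identical(X["CGG", "ATC"], 2)
  expect_identical(X["ATC", "CGG"], 2)
  expect_true(isTRUE(all.equal(X, t(X))))
})

test_that("single-token documents produce an all-zero matrix", {
  corp <- make_corpus(list(1, 2, 1), c("AAA", "CCC"))
  expect_true(all(coocMatrix(buildCooccurrence(corp, window = 3)) == 0))
})

test_that("co-occurrence equals exhaustive pair enumeration on random corpora", {
  set.seed(21)
  for (rep in 1:50) {
    nTok <- sample(3:8, 1)
    corp <- random_token_corpus(nDocs = sample(2:10, 1),
                                docLen = sample(2:10, 1), nTokens = nTok)
    w <- sample(1:3, 1)
    got <- buildCooccurrence(corp, window = w)
    want <- oracle_cooccurrence(corp@docs, nTok, w)
    expect_equal(unname(coocMatrix(got)), want)
  }
})

test_that("inverse-distance weighting scales pair contributions by 1/s", {
  corp <- make_corpus(list(c(1, 2, 3)), c("AAA", "CCC", "GGG"))
  X <- coocMatrix(buildCooccurrence(corp, window = 2, distanceWeight = TRUE))
  expect_equal(X["AAA", "CCC"], 1)       # adjacent
  expect_equal(X["AAA", "GGG"], 0.5)     # distance 2
})

test_that("the truncated power weighting obeys its closed forms", {
  expect_equal(gloveWeight(100, tX = 100), 1)
  expect_equal(gloveWeight(250, tX = 100), 1)
  expect_equal(gloveWeight(100 / 16, tX = 100, alpha = 0.75), 0.125)
  expect_equal(gloveWeight(0), 0)
  expect_error(gloveWeight(-1), "nonnegative")
  # non-decreasing, continuous at the truncation point
  xs <- seq(0, 200, by = 0.5)
  ws <- gloveWeight(xs, tX = 100)
  expect_true(all(diff(ws) >= -1e-12))
  expect_equal(gloveWeight(100 - 1e-9), 1, tolerance = 1e-7)
})

test_that("the objective is the weighted squared residual over nonzero pairs", {
  X <- matrix(c(0, 4, 4, 0), 2, 2)
  zero <- list(V = matrix(0, 2, 2), Vtilde = matrix(0, 2, 2),
               b = c(0, 0), btilde = c(0, 0))
  # two symmetric nonzero cells, each f(4) * (0 - log 4)^2
  expect_equal(gloveLoss(zero, X), 2 * (4 / 100)^0.75 * log(4)^2)

  # residual-free parameters give exactly zero
  fit <- list(V = matrix(0, 2, 2), Vtilde = matrix(0, 2, 2),
              b = c(log(4), log(4)), btilde = c(0, 0))
  expect_equal(gloveLoss(fit, X), 0)

  expect_error(gloveLoss(zero, matrix(0, 3, 3)), "shapes")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(5)
  for (rep in 1:3) {
    n <- sample(3:5, 1); d <- sample(2:3, 1)
    D <- matrix(rpois(n * n, 3), n, n)
    X <- D + t(D); diag(X) <- 0
    p <- random_glove_params(n, d)
    g <- gloveGradient(p, X)
    num <- finite_diff(function(q) gloveLoss(q, X), p)
    for (blk in names(p)) {
      denom <- pmax(abs(num[[blk]]), 1e-6)
      expect_lt(max(abs(g[[blk]] - num[[blk]]) / denom), 1e-5)
    }
  }
})

test_that("fitting is seeded-deterministic and reduces the objective", {
  set.seed(31)
  corp <- random_token_corpus(nDocs = 12, docLen = 8, nTokens = 6)
  cooc <- buildCooccurrence(corp, window = 1)
  e1 <- fitGlove(cooc, d = 4, epochs = 30, seed = 17)
  e2 <- fitGlove(cooc, d = 4, epochs = 30, seed = 17)
  expect_identical(e1@V, e2@V)
  expect_identical(lossHistory(e1), lossHistory(e2))
  expect_false(identical(e1@V, fitGlove(cooc, d = 4, epochs = 30, seed = 18)@V))

  h <- lossHistory(e1)
  expect_lt(tail(h, 1), h[1])
  # near-monotone decrease: stochastic updates may wiggle slightly
  expect_true(all(diff(h) <= 0.05 * h[1] + 1e-8))
  expect_identical(dim(e1@V), c(6L, 4L))
})

test_that("an exactly-fittable instance is driven to (numerically) zero loss", {
  vo <- new("KmerVocabulary", k = 3L, tokens = c("AAA", "AAC"))
  cooc <- new("CooccurrenceMatrix", X = matrix(c(0, 4, 4, 0), 2, 2),
              vocab = vo, window = 1L)
  emb <- fitGlove(cooc, d = 2, epochs = 500, lr = 0.2, seed = 7)
  expect_lt(tail(lossHistory(emb), 1), 1e-4)
})

test_that("tokens used in identical contexts acquire similar vectors", {
  # targets 1 and 2 are interchangeable; context tokens are 5..10
  set.seed(13)
  docs <- lapply(1:300, function(i) {
    c(sample(5:10, 1), if (i %% 2) 1L else 2L, sample(5:10, 1))
  })
  toks <- vocabTokens(fullVocab(3))[1:10]
  corp <- make_corpus(docs, toks)
  emb <- fitGlove(buildCooccurrence(corp, window = 1), d = 6, epochs = 60,
                  seed = 3)
  m <- embeddingMatrix(emb)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  twin <- cosine(m[1, ], m[2, ])
  others <- vapply(5:10, function(j) cosine(m[1, ], m[j, ]), numeric(1))
  expect_gt(twin, max(others))
})

test_that("the sparse co-occurrence dump lists every nonzero cell", {
  toks <- c("CGG", "ATC", "TAC")
  corp <- make_corpus(list(c(1, 2), c(1, 2), c(3, 1)), toks)
  co <- buildCooccurrence(corp, window = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCooccurrence(co, path)
  df <- read.delim(path)
  expect_identical(nrow(df), sum(coocMatrix(co) > 0))
  expect_equal(df$count[df$i == "CGG" & df$j == "ATC"], 2)
})

test_that("embedding text files round-trip and reject malformed input", {
  emb <- fixed_embedding(vocabTokens(fullVocab(3)), d = 20)
  path <- withr::local_tempfile(fileext = ".txt")
  saveEmbedding(emb, path)
  back <- loadEmbedding(path)
  expect_identical(embeddingTokens(back), embeddingTokens(emb))
  expect_lt(max(abs(embeddingMatrix(back) - embeddingMatrix(emb))), 1e-6)

  lines <- readLines(path)
  lines[40] <- sub(" [^ ]+$", "", lines[40])  # drop one component
  writeLines(lines, path)
  expect_error(loadEmbedding(path), "line 40")

  writeLines(character(0), path)
  expect_error(loadEmbedding(path), "empty")
})
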