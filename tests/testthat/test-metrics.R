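test_that("confusion counts partition the samples", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(cc, c(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  perfect <- confusionCounts(c(1, 0, 1), c(1, 0, 1))
  expect_identical(perfect[["fp"]] + perfect[["fn"]], 0L)
  expect_error(confusionCounts(integer(0), integer(0)), "empty")
  expect_error(confusionCounts(c(1, 0), c(1)), "length")
  expect_error(confusionCounts(c(1, 2), c(1, 0)), "0 or 1")
})

test_that("rate metrics match direct formula evaluation", {
  r <- computeMetrics(c(tp = 8, tn = 0, fp = 0, fn = 2))
  expect_equal(r@sen, 0.8)

  bal <- computeMetrics(c(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(bal@mcc, 0)

  r2 <- computeMetrics(c(tp = 8, fn = 2, tn = 85, fp = 5))
  o <- oracle_metrics(8, 85, 5, 2)
  expect_equal(r2@sen, o$sen)
  expect_equal(r2@spe, o$spe)
  expect_equal(r2@acc, o$acc)
  expect_equal(r2@mcc, o$mcc)

  # random confusion tables against the oracle
  set.seed(8)
  for (rep in 1:50) {
    cnt <- rpois(4, 10) + 1
    r3 <- computeMetrics(c(tp = cnt[1], tn = cnt[2], fp = cnt[3],
                           fn = cnt[4]))
    o3 <- oracle_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(r3@mcc, o3$mcc)
    expect_equal(r3@acc, o3$acc)
    expect_true(abs(r3@mcc) <= 1)
    # mcc is invariant under simultaneous swap TP<->TN, FP<->FN
    sw <- computeMetrics(c(tp = cnt[2], tn = cnt[1], fp = cnt[4],
                           fn = cnt[3]))
    expect_equal(sw@mcc, r3@mcc)
  }
})

test_that("zero denominators flag metrics as undefined, never zero", {
  r <- computeMetrics(c(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(r@sen))
  expect_true(is.na(r@mcc))
  expect_true(all(c("sen", "mcc") %in% r@undefined))
  expect_equal(r@acc, 1)
})

test_that("AUC equals pair counting with half-credit ties", {
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))$auc, 1)
  expect_equal(rocAuc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(15)
  for (rep in 1:200) {
    n <- sample(10:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    got <- rocAuc(labels, scores)$auc
    expect_equal(got, oracle_auc(labels, scores))
    # label swap + score negation mirrors the AUC
    expect_equal(rocAuc(1 - labels, scores)$auc, 1 - got)
    # sample order is irrelevant
    perm <- sample(n)
    expect_equal(rocAuc(labels[perm], scores[perm])$auc, got)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(labels, scores)$auc, ref)
  }
})

test_that("full evaluation wires counts, rates and AUC together", {
  labels <- c(1, 1, 1, 0, 0, 0)
  probs <- c(0.9, 0.7, 0.2, 0.6, 0.3, 0.1)
  r <- evaluatePredictions(labels, probs, threshold = 0.5)
  expect_identical(c(r@tp, r@fp, r@fn, r@tn), c(2L, 1L, 1L, 2L))
  expect_equal(r@auc, oracle_auc(labels, probs))
  lst <- metricsAsList(r)
  expect_named(lst, c("tp", "tn", "fp", "fn", "sen", "spe", "acc",
                      "mcc", "auc"))
})
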