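test_that("confusion counts use a strict threshold", {
  expect_equal(unname(confusionCounts(c(1, 0), c(1, -1))), c(1, 0, 1, 0))
  cc <- confusionCounts(c(1, 1, 1, 0), c(-1, -2, -0.5, -3))
  expect_equal(unname(cc[c("tp", "fn")]), c(0, 3))
  # a score exactly at the threshold counts as a negative prediction
  cc0 <- confusionCounts(1, 0, threshold = 0)
  expect_equal(unname(cc0[c("tp", "fn")]), c(0, 1))
  expect_error(confusionCounts(c(1, 0), 1), "lengths differ")
})

test_that("precision/recall/F reproduce the printed-table arithmetic", {
  m <- precisionRecallF(64, 0, 31)
  expect_equal(unname(m[["precision"]]), 1)
  expect_equal(round(m[["recall"]], 3), 0.674)
  expect_equal(round(m[["f_measure"]], 3), 0.805)
  expect_equal(round(precisionRecallF(58, 10, 37)[["recall"]], 3), 0.611)
  # nothing predicted positive: precision (and F) undefined
  u <- precisionRecallF(0, 0, 95)
  expect_true(is.na(u[["precision"]]))
  expect_true(is.na(u[["f_measure"]]))
  expect_equal(u[["recall"]], 0)
  expect_error(precisionRecallF(-1, 0, 0), "nonnegative")
})

test_that("rocAuc handles separation, total ties and a hand-counted case", {
  sep <- rocAuc(c(1, 1, 0, 0), c(2, 1.5, 0.2, -1))
  expect_equal(sep$auc, 1)
  expect_equal(rocAuc(c(1, 0, 1, 0), rep(0.3, 4))$auc, 0.5)
  # pairwise concordance by hand: 3 concordant of 4 positive-negative pairs
  hand <- rocAuc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(hand$auc, 0.75)
  # curve bookkeeping: starts at (0,0), ends at (1,1), monotone
  rp <- hand$points
  expect_equal(unname(rp[1, ]), c(0, 0))
  expect_equal(unname(rp[nrow(rp), ]), c(1, 1))
  expect_false(is.unsorted(rp[, "fpr"]))
  expect_false(is.unsorted(rp[, "tpr"]))
  expect_error(rocAuc(c(1, 1), c(0.5, 0.2)), "both classes")
})

test_that("trapezoidal AUC equals brute-force concordance (oracle, property)", {
  withr::with_seed(2024, {
    for (i in 1:40) {
      n <- sample(10:200, 1)
      labels <- c(1L, 0L, sample(c(0L, 1L), n - 2, replace = TRUE))
      scores <- round(stats::rnorm(n), sample(0:2, 1))  # force ties often
      expect_equal(rocAuc(labels, scores)$auc,
                   bruteForceAuc(labels, scores), tolerance = 1e-12)
    }
  })
})

test_that("rocAuc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    labels <- sample(c(0L, 1L), 150, replace = TRUE, prob = c(0.8, 0.2))
    labels[1:2] <- c(0L, 1L)
    scores <- stats::rnorm(150) + labels
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAuc(labels, scores)$auc, ref, tolerance = 1e-12)
})

test_that("evalReport assembles a valid report and meanReport averages it", {
  labels <- c(1, 1, 0, 0, 0)
  scores <- c(2, -0.5, 0.8, -1, -2)
  r <- evalReport(labels, scores)
  expect_s4_class(r, "EvalReport")
  expect_equal(r@tp + r@fp + r@tn + r@fn, 5)
  expect_equal(r@tp, 1); expect_equal(r@fp, 1)
  m <- meanReport(list(r, r))
  expect_equal(m@auc, r@auc)
  expect_equal(m@tp, r@tp)
  # undefined metrics stay undefined through averaging
  rNA <- evalReport(c(1, 0), c(-1, -2))
  expect_true(is.na(meanReport(list(r, rNA))@precision))
  tab <- reportTable(list(a = r, b = rNA))
  expect_equal(tab$method, c("a", "b"))
  p <- tempfile(fileext = ".tsv")
  writeReport(list(a = r, b = rNA), p)
  out <- read.delim(p)
  expect_equal(out$precision[2], "—")
})

test_that("cross-validation recovers a planted superfamily signal", {
  bundle <- suppressWarnings(generateBundle(generatorConfig(
    nReceptors = 12, nLigands = 14, nReceptorDomains = 10,
    nLigandDomains = 12, nReceptorSuperfamilies = 4,
    nLigandSuperfamilies = 5, positiveRateTarget = 0.2,
    sequenceLength = c(60, 120), seed = 21)))
  ds <- buildPairDataset(bundle$dataset)
  res <- crossValidate(ds, "superfamily", nRepeats = 2, seed = 1)
  expect_gte(res$mean@auc, 0.9)
  expect_length(res$reports, 2)
  # reproducibility: identical protocol, identical reports
  res2 <- crossValidate(ds, "superfamily", nRepeats = 2, seed = 1)
  expect_identical(res$scores, res2$scores)
  expect_equal(res$mean@auc, res2$mean@auc)
  # label permutation destroys the signal (chance band over repeats)
  pairs <- pairExamples(ds)
  pairs$label <- withr::with_seed(5, sample(pairs$label))
  dsPerm <- PairDataset(proteins(ds), unname(proteinRoles(ds)),
                        domainHits(ds), pairs)
  resPerm <- crossValidate(dsPerm, "superfamily", nRepeats = 2, seed = 1)
  expect_lt(resPerm$mean@auc, 0.75)
  expect_gt(res$mean@auc, resPerm$mean@auc)
})

test_that("independent test holds out floor(fraction) per class and averages", {
  bundle <- suppressWarnings(generateBundle(generatorConfig(
    nReceptors = 12, nLigands = 14, nReceptorDomains = 10,
    nLigandDomains = 12, nReceptorSuperfamilies = 4,
    nLigandSuperfamilies = 5, positiveRateTarget = 0.2,
    sequenceLength = c(60, 120), seed = 21)))
  ds <- buildPairDataset(bundle$dataset)
  y <- pairExamples(ds)$label
  res <- independentTest(ds, "superfamily", nRepeats = 2, seed = 4)
  for (sp in res$splits) {
    expect_equal(sum(y[sp$test] == 1), floor(0.2 * sum(y == 1)))
    expect_equal(sum(y[sp$test] == 0), floor(0.2 * sum(y == 0)))
  }
  expect_gte(res$mean@auc, 0.8)
  res2 <- independentTest(ds, "superfamily", nRepeats = 2, seed = 4)
  expect_equal(reportTable(list(m = res$mean)), reportTable(list(m = res2$mean)))
})

test_that("combination protocol matches its degenerate identities", {
  bundle <- suppressWarnings(generateBundle(generatorConfig(
    nReceptors = 10, nLigands = 12, nReceptorDomains = 8,
    nLigandDomains = 10, nReceptorSuperfamilies = 3,
    nLigandSuperfamilies = 4, positiveRateTarget = 0.25,
    sequenceLength = c(60, 100), seed = 33)))
  ds <- buildPairDataset(bundle$dataset)
  # combining a recipe with itself reproduces the single-recipe scores
  self <- runCombinationProtocol(ds, "superfamily", "superfamily",
                                 nRepeats = 1, seed = 2)
  single <- crossValidate(ds, "superfamily", nRepeats = 1, seed = 2)
  expect_equal(self$reports[[1]]@auc, single$reports[[1]]@auc,
               tolerance = 1e-12)
  # two informative recipes: combined AUC is not catastrophically below
  # the weaker single recipe (degradation is possible, collapse is not)
  comb <- runCombinationProtocol(ds, "kmer2", "superfamily",
                                 nRepeats = 1, seed = 2)
  expect_true(comb$mean@auc >= 0.5)
  expect_equal(ncol(comb$weights), 4)
})
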