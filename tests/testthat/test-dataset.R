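test_that("pairwiseIdentity matches hand-aligned examples and is symmetric", {
  expect_equal(pairwiseIdentity("ACDEF", "ACDEF"), 1)
  expect_equal(pairwiseIdentity("AAAA", "CCCC"), 0)
  # optimal ungapped alignment of these 5-mers has 4/5 identical columns
  expect_equal(pairwiseIdentity("ACDEF", "ACDFF"), 0.8)
  expect_equal(pairwiseIdentity("MKVLACDE", "ACDE"),
               pairwiseIdentity("ACDE", "MKVLACDE"))
  expect_error(pairwiseIdentity("", "ACDE"), "nonempty")
})

test_that("greedy clustering follows representative-based assignment", {
  # A and B are 90% identical, B and C 80%, A and C 70%: C fails against
  # the representative A and founds its own cluster
  A <- "ACDEFGHIKLMNPQRSTVWY"
  B <- "WWDEFGHIKLMNPQRSTVWY"          # 2 mutations vs A -> 0.9
  C <- "WWYYWWHIKLMNPQRSTVWY"          # 4 more mutations vs B -> 0.8; vs A 0.7
  expect_equal(pairwiseIdentity(A, B), 0.9)
  expect_equal(pairwiseIdentity(B, C), 0.8)
  expect_equal(pairwiseIdentity(A, C), 0.7)
  res <- clusterRedundant(c(A = A, B = B, C = C), 0.8)
  expect_equal(length(res$clusters), 2)
  expect_setequal(res$clusters[[1]], c("A", "B"))
  expect_identical(res$clusters[[2]], "C")
  expect_identical(res$representatives, c("A", "C"))
})

test_that("clustering yields a partition with representative members", {
  withr::with_seed(7, {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    seqs <- setNames(vapply(1:12, function(i)
      paste(sample(aas, sample(15:30, 1), replace = TRUE), collapse = ""),
      character(1)), sprintf("P%02d", 1:12))
    res <- clusterRedundant(seqs, 0.8)
    members <- unlist(res$clusters)
    expect_setequal(members, names(seqs))
    expect_equal(length(members), length(seqs))
    for (i in seq_along(res$clusters)) {
      rep <- res$representatives[i]
      expect_true(rep %in% res$clusters[[i]])
      for (m in res$clusters[[i]])
        expect_gte(pairwiseIdentity(seqs[[m]], seqs[[rep]]), 0.8)
    }
    # identical sequences always collapse
    dup <- c(seqs[1:3], X1 = unname(seqs[[1]]))
    res2 <- clusterRedundant(dup, 0.8)
    cl <- res2$clusters[[which(vapply(res2$clusters, function(x)
      "X1" %in% x, logical(1)))]]
    expect_true(names(seqs)[1] %in% cl)
  })
})

test_that("reduceRedundancy keeps one representative per cluster and prunes", {
  seqs <- Biostrings::AAStringSet(c(
    R1 = "ACDEFGHIKLMNPQRSTVWY", R2 = "ACDEFGHIKLMNPQRSTVWY",
    L1 = "MKVLMKVLMKVLMKVLMKVL"))
  ds <- PairDataset(seqs, c("receptor", "receptor", "ligand"),
                    pairs = data.frame(receptor_id = c("R1", "R2"),
                                       ligand_id = c("L1", "L1"),
                                       label = 1L))
  red <- reduceRedundancy(ds)
  expect_equal(sum(proteinRoles(red) == "receptor"), 1)
  expect_equal(nrow(pairExamples(red)), 1)
})

test_that("generateNegatives enumerates the cross product minus positives", {
  pos <- data.frame(receptor_id = "R1", ligand_id = "L1")
  neg <- generateNegatives(c("R1", "R2"), c("L1", "L2", "L3"), pos)
  expect_equal(nrow(neg), 5)
  expect_true(all(neg$label == 0L))
  # lexicographic order, no duplicates, positives excluded
  key <- paste(neg$receptor_id, neg$ligand_id)
  expect_identical(key, sort(key))
  expect_false("R1 L1" %in% key)
  expect_equal(nrow(generateNegatives("R1", "L1",
    data.frame(receptor_id = "R1", ligand_id = "L1"))), 0)
  expect_equal(nrow(generateNegatives(c("R1", "R2"), c("L1", "L2", "L3"))), 6)
  expect_error(generateNegatives("R1", "L1",
    data.frame(receptor_id = "R9", ligand_id = "L1")), "unknown id")
})

test_that("negative enumeration equals brute-force set difference (property)", {
  withr::with_seed(31, {
    for (i in 1:10) {
      rs <- sprintf("R%d", seq_len(sample(2:6, 1)))
      ls <- sprintf("L%d", seq_len(sample(2:6, 1)))
      all <- expand.grid(receptor_id = rs, ligand_id = ls,
                         stringsAsFactors = FALSE)
      pos <- all[sample(nrow(all), sample(0:nrow(all), 1)), , drop = FALSE]
      neg <- generateNegatives(rs, ls, pos)
      expect_equal(nrow(neg), nrow(all) - nrow(pos))
      expect_setequal(paste(neg$receptor_id, neg$ligand_id),
                      setdiff(paste(all$receptor_id, all$ligand_id),
                              paste(pos$receptor_id, pos$ligand_id)))
    }
  })
})

test_that("class weights are proportional to the opposite class size", {
  w <- classWeights(95, 2183)
  expect_equal(unname(w[["pos"]]), 2183 / 95)
  expect_equal(unname(w[["neg"]]), 1)
  expect_equal(classWeights(100, 100)[["pos"]], 1)
  expect_error(classWeights(0, 10), "nonempty")
})

test_that("stratified folds balance classes and reproduce under a seed", {
  y <- c(rep(1L, 95), rep(0L, 2183))
  f <- stratifiedKfold(y, 5, seed = 11)
  expect_equal(sort(unique(f)), 1:5)
  posCounts <- table(f[y == 1])
  negCounts <- table(f[y == 0])
  expect_true(all(posCounts == 19))
  expect_true(all(negCounts %in% c(436, 437)))
  expect_equal(sum(negCounts), 2183)
  expect_identical(f, stratifiedKfold(y, 5, seed = 11))
  expect_false(identical(f, stratifiedKfold(y, 5, seed = 12)))
  expect_error(stratifiedKfold(c(1, 1, 0, 0), 5), "at least 5")
})

test_that("holdout split takes floor(fraction) per class, disjointly", {
  y <- c(rep(1L, 95), rep(0L, 2183))
  sp <- holdoutSplit(y, 0.2, seed = 3)
  expect_equal(sum(y[sp$test] == 1), 19)
  expect_equal(sum(y[sp$test] == 0), 436)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_identical(sp, holdoutSplit(y, 0.2, seed = 3))
  sp2 <- holdoutSplit(c(1, 1, 1, 1, 0, 0, 0, 0), 0.5, seed = 1)
  expect_equal(length(sp2$test), 4)
  expect_error(holdoutSplit(c(1, 0, 0, 0), 0.1), "degenerate")
})

test_that("buildPairDataset attaches the exhaustive negative class", {
  ds <- buildPairDataset(tinyDataset())
  pairs <- pairExamples(ds)
  expect_equal(nrow(pairs), 2 * 3)      # full cross product
  expect_equal(sum(pairs$label == 1), 2)
  expect_equal(sum(pairs$label == 0), 4)
  p <- tempfile(fileext = ".tsv")
  writeManifest(ds, p, fold = rep(1L, nrow(pairs)))
  back <- read.delim(p)
  expect_identical(colnames(back),
                   c("receptor_id", "ligand_id", "label", "fold"))
})
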