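test_that("kmerVector computes relative k-mer frequencies over valid windows", {
  v1 <- kmerVector("AAAA", 1)
  expect_length(v1, 20)
  expect_equal(unname(v1[["A"]]), 1)
  expect_equal(sum(v1), 1)

  # hand enumeration of the three windows of "ACDC": AC, CD, DC
  v2 <- kmerVector("ACDC", 2)
  expect_length(v2, 400)
  expect_equal(unname(v2[c("AC", "CD", "DC")]), rep(1 / 3, 3))
  expect_equal(sum(v2), 1)

  # windows touching an ambiguity code are dropped from both sides of the
  # fraction; with no valid window left the vector is all zero
  expect_warning(vx <- kmerVector("AXA", 2), "no valid")
  expect_equal(sum(vx), 0)
  vMixed <- kmerVector("AXAC", 2)   # valid windows: only "AC"
  expect_equal(unname(vMixed[["AC"]]), 1)

  expect_error(kmerVector("ACDE", 0), "positive integer")
  expect_error(kmerVector("", 1), "nonempty")
})

test_that("k-mer frequencies sum to one on canonical sequences (property)", {
  withr::with_seed(99, {
    for (i in 1:20) {
      len <- sample(5:80, 1)
      s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        len, replace = TRUE), collapse = "")
      for (k in 1:2)
        expect_equal(sum(kmerVector(s, k)), 1, tolerance = 1e-12)
    }
  })
})

test_that("buildVocabulary separates roles, sorts lists and maps domains", {
  ds <- tinyDataset()
  vocab <- buildVocabulary(domainHits(ds), proteinRoles(ds))
  expect_identical(vocabTypes(vocab, "receptor", "domain"), c("d1", "d2"))
  expect_identical(vocabTypes(vocab, "ligand", "domain"), c("d3", "d4"))
  expect_identical(vocabTypes(vocab, "receptor", "superfamily"), "SF1")
  expect_identical(vocabTypes(vocab, "ligand", "superfamily"),
                   c("SF2", "SF3"))
  expect_identical(domainToSuperfamily(vocab)[["d3"]], "SF2")

  empty <- buildVocabulary(domainHits(ds)[0, ], proteinRoles(ds))
  expect_length(vocabTypes(empty, "receptor", "domain"), 0)
})

test_that("a domain seen on both roles occupies both role lists", {
  hits <- data.frame(protein_id = c("R1", "L1"), domain_acc = "d1",
                     superfamily_acc = "SF1", e_value = 1e-10,
                     start = 1L, end = 5L, stringsAsFactors = FALSE)
  roles <- c(R1 = "receptor", L1 = "ligand")
  vocab <- buildVocabulary(hits, roles)
  expect_identical(vocabTypes(vocab, "receptor", "domain"), "d1")
  expect_identical(vocabTypes(vocab, "ligand", "domain"), "d1")
})

test_that("buildVocabulary rejects inconsistent superfamily annotation", {
  hits <- data.frame(protein_id = c("R1", "R1"), domain_acc = "d1",
                     superfamily_acc = c("SF1", "SF2"), e_value = 1e-10,
                     start = 1L, end = 5L, stringsAsFactors = FALSE)
  expect_error(buildVocabulary(hits, c(R1 = "receptor")),
               "more than one superfamily")
})

test_that("domainVector encodes presence/absence at both levels", {
  vocab <- new("DomainVocabulary",
               receptorDomains = c("d1", "d2", "d3", "d4"),
               ligandDomains = character(0),
               receptorSuperfamilies = c("SF1", "SF2", "SF3"),
               ligandSuperfamilies = character(0),
               domainToSuperfamily = c(d1 = "SF2", d2 = "SF1",
                                       d3 = "SF2", d4 = "SF3"))
  hits <- data.frame(protein_id = "R1", domain_acc = c("d1", "d3"),
                     superfamily_acc = c("SF2", "SF2"), e_value = 1e-10,
                     start = 1L, end = 5L, stringsAsFactors = FALSE)
  dv <- domainVector("R1", hits, vocab, "receptor", "domain")
  expect_equal(unname(as.numeric(dv)), c(1, 0, 1, 0))
  # two domains of one superfamily collapse to a single 1
  sv <- domainVector("R1", hits, vocab, "receptor", "superfamily")
  expect_equal(unname(as.numeric(sv)), c(0, 1, 0))
  # zero hits give the all-zero vector
  zv <- domainVector("R9", hits, vocab, "receptor", "domain")
  expect_equal(sum(zv), 0)
  expect_error(domainVector("R1", hits, vocab, "enzyme"), "unknown protein role")
})

test_that("superfamily vector is the OR-projection of the domain vector", {
  withr::with_seed(123, {
    for (i in 1:25) {
      w <- randomHitWorld(nProteins = 5, nDomains = 10, nSuperfamilies = 4)
      vocab <- buildVocabulary(w$hits, w$roles)
      id <- sample(names(w$roles), 1)
      role <- unname(w$roles[[id]])
      dv <- domainVector(id, w$hits, vocab, role, "domain")
      sv <- domainVector(id, w$hits, vocab, role, "superfamily")
      doms <- vocabTypes(vocab, role, "domain")
      proj <- vapply(vocabTypes(vocab, role, "superfamily"), function(sf)
        as.numeric(any(dv[doms[w$map[doms] == sf]] > 0)), numeric(1))
      expect_equal(unname(as.numeric(sv)), unname(proj))
    }
  })
})

test_that("pairVector concatenates receptor-first with matching recipes", {
  p1 <- pairVector(kmerVector("ACD", 1), kmerVector("MKV", 1))
  expect_length(p1, 40)
  expect_identical(recipeOf(p1), "kmer1")
  expect_equal(unname(p1[["R.A"]]), 1 / 3)
  expect_equal(unname(p1[["L.M"]]), 1 / 3)
  expect_length(pairVector(kmerVector("ACDE", 2), kmerVector("MKVL", 2)), 800)
  expect_error(pairVector(kmerVector("ACD", 1), kmerVector("MKV", 2)),
               "recipe mismatch")
})

test_that("compositeVector concatenates pair vectors in argument order", {
  a <- pairVector(kmerVector("ACDE", 2), kmerVector("MKVL", 2))
  sfR <- featureVector(c(1, 0), c("SF1", "SF2"), "superfamily")
  sfL <- featureVector(1, "SF9", "superfamily")
  b <- pairVector(sfR, sfL)
  comp <- compositeVector(a, b)
  expect_length(comp, 803)
  expect_identical(recipeOf(comp), "composite")
  # order is part of the layout
  expect_false(identical(names(compositeVector(a, b)),
                         names(compositeVector(b, a))))
  # composing with an empty vector preserves the values
  emptyVec <- featureVector(numeric(0), character(0), "superfamily")
  expect_equal(as.numeric(compositeVector(a, emptyVec)), as.numeric(a))
})

test_that("pairFeatureMatrix builds consistent matrices for all recipes", {
  ds <- tinyDataset()
  vocab <- buildVocabulary(domainHits(ds), proteinRoles(ds))
  pairs <- pairExamples(ds)
  dims <- c(kmer1 = 40, kmer2 = 800, domain = 4, superfamily = 3,
            composite = 803)
  for (recipe in names(dims)) {
    m <- pairFeatureMatrix(ds, recipe, vocab, pairs)
    expect_equal(dim(m), c(2L, unname(dims[[recipe]])),
                 info = recipe)
  }
  # matrix rows agree with the single-pair builders
  m <- pairFeatureMatrix(ds, "superfamily", vocab, pairs)
  single <- pairVector(
    domainVector("R1", domainHits(ds), vocab, "receptor", "superfamily"),
    domainVector("L1", domainHits(ds), vocab, "ligand", "superfamily"))
  expect_equal(unname(m["R1|L1", ]), unname(as.numeric(single)))
  # layouts are deterministic across calls
  expect_identical(m, pairFeatureMatrix(ds, "superfamily", vocab, pairs))
  expect_error(pairFeatureMatrix(ds, "domain", NULL, pairs), "DomainVocabulary")
})

test_that("feature matrices export to TSV with named columns", {
  ds <- tinyDataset()
  vocab <- buildVocabulary(domainHits(ds), proteinRoles(ds))
  m <- pairFeatureMatrix(ds, "superfamily", vocab)
  p <- tempfile(fileext = ".tsv")
  writeFeatureMatrix(m, p)
  back <- read.delim(p, check.names = FALSE)
  expect_identical(back$pair, rownames(m))
  expect_equal(as.matrix(back[, -1]), m, ignore_attr = TRUE)
})
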