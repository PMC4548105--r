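# Fixture builders shared by the unit tests. Everything is constructed in
# code so the suite carries no data files.

# Tiny two-role dataset with hand-written sequences and domain annotations.
tinyDataset <- function() {
  seqs <- Biostrings::AAStringSet(c(
    R1 = "MKVLACDEFGHIKLMNPQRS", R2 = "ACDEACDEACDEACDEACDE",
    L1 = "TVWYTVWYTVWYTVWYTVWY", L2 = "GGGGGGGGGGHHHHHHHHHH",
    L3 = "MKVLMKVLMKVLMKVLMKVL"))
  roles <- c("receptor", "receptor", "ligand", "ligand", "ligand")
  hits <- data.frame(
    protein_id = c("R1", "R1", "R2", "L1", "L2", "L3"),
    domain_acc = c("d1", "d2", "d1", "d3", "d4", "d3"),
    superfamily_acc = c("SF1", "SF1", "SF1", "SF2", "SF3", "SF2"),
    e_value = rep(1e-12, 6),
    start = c(1L, 5L, 1L, 1L, 1L, 1L),
    end = c(4L, 10L, 8L, 8L, 8L, 8L),
    stringsAsFactors = FALSE)
  pairs <- data.frame(receptor_id = c("R1", "R2"),
                      ligand_id = c("L1", "L3"),
                      label = c(1L, 1L), stringsAsFactors = FALSE)
  PairDataset(seqs, roles, hits = hits, pairs = pairs)
}

# Random hit table + roles for property-style checks of the binary
# encodings; draws depend on the caller's RNG state.
randomHitWorld <- function(nProteins = 6, nDomains = 8, nSuperfamilies = 3) {
  doms <- sprintf("d%02d", seq_len(nDomains))
  map <- setNames(sample(sprintf("SF%d", seq_len(nSuperfamilies)),
                         nDomains, replace = TRUE), doms)
  ids <- sprintf("P%02d", seq_len(nProteins))
  roles <- setNames(sample(c("receptor", "ligand"), nProteins,
                           replace = TRUE), ids)
  rows <- lapply(ids, function(id) {
    k <- sample.int(nDomains, 1)
    d <- sample(doms, k)
    data.frame(protein_id = id, domain_acc = d,
               superfamily_acc = unname(map[d]), e_value = 1e-10,
               start = 1L, end = 10L, stringsAsFactors = FALSE)
  })
  list(hits = do.call(rbind, rows), roles = roles, map = map)
}

# Linearly separable toy: positives around (1,1), negatives around (0,0).
separableToy <- function(nPos = 10, nNeg = 10, sd = 0.05, seed = 42) {
  withr::with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(2 * nPos, 1, sd), ncol = 2),
               matrix(stats::rnorm(2 * nNeg, 0, sd), ncol = 2))
    colnames(X) <- c("f1", "f2")
    list(X = X, y = c(rep(1L, nPos), rep(0L, nNeg)))
  })
}

# Independent AUC oracle: exhaustive positive-negative concordance with
# ties counted one half.
bruteForceAuc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
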