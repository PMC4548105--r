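#' @include AllClasses.R
NULL

# Identity substitution matrix over the full uppercase alphabet (ambiguity
# codes score 0 against everything but themselves; scoring is only used to
# produce the alignment, identity is recomputed column-wise).
.identityMatrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters27 <- c(LETTERS, "*")
      mm <- matrix(0, 27, 27, dimnames = list(letters27, letters27))
      diag(mm) <- 1
      m <<- mm
    }
    m
  }
})

#' Fraction of identical columns in an end-to-end global alignment
#'
#' Aligns the two sequences end to end (Needleman-Wunsch, match = 1,
#' mismatch = 0, linear gap cost) and returns the number of identical
#' columns divided by the total number of alignment columns. The global
#' alignment realizes the "full-length coverage" reading of the clustering
#' criterion, so no separate coverage check is needed.
#'
#' @param seqA,seqB Nonempty amino-acid strings (or `AAString`s).
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @examples
#' pairwiseIdentity("ACDEF", "ACDFF")   # 0.8
#' @export
pairwiseIdentity <- function(seqA, seqB) {
  seqA <- toupper(as.character(seqA)); seqB <- toupper(as.character(seqB))
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be nonempty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    substitutionMatrix = .identityMatrix(),
    gapOpening = 0, gapExtension = 1, type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

#' Greedy redundancy clustering at an identity threshold
#'
#' Stand-in for BLASTclust-style redundancy reduction: proteins (all of one
#' role) are sorted by decreasing length, ties broken by id, and processed in
#' order. Each protein joins the first existing cluster whose representative
#' it matches at `identityThreshold` or above under the end-to-end global
#' alignment of [pairwiseIdentity()]; otherwise it founds a new cluster and
#' becomes its representative. This honors the same thresholds as the
#' original clustering tool but is not a bit-exact clone of it.
#'
#' @param seqs Named `AAStringSet` (or named character vector) of proteins
#'   sharing one role.
#' @param identityThreshold Minimum identity fraction for cluster membership
#'   (default 0.80, i.e. 80% identity over the full-length alignment).
#' @return A list with `clusters` (list of id vectors, representative first)
#'   and `representatives` (character vector, one id per cluster).
#' @export
clusterRedundant <- function(seqs, identityThreshold = 0.80) {
  stopifnot(identityThreshold > 0, identityThreshold <= 1)
  ids <- names(seqs)
  seqChr <- stats::setNames(toupper(as.character(seqs)), ids)
  if (length(seqChr) && (is.null(ids) || any(!nzchar(ids))))
    stop("sequences must be named by protein id")
  ord <- order(-nchar(seqChr), ids)
  reps <- character(0)
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (pairwiseIdentity(seqChr[i], seqChr[reps[ci]]) >= identityThreshold) {
        clusters[[ci]] <- c(clusters[[ci]], ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[i])
      clusters[[length(clusters) + 1]] <- ids[i]
    }
  }
  list(clusters = clusters, representatives = reps)
}

#' Remove redundant proteins from a dataset, one representative per cluster
#'
#' Clusters receptors and ligands separately with [clusterRedundant()] and
#' keeps the cluster representatives only, dropping pairs that involve a
#' removed protein.
#'
#' @param dataset A [PairDataset-class].
#' @param identityThreshold Forwarded to [clusterRedundant()].
#' @return A reduced [PairDataset-class].
#' @export
reduceRedundancy <- function(dataset, identityThreshold = 0.80) {
  keep <- character(0)
  for (role in .PROTEIN_ROLES) {
    seqs <- proteins(dataset, role)
    if (length(seqs))
      keep <- c(keep, clusterRedundant(seqs, identityThreshold)$representatives)
  }
  roles <- proteinRoles(dataset)
  pr <- proteins(dataset)[keep]
  hits <- domainHits(dataset)
  hits <- hits[hits$protein_id %in% keep, , drop = FALSE]
  rownames(hits) <- NULL
  pairs <- pairExamples(dataset)
  pairs <- pairs[pairs$receptor_id %in% keep & pairs$ligand_id %in% keep, ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  PairDataset(pr, unname(roles[keep]), hits = hits, pairs = pairs)
}

#' Enumerate all non-interacting pairs
#'
#' Negative examples are the full receptor x ligand cross product minus the
#' known positive pairs, enumerated exhaustively (not sampled) in
#' lexicographic (receptor_id, ligand_id) order. With 34 receptors, 67
#' ligands and 95 positives this yields 34 * 67 - 95 = 2183 negatives.
#'
#' @param receptorIds,ligandIds Character vectors of ids.
#' @param positives `data.frame` with `receptor_id`, `ligand_id` columns;
#'   every referenced id must be listed.
#' @return `data.frame` of pairs with `label = 0`.
#' @export
generateNegatives <- function(receptorIds, ligandIds, positives = .emptyPairs()) {
  stopifnot(!anyDuplicated(receptorIds), !anyDuplicated(ligandIds))
  if (nrow(positives) > 0) {
    bad <- c(setdiff(positives$receptor_id, receptorIds),
             setdiff(positives$ligand_id, ligandIds))
    if (length(bad))
      stop("positive pair references unknown id(s): ",
           paste(unique(bad), collapse = ", "))
  }
  rs <- sort(receptorIds)
  ls <- sort(ligandIds)
  all <- expand.grid(ligand_id = ls, receptor_id = rs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  all <- all[, c("receptor_id", "ligand_id")]
  key <- paste(all$receptor_id, all$ligand_id, sep = "\r")
  poskey <- paste(positives$receptor_id, positives$ligand_id, sep = "\r")
  if (anyDuplicated(poskey)) stop("duplicate positive pair(s)")
  neg <- all[!key %in% poskey, , drop = FALSE]
  rownames(neg) <- NULL
  neg$label <- rep(0L, nrow(neg))
  neg
}

#' Attach the full labelled pair set to a dataset
#'
#' Takes the positive pairs already in `dataset` and adds the exhaustively
#' enumerated negatives, giving the all-against-all labelled dataset the
#' classifier is trained on.
#'
#' @param dataset A [PairDataset-class] whose `pairs` hold positives only.
#' @return The dataset with positives plus all negatives.
#' @export
buildPairDataset <- function(dataset) {
  roles <- proteinRoles(dataset)
  pos <- pairExamples(dataset)
  pos <- pos[pos$label == 1L, , drop = FALSE]
  neg <- generateNegatives(names(roles)[roles == "receptor"],
                           names(roles)[roles == "ligand"], pos)
  pairs <- rbind(pos, neg)
  rownames(pairs) <- NULL
  PairDataset(proteins(dataset), unname(roles), hits = domainHits(dataset),
              pairs = pairs)
}

#' Class weights proportional to the opposite class's size
#'
#' Compensates the positive/negative imbalance of all-against-all pair
#' datasets by penalizing misclassified positives `n_neg / n_pos` times more
#' than misclassified negatives.
#'
#' @param nPos,nNeg Positive class sizes (both >= 1).
#' @return Named numeric `c(pos = nNeg/nPos, neg = 1)`.
#' @examples
#' classWeights(95, 2183)   # pos ~ 22.98
#' @export
classWeights <- function(nPos, nNeg) {
  if (nPos < 1 || nNeg < 1) stop("both classes must be nonempty")
  c(pos = nNeg / nPos, neg = 1)
}

# Deterministic per-class shuffling used by the split helpers. Uses R's RNG
# under a local seed so callers' RNG state is untouched.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified k-fold assignment
#'
#' Assigns each example to one of `nFolds` folds so that per-fold class
#' counts differ from the ideal by at most one, deterministically for a
#' given seed. 95 positives split 5 ways give folds of 19 positives each;
#' 2183 negatives give folds of 436 or 437.
#'
#' @param labels Binary (0/1) label vector.
#' @param nFolds Number of folds (default 5).
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold ids in `1..nFolds`, parallel to `labels`.
#' @export
stratifiedKfold <- function(labels, nFolds = 5, seed = 1) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  if (min(table(factor(labels, levels = c(0, 1)))) < nFolds)
    stop("need at least ", nFolds, " examples per class")
  fold <- integer(length(labels))
  .withSeed(seed, {
    for (cl in c(1L, 0L)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}

#' Stratified holdout split
#'
#' Reserves `floor(fraction * class size)` examples of each class for
#' testing (20% of 95 positives = 19, 20% of 2183 negatives = 436) and
#' returns the index sets, deterministically for a given seed.
#'
#' @param labels Binary (0/1) label vector.
#' @param fraction Holdout fraction in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
holdoutSplit <- function(labels, fraction = 0.2, seed = 1) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), fraction > 0, fraction < 1)
  test <- integer(0)
  .withSeed(seed, {
    for (cl in c(1L, 0L)) {
      idx <- which(labels == cl)
      nTest <- floor(fraction * length(idx))
      if (nTest < 1 || nTest >= length(idx))
        stop("degenerate split for class ", cl,
             " (holdout would be empty or exhaustive)")
      test <- c(test, sample(idx, nTest))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Write a dataset manifest
#'
#' @param dataset A [PairDataset-class] with labelled pairs.
#' @param path Output TSV path.
#' @param fold Optional integer fold assignment (from [stratifiedKfold()]);
#'   written as a `fold` column when given.
#' @return The path, invisibly.
#' @export
writeManifest <- function(dataset, path, fold = NULL) {
  pairs <- pairExamples(dataset)
  if (!is.null(fold)) {
    stopifnot(length(fold) == nrow(pairs))
    pairs$fold <- as.integer(fold)
  }
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
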