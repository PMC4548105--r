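#' @include AllClasses.R
NULL

#' Synthetic dataset generator configuration
#'
#' Defaults emulate the shape of a curated RTK-ligand interaction dataset:
#' 34 receptors and 67 ligands; 80 receptor / 98 ligand domain types grouped
#' into 26 / 68 superfamilies; 2 to 5 domains per protein; a positive rate
#' targeting 95 interacting pairs out of the 34 x 67 cross product. True
#' labels are driven by a compatibility set of (receptor superfamily, ligand
#' superfamily) combinations — a pair interacts iff it carries at least one
#' compatible combination — mirroring the observation that superfamily-level
#' features are the most informative. Residue composition is tilted per
#' domain so k-mer features carry a tunable echo of the domain signal.
#'
#' @param nReceptors,nLigands Numbers of proteins per role.
#' @param nReceptorDomains,nLigandDomains Domain-vocabulary sizes per role.
#' @param nReceptorSuperfamilies,nLigandSuperfamilies Superfamily counts
#'   (each at most the corresponding domain count; every domain belongs to
#'   exactly one superfamily).
#' @param domainsPerProtein Integer range `c(min, max)` of domains drawn
#'   (without replacement) per protein.
#' @param compatibility Two-column matrix/data.frame of compatible
#'   (receptor superfamily, ligand superfamily) accessions, or `NULL` to
#'   calibrate a set greedily toward `positiveRateTarget`.
#' @param positiveRateTarget Target fraction of interacting pairs among the
#'   full cross product (default 95 / 2278).
#' @param labelNoise Probability in `[0, 0.5)` of flipping each observed
#'   label (default 0: labels follow the compatibility rule exactly).
#' @param sequenceLength Integer range `c(min, max)` of sequence lengths.
#' @param compositionBias Strength in `[0, 1]` of the per-domain residue
#'   composition tilt (0 = uniform residues, domain signal absent from
#'   k-mer features).
#' @param seed Integer seed; all draws flow from it.
#' @return A list of class `generatorConfig`.
#' @export
generatorConfig <- function(nReceptors = 34, nLigands = 67,
                            nReceptorDomains = 80, nLigandDomains = 98,
                            nReceptorSuperfamilies = 26,
                            nLigandSuperfamilies = 68,
                            domainsPerProtein = c(2, 5),
                            compatibility = NULL,
                            positiveRateTarget = 95 / (34 * 67),
                            labelNoise = 0,
                            sequenceLength = c(200, 1200),
                            compositionBias = 0.5, seed = 1L) {
  stopifnot(nReceptors >= 1, nLigands >= 1,
            nReceptorSuperfamilies <= nReceptorDomains,
            nLigandSuperfamilies <= nLigandDomains,
            length(domainsPerProtein) == 2,
            domainsPerProtein[1] >= 1,
            domainsPerProtein[2] >= domainsPerProtein[1],
            domainsPerProtein[2] <= min(nReceptorDomains, nLigandDomains),
            positiveRateTarget >= 0, positiveRateTarget < 1,
            labelNoise >= 0, labelNoise < 0.5,
            length(sequenceLength) == 2, sequenceLength[1] >= 10,
            sequenceLength[2] >= sequenceLength[1],
            compositionBias >= 0, compositionBias <= 1)
  structure(list(
    nReceptors = nReceptors, nLigands = nLigands,
    nReceptorDomains = nReceptorDomains, nLigandDomains = nLigandDomains,
    nReceptorSuperfamilies = nReceptorSuperfamilies,
    nLigandSuperfamilies = nLigandSuperfamilies,
    domainsPerProtein = as.integer(domainsPerProtein),
    compatibility = compatibility,
    positiveRateTarget = positiveRateTarget, labelNoise = labelNoise,
    sequenceLength = as.integer(sequenceLength),
    compositionBias = compositionBias, seed = as.integer(seed)
  ), class = "generatorConfig")
}

.padIds <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))

# Greedy calibration of the compatibility set: add the (receptor SF, ligand
# SF) combination with the largest marginal gain that does not overshoot the
# target count; when none fits, take one overshooting combination iff it
# lands closer to the target than stopping short.
.calibrateCompatibility <- function(recSF, ligSF, target) {
  rsfs <- sort(unique(unlist(recSF)))
  lsfs <- sort(unique(unlist(ligSF)))
  cand <- expand.grid(r = rsfs, l = lsfs, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  recHas <- vapply(rsfs, function(s)
    vapply(recSF, function(x) s %in% x, logical(1)), logical(length(recSF)))
  ligHas <- vapply(lsfs, function(s)
    vapply(ligSF, function(x) s %in% x, logical(1)), logical(length(ligSF)))
  activated <- function(i) outer(recHas[, cand$r[i]], ligHas[, cand$l[i]], "&")
  pos <- matrix(FALSE, length(recSF), length(ligSF))
  used <- logical(nrow(cand))
  chosen <- integer(0)
  while (sum(pos) < target) {
    gains <- vapply(seq_len(nrow(cand)), function(i) {
      if (used[i]) return(0L)
      sum(activated(i) & !pos)
    }, integer(1))
    room <- target - sum(pos)
    fit <- which(gains > 0 & gains <= room)
    if (length(fit)) {
      i <- fit[which.max(gains[fit])]
    } else {
      over <- which(gains > 0)
      if (!length(over)) break
      i <- over[which.min(gains[over])]
      # overshoot only if it lands closer to the target than stopping does;
      # always take one combination rather than none
      if (length(chosen) > 0 && gains[i] - room >= room) break
    }
    pos <- pos | activated(i)
    used[i] <- TRUE
    chosen <- c(chosen, i)
  }
  cbind(receptor_superfamily = cand$r[chosen],
        ligand_superfamily = cand$l[chosen])
}

#' Generate a synthetic receptor-ligand dataset bundle
#'
#' Draws domain vocabularies, per-protein domain annotations, sequences
#' whose residue composition is tilted toward their domains' preferences,
#' and interaction labels from the superfamily compatibility rule (flipped
#' with probability `labelNoise`). Everything is seeded: the same config
#' yields an identical bundle. If no compatibility set is supplied, one is
#' calibrated greedily toward the target positive rate; when the target
#' count cannot be hit exactly the achieved count is reported with a
#' warning.
#'
#' @param config A [generatorConfig()].
#' @return A list of class `SynthBundle` with elements `dataset` (a
#'   [PairDataset-class] holding proteins, hits and the observed positive
#'   pairs), `groundTruth` (`data.frame` over the full cross product:
#'   `receptor_id`, `ligand_id`, `true_label` — the noise-free
#'   Bayes-optimal label — and `observed_label`), `compatibility` (the
#'   set actually used), `domainSuperfamily` (named mapping), and `config`.
#' @export
generateBundle <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "generatorConfig"))
  .withSeed(config$seed, {
    recIds <- .padIds("R", config$nReceptors)
    ligIds <- .padIds("L", config$nLigands)
    recDoms <- .padIds("RD", config$nReceptorDomains)
    ligDoms <- .padIds("LD", config$nLigandDomains)
    recSFs <- .padIds("RSF", config$nReceptorSuperfamilies)
    ligSFs <- .padIds("LSF", config$nLigandSuperfamilies)
    # partition domains among superfamilies (every superfamily nonempty)
    recMap <- stats::setNames(
      sample(rep_len(recSFs, length(recDoms))), recDoms)
    ligMap <- stats::setNames(
      sample(rep_len(ligSFs, length(ligDoms))), ligDoms)
    drawDomains <- function(ids, vocabulary) {
      stats::setNames(lapply(ids, function(id) {
        k <- sample(seq(config$domainsPerProtein[1],
                        config$domainsPerProtein[2]), 1)
        sort(sample(vocabulary, k))
      }), ids)
    }
    recAnn <- drawDomains(recIds, recDoms)
    ligAnn <- drawDomains(ligIds, ligDoms)
    recSFof <- lapply(recAnn, function(d) unique(unname(recMap[d])))
    ligSFof <- lapply(ligAnn, function(d) unique(unname(ligMap[d])))
    # compatibility set: supplied or calibrated toward the target count
    target <- round(config$positiveRateTarget *
                    config$nReceptors * config$nLigands)
    compat <- config$compatibility
    if (is.null(compat)) {
      compat <- if (target == 0) matrix(character(0), 0, 2)
        else .calibrateCompatibility(recSFof, ligSFof, target)
    } else {
      compat <- as.matrix(compat)
      if (nrow(compat) == 0 && config$positiveRateTarget > 0)
        stop("compatibility must be nonempty when positiveRateTarget > 0")
    }
    trueLab <- matrix(0L, config$nReceptors, config$nLigands,
                      dimnames = list(recIds, ligIds))
    if (nrow(compat) > 0)
      for (i in seq_len(nrow(compat))) {
        rs <- vapply(recSFof, function(x) compat[i, 1] %in% x, logical(1))
        ls <- vapply(ligSFof, function(x) compat[i, 2] %in% x, logical(1))
        trueLab[rs, ls] <- 1L
      }
    nTrue <- sum(trueLab)
    if (is.null(config$compatibility) && nTrue != target)
      warning("calibrated compatibility achieves ", nTrue,
              " positives (target ", target, ")")
    flip <- matrix(stats::runif(length(trueLab)) < config$labelNoise,
                   nrow(trueLab), ncol(trueLab))
    obsLab <- trueLab
    obsLab[flip] <- 1L - trueLab[flip]
    # per-domain residue preference: Dirichlet(1) over the canonical 20
    allDoms <- c(recDoms, ligDoms)
    pref <- vapply(allDoms, function(d) {
      g <- stats::rgamma(20, 1)
      g / sum(g)
    }, numeric(20))
    rownames(pref) <- .CANONICAL_AA
    drawSeq <- function(doms) {
      len <- sample(seq(config$sequenceLength[1], config$sequenceLength[2]), 1)
      p <- (1 - config$compositionBias) / 20 +
        config$compositionBias * rowMeans(pref[, doms, drop = FALSE])
      paste(sample(.CANONICAL_AA, len, replace = TRUE, prob = p),
            collapse = "")
    }
    seqs <- c(vapply(recIds, function(id) drawSeq(recAnn[[id]]), character(1)),
              vapply(ligIds, function(id) drawSeq(ligAnn[[id]]), character(1)))
    proteins <- Biostrings::AAStringSet(seqs)
    roles <- c(rep("receptor", config$nReceptors),
               rep("ligand", config$nLigands))
    # domain-hit table: one row per (protein, domain), E-values comfortably
    # below the standard 1e-8 retention cutoff, plausible coordinates
    fullMap <- c(recMap, ligMap)
    ann <- c(recAnn, ligAnn)
    hitRows <- lapply(names(ann), function(id) {
      doms <- ann[[id]]
      len <- nchar(seqs[[id]])
      span <- pmin(len, 40L + sample.int(60L, length(doms), replace = TRUE))
      start <- vapply(span, function(s)
        sample.int(len - s + 1L, 1), integer(1))
      data.frame(protein_id = id, domain_acc = doms,
                 superfamily_acc = unname(fullMap[doms]),
                 e_value = 10^-stats::runif(length(doms), 10, 50),
                 start = start, end = start + span - 1L,
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hitRows)
    gt <- expand.grid(ligand_id = ligIds, receptor_id = recIds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gt <- gt[, c("receptor_id", "ligand_id")]
    gt$true_label <- trueLab[cbind(gt$receptor_id, gt$ligand_id)]
    gt$observed_label <- obsLab[cbind(gt$receptor_id, gt$ligand_id)]
    positives <- gt[gt$observed_label == 1L,
                    c("receptor_id", "ligand_id"), drop = FALSE]
    positives$label <- rep(1L, nrow(positives))
    rownames(positives) <- NULL
    dataset <- PairDataset(proteins, roles, hits = hits, pairs = positives)
    structure(list(dataset = dataset, groundTruth = gt,
                   compatibility = compat, domainSuperfamily = fullMap,
                   config = config),
              class = "SynthBundle")
  })
}

#' Write a synthetic bundle to disk in the standard formats
#'
#' Emits `receptors.fasta`, `ligands.fasta`, `domain_hits.tsv`,
#' `positives.tsv` and `ground_truth.tsv` into a directory, all readable
#' back through the package's readers. Output is byte-identical for
#' identical bundles.
#'
#' @param bundle A `SynthBundle` from [generateBundle()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "SynthBundle"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  ds <- bundle$dataset
  Biostrings::writeXStringSet(proteins(ds, "receptor"),
                              file.path(dir, "receptors.fasta"))
  Biostrings::writeXStringSet(proteins(ds, "ligand"),
                              file.path(dir, "ligands.fasta"))
  hits <- domainHits(ds)
  hits$e_value <- sprintf("%.6e", hits$e_value)
  utils::write.table(hits, file.path(dir, "domain_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pos <- pairExamples(ds)[, c("receptor_id", "ligand_id"), drop = FALSE]
  utils::write.table(pos, file.path(dir, "positives.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$groundTruth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a synthetic bundle directory back into a dataset
#'
#' @param dir Directory written by [writeBundle()].
#' @param eCutoff E-value cutoff applied on re-read (default 1e-8).
#' @return A list with `dataset` (a [PairDataset-class], positives only) and
#'   `groundTruth`.
#' @export
readBundle <- function(dir, eCutoff = 1e-8) {
  dataset <- loadPairDataset(
    file.path(dir, "receptors.fasta"), file.path(dir, "ligands.fasta"),
    hitsPath = file.path(dir, "domain_hits.tsv"),
    pairsPath = file.path(dir, "positives.tsv"), eCutoff = eCutoff)
  gtPath <- file.path(dir, "ground_truth.tsv")
  gt <- if (file.exists(gtPath))
    utils::read.delim(gtPath, stringsAsFactors = FALSE) else NULL
  list(dataset = dataset, groundTruth = gt)
}
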