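#' @include AllClasses.R
NULL

#' Feature vectors
#'
#' Feature vectors are named numeric vectors carrying a `recipe` attribute
#' (`"kmer1"`, `"kmer2"`, `"domain"`, `"superfamily"` or `"composite"`).
#' The recipe travels with the vector so that pair concatenation and
#' composition can refuse to mix incompatible representations.
#'
#' @param values Numeric vector.
#' @param names Per-dimension labels (same length).
#' @param recipe Recipe identifier.
#' @return A named numeric vector of class `FeatureVector`.
#' @export
featureVector <- function(values, names, recipe) {
  stopifnot(length(values) == length(names), recipe %in% .RECIPES)
  v <- as.numeric(values)
  base::names(v) <- names
  attr(v, "recipe") <- recipe
  class(v) <- c("FeatureVector", "numeric")
  v
}

#' @rdname featureVector
#' @param x A `FeatureVector`.
#' @export
recipeOf <- function(x) attr(x, "recipe")

# prefixed dimension labels; zero-length vectors contribute no labels
# (paste0 would otherwise pad a zero-length argument to "")
.prefixNames <- function(prefix, x) {
  if (length(x) == 0) return(character(0))
  nm <- if (is.null(names(x))) character(length(x)) else names(x)
  paste0(prefix, nm)
}

#' All k-mers over the canonical amino-acid alphabet, in lexicographic order
#'
#' @param k k-mer length (1 or 2 in the standard recipes; any k >= 1 works).
#' @return Character vector of length `20^k` defining the fixed coordinate
#'   order of k-mer feature vectors.
#' @export
kmerAlphabet <- function(k) {
  stopifnot(k >= 1, k == floor(k))
  out <- .CANONICAL_AA
  if (k > 1)
    for (i in seq_len(k - 1))
      out <- as.vector(t(outer(out, .CANONICAL_AA, paste0)))
  out
}

#' k-mer composition vector of one sequence
#'
#' Slides a window of length `k` along the sequence and counts each k-mer.
#' Windows containing any non-canonical letter (ambiguity codes such as X or
#' B) are excluded from both the numerator and the denominator, so the
#' returned values are relative frequencies over valid windows and sum to 1
#' for clean sequences. If no valid window exists the vector is all zeros and
#' a warning is raised.
#'
#' @param sequence Amino-acid string (or `AAString`).
#' @param k k-mer length (the standard recipes use 1 and 2).
#' @return A `FeatureVector` of dimension `20^k` with recipe `"kmer1"` /
#'   `"kmer2"` (or `"kmer<k>"` for other k).
#' @examples
#' kmerVector("AAAA", 1)[["A"]]        # 1
#' kmerVector("ACDC", 2)[["AC"]]       # 1/3
#' @export
kmerVector <- function(sequence, k) {
  sequence <- toupper(as.character(sequence))
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a single nonempty string")
  if (k < 1 || k != floor(k)) stop("k must be a positive integer")
  alph <- kmerAlphabet(k)
  n <- nchar(sequence)
  counts <- stats::setNames(numeric(length(alph)), alph)
  if (n >= k) {
    windows <- substring(sequence, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
    valid <- windows[windows %in% alph]
    if (length(valid)) {
      tab <- table(valid)
      counts[names(tab)] <- as.numeric(tab) / length(valid)
    }
  }
  if (sum(counts) == 0)
    warning("no valid k-mer window (k=", k, ") in sequence; all-zero vector")
  featureVector(counts, alph, paste0("kmer", k))
}

#' Build the domain/superfamily vocabulary from filtered hits
#'
#' Collects the distinct domain accessions seen on receptor-role proteins and
#' on ligand-role proteins separately, together with the superfamilies those
#' domains belong to, and sorts each list lexicographically. The sorted lists
#' define the (deterministic) coordinate order of the binary encodings. A
#' domain accession annotated with two different superfamilies anywhere in
#' the hit set is an inconsistent annotation and raises an error.
#'
#' @param hits Domain-hit `data.frame` ([readDomainHits()] layout).
#' @param roles Named character vector mapping protein id to role, e.g.
#'   `proteinRoles(dataset)`.
#' @return A [DomainVocabulary-class].
#' @export
buildVocabulary <- function(hits, roles) {
  if (nrow(hits) > 0) {
    unknown <- setdiff(hits$protein_id, names(roles))
    if (length(unknown))
      stop("hits reference protein(s) without a role: ",
           paste(unique(unknown), collapse = ", "))
    mapTab <- unique(hits[, c("domain_acc", "superfamily_acc")])
    if (anyDuplicated(mapTab$domain_acc)) {
      bad <- mapTab$domain_acc[duplicated(mapTab$domain_acc)][1]
      stop("domain ", bad, " is annotated with more than one superfamily")
    }
    map <- stats::setNames(mapTab$superfamily_acc, mapTab$domain_acc)
    hitRole <- roles[hits$protein_id]
    rd <- sort(unique(hits$domain_acc[hitRole == "receptor"]))
    ld <- sort(unique(hits$domain_acc[hitRole == "ligand"]))
    new("DomainVocabulary",
        receptorDomains = rd, ligandDomains = ld,
        receptorSuperfamilies = sort(unique(unname(map[rd]))),
        ligandSuperfamilies = sort(unique(unname(map[ld]))),
        domainToSuperfamily = map)
  } else {
    new("DomainVocabulary",
        receptorDomains = character(0), ligandDomains = character(0),
        receptorSuperfamilies = character(0),
        ligandSuperfamilies = character(0),
        domainToSuperfamily = stats::setNames(character(0), character(0)))
  }
}

#' Binary domain- or superfamily-presence vector of one protein
#'
#' Encodes presence/absence: a coordinate is 1 if the protein carries at
#' least one retained hit of that domain (or of any domain in that
#' superfamily), else 0. Two domains of the same superfamily still yield a
#' single 1 at superfamily level. Domain types on the protein that are absent
#' from the vocabulary (routine when the vocabulary was built on a training
#' fold only) are dropped with a log message.
#'
#' @param proteinId Protein identifier.
#' @param hits Domain-hit `data.frame` (already E-value filtered).
#' @param vocab A [DomainVocabulary-class].
#' @param role The protein's role (`"receptor"` or `"ligand"`).
#' @param level `"domain"` or `"superfamily"`.
#' @return A binary `FeatureVector` over the role's type list at that level.
#' @export
domainVector <- function(proteinId, hits, vocab, role,
                         level = c("domain", "superfamily")) {
  level <- match.arg(level)
  if (!role %in% .PROTEIN_ROLES)
    stop("unknown protein role: ", role)
  types <- vocabTypes(vocab, role, level)
  mine <- unique(hits$domain_acc[hits$protein_id == proteinId])
  if (level == "superfamily") {
    map <- domainToSuperfamily(vocab)
    known <- mine[mine %in% names(map)]
    if (length(known) < length(mine))
      message("domainVector: dropping domain type(s) absent from vocabulary on ",
              proteinId, ": ", paste(setdiff(mine, known), collapse = ", "))
    present <- unique(unname(map[known]))
  } else {
    present <- mine[mine %in% types]
    if (length(present) < length(mine))
      message("domainVector: dropping domain type(s) absent from vocabulary on ",
              proteinId, ": ", paste(setdiff(mine, present), collapse = ", "))
  }
  featureVector(as.numeric(types %in% present), types, level)
}

#' Concatenate receptor and ligand feature blocks into one pair vector
#'
#' The SVM classifies pairs, so per-protein vectors are concatenated:
#' receptor block first, then ligand block. Both blocks must come from the
#' same recipe. Dimension examples with the standard recipes: 1-mer pairs
#' have 20 + 20 = 40 dimensions, 2-mer pairs 400 + 400 = 800; domain-level
#' and superfamily-level pair dimensions are the summed vocabulary sizes.
#'
#' @param receptorVec,ligandVec `FeatureVector`s of the same recipe.
#' @return A `FeatureVector`; names are prefixed `R.` / `L.`.
#' @export
pairVector <- function(receptorVec, ligandVec) {
  ra <- recipeOf(receptorVec); la <- recipeOf(ligandVec)
  if (!identical(ra, la))
    stop("recipe mismatch: receptor block is ", ra, ", ligand block is ", la)
  featureVector(c(as.numeric(receptorVec), as.numeric(ligandVec)),
                c(.prefixNames("R.", receptorVec),
                  .prefixNames("L.", ligandVec)),
                ra)
}

#' Concatenate two pair-level vectors into a composite vector
#'
#' Builds the composite representation by concatenating two different
#' pair-level encodings of the same pair (the standard composite is
#' 2-mer + superfamily-level, 800 + 94 dimensions in the reference setup).
#' Block order is fixed: first argument first.
#'
#' @param vecA,vecB Pair-level `FeatureVector`s over the same pair.
#' @return A `FeatureVector` with recipe `"composite"`.
#' @export
compositeVector <- function(vecA, vecB) {
  featureVector(c(as.numeric(vecA), as.numeric(vecB)),
                c(.prefixNames(paste0(recipeOf(vecA), "."), vecA),
                  .prefixNames(paste0(recipeOf(vecB), "."), vecB)),
                "composite")
}

.kmerMatrix <- function(seqs, k) {
  m <- t(vapply(as.character(seqs), function(s)
    as.numeric(suppressWarnings(kmerVector(s, k))),
    numeric(20^k)))
  colnames(m) <- kmerAlphabet(k)
  rownames(m) <- names(seqs)
  m
}

.domainMatrix <- function(ids, hits, vocab, role, level) {
  types <- vocabTypes(vocab, role, level)
  m <- matrix(0, nrow = length(ids), ncol = length(types),
              dimnames = list(ids, types))
  if (length(types) == 0 || nrow(hits) == 0) return(m)
  h <- hits[hits$protein_id %in% ids, , drop = FALSE]
  if (level == "superfamily") {
    map <- domainToSuperfamily(vocab)
    h <- h[h$domain_acc %in% names(map), , drop = FALSE]
    acc <- unname(map[h$domain_acc])
  } else {
    acc <- h$domain_acc
  }
  keep <- acc %in% types
  idx <- cbind(match(h$protein_id[keep], ids), match(acc[keep], types))
  m[idx] <- 1
  m
}

#' Feature matrix for a set of pairs
#'
#' Vectorized counterpart of the single-pair builders: computes per-protein
#' feature blocks once and assembles the (pairs x features) numeric matrix
#' for any recipe. The `"composite"` recipe concatenates the 2-mer pair
#' block and the superfamily pair block.
#'
#' @param dataset A [PairDataset-class].
#' @param recipe One of `"kmer1"`, `"kmer2"`, `"domain"`, `"superfamily"`,
#'   `"composite"`.
#' @param vocab A [DomainVocabulary-class]; required for domain-based
#'   recipes. Pass the vocabulary built on the training portion to avoid
#'   information leakage across folds.
#' @param pairs `data.frame` of pairs to featurize (defaults to
#'   `pairExamples(dataset)`).
#' @return Numeric matrix with one row per pair (rownames
#'   `"<receptor>|<ligand>"`) and named feature columns.
#' @export
pairFeatureMatrix <- function(dataset, recipe, vocab = NULL, pairs = NULL) {
  recipe <- match.arg(recipe, .RECIPES)
  if (is.null(pairs)) pairs <- pairExamples(dataset)
  if (recipe == "composite") {
    m <- cbind(pairFeatureMatrix(dataset, "kmer2", vocab, pairs),
               pairFeatureMatrix(dataset, "superfamily", vocab, pairs))
    colnames(m) <- c(paste0("kmer2.", head(colnames(m), 800)),
                     paste0("superfamily.", tail(colnames(m), ncol(m) - 800)))
    rownames(m) <- paste(pairs$receptor_id, pairs$ligand_id, sep = "|")
    return(m)
  }
  roles <- proteinRoles(dataset)
  recIds <- names(roles)[roles == "receptor"]
  ligIds <- names(roles)[roles == "ligand"]
  if (recipe %in% c("kmer1", "kmer2")) {
    k <- if (recipe == "kmer1") 1 else 2
    seqs <- proteins(dataset)
    recBlock <- .kmerMatrix(seqs[recIds], k)
    ligBlock <- .kmerMatrix(seqs[ligIds], k)
  } else {
    if (is.null(vocab))
      stop("recipe '", recipe, "' needs a DomainVocabulary (see buildVocabulary)")
    hits <- domainHits(dataset)
    recBlock <- .domainMatrix(recIds, hits, vocab, "receptor", recipe)
    ligBlock <- .domainMatrix(ligIds, hits, vocab, "ligand", recipe)
  }
  m <- cbind(recBlock[match(pairs$receptor_id, recIds), , drop = FALSE],
             ligBlock[match(pairs$ligand_id, ligIds), , drop = FALSE])
  colnames(m) <- c(paste0("R.", colnames(recBlock)),
                   paste0("L.", colnames(ligBlock)))
  rownames(m) <- paste(pairs$receptor_id, pairs$ligand_id, sep = "|")
  m
}

#' Export a feature matrix as TSV
#'
#' @param m Matrix from [pairFeatureMatrix()].
#' @param path Output path. Rows are pairs, columns named features; the
#'   first column `pair` holds the `"<receptor>|<ligand>"` key.
#' @return The path, invisibly.
#' @export
writeFeatureMatrix <- function(m, path) {
  out <- data.frame(pair = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
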