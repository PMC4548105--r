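#' @import methods
#' @importClassesFrom Biostrings AAStringSet
NULL

.PROTEIN_ROLES <- c("receptor", "ligand")
.RECIPES <- c("kmer1", "kmer2", "domain", "superfamily", "composite")
.CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.MODEL_FORMAT_VERSION <- "rtkpair-model-1"

#' PairDataset: proteins, domain annotations and labelled pairs
#'
#' The central container of the package. It holds the two role sets
#' (receptor tyrosine kinases and their candidate growth-factor ligands) as an
#' [Biostrings::AAStringSet] with a per-protein role, the conserved-domain
#' hits retained after E-value filtering, and the labelled
#' (receptor, ligand) pair examples that the classifier is trained on.
#'
#' @slot proteins An `AAStringSet`; `names()` are unique protein identifiers.
#' @slot roles Character vector parallel to `proteins`, each entry
#'   `"receptor"` or `"ligand"`.
#' @slot hits `data.frame` of filtered domain hits with columns
#'   `protein_id`, `domain_acc`, `superfamily_acc`, `e_value`, `start`, `end`.
#' @slot pairs `data.frame` with columns `receptor_id`, `ligand_id`,
#'   `label` (1 = interacting, 0 = non-interacting).
#'
#' @seealso [PairDataset()], [readFasta()], [readDomainHits()], [readPairs()]
#' @exportClass PairDataset
setClass("PairDataset",
  representation(
    proteins = "AAStringSet",
    roles = "character",
    hits = "data.frame",
    pairs = "data.frame"
  )
)

.emptyHits <- function() {
  data.frame(
    protein_id = character(0), domain_acc = character(0),
    superfamily_acc = character(0), e_value = numeric(0),
    start = integer(0), end = integer(0), stringsAsFactors = FALSE
  )
}

.emptyPairs <- function() {
  data.frame(
    receptor_id = character(0), ligand_id = character(0),
    label = integer(0), stringsAsFactors = FALSE
  )
}

setValidity("PairDataset", function(object) {
  msgs <- character(0)
  ids <- names(object@proteins)
  if (length(object@proteins) > 0 && (is.null(ids) || any(!nzchar(ids))))
    msgs <- c(msgs, "all proteins must have nonempty identifiers")
  if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicate protein id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@roles) != length(object@proteins))
    msgs <- c(msgs, "roles must be parallel to proteins")
  if (!all(object@roles %in% .PROTEIN_ROLES))
    msgs <- c(msgs, "roles must be 'receptor' or 'ligand'")
  if (length(object@proteins) > 0 && any(Biostrings::width(object@proteins) < 1))
    msgs <- c(msgs, "all sequences must have length >= 1")
  hitCols <- c("protein_id", "domain_acc", "superfamily_acc",
               "e_value", "start", "end")
  if (!all(hitCols %in% colnames(object@hits)))
    msgs <- c(msgs, "hits must have columns protein_id, domain_acc, superfamily_acc, e_value, start, end")
  else {
    unknown <- setdiff(object@hits$protein_id, ids)
    if (length(unknown))
      msgs <- c(msgs, sprintf("domain hits reference unknown protein(s): %s",
        paste(unique(unknown), collapse = ", ")))
    if (any(object@hits$e_value < 0))
      msgs <- c(msgs, "E-values must be nonnegative")
    if (any(object@hits$start < 1 | object@hits$end < object@hits$start))
      msgs <- c(msgs, "hit coordinates must satisfy 1 <= start <= end")
  }
  pairCols <- c("receptor_id", "ligand_id", "label")
  if (!all(pairCols %in% colnames(object@pairs)))
    msgs <- c(msgs, "pairs must have columns receptor_id, ligand_id, label")
  else if (nrow(object@pairs) > 0) {
    key <- paste(object@pairs$receptor_id, object@pairs$ligand_id, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate (receptor_id, ligand_id) pair(s)")
    if (!all(object@pairs$label %in% c(0L, 1L)))
      msgs <- c(msgs, "pair labels must be 0 or 1")
    rid <- object@pairs$receptor_id
    lid <- object@pairs$ligand_id
    roleOf <- stats::setNames(object@roles, ids)
    if (!all(rid %in% ids) || !all(lid %in% ids))
      msgs <- c(msgs, "pairs reference unknown protein id(s)")
    else {
      if (!all(roleOf[rid] == "receptor"))
        msgs <- c(msgs, "receptor_id column contains non-receptor protein(s)")
      if (!all(roleOf[lid] == "ligand"))
        msgs <- c(msgs, "ligand_id column contains non-ligand protein(s)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PairDataset
#'
#' @param proteins `AAStringSet` of all proteins (both roles), named by id.
#' @param roles Character vector of `"receptor"`/`"ligand"`, one per protein.
#' @param hits Domain-hit `data.frame` as returned by [readDomainHits()].
#'   Defaults to no hits.
#' @param pairs Labelled pair `data.frame` (`receptor_id`, `ligand_id`,
#'   `label`). Defaults to no pairs.
#' @return A validated [PairDataset-class] object.
#' @examples
#' aa <- Biostrings::AAStringSet(c(R1 = "MKVLACDE", L1 = "ACDEFGHI"))
#' ds <- PairDataset(aa, c("receptor", "ligand"),
#'   pairs = data.frame(receptor_id = "R1", ligand_id = "L1", label = 1L))
#' ds
#' @export
PairDataset <- function(proteins, roles, hits = .emptyHits(), pairs = .emptyPairs()) {
  if (!is(proteins, "AAStringSet"))
    proteins <- Biostrings::AAStringSet(proteins)
  pairs$label <- as.integer(pairs$label)
  new("PairDataset", proteins = proteins, roles = as.character(roles),
      hits = hits, pairs = pairs)
}

#' DomainVocabulary: ordered domain and superfamily type lists
#'
#' Defines the coordinate system of the binary domain-presence encodings.
#' Receptor and ligand blocks keep separate vocabularies, so an accession
#' annotated on both roles occupies one coordinate in each block. Lists are
#' lexicographically sorted, which fixes the vector layout across runs.
#'
#' @slot receptorDomains,ligandDomains Sorted unique domain accessions seen
#'   on receptor-role / ligand-role proteins.
#' @slot receptorSuperfamilies,ligandSuperfamilies Sorted unique superfamily
#'   accessions for each role.
#' @slot domainToSuperfamily Named character vector mapping each listed
#'   domain accession to its (unique) superfamily accession.
#' @seealso [buildVocabulary()], [domainVector()]
#' @exportClass DomainVocabulary
setClass("DomainVocabulary",
  representation(
    receptorDomains = "character",
    ligandDomains = "character",
    receptorSuperfamilies = "character",
    ligandSuperfamilies = "character",
    domainToSuperfamily = "character"
  )
)

setValidity("DomainVocabulary", function(object) {
  msgs <- character(0)
  sortedUnique <- function(x) !anyDuplicated(x) && !is.unsorted(x)
  for (sl in c("receptorDomains", "ligandDomains",
               "receptorSuperfamilies", "ligandSuperfamilies"))
    if (!sortedUnique(slot(object, sl)))
      msgs <- c(msgs, sprintf("%s must be sorted and unique", sl))
  map <- object@domainToSuperfamily
  doms <- union(object@receptorDomains, object@ligandDomains)
  if (!all(doms %in% names(map)))
    msgs <- c(msgs, "domainToSuperfamily must cover every listed domain")
  else {
    if (!all(map[object@receptorDomains] %in% object@receptorSuperfamilies))
      msgs <- c(msgs, "receptor domain superfamilies missing from receptorSuperfamilies")
    if (!all(map[object@ligandDomains] %in% object@ligandSuperfamilies))
      msgs <- c(msgs, "ligand domain superfamilies missing from ligandSuperfamilies")
  }
  if (length(msgs)) msgs else TRUE
})

#' TrainedPairModel: a fitted class-weighted pair classifier
#'
#' Wraps a fitted C-SVM together with everything needed to reproduce its
#' feature space: the feature recipe, the domain vocabulary snapshot (for
#' domain-based recipes), the resolved hyperparameters and the class weights.
#' Decision values follow the convention that positive values predict an
#' interacting pair.
#'
#' @slot fit The underlying fitted `e1071::svm` object.
#' @slot recipe One of `"kmer1"`, `"kmer2"`, `"domain"`, `"superfamily"`,
#'   `"composite"`.
#' @slot config Resolved [svmConfig()] list (kernel, cost, gamma, seed).
#' @slot classWeights Named numeric `c(pos = , neg = )` misclassification
#'   weights used at fit time.
#' @slot vocabulary `DomainVocabulary` snapshot, or `NULL` for pure k-mer
#'   recipes.
#' @slot featureNames Column layout the model expects at prediction time.
#' @slot trainAUC Training AUC (resubstitution or inner-CV, see the caller).
#' @slot flipSign Internal: whether the libsvm decision-value orientation had
#'   to be flipped so that positive means "interacting".
#' @slot version Serialized-format version tag.
#' @exportClass TrainedPairModel
setClass("TrainedPairModel",
  representation(
    fit = "ANY",
    recipe = "character",
    config = "list",
    classWeights = "numeric",
    vocabulary = "ANY",
    featureNames = "character",
    trainAUC = "numeric",
    flipSign = "logical",
    version = "character"
  )
)

setValidity("TrainedPairModel", function(object) {
  msgs <- character(0)
  if (length(object@recipe) != 1 || !object@recipe %in% .RECIPES)
    msgs <- c(msgs, sprintf("recipe must be one of: %s",
                            paste(.RECIPES, collapse = ", ")))
  if (length(object@trainAUC) == 1 && !is.na(object@trainAUC) &&
      (object@trainAUC < 0 || object@trainAUC > 1))
    msgs <- c(msgs, "trainAUC must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' EvalReport: confusion counts, threshold metrics and ROC/AUC
#'
#' One evaluation run's results. Counts are stored as reals because averaged
#' reports (over cross-validation repeats) have fractional counts; they are
#' rounded only for display. Undefined metrics (e.g. precision when no pair
#' is predicted positive) are `NA` and printed as an em dash.
#'
#' @slot tp,fp,tn,fn Confusion counts (nonnegative reals).
#' @slot precision,recall,fMeasure Threshold metrics in `[0,1]`, `NA` when
#'   undefined.
#' @slot auc Area under the ROC curve.
#' @slot rocPoints Two-column matrix (`fpr`, `tpr`), monotone from (0,0)
#'   to (1,1); may have zero rows for averaged reports.
#' @seealso [evalReport()], [crossValidate()], [independentTest()]
#' @exportClass EvalReport
setClass("EvalReport",
  representation(
    tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric",
    precision = "numeric", recall = "numeric", fMeasure = "numeric",
    auc = "numeric", rocPoints = "matrix"
  )
)

setValidity("EvalReport", function(object) {
  msgs <- character(0)
  cnt <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(cnt) != 4 || any(cnt < 0))
    msgs <- c(msgs, "confusion counts must be four nonnegative numbers")
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    msgs <- c(msgs, "auc must lie in [0, 1]")
  if (nrow(object@rocPoints) > 0) {
    rp <- object@rocPoints
    if (ncol(rp) != 2 ||
        any(abs(rp[1, ] - c(0, 0)) > 1e-12) ||
        any(abs(rp[nrow(rp), ] - c(1, 1)) > 1e-12) ||
        is.unsorted(rp[, 1]) || is.unsorted(rp[, 2]))
      msgs <- c(msgs, "rocPoints must run monotonically from (0,0) to (1,1)")
  }
  if (length(msgs)) msgs else TRUE
})
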