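#' @include AllClasses.R
NULL

#' Accessors for PairDataset
#'
#' @param x A [PairDataset-class].
#' @param role Optional role filter (`"receptor"` or `"ligand"`).
#' @return `proteins()` returns the `AAStringSet` (optionally restricted to
#'   one role); `proteinRoles()` a named character vector of roles;
#'   `domainHits()` the hit `data.frame`; `pairExamples()` the labelled pair
#'   `data.frame`.
#' @name PairDataset-accessors
NULL

#' @rdname PairDataset-accessors
#' @export
setGeneric("proteins", function(x, role = NULL) standardGeneric("proteins"))

#' @rdname PairDataset-accessors
#' @export
setGeneric("proteinRoles", function(x) standardGeneric("proteinRoles"))

#' @rdname PairDataset-accessors
#' @export
setGeneric("domainHits", function(x) standardGeneric("domainHits"))

#' @rdname PairDataset-accessors
#' @export
setGeneric("pairExamples", function(x) standardGeneric("pairExamples"))

#' @rdname PairDataset-accessors
setMethod("proteins", "PairDataset", function(x, role = NULL) {
  if (is.null(role)) return(x@proteins)
  role <- match.arg(role, .PROTEIN_ROLES)
  x@proteins[x@roles == role]
})

#' @rdname PairDataset-accessors
setMethod("proteinRoles", "PairDataset", function(x)
  stats::setNames(x@roles, names(x@proteins)))

#' @rdname PairDataset-accessors
setMethod("domainHits", "PairDataset", function(x) x@hits)

#' @rdname PairDataset-accessors
setMethod("pairExamples", "PairDataset", function(x) x@pairs)

setMethod("show", "PairDataset", function(object) {
  nr <- sum(object@roles == "receptor")
  nl <- sum(object@roles == "ligand")
  np <- sum(object@pairs$label == 1L)
  nn <- sum(object@pairs$label == 0L)
  cat("PairDataset with", nr, "receptor(s),", nl, "ligand(s)\n")
  cat("  domain hits:", nrow(object@hits), "\n")
  cat("  pairs:", np, "positive /", nn, "negative\n")
})

#' Accessors for DomainVocabulary
#'
#' @param x A [DomainVocabulary-class].
#' @param role `"receptor"` or `"ligand"`.
#' @param level `"domain"` or `"superfamily"`.
#' @return `vocabTypes()` returns the ordered accession list defining the
#'   binary-vector coordinates for that role and level;
#'   `domainToSuperfamily()` the named domain-to-superfamily mapping.
#' @name DomainVocabulary-accessors
NULL

#' @rdname DomainVocabulary-accessors
#' @export
setGeneric("vocabTypes", function(x, role, level = c("domain", "superfamily"))
  standardGeneric("vocabTypes"))

#' @rdname DomainVocabulary-accessors
setMethod("vocabTypes", "DomainVocabulary", function(x, role,
    level = c("domain", "superfamily")) {
  role <- match.arg(role, .PROTEIN_ROLES)
  level <- match.arg(level)
  slot(x, paste0(role, if (level == "domain") "Domains" else "Superfamilies"))
})

#' @rdname DomainVocabulary-accessors
#' @export
setGeneric("domainToSuperfamily", function(x) standardGeneric("domainToSuperfamily"))

#' @rdname DomainVocabulary-accessors
setMethod("domainToSuperfamily", "DomainVocabulary", function(x)
  x@domainToSuperfamily)

setMethod("show", "DomainVocabulary", function(object) {
  cat("DomainVocabulary\n")
  cat(sprintf("  receptor: %d domain type(s), %d superfamily type(s)\n",
              length(object@receptorDomains), length(object@receptorSuperfamilies)))
  cat(sprintf("  ligand:   %d domain type(s), %d superfamily type(s)\n",
              length(object@ligandDomains), length(object@ligandSuperfamilies)))
  cat(sprintf("  pair dims: domain-level %d, superfamily-level %d\n",
              length(object@receptorDomains) + length(object@ligandDomains),
              length(object@receptorSuperfamilies) + length(object@ligandSuperfamilies)))
})

setMethod("show", "TrainedPairModel", function(object) {
  cat("TrainedPairModel (", object@recipe, " recipe)\n", sep = "")
  cat(sprintf("  kernel=%s cost=%g%s\n", object@config$kernel,
              object@config$cost,
              if (object@config$kernel == "radial")
                sprintf(" gamma=%g", object@config$gamma) else ""))
  cat(sprintf("  class weights: pos=%.4g neg=%.4g\n",
              object@classWeights[["pos"]], object@classWeights[["neg"]]))
  cat(sprintf("  features: %d  training AUC: %s\n", length(object@featureNames),
              ifelse(is.na(object@trainAUC), "NA", sprintf("%.3f", object@trainAUC))))
})

.fmtMetric <- function(x, digits = 3) {
  ifelse(is.na(x), "—", formatC(x, format = "f", digits = digits))
}

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  precision=%s recall=%s F=%s AUC=%s\n",
              .fmtMetric(object@precision), .fmtMetric(object@recall),
              .fmtMetric(object@fMeasure), .fmtMetric(object@auc)))
  cat(sprintf("  TP=%.6g FP=%.6g TN=%.6g FN=%.6g\n",
              object@tp, object@fp, object@tn, object@fn))
})

#' Turn evaluation reports into a one-row-per-method table
#'
#' @param reports A named list of [EvalReport-class] objects (names become the
#'   `method` column), or a single report.
#' @return A `data.frame` with columns `method`, `precision`, `recall`,
#'   `f_measure`, `auc`, `tp`, `fp`, `tn`, `fn`.
#' @export
reportTable <- function(reports) {
  if (is(reports, "EvalReport")) reports <- list(report = reports)
  stopifnot(length(reports) > 0)
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(method = nm, precision = r@precision, recall = r@recall,
               f_measure = r@fMeasure, auc = r@auc,
               tp = r@tp, fp = r@fp, tn = r@tn, fn = r@fn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
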