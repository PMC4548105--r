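#' @include AllClasses.R
NULL

#' Read protein sequences from FASTA and assign a role
#'
#' Reads a multi-record FASTA file, uppercases the sequences, takes the first
#' whitespace-delimited token of each header as the protein identifier and
#' attaches the given role to every record. Ambiguity codes
#' (X, B, Z, U, O, J) are accepted here; featurization decides how to treat
#' them.
#'
#' @param path Path to a FASTA file.
#' @param role `"receptor"` or `"ligand"`, applied to all records.
#' @return An `AAStringSet` named by id, with a `role` metadata column.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">R1 some receptor", "ACDE", ">R2", "MKV"), f)
#' readFasta(f, "receptor")
#' @export
readFasta <- function(path, role = c("receptor", "ligand")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) > 0) {
    ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[`, character(1), 1)
    if (any(is.na(ids) | !nzchar(ids)))
      stop("FASTA header without an identifier in ", path)
    if (anyDuplicated(ids))
      stop("duplicate FASTA id(s) in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(seqs) <- ids
    seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
    if (any(Biostrings::width(seqs) < 1))
      stop("empty sequence(s) in ", path, ": ",
           paste(ids[Biostrings::width(seqs) < 1], collapse = ", "))
  }
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    role = rep(role, length(seqs)))
  seqs
}

.hitColumns <- c("protein_id", "domain_acc", "superfamily_acc",
                 "e_value", "start", "end")

#' Read a conserved-domain hit table and filter by E-value
#'
#' The table layout mirrors NCBI Batch CD-Search hit exports: one row per
#' domain hit with the query protein id, the domain accession, the accession
#' of the superfamily the domain belongs to, the hit E-value and 1-based
#' inclusive residue coordinates. Only hits with `e_value <= eCutoff` are
#' retained (a retention bound, matching search-tool convention); row order
#' is preserved.
#'
#' @param path Path to a tab-separated file with a header row and columns
#'   `protein_id`, `domain_acc`, `superfamily_acc`, `e_value`, `start`, `end`.
#' @param eCutoff E-value retention cutoff; default `1e-8`. Use `Inf` to keep
#'   every row.
#' @return A `data.frame` of retained hits with the six columns above.
#' @export
readDomainHits <- function(path, eCutoff = 1e-8) {
  if (!file.exists(path)) stop("domain-hit file not found: ", path)
  stopifnot(is.numeric(eCutoff), length(eCutoff) == 1, eCutoff >= 0)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!identical(colnames(raw), .hitColumns))
    stop("domain-hit file must have columns: ",
         paste(.hitColumns, collapse = ", "))
  if (nrow(raw) == 0) return(.emptyHits())
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed %s at data line %d of %s", what, bad[1], path))
    v
  }
  ev <- num("e_value", "e_value")
  st <- num("start", "start")
  en <- num("end", "end")
  if (any(ev < 0))
    stop(sprintf("negative E-value at data line %d of %s",
                 which(ev < 0)[1], path))
  badc <- which(st < 1 | en < st | st != floor(st) | en != floor(en))
  if (length(badc))
    stop(sprintf("invalid coordinates (need 1 <= start <= end) at data line %d of %s",
                 badc[1], path))
  if (any(!nzchar(raw$protein_id)))
    stop("empty protein_id in ", path)
  hits <- data.frame(
    protein_id = raw$protein_id, domain_acc = raw$domain_acc,
    superfamily_acc = raw$superfamily_acc, e_value = ev,
    start = as.integer(st), end = as.integer(en), stringsAsFactors = FALSE
  )
  hits <- hits[hits$e_value <= eCutoff, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read a positive-pair table
#'
#' @param path Path to a two-column tab-separated file with header columns
#'   `receptor_id` and `ligand_id`. Every row is read as a positive
#'   (interacting) pair.
#' @return A `data.frame` with columns `receptor_id`, `ligand_id`, `label`
#'   (all 1).
#' @export
readPairs <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!identical(colnames(raw), c("receptor_id", "ligand_id")))
    stop("pair file must have exactly two columns: receptor_id, ligand_id")
  if (nrow(raw) == 0) return(.emptyPairs())
  key <- paste(raw$receptor_id, raw$ligand_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- raw[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate pair (%s, %s) in %s",
                 d$receptor_id, d$ligand_id, path))
  }
  data.frame(receptor_id = raw$receptor_id, ligand_id = raw$ligand_id,
             label = 1L, stringsAsFactors = FALSE)
}

#' Write predicted pairs with decision values
#'
#' @param path Output path.
#' @param pairs `data.frame` with `receptor_id` and `ligand_id` columns.
#' @param scores Numeric decision values, one per pair.
#' @param labels Predicted labels (0/1), one per pair; defaults to
#'   `as.integer(scores > 0)`.
#' @return The path, invisibly. The file is a 4-column TSV
#'   (`receptor_id`, `ligand_id`, `decision_value`, `predicted_label`) in
#'   input row order; decision values are written with 6 decimal places.
#' @export
writePredictions <- function(path, pairs, scores,
                             labels = as.integer(scores > 0)) {
  if (nrow(pairs) != length(scores) || length(scores) != length(labels))
    stop("pairs, scores and labels must have equal lengths")
  out <- data.frame(
    receptor_id = pairs$receptor_id, ligand_id = pairs$ligand_id,
    decision_value = sprintf("%.6f", scores),
    predicted_label = as.integer(labels), stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table written by [writePredictions()]
#'
#' @param path Path to a prediction TSV.
#' @return `data.frame` with columns `receptor_id`, `ligand_id`,
#'   `decision_value` (numeric), `predicted_label` (integer).
#' @export
readPredictions <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("receptor_id", "ligand_id", "decision_value", "predicted_label")
  if (!identical(colnames(raw), need))
    stop("prediction file must have columns: ", paste(need, collapse = ", "))
  raw$decision_value <- as.numeric(raw$decision_value)
  raw$predicted_label <- as.integer(raw$predicted_label)
  raw
}

#' Assemble a PairDataset from the three on-disk inputs
#'
#' Convenience loader: reads receptor and ligand FASTA files, a domain-hit
#' table (E-value filtered) and a positive-pair table, cross-validates all
#' references and returns the dataset with positives only. Use
#' [generateNegatives()] / [buildPairDataset()] to add the negative class.
#'
#' @param receptorFasta,ligandFasta FASTA paths for the two roles.
#' @param hitsPath Domain-hit TSV path, or `NULL` for no domain information.
#' @param pairsPath Positive-pair TSV path, or `NULL` for no pairs.
#' @param eCutoff E-value cutoff forwarded to [readDomainHits()].
#' @return A [PairDataset-class].
#' @export
loadPairDataset <- function(receptorFasta, ligandFasta, hitsPath = NULL,
                            pairsPath = NULL, eCutoff = 1e-8) {
  rec <- readFasta(receptorFasta, "receptor")
  lig <- readFasta(ligandFasta, "ligand")
  dup <- intersect(names(rec), names(lig))
  if (length(dup))
    stop("id(s) present in both FASTA files: ", paste(dup, collapse = ", "))
  proteins <- c(rec, lig)
  roles <- c(rep("receptor", length(rec)), rep("ligand", length(lig)))
  hits <- if (is.null(hitsPath)) .emptyHits() else readDomainHits(hitsPath, eCutoff)
  pairs <- if (is.null(pairsPath)) .emptyPairs() else readPairs(pairsPath)
  PairDataset(proteins, roles, hits = hits, pairs = pairs)
}
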