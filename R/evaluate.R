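#' @include AllClasses.R
NULL

#' Confusion counts at a decision threshold
#'
#' A pair is predicted interacting iff its decision value is strictly above
#' the threshold (a value exactly at the threshold counts as negative).
#'
#' @param labels Binary 0/1 truth vector.
#' @param scores Numeric decision values, same length.
#' @param threshold Decision threshold (default 0, the SVM convention).
#' @return Named numeric `c(tp, fp, tn, fn)`.
#' @export
confusionCounts <- function(labels, scores, threshold = 0) {
  if (length(labels) != length(scores)) stop("labels and scores lengths differ")
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  pred <- scores > threshold
  c(tp = sum(pred & labels == 1L), fp = sum(pred & labels == 0L),
    tn = sum(!pred & labels == 0L), fn = sum(!pred & labels == 1L))
}

#' Precision, recall and F-measure from confusion counts
#'
#' `p = TP/(TP+FP)`, `r = TP/(TP+FN)`, `F = 2pr/(p+r)`. A metric whose
#' denominator is zero is undefined and returned as `NA` (rendered as an em
#' dash in reports); F is undefined when either p or r is, or when
#' `p + r = 0`.
#'
#' @param tp,fp,fn Nonnegative counts (reals allowed, for averaged reports).
#' @return Named numeric `c(precision, recall, f_measure)` with `NA` for
#'   undefined entries.
#' @examples
#' precisionRecallF(64, 0, 31)   # precision 1, recall ~0.674
#' @export
precisionRecallF <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be nonnegative")
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  c(precision = p, recall = r, f_measure = f)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold from high to low, collapsing tied scores
#' into single steps, and integrates by the trapezoidal rule. The result
#' equals the Mann-Whitney concordance probability with ties counted 1/2:
#' the probability that a random positive outscores a random negative.
#'
#' @param labels Binary 0/1 truth vector (both classes required).
#' @param scores Numeric decision values.
#' @return List with `points` (two-column matrix `fpr`, `tpr`, running
#'   monotonically from (0,0) to (1,1)) and `auc`.
#' @export
rocAuc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels and scores lengths differ")
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0 || nNeg == 0) stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]; s <- scores[ord]
  cutoff <- c(which(diff(s) != 0), length(s))   # last index of each tie group
  tpr <- c(0, cumsum(l)[cutoff] / nPos)
  fpr <- c(0, cumsum(1L - l)[cutoff] / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = cbind(fpr = fpr, tpr = tpr), auc = auc)
}

#' Build an EvalReport from labels and decision values
#'
#' @param labels Binary 0/1 truth vector (both classes required).
#' @param scores Decision values.
#' @param threshold Label threshold for the confusion counts (default 0).
#' @return An [EvalReport-class].
#' @export
evalReport <- function(labels, scores, threshold = 0) {
  cc <- confusionCounts(labels, scores, threshold)
  prf <- precisionRecallF(cc[["tp"]], cc[["fp"]], cc[["fn"]])
  roc <- rocAuc(labels, scores)
  new("EvalReport", tp = cc[["tp"]], fp = cc[["fp"]], tn = cc[["tn"]],
      fn = cc[["fn"]], precision = prf[["precision"]],
      recall = prf[["recall"]], fMeasure = prf[["f_measure"]],
      auc = roc$auc, rocPoints = roc$points)
}

#' Average evaluation reports over repeats
#'
#' Counts and metrics are averaged as reals (fractional counts are expected
#' for repeated protocols); an undefined metric in any repeat leaves the
#' average undefined. The averaged report carries no ROC points.
#'
#' @param reports List of [EvalReport-class] objects.
#' @return An [EvalReport-class].
#' @export
meanReport <- function(reports) {
  stopifnot(length(reports) >= 1)
  g <- function(f) vapply(reports, f, numeric(1))
  new("EvalReport",
      tp = mean(g(function(r) r@tp)), fp = mean(g(function(r) r@fp)),
      tn = mean(g(function(r) r@tn)), fn = mean(g(function(r) r@fn)),
      precision = mean(g(function(r) r@precision)),
      recall = mean(g(function(r) r@recall)),
      fMeasure = mean(g(function(r) r@fMeasure)),
      auc = mean(g(function(r) r@auc)),
      rocPoints = matrix(numeric(0), 0, 2,
                         dimnames = list(NULL, c("fpr", "tpr"))))
}

# Vocabulary restricted to proteins that occur in the given pairs — used to
# keep fold vocabularies free of information from held-out pairs.
.foldVocabulary <- function(dataset, pairs) {
  ids <- unique(c(pairs$receptor_id, pairs$ligand_id))
  hits <- domainHits(dataset)
  buildVocabulary(hits[hits$protein_id %in% ids, , drop = FALSE],
                  proteinRoles(dataset))
}

.needsVocab <- function(recipe) recipe %in% c("domain", "superfamily", "composite")

.fitAndScore <- function(dataset, recipe, trainPairs, testPairs, config,
                         vocabScope, tune, tuneSeed, fullVocab = NULL) {
  vocab <- if (!.needsVocab(recipe)) NULL
    else if (vocabScope == "train") .foldVocabulary(dataset, trainPairs)
    else fullVocab
  Xtr <- pairFeatureMatrix(dataset, recipe, vocab, trainPairs)
  Xte <- pairFeatureMatrix(dataset, recipe, vocab, testPairs)
  cfg <- if (tune) tuneSvm(Xtr, trainPairs$label, config, seed = tuneSeed)
         else config
  model <- trainPairModel(Xtr, trainPairs$label, recipe = recipe,
                          config = cfg, vocab = vocab)
  list(model = model, scores = decisionValues(model, Xte), config = cfg)
}

# Pooled inner-CV decision values on the training portion; used both for
# hyperparameter-free AUC weighting (combination protocol) and diagnostics.
.innerCvAuc <- function(dataset, recipe, trainPairs, config, vocabScope,
                        nFolds, seed, fullVocab = NULL) {
  y <- trainPairs$label
  fold <- stratifiedKfold(y, nFolds, seed)
  scores <- numeric(length(y))
  for (f in seq_len(nFolds)) {
    fs <- .fitAndScore(dataset, recipe,
                       trainPairs[fold != f, , drop = FALSE],
                       trainPairs[fold == f, , drop = FALSE],
                       config, vocabScope, tune = FALSE, tuneSeed = seed,
                       fullVocab = fullVocab)
    scores[fold == f] <- fs$scores
  }
  rocAuc(y, scores)$auc
}

#' Repeated stratified cross-validation of one feature recipe
#'
#' The evaluation protocol: stratified `nFolds`-fold cross-validation,
#' repeated `nRepeats` times with different fold shuffles. Within each fold
#' the domain vocabulary (for domain-based recipes) and any hyperparameter
#' tuning use the training portion only; held-out decision values are pooled
#' over the folds into one [EvalReport-class] per repeat, and the repeats
#' are averaged with [meanReport()].
#'
#' @param dataset A [PairDataset-class] with labelled pairs (both classes).
#' @param recipe Feature recipe.
#' @param config An [svmConfig()].
#' @param nFolds,nRepeats Protocol sizes (defaults 5 and 5).
#' @param seed Base seed; repeat `i` uses `seed + i - 1`.
#' @param tune If `TRUE`, grid-search hyperparameters inside every training
#'   fold with [tuneSvm()] (inner 5-fold CV, criterion: pooled AUC).
#' @param vocabScope `"train"` (default; fold vocabularies are built from
#'   training-fold proteins only, preventing leakage) or `"all"` (whole
#'   dataset vocabulary).
#' @return List with `reports` (one [EvalReport-class] per repeat), `mean`
#'   (their average) and `scores` (per-repeat pooled decision values).
#' @export
crossValidate <- function(dataset, recipe, config = svmConfig(), nFolds = 5,
                          nRepeats = 5, seed = 1, tune = FALSE,
                          vocabScope = c("train", "all")) {
  recipe <- match.arg(recipe, .RECIPES)
  vocabScope <- match.arg(vocabScope)
  pairs <- pairExamples(dataset)
  y <- pairs$label
  fullVocab <- if (.needsVocab(recipe) && vocabScope == "all")
    buildVocabulary(domainHits(dataset), proteinRoles(dataset)) else NULL
  reports <- vector("list", nRepeats)
  allScores <- vector("list", nRepeats)
  for (rep in seq_len(nRepeats)) {
    repSeed <- seed + rep - 1L
    fold <- stratifiedKfold(y, nFolds, repSeed)
    scores <- numeric(length(y))
    for (f in seq_len(nFolds)) {
      fs <- tryCatch(
        .fitAndScore(dataset, recipe, pairs[fold != f, , drop = FALSE],
                     pairs[fold == f, , drop = FALSE], config, vocabScope,
                     tune, tuneSeed = repSeed, fullVocab = fullVocab),
        error = function(e) stop("repeat ", rep, ", fold ", f, ": ",
                                 conditionMessage(e)))
      scores[fold == f] <- fs$scores
    }
    reports[[rep]] <- evalReport(y, scores)
    allScores[[rep]] <- scores
  }
  list(reports = reports, mean = meanReport(reports), scores = allScores)
}

#' Independent test: stratified holdout with tuning on training data only
#'
#' Reserves a stratified fraction of each class (floor per class: 20% of
#' 95 positives is 19 pairs, of 2183 negatives 436 pairs), determines SVM
#' parameters by 5-fold cross-validation on the training data only (when
#' `tune = TRUE`), refits on all training data and evaluates once on the
#' holdout; repeated `nRepeats` times and averaged.
#'
#' @inheritParams crossValidate
#' @param fraction Holdout fraction (default 0.2).
#' @param nRepeats Number of repeats (default 3).
#' @return List with `reports`, `mean` and `splits` (the holdout index sets).
#' @export
independentTest <- function(dataset, recipe, config = svmConfig(),
                            fraction = 0.2, nRepeats = 3, seed = 1,
                            tune = FALSE, vocabScope = c("train", "all")) {
  recipe <- match.arg(recipe, .RECIPES)
  vocabScope <- match.arg(vocabScope)
  pairs <- pairExamples(dataset)
  y <- pairs$label
  fullVocab <- if (.needsVocab(recipe) && vocabScope == "all")
    buildVocabulary(domainHits(dataset), proteinRoles(dataset)) else NULL
  reports <- vector("list", nRepeats)
  splits <- vector("list", nRepeats)
  for (rep in seq_len(nRepeats)) {
    repSeed <- seed + rep - 1L
    sp <- holdoutSplit(y, fraction, repSeed)
    fs <- .fitAndScore(dataset, recipe, pairs[sp$train, , drop = FALSE],
                       pairs[sp$test, , drop = FALSE], config, vocabScope,
                       tune, tuneSeed = repSeed, fullVocab = fullVocab)
    reports[[rep]] <- evalReport(y[sp$test], fs$scores)
    splits[[rep]] <- sp
  }
  list(reports = reports, mean = meanReport(reports), splits = splits)
}

#' Combine two recipes' predictions by AUC-weighted decision values
#'
#' Within each cross-validation fold, one model per recipe is trained on the
#' same training portion; each model's weight is its AUC minus 0.5 measured
#' by inner cross-validation on that training portion (never on the
#' evaluation fold). Held-out decision values are combined with
#' [combineDecisions()], pooled over folds, and scored as one report per
#' repeat.
#'
#' @inheritParams crossValidate
#' @param recipeA,recipeB The two feature recipes (the standard combination
#'   is `"kmer2"` with `"superfamily"`).
#' @param innerFolds Folds of the inner CV that estimates each model's AUC
#'   weight (default 5).
#' @return List with `reports` (per repeat), `mean`, and `weights` (the
#'   per-fold inner-CV AUC pairs actually used).
#' @export
runCombinationProtocol <- function(dataset, recipeA = "kmer2",
                                   recipeB = "superfamily",
                                   config = svmConfig(), nFolds = 5,
                                   nRepeats = 5, innerFolds = 5, seed = 1,
                                   tune = FALSE,
                                   vocabScope = c("train", "all")) {
  recipeA <- match.arg(recipeA, .RECIPES)
  recipeB <- match.arg(recipeB, .RECIPES)
  vocabScope <- match.arg(vocabScope)
  pairs <- pairExamples(dataset)
  y <- pairs$label
  fullVocab <- if ((.needsVocab(recipeA) || .needsVocab(recipeB)) &&
                   vocabScope == "all")
    buildVocabulary(domainHits(dataset), proteinRoles(dataset)) else NULL
  reports <- vector("list", nRepeats)
  weightLog <- list()
  for (rep in seq_len(nRepeats)) {
    repSeed <- seed + rep - 1L
    fold <- stratifiedKfold(y, nFolds, repSeed)
    scores <- numeric(length(y))
    for (f in seq_len(nFolds)) {
      trainPairs <- pairs[fold != f, , drop = FALSE]
      testPairs <- pairs[fold == f, , drop = FALSE]
      aucA <- .innerCvAuc(dataset, recipeA, trainPairs, config, vocabScope,
                          innerFolds, repSeed, fullVocab)
      aucB <- .innerCvAuc(dataset, recipeB, trainPairs, config, vocabScope,
                          innerFolds, repSeed, fullVocab)
      fsA <- .fitAndScore(dataset, recipeA, trainPairs, testPairs, config,
                          vocabScope, tune, repSeed, fullVocab)
      fsB <- .fitAndScore(dataset, recipeB, trainPairs, testPairs, config,
                          vocabScope, tune, repSeed, fullVocab)
      scores[fold == f] <- combineDecisions(fsA$scores, fsB$scores, aucA, aucB)
      weightLog[[length(weightLog) + 1]] <-
        c(repeat_ = rep, fold = f, aucA = aucA, aucB = aucB)
    }
    reports[[rep]] <- evalReport(y, scores)
  }
  list(reports = reports, mean = meanReport(reports),
       weights = do.call(rbind, weightLog))
}

#' Write a method-by-metric report table as TSV
#'
#' Columns: `method`, `precision`, `recall`, `f_measure`, `auc`, `tp`,
#' `fp`, `tn`, `fn`. Undefined metrics are written as an em dash.
#'
#' @param reports Named list of [EvalReport-class] objects (or one report).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeReport <- function(reports, path) {
  tab <- reportTable(reports)
  for (col in c("precision", "recall", "f_measure", "auc"))
    tab[[col]] <- .fmtMetric(tab[[col]], digits = 4)
  for (col in c("tp", "fp", "tn", "fn"))
    tab[[col]] <- formatC(tab[[col]], format = "fg", digits = 7)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ROC points as a two-column TSV
#'
#' @param report An [EvalReport-class] with ROC points.
#' @param path Output path (columns `fpr`, `tpr`).
#' @return The path, invisibly.
#' @export
writeRocPoints <- function(report, path) {
  stopifnot(is(report, "EvalReport"))
  utils::write.table(as.data.frame(report@rocPoints), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
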