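#' @include AllClasses.R
NULL

#' SVM configuration
#'
#' Settings for the class-weighted C-SVM. The default kernel is RBF
#' (`"radial"`), the standard choice for dense low-dimensional features, with
#' a log2-spaced hyperparameter grid (cost 2^-5..2^15, gamma 2^-15..2^3,
#' step 2^2) for [tuneSvm()]; a linear kernel is available as an option.
#' `gamma = NULL` resolves to the library default `1 / n_features` at fit
#' time.
#'
#' @param kernel `"radial"` or `"linear"`.
#' @param cost Misclassification cost C (> 0).
#' @param gamma RBF kernel width (> 0), or `NULL` for `1 / n_features`.
#' @param costGrid,gammaGrid Candidate values for [tuneSvm()]; nonempty.
#' @param scaleFeatures If `TRUE`, min-max scale each feature column to
#'   `[0, 1]` before fitting (off by default: binary and k-mer features
#'   already lie in `[0, 1]`).
#' @param seed Integer seed recorded with the model (training itself is
#'   deterministic; the seed feeds resampling done around it).
#' @return A list of class `svmConfig`.
#' @export
svmConfig <- function(kernel = c("radial", "linear"), cost = 1, gamma = NULL,
                      costGrid = 2^seq(-5, 15, by = 2),
                      gammaGrid = 2^seq(-15, 3, by = 2),
                      scaleFeatures = FALSE, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, is.null(gamma) || gamma > 0,
            length(costGrid) >= 1, all(costGrid > 0),
            length(gammaGrid) >= 1, all(gammaGrid > 0))
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 costGrid = sort(costGrid), gammaGrid = sort(gammaGrid),
                 scaleFeatures = scaleFeatures, seed = as.integer(seed)),
            class = "svmConfig")
}

.checkXy <- function(X, y) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("feature matrix must be numeric and finite")
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2)
    stop("training labels contain a single class")
  list(X = X, y = y)
}

.minMaxScale <- function(X) {
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  sweep(sweep(X, 2, rng[1, ], "-"), 2, span, "/")
}

#' Train the class-weighted pair classifier
#'
#' Fits a C-SVM (LIBSVM via \pkg{e1071}) on a pair feature matrix with
#' per-class misclassification weights, by default proportional to the
#' opposite class's size ([classWeights()]), which keeps the minority
#' positive class from being swamped by the exhaustive negatives. Training
#' is deterministic given the inputs.
#'
#' @param X Numeric feature matrix (rows = pairs), e.g. from
#'   [pairFeatureMatrix()].
#' @param y Binary 0/1 labels (both classes required).
#' @param recipe Feature recipe identifier recorded with the model.
#' @param config An [svmConfig()] with resolved `cost` (and `gamma`).
#' @param weights Named `c(pos=, neg=)` class weights; default derived from
#'   `y` via [classWeights()]. Use `c(pos = 1, neg = 1)` to disable
#'   weighting.
#' @param vocab Optional [DomainVocabulary-class] snapshot stored with the
#'   model for domain-based recipes.
#' @return A [TrainedPairModel-class]; its `trainAUC` slot holds the
#'   resubstitution AUC.
#' @export
trainPairModel <- function(X, y, recipe = "composite", config = svmConfig(),
                           weights = NULL, vocab = NULL) {
  chk <- .checkXy(X, y)
  X <- chk$X; y <- chk$y
  recipe <- match.arg(recipe, .RECIPES)
  if (is.null(weights)) weights <- classWeights(sum(y == 1), sum(y == 0))
  stopifnot(all(c("pos", "neg") %in% names(weights)), all(weights > 0))
  if (isTRUE(config$scaleFeatures)) X <- .minMaxScale(X)
  gamma <- if (is.null(config$gamma)) 1 / ncol(X) else config$gamma
  yf <- factor(y, levels = c(0, 1))
  fit <- e1071::svm(X, yf, type = "C-classification", kernel = config$kernel,
                    cost = config$cost, gamma = gamma,
                    class.weights = c("1" = unname(weights[["pos"]]),
                                      "0" = unname(weights[["neg"]])),
                    scale = FALSE,
                    # all-against-all pair datasets keep the working set
                    # large; a cache that holds the full kernel matrix for
                    # a few thousand pairs roughly halves the fit time
                    cache.size = 256)
  pred <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm orients decision values toward the first class it saw; flip so
  # that positive always means "interacting"
  flip <- identical(colnames(dv), "0/1")
  scores <- as.numeric(dv) * if (flip) -1 else 1
  trainAUC <- if (length(unique(y)) == 2) rocAuc(y, scores)$auc else NA_real_
  resolved <- config
  resolved$gamma <- gamma
  new("TrainedPairModel", fit = fit, recipe = recipe,
      config = unclass(resolved),
      classWeights = c(pos = unname(weights[["pos"]]),
                       neg = unname(weights[["neg"]])),
      vocabulary = vocab,
      featureNames = colnames(X) %||% character(0),
      trainAUC = trainAUC, flipSign = flip,
      version = .MODEL_FORMAT_VERSION)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decision values of a trained model
#'
#' @param model A [TrainedPairModel-class].
#' @param X Feature matrix whose column layout matches the training recipe.
#' @return One finite real per row; values above 0 predict an interacting
#'   pair.
#' @export
setGeneric("decisionValues", function(model, X) standardGeneric("decisionValues"))

#' @rdname decisionValues
setMethod("decisionValues", "TrainedPairModel", function(model, X) {
  X <- as.matrix(X)
  nExpected <- length(model@featureNames)
  if (nExpected > 0 && ncol(X) != nExpected)
    stop("feature dimension mismatch: model expects ", nExpected,
         " columns, got ", ncol(X))
  if (nExpected > 0 && !is.null(colnames(X)) &&
      !identical(colnames(X), model@featureNames))
    stop("feature column layout differs from the training layout")
  if (isTRUE(model@config$scaleFeatures)) X <- .minMaxScale(X)
  pred <- stats::predict(model@fit, X, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values"))
  if (model@flipSign) dv <- -dv
  dv
})

#' Grid search for SVM hyperparameters by inner cross-validated AUC
#'
#' Evaluates every (cost, gamma) point of the config's grid by stratified
#' `nFolds`-fold cross-validation on `(X, y)`, pooling held-out decision
#' values into one AUC per point, and returns the config resolved to the
#' best point. Ties are broken toward smaller cost, then smaller gamma.
#' For a linear kernel only the cost grid is searched.
#'
#' @param X,y Training data as in [trainPairModel()].
#' @param config An [svmConfig()] carrying the grids.
#' @param nFolds Inner folds (default 5).
#' @param seed Seed for the inner fold assignment.
#' @param weights Class weights forwarded to training.
#' @return The config with `cost`/`gamma` set to the selected point, plus a
#'   `tuningAUC` entry with the winning mean AUC.
#' @export
tuneSvm <- function(X, y, config = svmConfig(), nFolds = 5, seed = 1,
                    weights = NULL) {
  chk <- .checkXy(X, y)
  X <- chk$X; y <- chk$y
  grid <- if (config$kernel == "linear")
    data.frame(cost = config$costGrid, gamma = NA_real_)
  else
    expand.grid(gamma = config$gammaGrid, cost = config$costGrid,
                KEEP.OUT.ATTRS = FALSE)[, c("cost", "gamma")]
  fold <- stratifiedKfold(y, nFolds, seed)
  aucs <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$cost <- grid$cost[i]
    if (!is.na(grid$gamma[i])) cfg$gamma <- grid$gamma[i]
    scores <- numeric(length(y))
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      m <- trainPairModel(X[tr, , drop = FALSE], y[tr], recipe = "composite",
                          config = cfg, weights = weights)
      scores[!tr] <- decisionValues(m, X[!tr, , drop = FALSE])
    }
    rocAuc(y, scores)$auc
  }, numeric(1))
  best <- order(-aucs, grid$cost, grid$gamma)[1]
  out <- config
  out$cost <- grid$cost[best]
  if (!is.na(grid$gamma[best])) out$gamma <- grid$gamma[best]
  out$tuningAUC <- aucs[best]
  out
}

#' Combine two models' decision values by AUC-derived weights
#'
#' Weighted average of two discriminant functions,
#' `f_comp = (a f_A + b f_B) / (a + b)`, where each weight is the model's
#' AUC minus 0.5 — its improvement over random prediction — floored at a
#' small epsilon so a chance-level (or worse) partner contributes
#' (essentially) nothing rather than a negative or undefined weight.
#'
#' @param fA,fB Equal-length numeric decision-value vectors.
#' @param aucA,aucB The two models' AUCs in `[0, 1]`.
#' @param eps Weight floor (default `1e-6`).
#' @return Combined decision values, same length as the inputs.
#' @examples
#' combineDecisions(1, 0, 0.9, 0.9)           # 0.5: equal weights
#' combineDecisions(1, -1, 0.713, 0.974)      # ~ -0.3799
#' @export
combineDecisions <- function(fA, fB, aucA, aucB, eps = 1e-6) {
  if (length(fA) != length(fB)) stop("decision-value lengths differ")
  stopifnot(aucA >= 0, aucA <= 1, aucB >= 0, aucB <= 1, eps > 0)
  a <- max(aucA - 0.5, eps)
  b <- max(aucB - 0.5, eps)
  # agreeing models are a fixed point regardless of the weights; return the
  # input unrounded rather than routing it through the arithmetic
  if (identical(fA, fB)) return(fA)
  (a * fA + b * fB) / (a + b)
}

#' Save / load a trained model
#'
#' The on-disk bundle is self-describing (format version, recipe, vocabulary
#' snapshot, resolved hyperparameters, fitted state); a round trip preserves
#' decision values exactly.
#'
#' @param model A [TrainedPairModel-class].
#' @param path File path.
#' @return `saveModel()` the path invisibly; `loadModel()` the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedPairModel"))
  saveRDS(list(format = .MODEL_FORMAT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable model file: ", path, " (", conditionMessage(e), ")"))
  if (!is.list(obj) || is.null(obj$format))
    stop("not an rtkpair model bundle: ", path)
  if (!identical(obj$format, .MODEL_FORMAT_VERSION))
    stop("model format version mismatch: file has '", obj$format,
         "', this build reads '", .MODEL_FORMAT_VERSION, "'")
  validObject(obj$model)
  obj$model
}
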