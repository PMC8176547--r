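#' @include AllClasses.R
NULL

#' Quadratic kernel
#'
#' k(x, y) = (gamma * <x, y> + coef0)^2, the degree-2 polynomial kernel.
#'
#' @param x,y numeric vectors of equal length.
#' @param spec a [KernelSpec-class]; `gamma = NA` resolves to
#'   `1/length(x)`.
#' @return A single nonnegative number.
#' @examples
#' quadraticKernel(c(1, 1), c(2, 0), kernelSpec(gamma = 1, coef0 = 0))  # 4
#' @export
quadraticKernel <- function(x, y, spec = kernelSpec()) {
  if (length(x) != length(y))
    stop("shape error: kernel arguments must have equal length",
         call. = FALSE)
  g <- if (is.na(spec@gamma)) 1 / length(x) else spec@gamma
  (g * sum(x * y) + spec@coef0)^2
}

#' Gram matrix of the quadratic kernel
#'
#' @param x numeric matrix, one sample per row.
#' @param spec a [KernelSpec-class].
#' @return The symmetric positive semidefinite matrix K with
#'   K[i, j] = k(x[i, ], x[j, ]).
#' @export
gramMatrix <- function(x, spec = kernelSpec()) {
  x <- as.matrix(x)
  g <- if (is.na(spec@gamma)) 1 / ncol(x) else spec@gamma
  (g * tcrossprod(x) + spec@coef0)^2
}

resolveKernel <- function(spec, dim) {
  if (is.na(spec@gamma)) spec@gamma <- 1 / dim
  spec
}

#' Train a one-vs-all quadratic-kernel SVM
#'
#' Fits one binary soft-margin machine per class (that class against the
#' rest) with the quadratic kernel, each solved to KKT tolerance 1e-3 by
#' the libsvm SMO solver ([e1071::svm]). The multiclass decision is the
#' argmax over per-class (uncalibrated) decision values, ties broken by the
#' lowest class index.
#'
#' @param x numeric matrix of fused features, one sample per row.
#' @param labels class label per row; at least 2 classes.
#' @param kernel a [KernelSpec-class]; `gamma = NA` resolves to
#'   `1/ncol(x)`.
#' @return An [SvmModel-class].
#' @examples
#' x <- rbind(c(0, 0), c(0, 1), c(3, 0), c(3, 1))
#' m <- trainOvaSvm(x, c("A", "A", "B", "B"), kernelSpec(C = 100))
#' predict(m, x)
#' @export
trainOvaSvm <- function(x, labels, kernel = kernelSpec()) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("degenerate labels: at least 2 classes are required",
         call. = FALSE)
  kernel <- resolveKernel(kernel, ncol(x))
  machines <- lapply(classes, function(cls) {
    ybin <- factor(ifelse(labels == cls, "__pos__", "__rest__"),
                   levels = c("__pos__", "__rest__"))
    fit <- e1071::svm(x, ybin, scale = FALSE, type = "C-classification",
                      kernel = "polynomial", degree = 2,
                      gamma = kernel@gamma, coef0 = kernel@coef0,
                      cost = kernel@C, tolerance = 1e-3)
    dv <- attr(stats::predict(fit, x[1, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    list(svm = fit, flip = identical(colnames(dv), "__rest__/__pos__"),
         class = cls)
  })
  new("SvmModel", machines = machines, classes = classes, kernel = kernel,
      dim = ncol(x))
}

#' Per-class decision values of a one-vs-all model
#'
#' @param model an [SvmModel-class].
#' @param x numeric matrix of samples (rows).
#' @return samples x classes matrix of decision values f_c(x); positive
#'   means "looks like class c".
#' @export
decisionValues <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model@dim)
    stop(sprintf("shape error: %d feature dims, model expects %d",
                 ncol(x), model@dim), call. = FALSE)
  d <- vapply(model@machines, function(m) {
    dv <- attr(stats::predict(m$svm, x, decision.values = TRUE),
               "decision.values")[, 1]
    if (m$flip) -dv else dv
  }, numeric(nrow(x)))
  d <- matrix(d, nrow = nrow(x), dimnames = list(NULL, model@classes))
  d
}

#' Predict classes with a one-vs-all SVM
#'
#' @param object an [SvmModel-class].
#' @param newdata numeric matrix of samples (rows).
#' @param ... ignored.
#' @return Character vector of predicted class labels (argmax of the
#'   decision values, ties to the lowest class index).
#' @export
setMethod("predict", "SvmModel", function(object, newdata, ...) {
  d <- decisionValues(object, newdata)
  object@classes[max.col(d, ties.method = "first")]
})

#' Dual-solution diagnostics of a one-vs-all model
#'
#' Per binary machine: the dual coefficients alpha_i * y_i over the support
#' vectors, the bias b, the box constraint C, and the maximum-margin width
#' d = 1 / ||w|| derived from the dual expansion
#' ||w||^2 = sum_ij (a_i y_i)(a_j y_j) k(sv_i, sv_j).
#'
#' @param model an [SvmModel-class].
#' @return A named list (one element per class), each with `alphaY`, `bias`,
#'   `C`, `sumAlphaY`, `marginWidth` and `supportVectors`.
#' @export
dualDiagnostics <- function(model) {
  out <- lapply(model@machines, function(m) {
    coefs <- as.numeric(m$svm$coefs)
    sv <- as.matrix(m$svm$SV)
    K <- gramMatrix(sv, model@kernel)
    w2 <- as.numeric(t(coefs) %*% K %*% coefs)
    list(alphaY = coefs, bias = -m$svm$rho, C = model@kernel@C,
         sumAlphaY = sum(coefs),
         marginWidth = if (w2 > 0) 1 / sqrt(w2) else Inf,
         supportVectors = sv)
  })
  names(out) <- model@classes
  out
}

#' Stratified fold assignment
#'
#' Shuffles the samples with the given seed, then deals the members of each
#' class cyclically over the folds, so per-fold class proportions are
#' within one sample of the global proportions and every sample is held
#' out exactly once.
#'
#' @param labels class label per sample.
#' @param folds number of folds.
#' @param seed shuffle seed.
#' @return Integer vector of fold indices in 1..folds.
#' @export
stratifiedFolds <- function(labels, folds, seed = 1L) {
  n <- length(labels)
  ord <- withSeed(seed, sample.int(n))
  fold <- integer(n)
  for (cls in unique(labels)) {
    members <- ord[labels[ord] == cls]
    fold[members] <- rep_len(seq_len(folds), length(members))
  }
  fold
}

#' Stratified k-fold cross-validation of the fused-feature SVM
#'
#' Splits the samples into stratified folds from a seeded shuffle; in each
#' fold, fits the per-(backbone, tile) PCA models and the z-score
#' parameters on the training portion only (unless `paperMode = TRUE`,
#' which fits them once on all data), trains the one-vs-all SVM, and
#' predicts the held-out portion. Accuracy is pooled over all held-out
#' predictions.
#'
#' If a class has fewer members than `folds`, the fold count is reduced to
#' that size with a warning recorded in the report notes.
#'
#' @param blocks either a list of raw [FeatureMatrix-class] blocks in
#'   fusion order (the standard route; requires `fusion`), or a single
#'   matrix/[FeatureMatrix-class] of ready-made features (then only
#'   z-score is fitted per fold).
#' @param labels class label per sample.
#' @param fusion a [FusionSpec-class]; required when `blocks` is a list.
#' @param kernel a [KernelSpec-class].
#' @param folds number of folds, default 10.
#' @param seed shuffle seed.
#' @param paperMode fit PCA and z-score once on all data instead of per
#'   fold.
#' @param configEcho named list echoed into the report.
#' @return An [EvalReport-class].
#' @export
crossValidate <- function(blocks, labels, fusion = NULL,
                          kernel = kernelSpec(), folds = 10L, seed = 1L,
                          paperMode = FALSE, configEcho = list()) {
  labels <- as.character(labels)
  n <- length(labels)
  classes <- sort(unique(labels))
  if (folds < 2L) stop("configuration error: folds must be >= 2",
                       call. = FALSE)
  notes <- character(0)
  minClass <- min(table(labels))
  if (minClass < folds) {
    folds <- max(2L, as.integer(minClass))
    notes <- c(notes, sprintf(
      "folds reduced to %d: smallest class has %d members", folds,
      minClass))
    warning(notes[length(notes)], call. = FALSE)
  }
  rawBlocks <- is.list(blocks) && !is(blocks, "FeatureMatrix")
  if (rawBlocks && is.null(fusion))
    stop("fusion spec is required with raw feature blocks", call. = FALSE)
  fold <- stratifiedFolds(labels, folds, seed)
  pred <- character(n)
  globalTransforms <- if (rawBlocks && paperMode)
    fitTransforms(blocks, seq_len(n), fusion)
  for (f in seq_len(folds)) {
    trainIdx <- which(fold != f)
    testIdx <- which(fold == f)
    if (rawBlocks) {
      tr <- if (paperMode) globalTransforms
            else fitTransforms(blocks, trainIdx, fusion)
      xTrain <- applyTransforms(tr, blocks, rows = trainIdx)
      xTest <- applyTransforms(tr, blocks, rows = testIdx)
    } else {
      x <- asValues(blocks)
      fitIdx <- if (paperMode) seq_len(n) else trainIdx
      zs <- zscoreFitApply(x[fitIdx, , drop = FALSE],
                           others = list(x[trainIdx, , drop = FALSE],
                                         x[testIdx, , drop = FALSE]))
      xTrain <- zs$others[[1]]
      xTest <- zs$others[[2]]
    }
    model <- trainOvaSvm(xTrain, labels[trainIdx], kernel)
    pred[testIdx] <- predict(model, xTest)
  }
  cm <- unclass(table(factor(labels, classes), factor(pred, classes)))
  dimnames(cm) <- list(true = classes, predicted = classes)
  new("EvalReport",
      accuracy = 100 * sum(diag(cm)) / n, confusion = cm,
      foldAssignments = fold, predictions = pred, labels = labels,
      classes = classes, folds = as.integer(folds),
      seed = as.integer(seed),
      config = c(configEcho,
                 list(kernel = list(degree = 2, gamma = kernel@gamma,
                                    coef0 = kernel@coef0, C = kernel@C),
                      folds = as.integer(folds),
                      paper_mode = isTRUE(paperMode))),
      notes = notes)
}

#' Serialize an evaluation report to JSON text
#'
#' Deterministic JSON rendering of an [EvalReport-class]; identical reports
#' give byte-identical strings.
#'
#' @param report an [EvalReport-class].
#' @return A JSON string.
#' @export
reportAsJson <- function(report) {
  as.character(jsonlite::toJSON(list(
    accuracy = report@accuracy,
    classes = report@classes,
    folds = report@folds,
    seed = report@seed,
    confusion_matrix = unname(apply(report@confusion, 1, as.integer,
                                    simplify = FALSE)),
    fold_assignments = report@foldAssignments,
    predictions = report@predictions,
    labels = report@labels,
    config = report@config,
    notes = report@notes), auto_unbox = TRUE, digits = NA))
}

#' Write an evaluation report to disk
#'
#' Writes `report.json` and `confusion.csv` (class labels as header and
#' first column) under `dir`.
#'
#' @param report an [EvalReport-class].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
writeEvalReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonPath <- file.path(dir, "report.json")
  writeLines(reportAsJson(report), jsonPath)
  csvPath <- file.path(dir, "confusion.csv")
  utils::write.csv(as.data.frame(report@confusion[, , drop = FALSE]),
                   csvPath, row.names = TRUE)
  invisible(c(jsonPath, csvPath))
}
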