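#' @include AllClasses.R
NULL

#' Accessors for leafgrid objects
#'
#' Small generic accessors used across the package instead of direct slot
#' access.
#'
#' @param x an object.
#' @param ... ignored.
#' @return The accessed component; see the individual methods.
#' @name leafgrid-accessors
NULL

#' @rdname leafgrid-accessors
#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))

#' @rdname leafgrid-accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname leafgrid-accessors
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))

#' @rdname leafgrid-accessors
#' @export
setGeneric("accuracy", function(x, ...) standardGeneric("accuracy"))

#' @rdname leafgrid-accessors
#' @export
setGeneric("confusionMatrix", function(x, ...)
  standardGeneric("confusionMatrix"))

#' @rdname leafgrid-accessors
#' @export
setGeneric("foldAssignments", function(x, ...)
  standardGeneric("foldAssignments"))

#' @rdname leafgrid-accessors
#' @export
setGeneric("fusedDim", function(x, ...) standardGeneric("fusedDim"))

#' @rdname leafgrid-accessors
#' @export
setGeneric("tiles", function(x, ...) standardGeneric("tiles"))

#' @rdname leafgrid-accessors
#' @export
setGeneric("sourceBoxes", function(x, ...) standardGeneric("sourceBoxes"))

# ------------------------------------------------------------------- methods

#' @rdname leafgrid-accessors
setMethod("featureValues", "FeatureMatrix", function(x, ...) x@values)

#' @rdname leafgrid-accessors
setMethod("sampleIds", "FeatureMatrix", function(x, ...) x@sampleIds)

#' @rdname leafgrid-accessors
setMethod("provenance", "FeatureMatrix", function(x, ...) x@provenance)

#' @rdname leafgrid-accessors
setMethod("accuracy", "EvalReport", function(x, ...) x@accuracy)

#' @rdname leafgrid-accessors
setMethod("confusionMatrix", "EvalReport", function(x, ...) x@confusion)

#' @rdname leafgrid-accessors
setMethod("foldAssignments", "EvalReport", function(x, ...)
  x@foldAssignments)

#' @rdname leafgrid-accessors
setMethod("fusedDim", "FusionSpec", function(x, ...) {
  nb <- length(x@backboneNames)
  k <- rep_len(x@kPerTile, nb)
  as.integer(x@division@n^2 * sum(k))
})

#' @rdname leafgrid-accessors
setMethod("fusedDim", "PipelineConfig", function(x, ...)
  fusedDim(fusionSpec(divisionSpec(x@n, x@targetSize), x@backbones,
                      x@kPerTile)))

#' @rdname leafgrid-accessors
setMethod("tiles", "TileSet", function(x, ...) x@tiles)

#' @rdname leafgrid-accessors
setMethod("sourceBoxes", "TileSet", function(x, ...) x@sourceBoxes)

# ---------------------------------------------------------------------- show

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox rows %d..%d, cols %d..%d (1-based, inclusive)\n",
              object@rowMin, object@rowMax, object@colMin, object@colMax))
})

setMethod("show", "TileSet", function(object) {
  n <- sqrt(length(object@tiles))
  cat(sprintf("TileSet: %dx%d grid (%d tiles) of a %dx%d image\n",
              n, n, length(object@tiles), object@sourceDim[1],
              object@sourceDim[2]))
})

setMethod("show", "FeatureMatrix", function(object) {
  p <- object@provenance
  tile <- if (all(is.na(p$tile))) "-" else paste(p$tile, collapse = ",")
  cat(sprintf(
    "FeatureMatrix: %d samples x %d dims [backbone=%s tile=%s stage=%s]\n",
    nrow(object@values), ncol(object@values), p$backbone, tile, p$stage))
})

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d components over %d dims; explained variance %s\n",
              object@k, ncol(object@components),
              paste(signif(object@explainedVariance, 3), collapse = ", ")))
})

setMethod("show", "BackboneSpec", function(object) {
  cat(sprintf("BackboneSpec '%s': %d features from %dx%d tiles [%s]\n",
              object@name, object@featureDim, object@inputSize[1],
              object@inputSize[2], object@preprocessingId))
})

setMethod("show", "SvmModel", function(object) {
  cat(sprintf(
    "SvmModel: one-vs-all quadratic kernel, %d classes, dim %d (C=%g)\n",
    length(object@classes), object@dim, object@kernel@C))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport: %d samples, %d classes, %d-fold CV (seed %d)\n",
    length(object@labels), length(object@classes), object@folds,
    object@seed))
  cat(sprintf("  pooled held-out accuracy: %.2f%%\n", object@accuracy))
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d images, %d classes (seed %d), %dx%d px\n",
    length(object@images), length(unique(object@labels)), object@seed,
    dim(object@images[[1]])[1], dim(object@images[[1]])[2]))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: n=%d, k=%s, backbones=[%s], folds=%d, seed=%d%s%s\n",
    object@n, paste(object@kPerTile, collapse = "/"),
    paste(object@backbones, collapse = ", "), object@folds, object@seed,
    if (object@paperMode) ", paper-mode transforms" else "",
    if (!object@cropEnabled) ", cropping disabled" else ""))
})

setMethod("show", "LabeledImageFolder", function(object) {
  cat(sprintf("LabeledImageFolder '%s': %d images in %d classes\n",
              object@root, nrow(object@samples), length(object@classes)))
})
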