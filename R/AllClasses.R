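#' @import methods
NULL

# ---------------------------------------------------------------- BoundingBox

#' Axis-aligned bounding box
#'
#' Tight axis-aligned pixel box, 1-based and inclusive on both ends
#' (the R/Bioconductor indexing convention, as in [IRanges][IRanges::IRanges]).
#' `rowMin`/`rowMax` index image rows (top to bottom), `colMin`/`colMax`
#' columns (left to right).
#'
#' @slot rowMin,rowMax,colMin,colMax integer, 1-based inclusive pixel indices.
#' @export
setClass("BoundingBox",
  representation(rowMin = "integer", rowMax = "integer",
                 colMin = "integer", colMax = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@rowMin < 1L || object@colMin < 1L)
      msg <- c(msg, "box indices are 1-based; minima must be >= 1")
    if (object@rowMin > object@rowMax)
      msg <- c(msg, "rowMin must be <= rowMax")
    if (object@colMin > object@colMax)
      msg <- c(msg, "colMin must be <= colMax")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a BoundingBox
#'
#' @param rowMin,rowMax,colMin,colMax 1-based inclusive pixel indices.
#' @return A [BoundingBox-class] object.
#' @examples
#' boundingBox(10, 20, 5, 15)
#' @export
boundingBox <- function(rowMin, rowMax, colMin, colMax) {
  new("BoundingBox", rowMin = as.integer(rowMin), rowMax = as.integer(rowMax),
      colMin = as.integer(colMin), colMax = as.integer(colMax))
}

# ------------------------------------------------------------- configuration

#' Segmentation configuration
#'
#' Controls the background-removal stage: thresholding mode, structuring
#' element radius for the erosion cleanup, the smallest object (as a fraction
#' of image area) accepted as a leaf, and foreground polarity.
#'
#' @slot thresholdMode `"otsu"` (threshold maximizing between-class variance
#'   over a 256-bin histogram) or `"fixed"`.
#' @slot fixedT fixed threshold in (0, 1); used only when
#'   `thresholdMode == "fixed"`.
#' @slot erosionRadius nonnegative integer radius of the Euclidean-disk
#'   structuring element used to erode the mask.
#' @slot minObjectFraction smallest admissible leaf area as a fraction of the
#'   image area; guards against speckle winning the largest-object selection.
#' @slot invert logical; `FALSE` (default) treats pixels *below* the threshold
#'   as foreground (leaf darker than background), `TRUE` flips the polarity
#'   for dark-background datasets.
#' @export
setClass("SegmentationConfig",
  representation(thresholdMode = "character", fixedT = "numeric",
                 erosionRadius = "integer", minObjectFraction = "numeric",
                 invert = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!object@thresholdMode %in% c("otsu", "fixed"))
      msg <- c(msg, "thresholdMode must be 'otsu' or 'fixed'")
    if (object@thresholdMode == "fixed" &&
        (length(object@fixedT) != 1L || is.na(object@fixedT) ||
         object@fixedT <= 0 || object@fixedT >= 1))
      msg <- c(msg, "fixed mode requires fixedT in (0, 1)")
    if (object@erosionRadius < 0L)
      msg <- c(msg, "erosionRadius must be >= 0")
    if (object@minObjectFraction < 0 || object@minObjectFraction >= 1)
      msg <- c(msg, "minObjectFraction must lie in [0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SegmentationConfig
#'
#' @param thresholdMode `"otsu"` or `"fixed"`.
#' @param fixedT threshold in (0, 1), required iff `thresholdMode = "fixed"`.
#' @param erosionRadius disk radius for mask erosion (default 1).
#' @param minObjectFraction minimum leaf area fraction (default 0.001).
#' @param invert flip foreground polarity (default `FALSE`).
#' @return A [SegmentationConfig-class] object.
#' @examples
#' segmentationConfig()                       # Otsu, radius-1 disk
#' segmentationConfig("fixed", fixedT = 0.5)
#' @export
segmentationConfig <- function(thresholdMode = c("otsu", "fixed"),
                               fixedT = NA_real_, erosionRadius = 1L,
                               minObjectFraction = 0.001, invert = FALSE) {
  new("SegmentationConfig", thresholdMode = match.arg(thresholdMode),
      fixedT = as.numeric(fixedT), erosionRadius = as.integer(erosionRadius),
      minObjectFraction = as.numeric(minObjectFraction),
      invert = isTRUE(invert))
}

#' Grid-division specification
#'
#' @slot n grid order: the image is divided into `n` x `n` tiles. The
#'   supported study grid sizes are 2--5; other `n >= 1` are allowed with a
#'   warning at construction.
#' @slot targetSize integer (height, width) every tile is resized to before
#'   feature extraction; default `c(224, 224)`, the input size of the
#'   1,000-way backbones.
#' @export
setClass("DivisionSpec",
  representation(n = "integer", targetSize = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@n) != 1L || object@n < 1L)
      msg <- c(msg, "n must be a single integer >= 1")
    if (length(object@targetSize) != 2L || any(object@targetSize < 1L))
      msg <- c(msg, "targetSize must be two positive integers")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a DivisionSpec
#'
#' @param n grid order (2--5 are the evaluated sizes).
#' @param targetSize tile size (height, width) after bilinear resizing.
#' @return A [DivisionSpec-class] object.
#' @examples
#' divisionSpec(2)
#' @export
divisionSpec <- function(n = 2L, targetSize = c(224L, 224L)) {
  n <- as.integer(n)
  if (length(n) == 1L && !is.na(n) && n >= 1L && !n %in% 2:5)
    warning("grid order n = ", n, " is outside the evaluated range 2..5",
            call. = FALSE)
  new("DivisionSpec", n = n, targetSize = as.integer(targetSize))
}

#' Quadratic-kernel specification
#'
#' Parameters of the degree-2 polynomial (quadratic) kernel
#' k(x, y) = (gamma * <x, y> + coef0)^2 and the soft-margin box constraint C.
#' The polynomial degree is fixed at 2.
#'
#' @slot gamma positive inner-product scale; `NA` means "resolve to
#'   1/fused_dim when the machine is trained".
#' @slot coef0 additive offset inside the square (default 1).
#' @slot C positive box constraint of the soft margin (default 1).
#' @export
setClass("KernelSpec",
  representation(gamma = "numeric", coef0 = "numeric", C = "numeric"),
  prototype = list(gamma = NA_real_, coef0 = 1, C = 1),
  validity = function(object) {
    msg <- NULL
    if (!is.na(object@gamma) && object@gamma <= 0)
      msg <- c(msg, "gamma must be positive (or NA for 1/fused_dim)")
    if (object@C <= 0) msg <- c(msg, "C must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a KernelSpec
#'
#' @param gamma kernel scale; `NA` (default) resolves to 1/fused dimension
#'   at training time.
#' @param coef0 kernel offset, default 1.
#' @param C box constraint, default 1.
#' @return A [KernelSpec-class] object.
#' @examples
#' kernelSpec()
#' kernelSpec(gamma = 1, coef0 = 0, C = 100)
#' @export
kernelSpec <- function(gamma = NA_real_, coef0 = 1, C = 1) {
  k <- new("KernelSpec", gamma = as.numeric(gamma),
           coef0 = as.numeric(coef0))
  k@C <- as.numeric(C)  # named arg would partially match new()'s Class
  validObject(k)
  k
}

# -------------------------------------------------------------------- tiling

#' An ordered set of image tiles
#'
#' The n^2 sub-images of one source image in row-major grid order, with the
#' grid coordinate and source bounding box of every tile. The source boxes
#' partition the source image exactly.
#'
#' @slot tiles list of H x W x 3 arrays in row-major grid order.
#' @slot gridCoords integer matrix (n^2 x 2) of 1-based (gridRow, gridCol).
#' @slot sourceBoxes list of [BoundingBox-class], one per tile, into the
#'   source image.
#' @slot sourceDim integer (height, width) of the source image.
#' @export
setClass("TileSet",
  representation(tiles = "list", gridCoords = "matrix",
                 sourceBoxes = "list", sourceDim = "integer"),
  validity = function(object) {
    msg <- NULL
    k <- length(object@tiles)
    n <- sqrt(k)
    if (n != round(n)) msg <- c(msg, "tile count must be a perfect square")
    if (nrow(object@gridCoords) != k || length(object@sourceBoxes) != k)
      msg <- c(msg, "gridCoords and sourceBoxes must match the tile count")
    area <- sum(vapply(object@sourceBoxes, function(b)
      (b@rowMax - b@rowMin + 1) * (b@colMax - b@colMin + 1), numeric(1)))
    if (k > 0 && area != prod(object@sourceDim))
      msg <- c(msg, "source boxes must partition the source image")
    if (is.null(msg)) TRUE else msg
  })

# ------------------------------------------------------------------ features

#' Backbone feature-extractor specification
#'
#' The pluggable contract through which per-tile deep features are obtained:
#' a named extractor mapping one resized RGB tile to a fixed-length numeric
#' vector. Production adapters wrap pretrained 1,000-way convolutional
#' networks; the deterministic stand-in backbone ([standinBackbone()]) serves
#' tests and examples without any model download.
#'
#' @slot name backbone identifier, e.g. `"resnet101"`, `"densenet201"`,
#'   `"standin"`.
#' @slot featureDim output vector length (default 1000, the class-score
#'   layer width of the pretrained nets).
#' @slot inputSize required tile size (height, width).
#' @slot preprocessingId identifier of the normalization recipe the extractor
#'   applies internally, recorded so feature files are self-describing.
#' @slot extractor function(H x W x 3 array) -> numeric(featureDim).
#' @export
setClass("BackboneSpec",
  representation(name = "character", featureDim = "integer",
                 inputSize = "integer", preprocessingId = "character",
                 extractor = "function"),
  validity = function(object) {
    msg <- NULL
    if (object@featureDim < 1L) msg <- c(msg, "featureDim must be positive")
    if (length(object@inputSize) != 2L || any(object@inputSize < 1L))
      msg <- c(msg, "inputSize must be two positive integers")
    if (is.null(msg)) TRUE else msg
  })

#' Feature matrix with provenance
#'
#' A samples x dimensions numeric matrix plus the provenance needed to keep
#' multi-tile, multi-backbone bookkeeping honest: which backbone produced it,
#' which tile position it came from, and its processing stage (`"raw"`
#' backbone output, `"reduced"` after PCA, `"fused"` after concatenation).
#'
#' @slot values numeric matrix, one row per sample, all entries finite.
#' @slot sampleIds character, one id per row.
#' @slot provenance list with elements `backbone`, `tile` (1-based
#'   (gridRow, gridCol) or `NA`), `stage`.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", sampleIds = "character",
                 provenance = "list"),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@values))
      msg <- c(msg, "values must be numeric")
    if (nrow(object@values) != length(object@sampleIds))
      msg <- c(msg, "sampleIds length must equal the row count")
    if (length(object@values) && !all(is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    st <- object@provenance$stage
    if (is.null(st) || !st %in% c("raw", "reduced", "fused"))
      msg <- c(msg, "provenance$stage must be raw, reduced or fused")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix (samples x dims).
#' @param sampleIds sample identifiers, one per row; defaults to rownames or
#'   `sample_1 ... sample_m`.
#' @param backbone backbone name for provenance.
#' @param tile 1-based (gridRow, gridCol) of the originating tile, or `NA`.
#' @param stage `"raw"`, `"reduced"` or `"fused"`.
#' @return A [FeatureMatrix-class] object.
#' @export
featureMatrix <- function(values, sampleIds = NULL, backbone = "unknown",
                          tile = NA, stage = "raw") {
  values <- as.matrix(values)
  if (is.null(sampleIds))
    sampleIds <- rownames(values) %||% paste0("sample_", seq_len(nrow(values)))
  new("FeatureMatrix", values = unname(values),
      sampleIds = as.character(sampleIds),
      provenance = list(backbone = backbone, tile = tile, stage = stage))
}

# --------------------------------------------------------------- reduce/fuse

#' Fitted principal-component model
#'
#' Orthonormal projection onto the top-k directions of maximal training
#' variance, used to select effective features from each tile's raw
#' backbone output.
#'
#' @slot center training column means (length = input dims).
#' @slot components k x dims matrix with orthonormal rows ordered by
#'   descending explained variance; the largest-magnitude loading of each row
#'   is forced positive so results are backend-independent.
#' @slot explainedVariance nonincreasing, nonnegative variances of the
#'   training scores (n - 1 denominator).
#' @slot k number of retained components.
#' @export
setClass("PcaModel",
  representation(center = "numeric", components = "matrix",
                 explainedVariance = "numeric", k = "integer"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@components) != object@k)
      msg <- c(msg, "components must have k rows")
    if (length(object@explainedVariance) != object@k)
      msg <- c(msg, "explainedVariance must have length k")
    if (any(object@explainedVariance < -1e-12))
      msg <- c(msg, "explainedVariance must be nonnegative")
    if (object@k > 1 && any(diff(object@explainedVariance) > 1e-8))
      msg <- c(msg, "explainedVariance must be nonincreasing")
    g <- tcrossprod(object@components)
    if (max(abs(g - diag(nrow(g)))) > 1e-8)
      msg <- c(msg, "component rows must be orthonormal within 1e-8")
    if (is.null(msg)) TRUE else msg
  })

#' z-score normalization parameters
#'
#' Per-column mean and standard deviation learned on training data and
#' applied as (x - mean) / (sd + epsilon); the epsilon guard maps
#' constant columns to zero instead of NaN.
#'
#' @slot mean,sd numeric vectors over the fused dimensions.
#' @slot epsilon small positive guard added to every sd.
#' @export
setClass("ZScoreParams",
  representation(mean = "numeric", sd = "numeric", epsilon = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@mean) != length(object@sd))
      msg <- c(msg, "mean and sd must have equal length")
    if (any(object@sd < 0)) msg <- c(msg, "sd entries must be >= 0")
    if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Fusion specification
#'
#' Fixes the ordered structure of the fused feature vector: grid division,
#' backbone order, and the number k of principal components kept per
#' (backbone, tile) block. The fused dimension is always
#' n^2 * sum over backbones of k.
#'
#' @slot division a [DivisionSpec-class].
#' @slot backboneNames ordered backbone names (fusion is backbone-major).
#' @slot kPerTile integer k per backbone (length 1 recycled, or one k per
#'   backbone).
#' @export
setClass("FusionSpec",
  representation(division = "DivisionSpec", backboneNames = "character",
                 kPerTile = "integer"),
  validity = function(object) {
    msg <- NULL
    nb <- length(object@backboneNames)
    if (nb < 1L) msg <- c(msg, "at least one backbone is required")
    if (!length(object@kPerTile) %in% c(1L, nb))
      msg <- c(msg, "kPerTile must have length 1 or one entry per backbone")
    if (any(object@kPerTile < 1L)) msg <- c(msg, "kPerTile must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a FusionSpec
#'
#' @param division a [DivisionSpec-class] (or grid order n).
#' @param backboneNames ordered character vector of backbone names.
#' @param kPerTile components kept per (backbone, tile) block; scalar or one
#'   value per backbone. Default 30.
#' @return A [FusionSpec-class] object.
#' @examples
#' fusedDim(fusionSpec(2, c("resnet101", "densenet201"), 30))  # 240
#' @export
fusionSpec <- function(division, backboneNames, kPerTile = 30L) {
  if (!is(division, "DivisionSpec")) division <- divisionSpec(division)
  new("FusionSpec", division = division,
      backboneNames = as.character(backboneNames),
      kPerTile = as.integer(kPerTile))
}

#' Fitted per-fold transforms
#'
#' The per-(backbone, tile) PCA models plus the global z-score parameters,
#' all fitted on training rows only, bundled with the fusion layout that
#' produced them.
#'
#' @slot pcas list of [PcaModel-class], one per fused block, in fusion order
#'   (backbone-major, tiles row-major).
#' @slot zscore a [ZScoreParams-class] over the fused dimensions.
#' @slot fusion the [FusionSpec-class] the transforms were fitted under.
#' @export
setClass("FittedTransforms",
  representation(pcas = "list", zscore = "ZScoreParams",
                 fusion = "FusionSpec"))

# ------------------------------------------------------------------ classify

#' One-vs-all SVM model
#'
#' One binary soft-margin machine per class (that class against the rest),
#' each with its support vectors, dual coefficients alpha_i * y_i and bias.
#' Multiclass decision is the argmax of the per-class decision values, ties
#' broken by the lowest class index.
#'
#' @slot machines list of fitted binary machines (one per class, in class
#'   order), each a list with `svm` (the underlying solver fit), `flip`
#'   (decision-value orientation), and `class`.
#' @slot classes ordered class labels.
#' @slot kernel the [KernelSpec-class] used, with gamma resolved.
#' @slot dim training feature dimension.
#' @export
setClass("SvmModel",
  representation(machines = "list", classes = "character",
                 kernel = "KernelSpec", dim = "integer"),
  validity = function(object) {
    if (length(object@machines) != length(object@classes))
      "one binary machine per class is required" else TRUE
  })

#' Cross-validation evaluation report
#'
#' Pooled held-out predictions of a stratified k-fold cross-validation, with
#' the fold assignment of every sample, overall accuracy (percent), the
#' confusion matrix (rows = true class), and an echo of the configuration
#' and seed that produced the report.
#'
#' @slot accuracy pooled held-out accuracy in percent
#'   (100 * trace / total of the confusion matrix).
#' @slot confusion C x C integer matrix of counts, rows = true classes.
#' @slot foldAssignments integer fold index per sample (1..folds).
#' @slot predictions held-out predicted class per sample.
#' @slot labels true class per sample.
#' @slot classes ordered class labels.
#' @slot folds number of folds actually used.
#' @slot seed RNG seed that shuffled the folds.
#' @slot config configuration echo (named list).
#' @slot notes character vector of warnings recorded during evaluation.
#' @export
setClass("EvalReport",
  representation(accuracy = "numeric", confusion = "matrix",
                 foldAssignments = "integer", predictions = "character",
                 labels = "character", classes = "character",
                 folds = "integer", seed = "integer", config = "list",
                 notes = "character"),
  validity = function(object) {
    msg <- NULL
    ns <- length(object@labels)
    if (length(object@predictions) != ns || length(object@foldAssignments) != ns)
      msg <- c(msg, "predictions and foldAssignments must cover every sample")
    if (sum(object@confusion) != ns)
      msg <- c(msg, "confusion-matrix total must equal the sample count")
    acc <- 100 * sum(diag(object@confusion)) / max(1, ns)
    if (abs(acc - object@accuracy) > 1e-8)
      msg <- c(msg, "accuracy must equal 100 * trace / total")
    if (is.null(msg)) TRUE else msg
  })

# ----------------------------------------------------------------- synthetic

#' Synthetic leaf class parameters
#'
#' Shape, texture and color parameters of one synthetic species: a lobed
#' polar contour r(theta) = R * (1 + lobeDepth * cos(lobeCount * theta))
#' stretched by `aspectRatio`, shaded with a sinusoidal vein texture, drawn
#' on a uniform monochrome-gray, red or white background. Leaf colors are
#' constrained darker (in grayscale) than every background so the
#' darker-than-background thresholding polarity holds by construction.
#'
#' @slot aspectRatio width/height stretch of the leaf (> 0).
#' @slot lobeCount number of contour lobes (0 = smooth ellipse).
#' @slot lobeDepth relative lobe amplitude in [0, 0.5).
#' @slot textureFrequency vein-stripe spatial frequency (cycles across the
#'   leaf).
#' @slot leafColor RGB triple in [0, 1]^3.
#' @slot background `"gray"` (0.85 monochrome), `"red"` or `"white"`.
#' @export
setClass("LeafClassParams",
  representation(aspectRatio = "numeric", lobeCount = "integer",
                 lobeDepth = "numeric", textureFrequency = "numeric",
                 leafColor = "numeric", background = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@aspectRatio <= 0) msg <- c(msg, "aspectRatio must be > 0")
    if (object@lobeDepth < 0 || object@lobeDepth >= 0.5)
      msg <- c(msg, "lobeDepth must lie in [0, 0.5)")
    if (object@textureFrequency <= 0)
      msg <- c(msg, "textureFrequency must be positive")
    if (length(object@leafColor) != 3L || any(object@leafColor < 0) ||
        any(object@leafColor > 1))
      msg <- c(msg, "leafColor must be an RGB triple in [0,1]")
    if (!object@background %in% c("gray", "red", "white"))
      msg <- c(msg, "background must be gray, red or white")
    if (is.null(msg)) TRUE else msg
  })

#' Construct LeafClassParams
#'
#' @param aspectRatio leaf width/height stretch.
#' @param lobeCount integer number of lobes (0 for a smooth ellipse).
#' @param lobeDepth lobe amplitude in [0, 0.5).
#' @param textureFrequency vein-stripe frequency.
#' @param leafColor RGB triple; keep it dark so the leaf stays darker than
#'   the background in grayscale.
#' @param background `"gray"`, `"red"` or `"white"`.
#' @return A [LeafClassParams-class] object.
#' @export
leafClassParams <- function(aspectRatio = 1, lobeCount = 0L, lobeDepth = 0,
                            textureFrequency = 4,
                            leafColor = c(0.15, 0.4, 0.12),
                            background = "gray") {
  new("LeafClassParams", aspectRatio = as.numeric(aspectRatio),
      lobeCount = as.integer(lobeCount), lobeDepth = as.numeric(lobeDepth),
      textureFrequency = as.numeric(textureFrequency),
      leafColor = as.numeric(leafColor), background = background)
}

#' Synthetic leaf-image dataset
#'
#' Labeled synthetic leaf images with per-image ground truth: the exact
#' rendered foreground mask and its tight bounding box, so segmentation and
#' the full pipeline are testable without external data.
#'
#' @slot images list of H x W x 3 arrays in [0, 1].
#' @slot labels character class label per image.
#' @slot truthMasks list of {0,1} matrices, the exact rendered leaf support.
#' @slot truthBoxes list of [BoundingBox-class], tight boxes of the masks.
#' @slot seed integer seed the dataset was generated from.
#' @slot classParams named list of [LeafClassParams-class] per class.
#' @export
setClass("SyntheticDataset",
  representation(images = "list", labels = "character", truthMasks = "list",
                 truthBoxes = "list", seed = "integer", classParams = "list"),
  validity = function(object) {
    n <- length(object@images)
    if (length(object@labels) != n || length(object@truthMasks) != n ||
        length(object@truthBoxes) != n)
      "one label, mask and box per image is required" else TRUE
  })

# ------------------------------------------------------------------ pipeline

#' End-to-end pipeline configuration
#'
#' Everything one evaluation run depends on: grid order, per-tile component
#' count, backbone list, segmentation settings, kernel, folds, seed, the
#' transform-fitting protocol, and whether cropping is enabled. Round-trips
#' through JSON via [writePipelineConfig()] / [readPipelineConfig()], and is
#' echoed inside every report it produces.
#'
#' @slot n grid order.
#' @slot targetSize tile size after resizing (height, width).
#' @slot kPerTile components per (backbone, tile) block.
#' @slot backbones backbone names, fusion order. `"standin"` entries are
#'   instantiated internally from the run seed; other names require extractor
#'   functions supplied to [runPipeline()].
#' @slot segmentation a [SegmentationConfig-class].
#' @slot kernel a [KernelSpec-class].
#' @slot folds cross-validation folds (default 10).
#' @slot seed master seed; every source of randomness (fold shuffle, stand-in
#'   projection, synthetic jitter) derives from it.
#' @slot paperMode logical; `FALSE` (default) fits PCA and z-score inside
#'   each training fold, `TRUE` fits them once on all data (a plausible but
#'   potentially optimistic protocol; see the vignette).
#' @slot cropEnabled logical; background cropping is an optional stage.
#' @export
setClass("PipelineConfig",
  representation(n = "integer", targetSize = "integer", kPerTile = "integer",
                 backbones = "character", segmentation = "SegmentationConfig",
                 kernel = "KernelSpec", folds = "integer", seed = "integer",
                 paperMode = "logical", cropEnabled = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (object@folds < 2L) msg <- c(msg, "folds must be >= 2")
    if (length(object@backbones) < 1L)
      msg <- c(msg, "at least one backbone is required")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a PipelineConfig
#'
#' @param n grid order, default 2.
#' @param kPerTile principal components per (backbone, tile), default 30.
#' @param backbones backbone name vector, default `"standin"`.
#' @param segmentation a [SegmentationConfig-class].
#' @param kernel a [KernelSpec-class].
#' @param folds cross-validation folds, default 10.
#' @param seed master seed, default 1.
#' @param paperMode fit transforms on all data instead of per fold.
#' @param cropEnabled run the background-cropping stage, default `TRUE`.
#' @param targetSize tile size, default `c(224, 224)`.
#' @return A [PipelineConfig-class] object.
#' @examples
#' pipelineConfig(n = 2, kPerTile = 10, folds = 5, seed = 42)
#' @export
pipelineConfig <- function(n = 2L, kPerTile = 30L, backbones = "standin",
                           segmentation = segmentationConfig(),
                           kernel = kernelSpec(), folds = 10L, seed = 1L,
                           paperMode = FALSE, cropEnabled = TRUE,
                           targetSize = c(224L, 224L)) {
  new("PipelineConfig", n = as.integer(n), targetSize = as.integer(targetSize),
      kPerTile = as.integer(kPerTile), backbones = as.character(backbones),
      segmentation = segmentation, kernel = kernel, folds = as.integer(folds),
      seed = as.integer(seed), paperMode = isTRUE(paperMode),
      cropEnabled = isTRUE(cropEnabled))
}

#' Labeled image folder
#'
#' A class-per-subdirectory image dataset root (the layout of the classic
#' leaf benchmarks): class names are the subdirectory names, samples are the
#' image files inside them, both in sorted order so runs are deterministic.
#'
#' @slot root dataset root directory.
#' @slot samples data.frame with columns `path`, `class`, sorted.
#' @slot classes ordered class names.
#' @export
setClass("LabeledImageFolder",
  representation(root = "character", samples = "data.frame",
                 classes = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@classes) < 2L)
      msg <- c(msg, "at least 2 classes are required")
    if (!all(c("path", "class") %in% names(object@samples)))
      msg <- c(msg, "samples must have columns path and class")
    if (is.null(msg)) TRUE else msg
  })
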