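#' @include AllClasses.R
NULL

# Block-mean pooling of one channel to a g x g grid, using the same
# ceil-first band partition as the tiler.
poolChannel <- function(m, g) {
  rg <- rep.int(seq_len(g), bandSizes(nrow(m), g))
  cg <- rep.int(seq_len(g), bandSizes(ncol(m), g))
  sums <- rowsum(t(rowsum(m, rg)), cg)              # g x g (cols x rows)
  counts <- tcrossprod(tabulate(rg, g), tabulate(cg, g))
  t(sums) / counts
}

#' Deterministic stand-in backbone
#'
#' A test-time feature extractor fulfilling the backbone contract with no
#' model download: each tile is block-mean pooled to a `poolGrid` x
#' `poolGrid` x 3 grid, flattened, and passed through a fixed random linear
#' projection to `featureDim` outputs. The projection matrix is generated
#' once from `seed`, so the extractor is pure and bit-reproducible, and the
#' map is linear (a zero tile yields a zero vector).
#'
#' @param seed integer seed generating the projection matrix.
#' @param featureDim output dimension, default 1000 (matching the
#'   class-score layer width of the pretrained backbones).
#' @param poolGrid pooling grid order, default 8.
#' @param inputSize required tile size, default `c(224, 224)`.
#' @param name backbone identifier, default `"standin"`.
#' @return A [BackboneSpec-class].
#' @examples
#' bb <- standinBackbone(seed = 1)
#' length(bb@extractor(array(0.5, c(224, 224, 3))))  # 1000
#' @export
standinBackbone <- function(seed = 1L, featureDim = 1000L, poolGrid = 8L,
                            inputSize = c(224L, 224L), name = "standin") {
  featureDim <- as.integer(featureDim)
  poolGrid <- as.integer(poolGrid)
  d <- 3L * poolGrid^2
  proj <- withSeed(seed, matrix(stats::rnorm(featureDim * d), featureDim, d)) /
    sqrt(d)
  inputSize <- as.integer(inputSize)
  extractor <- function(tile) {
    pooled <- vapply(1:3, function(c) poolChannel(tile[, , c], poolGrid),
                     matrix(0, poolGrid, poolGrid))
    as.numeric(proj %*% as.numeric(pooled))
  }
  new("BackboneSpec", name = name, featureDim = featureDim,
      inputSize = inputSize,
      preprocessingId = sprintf("pool%d-randproj-seed%d", poolGrid,
                                as.integer(seed)),
      extractor = extractor)
}

#' Pretrained-backbone adapter contract
#'
#' Wraps a user-supplied extractor for a pretrained 1,000-way convolutional
#' network (e.g. ResNet101 or DenseNet201) in the backbone contract. The
#' extractor must map one `inputSize` RGB tile (H x W x 3 array in [0, 1])
#' to a numeric vector of length `featureDim` — conventionally the 1,000-way
#' class-score layer output — and apply the network's own input
#' normalization internally (identified by `preprocessingId` so feature
#' files are self-describing). Pretrained weights are not bundled with this
#' package; without an `extractor`, construction fails with a pointer to
#' this contract.
#'
#' @param name `"resnet101"` or `"densenet201"` (any identifier is
#'   accepted).
#' @param extractor function(tile array) -> numeric(featureDim).
#' @param featureDim output dimension, default 1000.
#' @param inputSize required tile size, default `c(224, 224)` (the input
#'   size of both reference architectures).
#' @param preprocessingId normalization recipe identifier, default
#'   `"imagenet-mean-std"`.
#' @return A [BackboneSpec-class].
#' @export
pretrainedBackbone <- function(name, extractor = NULL, featureDim = 1000L,
                               inputSize = c(224L, 224L),
                               preprocessingId = "imagenet-mean-std") {
  if (is.null(extractor))
    stop("backbone '", name, "' needs an extractor function ",
         "(tile array -> numeric feature vector); pretrained weights are ",
         "not bundled. See ?pretrainedBackbone for the contract, or use ",
         "standinBackbone() for a deterministic test-time extractor.",
         call. = FALSE)
  new("BackboneSpec", name = name, featureDim = as.integer(featureDim),
      inputSize = as.integer(inputSize), preprocessingId = preprocessingId,
      extractor = extractor)
}

#' Extract per-tile deep features
#'
#' Runs the backbone extractor over a list of resized tiles and stacks the
#' resulting vectors into a raw [FeatureMatrix-class], one row per tile in
#' input order. Extraction is pure: identical inputs give bit-identical
#' matrices.
#'
#' @param tiles list of H x W x 3 arrays, all at the backbone `inputSize`.
#' @param backbone a [BackboneSpec-class].
#' @param sampleIds optional ids, one per tile.
#' @param tileCoord 1-based (gridRow, gridCol) recorded in provenance, or
#'   `NA`.
#' @return A [FeatureMatrix-class] with stage `"raw"` and `featureDim`
#'   columns.
#' @examples
#' bb <- standinBackbone(seed = 1)
#' fm <- extractFeatures(list(array(0.2, c(224, 224, 3))), bb)
#' dim(featureValues(fm))  # 1 x 1000
#' @export
extractFeatures <- function(tiles, backbone, sampleIds = NULL,
                            tileCoord = NA) {
  if (!is(backbone, "BackboneSpec"))
    stop("unknown backbone: pass a BackboneSpec", call. = FALSE)
  vals <- matrix(0, length(tiles), backbone@featureDim)
  for (i in seq_along(tiles)) {
    tile <- tiles[[i]]
    if (!all(dim(tile)[1:2] == backbone@inputSize))
      stop(sprintf(
        "tile %d is %d x %d but backbone '%s' expects %d x %d",
        i, dim(tile)[1], dim(tile)[2], backbone@name,
        backbone@inputSize[1], backbone@inputSize[2]), call. = FALSE)
    v <- backbone@extractor(tile)
    if (length(v) != backbone@featureDim)
      stop(sprintf("backbone '%s' returned %d values, expected %d",
                   backbone@name, length(v), backbone@featureDim),
           call. = FALSE)
    vals[i, ] <- v
  }
  featureMatrix(vals, sampleIds = sampleIds, backbone = backbone@name,
                tile = tileCoord, stage = "raw")
}
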