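#' @include AllClasses.R
NULL

#' Load a class-per-subdirectory image folder
#'
#' Subdirectory names become class labels; files inside them are the
#' samples. Both are sorted, so the sample order is deterministic.
#'
#' @param root dataset root directory.
#' @return A [LabeledImageFolder-class].
#' @export
loadImageFolder <- function(root) {
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  classes <- classes[nzchar(classes)]
  samples <- do.call(rbind, lapply(classes, function(cls) {
    files <- sort(list.files(file.path(root, cls), full.names = TRUE,
                             pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                             ignore.case = TRUE))
    if (!length(files))
      stop("class directory '", cls, "' contains no images", call. = FALSE)
    data.frame(path = files, class = cls)
  }))
  new("LabeledImageFolder", root = root, samples = samples,
      classes = classes)
}

# ----------------------------------------------------------- config <-> JSON

#' Represent a PipelineConfig as a plain list
#'
#' @param config a [PipelineConfig-class].
#' @return A named list mirroring every configuration field; this is the
#'   form echoed inside reports and serialized to JSON.
#' @export
configAsList <- function(config) {
  s <- config@segmentation
  k <- config@kernel
  list(n = config@n, target_size = config@targetSize,
       k_per_tile = config@kPerTile, backbones = config@backbones,
       segmentation = list(threshold_mode = s@thresholdMode,
                           fixed_t = s@fixedT,
                           erosion_radius = s@erosionRadius,
                           min_object_fraction = s@minObjectFraction,
                           invert = s@invert),
       kernel = list(degree = 2L, gamma = k@gamma, coef0 = k@coef0,
                     C = k@C),
       folds = config@folds, seed = config@seed,
       paper_mode = config@paperMode, crop_enabled = config@cropEnabled)
}

#' Write a PipelineConfig to a JSON file
#'
#' @param config a [PipelineConfig-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(configAsList(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a PipelineConfig from a JSON file
#'
#' Inverse of [writePipelineConfig()]: the round trip reproduces the
#' configuration exactly.
#'
#' @param path JSON file path.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- l$segmentation
  pipelineConfig(
    n = l$n, kPerTile = l$k_per_tile, backbones = l$backbones,
    segmentation = segmentationConfig(
      thresholdMode = s$threshold_mode, fixedT = s$fixed_t,
      erosionRadius = s$erosion_radius,
      minObjectFraction = s$min_object_fraction, invert = s$invert),
    kernel = kernelSpec(gamma = l$kernel$gamma, coef0 = l$kernel$coef0,
                        C = l$kernel$C),
    folds = l$folds, seed = l$seed, paperMode = l$paper_mode,
    cropEnabled = l$crop_enabled, targetSize = l$target_size)
}

# ------------------------------------------------------------ stage helpers

resolveDataset <- function(data) {
  if (is(data, "SyntheticDataset"))
    return(list(images = data@images, labels = data@labels,
                ids = sprintf("%s_%04d", data@labels,
                              seq_along(data@images))))
  if (is.character(data)) data <- loadImageFolder(data)
  if (!is(data, "LabeledImageFolder"))
    stop("data must be a SyntheticDataset, LabeledImageFolder or path",
         call. = FALSE)
  images <- lapply(data@samples$path, function(p)
    tryCatch(loadRgbImage(p),
             error = function(e) stopStage("load", p, conditionMessage(e))))
  list(images = images, labels = data@samples$class,
       ids = data@samples$path)
}

resolveBackbones <- function(config, extractors = list()) {
  lapply(seq_along(config@backbones), function(i) {
    nm <- config@backbones[i]
    if (nm == "standin")
      standinBackbone(seed = deriveSeed(config@seed, 7000 + i),
                      inputSize = config@targetSize)
    else if (!is.null(extractors[[nm]]))
      pretrainedBackbone(nm, extractor = extractors[[nm]],
                         inputSize = config@targetSize)
    else stop("configuration error: backbone '", nm,
              "' has no extractor; supply one via extractors=",
              call. = FALSE)
  })
}

cropImages <- function(images, ids, config) {
  lapply(seq_along(images), function(i)
    tryCatch(segmentLeaf(images[[i]], config@segmentation)$image,
             error = function(e)
               stopStage("segmentation", ids[i], conditionMessage(e))))
}

# Per-(backbone, tile) raw blocks in fusion order (backbone-major, tiles
# row-major). One pass divides and resizes each image; each backbone then
# consumes the resized tiles.
featurizeImages <- function(images, ids, config, backbones) {
  division <- divisionSpec(config@n, config@targetSize)
  n2 <- config@n^2
  resized <- lapply(seq_along(images), function(i)
    tryCatch({
      ts <- divideImage(images[[i]], division)
      lapply(ts@tiles, resizeTile, spec = division)
    }, error = function(e)
      stopStage("tiling", ids[i], conditionMessage(e))))
  coords <- cbind(gridRow = rep(seq_len(config@n), each = config@n),
                  gridCol = rep(seq_len(config@n), times = config@n))
  blocks <- vector("list", n2 * length(backbones))
  for (b in seq_along(backbones)) for (t in seq_len(n2)) {
    tiles <- lapply(resized, `[[`, t)
    blocks[[(b - 1L) * n2 + t]] <-
      extractFeatures(tiles, backbones[[b]], sampleIds = ids,
                      tileCoord = coords[t, ])
  }
  blocks
}

cacheKey <- function(config, ids) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(as.character(jsonlite::toJSON(configAsList(config),
                                             auto_unbox = TRUE,
                                             digits = NA)), ids), tmp)
  unname(tools::md5sum(tmp))
}

#' Compute raw per-(backbone, tile) feature blocks for a dataset
#'
#' The featurization front half of [runPipeline()]: optional background
#' cropping, grid division, bilinear tile resizing, and per-tile backbone
#' extraction, returning the raw feature blocks in fusion order
#' (backbone-major, tiles row-major).
#'
#' @param config a [PipelineConfig-class].
#' @param data a [SyntheticDataset-class], [LabeledImageFolder-class] or
#'   dataset root path.
#' @param extractors named list of extractor functions for non-stand-in
#'   backbones.
#' @return A list with `blocks` (raw [FeatureMatrix-class] list), `labels`
#'   and `ids`.
#' @export
featurizeDataset <- function(config, data, extractors = list()) {
  ds <- resolveDataset(data)
  backbones <- resolveBackbones(config, extractors)
  images <- if (config@cropEnabled)
    cropImages(ds$images, ds$ids, config) else ds$images
  list(blocks = featurizeImages(images, ds$ids, config, backbones),
       labels = ds$labels, ids = ds$ids)
}

# ----------------------------------------------------------------- pipeline

#' Run the full evaluation pipeline
#'
#' Executes the enabled stages in order — background cropping, n x n
#' division with bilinear tile resizing, per-tile backbone feature
#' extraction, per-(backbone, tile) PCA selection, fusion with z-score
#' normalization, and stratified k-fold cross-validation of the one-vs-all
#' quadratic-kernel SVM — and returns the evaluation report with the
#' configuration echoed inside it. A stage failure propagates with the
#' stage name and the failing sample.
#'
#' With `cacheDir` set, the raw feature blocks are cached on disk keyed by
#' a hash of the configuration and sample ids; a cached run returns
#' identical results.
#'
#' @param config a [PipelineConfig-class].
#' @param data a [SyntheticDataset-class], [LabeledImageFolder-class] or
#'   dataset root path.
#' @param extractors named list of extractor functions for non-stand-in
#'   backbones (see [pretrainedBackbone()]).
#' @param cacheDir optional directory for feature caching.
#' @return An [EvalReport-class].
#' @examples
#' ds <- generateLeafDataset(3, 9, seed = 5, size = c(96, 96))
#' cfg <- pipelineConfig(n = 2, kPerTile = 5, folds = 3, seed = 5)
#' report <- runPipeline(cfg, ds)
#' accuracy(report)
#' @export
runPipeline <- function(config, data, extractors = list(),
                        cacheDir = NULL) {
  ds <- resolveDataset(data)
  backbones <- resolveBackbones(config, extractors)
  blocks <- NULL
  cacheFile <- NULL
  if (!is.null(cacheDir)) {
    dir.create(cacheDir, recursive = TRUE, showWarnings = FALSE)
    cacheFile <- file.path(cacheDir,
                           paste0(cacheKey(config, ds$ids), ".rds"))
    if (file.exists(cacheFile)) blocks <- readRDS(cacheFile)
  }
  if (is.null(blocks)) {
    images <- if (config@cropEnabled)
      cropImages(ds$images, ds$ids, config) else ds$images
    blocks <- featurizeImages(images, ds$ids, config, backbones)
    if (!is.null(cacheFile)) saveRDS(blocks, cacheFile)
  }
  fusion <- fusionSpec(divisionSpec(config@n, config@targetSize),
                       config@backbones, config@kPerTile)
  crossValidate(blocks, ds$labels, fusion = fusion, kernel = config@kernel,
                folds = config@folds, seed = config@seed,
                paperMode = config@paperMode,
                configEcho = c(configAsList(config),
                               list(fused_dim = fusedDim(fusion))))
}

#' Sweep the grid order n
#'
#' Runs the pipeline once per grid order in `grid`, sharing the cropped
#' images across runs, and summarizes accuracy and fused dimensionality
#' per n.
#'
#' @param config a [PipelineConfig-class]; its `n` is overridden by each
#'   grid entry.
#' @param data dataset as in [runPipeline()].
#' @param grid integer vector of grid orders, e.g. `2:5`.
#' @param extractors named list of extractor functions, as in
#'   [runPipeline()].
#' @return A data.frame with columns `n`, `accuracy`, `fusedDim`, plus the
#'   reports as attribute `"reports"`.
#' @export
sweepDivisions <- function(config, data, grid = 2:5, extractors = list()) {
  if (!length(grid)) stop("grid must be nonempty", call. = FALSE)
  ds <- resolveDataset(data)
  images <- if (config@cropEnabled)
    cropImages(ds$images, ds$ids, config) else ds$images
  shared <- new("SyntheticDataset", images = images, labels = ds$labels,
                truthMasks = rep(list(matrix(1, 1, 1)), length(images)),
                truthBoxes = rep(list(boundingBox(1, 1, 1, 1)),
                                 length(images)),
                seed = config@seed, classParams = list())
  reports <- lapply(grid, function(n) {
    cfg <- config
    cfg@n <- as.integer(n)
    cfg@cropEnabled <- FALSE  # crops already shared
    runPipeline(cfg, shared, extractors = extractors)
  })
  out <- data.frame(
    n = as.integer(grid),
    accuracy = vapply(reports, accuracy, numeric(1)),
    fusedDim = vapply(reports, function(r)
      as.integer(r@config$fused_dim), integer(1)))
  attr(out, "reports") <- reports
  out
}
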