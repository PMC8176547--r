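#' @include AllClasses.R
NULL

asValues <- function(x) if (is(x, "FeatureMatrix")) x@values else as.matrix(x)

#' Fit a principal-component model
#'
#' Computes the top-k principal components of the training rows via
#' singular value decomposition of the centered matrix (numerically
#' preferable to forming the covariance matrix; the rows equal the top-k
#' covariance eigenvectors). The largest-magnitude loading of every
#' component is forced positive so the fit is deterministic across
#' linear-algebra backends.
#'
#' @param train training data: a [FeatureMatrix-class] or numeric matrix
#'   with at least 2 rows.
#' @param k number of components; must satisfy
#'   `k <= min(nrow - 1, ncol)`.
#' @return A [PcaModel-class].
#' @examples
#' x <- cbind(1:6, 2 * (1:6))        # points on y = 2x
#' m <- fitPca(x, 1)
#' m@explainedVariance               # all variance in one component
#' @export
fitPca <- function(train, k) {
  x <- asValues(train)
  k <- as.integer(k)
  if (nrow(x) < 2L)
    stop("PCA needs at least 2 training samples", call. = FALSE)
  if (k > min(nrow(x) - 1L, ncol(x)))
    stop(sprintf("rank error: k = %d exceeds min(samples - 1, dims) = %d",
                 k, min(nrow(x) - 1L, ncol(x))), call. = FALSE)
  if (all(apply(x, 2, function(col) max(col) == min(col))))
    stop("degenerate data: zero-variance training matrix", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  comp <- t(p$rotation[, seq_len(k), drop = FALSE])
  for (j in seq_len(k)) {
    i <- which.max(abs(comp[j, ]))
    if (comp[j, i] < 0) comp[j, ] <- -comp[j, ]
  }
  new("PcaModel", center = unname(p$center), components = unname(comp),
      explainedVariance = unname(p$sdev[seq_len(k)]^2), k = k)
}

#' Project data onto a fitted principal-component basis
#'
#' Output = (x - center) %*% t(components); the provenance stage becomes
#' `"reduced"`.
#'
#' @param model a [PcaModel-class].
#' @param data a [FeatureMatrix-class] or numeric matrix with the model's
#'   input dimensionality.
#' @return A [FeatureMatrix-class] with `k` columns.
#' @export
transformPca <- function(model, data) {
  x <- asValues(data)
  if (ncol(x) != ncol(model@components))
    stop(sprintf("shape error: data has %d dims, model expects %d",
                 ncol(x), ncol(model@components)), call. = FALSE)
  scores <- sweep(x, 2, model@center) %*% t(model@components)
  prov <- if (is(data, "FeatureMatrix")) data@provenance
          else list(backbone = "unknown", tile = NA)
  featureMatrix(scores,
                sampleIds = if (is(data, "FeatureMatrix")) data@sampleIds,
                backbone = prov$backbone, tile = prov$tile,
                stage = "reduced")
}

#' Concatenate reduced feature blocks into one fused matrix
#'
#' Column-wise concatenation of per-(backbone, tile) reduced blocks in
#' fixed fusion order: backbone-major, tiles row-major within each
#' backbone. All blocks must share the same samples in the same order.
#' Column names encode provenance (e.g. `b1_t11_pc03`).
#'
#' @param blocks list of reduced [FeatureMatrix-class] objects, already in
#'   fusion order.
#' @param spec a [FusionSpec-class]; the result must have exactly
#'   `fusedDim(spec)` columns.
#' @return A [FeatureMatrix-class] with stage `"fused"`.
#' @examples
#' sp <- fusionSpec(2, c("resnet101", "densenet201"), 30)
#' fusedDim(sp)  # 240
#' @export
fuseBlocks <- function(blocks, spec) {
  n2 <- spec@division@n^2
  nb <- length(spec@backboneNames)
  if (length(blocks) != n2 * nb)
    stop(sprintf("fusion expects %d blocks (n^2 x backbones), got %d",
                 n2 * nb, length(blocks)), call. = FALSE)
  ids <- blocks[[1]]@sampleIds
  for (b in blocks)
    if (!identical(b@sampleIds, ids))
      stop("alignment error: blocks disagree on samples or their order",
           call. = FALSE)
  vals <- do.call(cbind, lapply(blocks, featureValues))
  cn <- unlist(lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    tile <- b@provenance$tile
    tileTag <- if (all(is.na(tile))) "tNA"
               else sprintf("t%d%d", tile[1], tile[2])
    bi <- ((i - 1L) %/% n2) + 1L
    sprintf("b%d_%s_pc%02d", bi, tileTag, seq_len(ncol(b@values)))
  }))
  colnames(vals) <- cn
  if (ncol(vals) != fusedDim(spec))
    stop(sprintf("fused dims %d do not match spec fused_dim %d",
                 ncol(vals), fusedDim(spec)), call. = FALSE)
  out <- featureMatrix(vals, sampleIds = ids,
                       backbone = paste(spec@backboneNames, collapse = "+"),
                       tile = NA, stage = "fused")
  colnames(out@values) <- cn
  out
}

#' Fit z-score parameters on training data and apply them everywhere
#'
#' Column means and standard deviations (n - 1 denominator) are computed on
#' the training matrix only and applied as (x - mean) / (sd + epsilon) to
#' the training matrix and every other matrix, with the same frozen
#' parameters. Constant training columns map to zero via the epsilon guard.
#'
#' @param train fused training [FeatureMatrix-class] or matrix.
#' @param others list of matrices to normalize with the training
#'   parameters (e.g. held-out folds).
#' @param epsilon positive guard added to every sd, default 1e-8.
#' @return A list with `params` ([ZScoreParams-class]), `train` and
#'   `others` (normalized, same types as the inputs' values).
#' @export
zscoreFitApply <- function(train, others = list(), epsilon = 1e-8) {
  x <- asValues(train)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  params <- new("ZScoreParams", mean = unname(mu), sd = unname(sd),
                epsilon = epsilon)
  normalize <- function(m) sweep(sweep(asValues(m), 2, mu), 2, sd + epsilon,
                                 "/")
  list(params = params, train = normalize(train),
       others = lapply(others, normalize))
}

#' Apply fitted z-score parameters
#'
#' @param params a [ZScoreParams-class].
#' @param data matrix or [FeatureMatrix-class].
#' @return Normalized numeric matrix.
#' @export
applyZscore <- function(params, data) {
  sweep(sweep(asValues(data), 2, params@mean), 2, params@sd + params@epsilon,
        "/")
}

#' Fit per-block PCA models and global z-score on training rows
#'
#' For each raw (backbone, tile) block, fits a PCA on the training rows
#' only; fuses the reduced training rows; fits z-score parameters on the
#' fused training matrix. This is the leakage-safe protocol used inside
#' every cross-validation fold.
#'
#' @param blocks list of raw [FeatureMatrix-class] blocks in fusion order
#'   (backbone-major, tiles row-major).
#' @param trainIdx integer indices of the training rows.
#' @param fusion a [FusionSpec-class].
#' @return A [FittedTransforms-class].
#' @export
fitTransforms <- function(blocks, trainIdx, fusion) {
  n2 <- fusion@division@n^2
  kPerBackbone <- rep_len(fusion@kPerTile, length(fusion@backboneNames))
  pcas <- lapply(seq_along(blocks), function(i) {
    k <- kPerBackbone[((i - 1L) %/% n2) + 1L]
    fitPca(blocks[[i]]@values[trainIdx, , drop = FALSE], k)
  })
  reducedTrain <- lapply(seq_along(blocks), function(i) {
    sub <- featureMatrix(blocks[[i]]@values[trainIdx, , drop = FALSE],
                         sampleIds = blocks[[i]]@sampleIds[trainIdx],
                         backbone = blocks[[i]]@provenance$backbone,
                         tile = blocks[[i]]@provenance$tile)
    transformPca(pcas[[i]], sub)
  })
  fusedTrain <- fuseBlocks(reducedTrain, fusion)
  zs <- zscoreFitApply(fusedTrain)
  new("FittedTransforms", pcas = pcas, zscore = zs$params, fusion = fusion)
}

#' Apply fitted transforms to raw feature blocks
#'
#' Projects every block through its fitted PCA, fuses, and z-scores with
#' the frozen training parameters.
#'
#' @param transforms a [FittedTransforms-class].
#' @param blocks list of raw [FeatureMatrix-class] blocks in the same
#'   fusion order the transforms were fitted under.
#' @param rows optional integer row subset to transform (default: all).
#' @return A numeric matrix (samples x fusedDim), z-score normalized.
#' @export
applyTransforms <- function(transforms, blocks, rows = NULL) {
  reduced <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (!is.null(rows))
      b <- featureMatrix(b@values[rows, , drop = FALSE],
                         sampleIds = b@sampleIds[rows],
                         backbone = b@provenance$backbone,
                         tile = b@provenance$tile)
    transformPca(transforms@pcas[[i]], b)
  })
  fused <- fuseBlocks(reduced, transforms@fusion)
  out <- applyZscore(transforms@zscore, fused)
  rownames(out) <- fused@sampleIds
  out
}

# ------------------------------------------------------- feature-file I/O

#' Write raw feature blocks to a directory
#'
#' One CSV matrix per (backbone, tile) block plus a JSON sidecar carrying
#' provenance: backbone name, tile coordinate, grid order, preprocessing
#' id and sample ids.
#'
#' @param blocks list of raw [FeatureMatrix-class] blocks in fusion order.
#' @param dir output directory.
#' @param division the [DivisionSpec-class] that produced the tiles.
#' @param preprocessingIds optional character vector, one per block.
#' @return Invisibly, the file paths written.
#' @export
writeFeatureBlocks <- function(blocks, dir, division,
                               preprocessingIds = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    tile <- b@provenance$tile
    stem <- sprintf("block%02d_%s_t%d%d", i, b@provenance$backbone,
                    tile[1], tile[2])
    csv <- file.path(dir, paste0(stem, ".csv"))
    utils::write.csv(as.data.frame(b@values), csv, row.names = FALSE)
    sidecar <- list(backbone = b@provenance$backbone,
                    tile = as.integer(tile), stage = b@provenance$stage,
                    n = division@n,
                    target_size = as.integer(division@targetSize),
                    preprocessing_id =
                      preprocessingIds[i] %||% "unspecified",
                    sample_ids = b@sampleIds)
    jsonlite::write_json(sidecar, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, csv)
  }
  invisible(paths)
}

#' Read feature blocks written by [writeFeatureBlocks()]
#'
#' @param dir directory of block CSVs and JSON sidecars.
#' @return A list with `blocks` (raw [FeatureMatrix-class] list in file
#'   order) and `n` (the grid order recorded in the sidecars).
#' @export
readFeatureBlocks <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "^block.*\\.csv$",
                          full.names = TRUE))
  if (!length(csvs)) stop("no feature blocks found in ", dir, call. = FALSE)
  n <- NA_integer_
  blocks <- lapply(csvs, function(csv) {
    meta <- jsonlite::read_json(sub("\\.csv$", ".json", csv),
                                simplifyVector = TRUE)
    n <<- as.integer(meta$n)
    featureMatrix(as.matrix(utils::read.csv(csv)),
                  sampleIds = meta$sample_ids, backbone = meta$backbone,
                  tile = as.integer(meta$tile), stage = meta$stage)
  })
  list(blocks = blocks, n = n)
}

#' Serialize fitted transforms as a text archive
#'
#' Writes a directory with `manifest.json` (fusion layout, z-score
#' parameters) and one CSV per PCA model (center row, explained-variance
#' row, then the component rows), keyed by block index.
#'
#' @param transforms a [FittedTransforms-class].
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
writeFittedTransforms <- function(transforms, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fu <- transforms@fusion
  manifest <- list(
    n = fu@division@n, target_size = as.integer(fu@division@targetSize),
    backbones = fu@backboneNames, k_per_tile = as.integer(fu@kPerTile),
    zscore = list(mean = transforms@zscore@mean, sd = transforms@zscore@sd,
                  epsilon = transforms@zscore@epsilon),
    blocks = length(transforms@pcas))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(transforms@pcas)) {
    p <- transforms@pcas[[i]]
    m <- rbind(p@center, c(p@explainedVariance,
                           rep(NA_real_,
                               ncol(p@components) - p@k)),
               p@components)
    utils::write.table(m, file.path(dir, sprintf("pca%02d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read fitted transforms written by [writeFittedTransforms()]
#'
#' @param dir archive directory.
#' @return A [FittedTransforms-class].
#' @export
readFittedTransforms <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  pcas <- lapply(seq_len(manifest$blocks), function(i) {
    m <- as.matrix(utils::read.table(
      file.path(dir, sprintf("pca%02d.csv", i)), sep = ","))
    k <- nrow(m) - 2L
    ev <- m[2, seq_len(k)]
    new("PcaModel", center = unname(m[1, ]),
        components = unname(m[3:nrow(m), , drop = FALSE]),
        explainedVariance = unname(ev), k = k)
  })
  fusion <- fusionSpec(divisionSpec(manifest$n, manifest$target_size),
                       manifest$backbones, manifest$k_per_tile)
  new("FittedTransforms", pcas = pcas,
      zscore = new("ZScoreParams", mean = manifest$zscore$mean,
                   sd = manifest$zscore$sd,
                   epsilon = manifest$zscore$epsilon),
      fusion = fusion)
}
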