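#' @include AllClasses.R
NULL

# Rasters are plain base-R objects with documented contracts rather than
# classes: RGB images are H x W x 3 arrays in [0, 1] (rows top to bottom),
# grayscale images H x W matrices, binary masks H x W {0,1} matrices.
# EBImage stores images width-first, so every call into it transposes.

#' Read an RGB image as an H x W x 3 array in [0, 1]
#'
#' Decodes PNG/JPEG/TIFF. Integer samples are scaled to [0, 1] by the
#' decoder (8-bit values divided by 255); grayscale files are promoted to
#' three equal channels; any alpha channel is dropped.
#'
#' @param path image file path.
#' @return An H x W x 3 numeric array with values in [0, 1].
#' @export
loadRgbImage <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  a <- aperm(a, c(2, 1, 3))  # EBImage is (x, y, c); we use (row, col, c)
  a[a < 0] <- 0; a[a > 1] <- 1
  assertRgb(a, path)
}

#' Write an H x W x 3 array in [0, 1] to an image file
#'
#' @param image H x W x 3 array in [0, 1].
#' @param path output path; the extension selects the format (png/jpeg/tiff).
#' @return Invisibly, `path`.
#' @export
writeRgbImage <- function(image, path) {
  assertRgb(image)
  EBImage::writeImage(
    EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color"), path)
  invisible(path)
}

#' Convert an RGB image to grayscale
#'
#' Weighted luminance sum gray = 0.2989 R + 0.5870 G + 0.1140 B, applied
#' per pixel with no clipping.
#'
#' @param image H x W x 3 array, channels R, G, B, values in [0, 1].
#' @return H x W numeric matrix.
#' @examples
#' px <- array(c(1, 0, 0), c(1, 1, 3))
#' rgbToGray(px)  # 0.2989
#' @export
rgbToGray <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("rgbToGray expects an H x W x 3 array (3 channels)", call. = FALSE)
  0.2989 * image[, , 1] + 0.5870 * image[, , 2] + 0.1140 * image[, , 3]
}

#' Max-min normalize a grayscale image to [0, 1]
#'
#' Applies (x - min) / (max - min) elementwise so the output attains 0 and 1
#' exactly. A constant image (max = min) signals a blank or failed capture
#' and raises an error.
#'
#' @param image H x W numeric matrix.
#' @return H x W matrix with minimum 0 and maximum 1.
#' @export
minmaxNormalize <- function(image) {
  r <- range(image)
  if (r[1] == r[2])
    stop("degenerate image: constant intensity, cannot normalize",
         call. = FALSE)
  (image - r[1]) / (r[2] - r[1])
}

#' Otsu threshold over a 256-bin histogram
#'
#' Threshold maximizing the between-class variance of the binary split of a
#' 256-bin histogram on [0, 1].
#'
#' @param image H x W numeric matrix with values in [0, 1].
#' @param levels histogram bins, default 256.
#' @return The threshold, a value in (0, 1).
#' @export
otsuThreshold <- function(image, levels = 256L) {
  if (min(image) == max(image))
    stop("degenerate image: constant intensity, Otsu threshold undefined",
         call. = FALSE)
  EBImage::otsu(EBImage::Image(image), range = c(0, 1),
                levels = as.integer(levels))
}

#' Threshold a normalized grayscale image into a binary mask
#'
#' Foreground is the set of pixels strictly below the threshold T (the leaf
#' is darker than the background); `invert = TRUE` in the configuration
#' selects pixels strictly above T instead. In `"otsu"` mode T maximizes the
#' between-class variance over a 256-bin histogram; `"fixed"` mode uses the
#' configured constant.
#'
#' @param image normalized H x W grayscale matrix.
#' @param config a [SegmentationConfig-class].
#' @return H x W {0,1} matrix with attribute `"threshold"` carrying T.
#' @export
binarize <- function(image, config = segmentationConfig()) {
  T <- if (config@thresholdMode == "otsu") otsuThreshold(image)
       else config@fixedT
  mask <- if (config@invert) (image > T) * 1 else (image < T) * 1
  storage.mode(mask) <- "double"
  attr(mask, "threshold") <- as.numeric(T)
  mask
}

# Euclidean-disk structuring element: {(dx, dy): dx^2 + dy^2 <= r^2}.
diskKernel <- function(radius) {
  r <- as.integer(radius)
  d <- seq(-r, r)
  (outer(d^2, d^2, "+") <= r^2) * 1
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a union-find pass.
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  parent <- seq_len(nl)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
  H <- nrow(lab); W <- ncol(lab)
  for (sh in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(H - 1), if (sh[2] > 0) seq_len(W - 1) else -1, drop = FALSE]
    b <- lab[-1, if (sh[2] > 0) -1 else seq_len(W - 1), drop = FALSE]
    touch <- which(a > 0 & b > 0 & a != b)
    for (i in touch) {
      ra <- findRoot(a[i]); rb <- findRoot(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nl), findRoot, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Clean a binary mask into a single leaf object
#'
#' In order: (1) fill enclosed holes; (2) erode with a Euclidean disk of the
#' configured radius; (3) keep only the largest 8-connected component. The
#' result has exactly one connected component.
#'
#' @param mask H x W {0,1} matrix.
#' @param config a [SegmentationConfig-class]; `erosionRadius` and
#'   `minObjectFraction` are used.
#' @return H x W {0,1} matrix containing a single connected object.
#' @export
cleanMask <- function(mask, config = segmentationConfig()) {
  assertMask(mask)
  filled <- EBImage::imageData(EBImage::fillHull(mask))
  if (config@erosionRadius > 0L && sum(filled) > 0)
    filled <- EBImage::imageData(
      EBImage::erode(filled, diskKernel(config@erosionRadius)))
  if (sum(filled) == 0)
    stop("no object: empty foreground after erosion", call. = FALSE)
  lab <- label8(filled)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < config@minObjectFraction * length(mask))
    stop(sprintf(
      "no object: largest component (%d px) is below min_object_fraction",
      sizes[big]), call. = FALSE)
  out <- (lab == big) * 1
  storage.mode(out) <- "double"
  out
}

#' Tight bounding box of a mask's foreground
#'
#' @param mask H x W {0,1} matrix with at least one foreground pixel.
#' @return A [BoundingBox-class] (1-based, inclusive).
#' @export
maskBoundingBox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no object: mask has no foreground", call. = FALSE)
  boundingBox(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
}

#' Intersection-over-union of two bounding boxes
#'
#' @param a,b [BoundingBox-class] objects.
#' @return IoU in [0, 1].
#' @export
boxIoU <- function(a, b) {
  ir <- max(0, min(a@rowMax, b@rowMax) - max(a@rowMin, b@rowMin) + 1)
  ic <- max(0, min(a@colMax, b@colMax) - max(a@colMin, b@colMin) + 1)
  inter <- ir * ic
  areaA <- (a@rowMax - a@rowMin + 1) * (a@colMax - a@colMin + 1)
  areaB <- (b@rowMax - b@rowMin + 1) * (b@colMax - b@colMin + 1)
  inter / (areaA + areaB - inter)
}

#' Crop an image to the bounding box of a mask
#'
#' The box is the tight axis-aligned box of the mask foreground; the
#' returned image is the original RGB content inside it (background pixels
#' inside the box are retained unless `maskBackground = TRUE`).
#'
#' @param image H x W x 3 array.
#' @param mask H x W {0,1} matrix with at least one foreground pixel.
#' @param maskBackground if `TRUE`, zero out background pixels inside the
#'   box.
#' @return A list with `image` (the crop) and `box` (a
#'   [BoundingBox-class]).
#' @export
cropToLeaf <- function(image, mask, maskBackground = FALSE) {
  assertRgb(image)
  box <- maskBoundingBox(mask)
  rows <- box@rowMin:box@rowMax
  cols <- box@colMin:box@colMax
  crop <- image[rows, cols, , drop = FALSE]
  if (maskBackground) {
    m <- mask[rows, cols]
    crop <- crop * array(rep(m, 3L), dim(crop))
  }
  list(image = crop, box = box)
}

#' Segment and crop a single leaf image
#'
#' The full background-removal procedure: grayscale conversion, max-min
#' normalization, thresholding, hole filling + erosion + largest-object
#' selection, then cropping to the object's bounding box.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param config a [SegmentationConfig-class].
#' @param maskBackground zero out background inside the crop (default
#'   `FALSE`).
#' @return A list with `image` (cropped RGB array), `box`
#'   ([BoundingBox-class] into the input), `mask` (cleaned full-size mask)
#'   and `threshold` (the T used).
#' @examples
#' ds <- generateLeafDataset(2, 1, seed = 7, size = c(96, 96))
#' seg <- segmentLeaf(ds@images[[1]])
#' boxIoU(seg$box, ds@truthBoxes[[1]])
#' @export
segmentLeaf <- function(image, config = segmentationConfig(),
                        maskBackground = FALSE) {
  g <- minmaxNormalize(rgbToGray(image))
  raw <- binarize(g, config)
  mask <- cleanMask(raw, config)
  out <- cropToLeaf(image, mask, maskBackground = maskBackground)
  list(image = out$image, box = out$box, mask = mask,
       threshold = attr(raw, "threshold"))
}

#' Batch-crop an image folder
#'
#' Applies [segmentLeaf()] to every image under a class-per-subdirectory
#' root, writes the crops (PNG) mirroring the layout, and optionally a CSV
#' of 1-based inclusive bounding boxes.
#'
#' @param folder a [LabeledImageFolder-class] or root directory path.
#' @param outDir output directory.
#' @param config a [SegmentationConfig-class].
#' @param boxCsv optional path of a CSV with columns
#'   path,row_min,row_max,col_min,col_max (1-based inclusive).
#' @param maskBackground zero out background inside each crop.
#' @return Invisibly, a data.frame of paths and boxes.
#' @export
cropFolder <- function(folder, outDir, config = segmentationConfig(),
                       boxCsv = NULL, maskBackground = FALSE) {
  if (is.character(folder)) folder <- loadImageFolder(folder)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(nrow(folder@samples)), function(i) {
    p <- folder@samples$path[i]
    cls <- folder@samples$class[i]
    seg <- tryCatch(
      segmentLeaf(loadRgbImage(p), config, maskBackground = maskBackground),
      error = function(e) stopStage("segmentation", p, conditionMessage(e)))
    destDir <- file.path(outDir, cls)
    dir.create(destDir, recursive = TRUE, showWarnings = FALSE)
    dest <- file.path(destDir,
                      paste0(tools::file_path_sans_ext(basename(p)), ".png"))
    writeRgbImage(seg$image, dest)
    data.frame(path = p, row_min = seg$box@rowMin, row_max = seg$box@rowMax,
               col_min = seg$box@colMin, col_max = seg$box@colMax)
  })
  boxes <- do.call(rbind, rows)
  if (!is.null(boxCsv)) utils::write.csv(boxes, boxCsv, row.names = FALSE)
  invisible(boxes)
}
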