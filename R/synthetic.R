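#' @include AllClasses.R
NULL

backgroundColor <- function(name) {
  switch(name,
         gray = c(0.85, 0.85, 0.85),
         red = c(1.0, 0.3, 0.3),
         white = c(1.0, 1.0, 1.0),
         stop("background must be gray, red or white", call. = FALSE))
}

#' Render one synthetic leaf image with its ground-truth mask
#'
#' Draws a single leaf as a lobed polar contour
#' r(theta) = R * (1 + lobeDepth * cos(lobeCount * theta)), stretched
#' horizontally by `aspectRatio`, randomly rotated and translated within
#' the canvas margins, and shaded with a sinusoidal vein texture of the
#' configured frequency. All per-image jitter (about +/-10% on the shape
#' parameters, plus rotation and translation) derives from `jitterSeed`,
#' so the same parameters and seed reproduce the image bit-exactly. The
#' returned mask is the exact rendered leaf support.
#'
#' If the jittered leaf would touch the canvas border, the scale is shrunk
#' and the draw retried, erroring after 5 attempts.
#'
#' @param params a [LeafClassParams-class].
#' @param jitterSeed integer per-image seed.
#' @param size canvas (height, width), at least 64 x 64.
#' @return A list with `image` (H x W x 3 array), `mask` ({0,1} matrix),
#'   `box` (the mask's tight [BoundingBox-class]), `radius` (the realized
#'   base radius R in pixels) and `realized` (the jittered shape
#'   parameters actually drawn).
#' @examples
#' leaf <- renderLeaf(leafClassParams(), jitterSeed = 3, size = c(96, 96))
#' sum(leaf$mask)  # leaf area in pixels
#' @export
renderLeaf <- function(params, jitterSeed = 1L, size = c(128L, 128L)) {
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < 64L || W < 64L)
    stop("canvas must be at least 64 x 64", call. = FALSE)
  withSeed(jitterSeed, {
    jit <- function(x) x * stats::runif(1, 0.9, 1.1)
    a <- jit(params@aspectRatio)
    depth <- min(jit(params@lobeDepth), 0.49)
    freq <- jit(params@textureFrequency)
    lobes <- params@lobeCount
    theta <- stats::runif(1, 0, 2 * pi)
    # base radius leaving room for lobes and stretch, with jittered scale
    ext <- (1 + depth) * max(a, 1)
    R <- 0.38 * min(H, W) / ext * stats::runif(1, 0.85, 1)
    margin <- pmax(0, 0.5 * min(H, W) - R * ext - 2)
    cy <- (H + 1) / 2 + stats::runif(1, -1, 1) * min(margin, H * 0.1)
    cx <- (W + 1) / 2 + stats::runif(1, -1, 1) * min(margin, W * 0.1)
    for (attempt in 1:5) {
      Y <- matrix(seq_len(H) - cy, H, W)
      X <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
      u0 <- cos(theta) * X + sin(theta) * Y
      v0 <- -sin(theta) * X + cos(theta) * Y
      u <- u0 / a
      rr <- sqrt(u^2 + v0^2)
      phi <- atan2(v0, u)
      inside <- rr <= R * (1 + depth * cos(lobes * phi))
      border <- any(inside[1, ]) || any(inside[H, ]) ||
        any(inside[, 1]) || any(inside[, W])
      if (!border) break
      if (attempt == 5)
        stop("leaf exceeds canvas after 5 shrink attempts", call. = FALSE)
      R <- R * 0.8
    }
    shade <- 1 - 0.3 * (0.5 + 0.5 * sin(2 * pi * freq * v0 / (2 * R)))
    bg <- backgroundColor(params@background)
    img <- array(0, c(H, W, 3L))
    for (c in 1:3) {
      ch <- matrix(bg[c], H, W)
      ch[inside] <- (params@leafColor[c] * shade)[inside]
      img[, , c] <- ch
    }
    mask <- inside * 1
    storage.mode(mask) <- "double"
    list(image = img, mask = mask, box = maskBoundingBox(mask), radius = R,
         realized = list(aspectRatio = a, lobeDepth = depth,
                         textureFrequency = freq, rotation = theta))
  })
}

#' Generate a labeled synthetic leaf dataset
#'
#' Class parameter sets are laid out on well-separated deterministic grids
#' (distinct aspect ratios, lobe counts, lobe depths, texture frequencies
#' and leaf colors per class); per-image variation comes from jitter seeds
#' derived from the master `seed`, so two datasets with the same arguments
#' and seed are identical. Setting `collapseClasses = TRUE` gives every
#' class the first class's parameters, removing the class signal (per-image
#' jitter remains) — useful as a negative control.
#'
#' @param nClasses number of classes, at least 2.
#' @param nPerClass images per class.
#' @param seed master seed.
#' @param size canvas (height, width) per image, default `c(128, 128)`.
#' @param background `"gray"`, `"red"` or `"white"`.
#' @param collapseClasses use identical parameters for all classes.
#' @return A [SyntheticDataset-class].
#' @examples
#' ds <- generateLeafDataset(3, 5, seed = 11, size = c(96, 96))
#' table(ds@labels)
#' @export
generateLeafDataset <- function(nClasses, nPerClass, seed = 1L,
                                size = c(128L, 128L), background = "gray",
                                collapseClasses = FALSE) {
  if (nClasses < 2L) stop("at least 2 classes are required", call. = FALSE)
  aspects <- seq(0.55, 1.6, length.out = nClasses)
  lobeCounts <- c(0L, seq(3L, by = 1L, length.out = max(0, nClasses - 1)))
  lobeDepths <- ifelse(lobeCounts == 0L, 0,
                       0.12 + 0.18 * (seq_len(nClasses) - 1) /
                         max(1, nClasses - 1))
  freqs <- seq(2, 2 + 1.5 * (nClasses - 1), length.out = nClasses)
  reds <- seq(0.08, 0.22, length.out = nClasses)
  greens <- seq(0.30, 0.50, length.out = nClasses)
  blues <- seq(0.20, 0.06, length.out = nClasses)
  classNames <- sprintf("class%02d", seq_len(nClasses))
  classParams <- lapply(seq_len(nClasses), function(i) {
    j <- if (collapseClasses) 1L else i
    leafClassParams(aspectRatio = aspects[j], lobeCount = lobeCounts[j],
                    lobeDepth = lobeDepths[j],
                    textureFrequency = freqs[j],
                    leafColor = c(reds[j], greens[j], blues[j]),
                    background = background)
  })
  names(classParams) <- classNames
  total <- nClasses * nPerClass
  images <- vector("list", total)
  masks <- vector("list", total)
  boxes <- vector("list", total)
  labels <- character(total)
  idx <- 0L
  for (i in seq_len(nClasses)) for (r in seq_len(nPerClass)) {
    idx <- idx + 1L
    leaf <- renderLeaf(classParams[[i]], deriveSeed(seed, idx), size)
    images[[idx]] <- leaf$image
    masks[[idx]] <- leaf$mask
    boxes[[idx]] <- leaf$box
    labels[idx] <- classNames[i]
  }
  new("SyntheticDataset", images = images, labels = labels,
      truthMasks = masks, truthBoxes = boxes, seed = as.integer(seed),
      classParams = classParams)
}

#' Write a synthetic dataset as a class-per-subdirectory image folder
#'
#' Writes one PNG per image under `dir/<class>/` plus `truth.csv` with
#' columns path, class, row_min, row_max, col_min, col_max (1-based
#' inclusive ground-truth boxes).
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output root directory.
#' @return Invisibly, the truth data.frame.
#' @export
writeLeafDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  perClass <- integer(0)
  rows <- lapply(seq_along(dataset@images), function(i) {
    cls <- dataset@labels[i]
    cnt <- if (cls %in% names(perClass)) perClass[[cls]] + 1L else 1L
    perClass[cls] <<- cnt
    clsDir <- file.path(dir, cls)
    dir.create(clsDir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(clsDir, sprintf("leaf%04d.png", cnt))
    writeRgbImage(dataset@images[[i]], path)
    b <- dataset@truthBoxes[[i]]
    data.frame(path = path, class = cls, row_min = b@rowMin,
               row_max = b@rowMax, col_min = b@colMin, col_max = b@colMax)
  })
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}
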