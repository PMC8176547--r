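#' @include AllClasses.R
NULL

# Contiguous band sizes for splitting `total` pixels into n bands:
# ceil-sized bands first, floor-sized after, so 225/2 -> 113, 112.
bandSizes <- function(total, n) {
  base <- total %/% n
  sizes <- rep.int(base, n)
  r <- total %% n
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  sizes
}

#' Divide an image into an n x n grid of tiles
#'
#' Rows are split into n contiguous bands of floor/ceil(H/n) pixels with the
#' ceil-sized bands first (same rule for columns); tiles are listed in
#' row-major grid order. The tile source boxes partition the image exactly,
#' so stitching them back reconstructs it bit-exactly.
#'
#' @param image H x W x 3 array.
#' @param spec a [DivisionSpec-class] (or grid order n).
#' @return A [TileSet-class].
#' @examples
#' img <- array(runif(30 * 40 * 3), c(30, 40, 3))
#' ts <- divideImage(img, divisionSpec(2))
#' length(tiles(ts))  # 4
#' @export
divideImage <- function(image, spec = divisionSpec()) {
  if (!is(spec, "DivisionSpec")) spec <- divisionSpec(spec)
  assertRgb(image)
  n <- spec@n
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < n || W < n)
    stop(sprintf("image (%d x %d) too small for a %d x %d division",
                 H, W, n, n), call. = FALSE)
  rEnd <- cumsum(bandSizes(H, n)); rStart <- c(1L, head(rEnd, -1L) + 1L)
  cEnd <- cumsum(bandSizes(W, n)); cStart <- c(1L, head(cEnd, -1L) + 1L)
  tiles <- vector("list", n * n)
  boxes <- vector("list", n * n)
  coords <- matrix(0L, n * n, 2, dimnames = list(NULL, c("gridRow", "gridCol")))
  k <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k <- k + 1L
    tiles[[k]] <- image[rStart[i]:rEnd[i], cStart[j]:cEnd[j], , drop = FALSE]
    boxes[[k]] <- boundingBox(rStart[i], rEnd[i], cStart[j], cEnd[j])
    coords[k, ] <- c(i, j)
  }
  new("TileSet", tiles = tiles, gridCoords = coords, sourceBoxes = boxes,
      sourceDim = c(H, W))
}

# Bilinear resize of one channel with the half-pixel-centers
# (align-corners-false) convention; EBImage::resize implements exactly this
# mapping (verified against direct evaluation of the interpolation weights).
resizeChannel <- function(m, outH, outW) {
  EBImage::imageData(EBImage::resize(EBImage::Image(m), w = outH, h = outW,
                                     filter = "bilinear"))
}

#' Resize a tile to the backbone input size
#'
#' Bilinear interpolation under the half-pixel-centers convention
#' (output sample i maps to source coordinate (i + 0.5) * scale - 0.5),
#' applied per channel; values are clipped to [0, 1]. Non-square tiles are
#' resized anisotropically.
#'
#' @param tile H x W x 3 array.
#' @param spec a [DivisionSpec-class]; its `targetSize` is the output size.
#' @return targetSize[1] x targetSize[2] x 3 array in [0, 1].
#' @export
resizeTile <- function(tile, spec = divisionSpec()) {
  assertRgb(tile)
  outH <- spec@targetSize[1]; outW <- spec@targetSize[2]
  out <- array(0, c(outH, outW, 3L))
  for (c in 1:3) out[, , c] <- resizeChannel(tile[, , c], outH, outW)
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Reassemble a TileSet into its source image
#'
#' Inverse of [divideImage()] using the stored source boxes; the
#' reconstruction is bit-exact.
#'
#' @param tileset a [TileSet-class].
#' @return H x W x 3 array equal to the divided source image.
#' @export
stitchTiles <- function(tileset) {
  out <- array(0, c(tileset@sourceDim, 3L))
  for (k in seq_along(tileset@tiles)) {
    b <- tileset@sourceBoxes[[k]]
    out[b@rowMin:b@rowMax, b@colMin:b@colMax, ] <- tileset@tiles[[k]]
  }
  out
}
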