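test_that("grayscale conversion uses the weighted luminance sum", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_identical(as.numeric(rgbToGray(px(1, 0, 0))), 0.2989)
  expect_identical(as.numeric(rgbToGray(px(0, 0, 0))), 0)
  expect_equal(as.numeric(rgbToGray(px(1, 1, 1))), 0.9999)
  expect_error(rgbToGray(array(0, c(2, 2, 4))), "3 channels")
  expect_error(rgbToGray(matrix(0, 2, 2)), "3")
})

test_that("grayscale conversion is linear in the image", {
  a <- randomRgb(7, 9, seed = 21)
  b <- randomRgb(7, 9, seed = 22)
  mix <- 0.3 * a + 0.6 * b
  expect_lt(max(abs(rgbToGray(mix) -
                      (0.3 * rgbToGray(a) + 0.6 * rgbToGray(b)))), 1e-10)
})

test_that("max-min normalization maps to [0, 1] and is idempotent", {
  m <- matrix(c(0, 10, 5, 5), 2, 2)
  expect_equal(minmaxNormalize(m), matrix(c(0, 1, 0.5, 0.5), 2, 2))
  once <- minmaxNormalize(randomRgb(6, 6, seed = 3)[, , 1] * 0.4 + 0.2)
  expect_lt(max(abs(minmaxNormalize(once) - once)), 1e-12)
  expect_identical(range(once), c(0, 1))
  expect_error(minmaxNormalize(matrix(0.7, 3, 3)), "degenerate")
})

test_that("Otsu binarization matches the brute-force 256-bin oracle", {
  g <- leafgrid:::withSeed(5, {
    v <- c(rep(0.2, 30), rep(0.9, 70))
    matrix(sample(v), 10, 10)
  })
  mask <- binarize(g, segmentationConfig("otsu"))
  T <- attr(mask, "threshold")
  expect_gt(T, 0.2)
  expect_lt(T, 0.9)
  oracleT <- bruteOtsu(g)
  expect_identical(unclass(mask) > 0, g < oracleT)  # same split
  expect_identical(which(mask > 0), which(g < 0.5))
  expect_error(binarize(matrix(0.5, 4, 4), segmentationConfig("otsu")),
               "degenerate")
})

test_that("fixed-threshold binarization selects pixels strictly below T", {
  cfgT <- segmentationConfig("fixed", fixedT = 0.5)
  allLow <- binarize(matrix(0, 5, 5), cfgT)
  expect_equal(sum(allLow), 25)
  allHigh <- binarize(matrix(0.9, 5, 5), cfgT)
  expect_equal(sum(allHigh), 0)
  expect_error(cleanMask(unclass(allHigh), cfgT), "no object")
  inv <- binarize(matrix(0.9, 5, 5),
                  segmentationConfig("fixed", fixedT = 0.5, invert = TRUE))
  expect_equal(sum(inv), 25)
})

test_that("mask cleanup fills holes, erodes, and keeps the largest object", {
  # hole filling: interior zero of a filled disk becomes foreground
  m <- matrix(0, 9, 9); m[3:7, 3:7] <- 1; m[5, 5] <- 0
  out <- cleanMask(m, segmentationConfig(erosionRadius = 0L))
  expect_equal(out[5, 5], 1)
  # largest of two components survives
  m2 <- matrix(0, 20, 20)
  m2[2:11, 2:11] <- 1          # 100 px
  m2[15:19, 18] <- 1           # 5 px
  out2 <- cleanMask(m2, segmentationConfig(erosionRadius = 0L))
  expect_equal(sum(out2), 100)
  expect_equal(sum(out2[15:19, 18]), 0)
  # radius-1 disk erosion of a 7x7 square gives the 5x5 interior
  m3 <- matrix(0, 11, 11); m3[3:9, 3:9] <- 1
  out3 <- cleanMask(m3, segmentationConfig(erosionRadius = 1L))
  expect_equal(unname(out3), bruteErodeDisk(m3, 1))
  expect_equal(sum(out3), 25)
  expect_equal(which(rowSums(out3) > 0), 4:8)
  # erosion that empties the mask is a no-object error
  tiny <- matrix(0, 8, 8); tiny[4, 4] <- 1
  expect_error(cleanMask(tiny, segmentationConfig(erosionRadius = 2L)),
               "no object")
  # speckle below min_object_fraction is a no-object error
  sp <- matrix(0, 50, 50); sp[25, 25] <- 1
  expect_error(
    cleanMask(sp, segmentationConfig(erosionRadius = 0L,
                                     minObjectFraction = 0.01)),
    "min_object_fraction")
})

test_that("cleanup output is one component inside the hole-filled input", {
  for (seed in 1:5) {
    m <- leafgrid:::withSeed(seed, {
      base <- matrix(0, 40, 40)
      base[10:30, 10:30] <- (matrix(runif(441), 21, 21) < 0.8) * 1
      base[35:38, 2:5] <- 1
      base
    })
    out <- tryCatch(cleanMask(m, segmentationConfig()),
                    error = function(e) NULL)
    if (is.null(out)) next
    expect_equal(countComponents8(out), 1L)
    filled <- EBImage::imageData(EBImage::fillHull(m))
    expect_true(all(out <= filled))  # subset of hole-filled input
  }
})

test_that("cropping returns the tight box and preserves pixels exactly", {
  img <- randomRgb(40, 40, seed = 9)
  mask <- matrix(0, 40, 40); mask[10:20, 5:15] <- 1
  res <- cropToLeaf(img, mask)
  expect_equal(dim(res$image), c(11L, 11L, 3L))
  expect_equal(c(res$box@rowMin, res$box@rowMax, res$box@colMin,
                 res$box@colMax), c(10L, 20L, 5L, 15L))
  # re-embedding at (rowMin, colMin) reproduces the original pixels
  reEmbed <- img
  reEmbed[10:20, 5:15, ] <- res$image
  expect_identical(reEmbed, img)
  # all-foreground mask is the identity crop
  full <- cropToLeaf(img, matrix(1, 40, 40))
  expect_identical(full$image, img)
  expect_error(cropToLeaf(img, matrix(0, 40, 40)), "no object")
  # background masking zeroes outside-mask pixels inside the box
  maskedCrop <- cropToLeaf(img, mask, maskBackground = TRUE)$image
  expect_identical(maskedCrop, res$image)  # rectangular mask: no change
})

test_that("segmentation recovers synthetic ground-truth boxes", {
  ds <- generateLeafDataset(3, 4, seed = 31, size = c(96, 96))
  for (i in seq_along(ds@images)) {
    seg <- segmentLeaf(ds@images[[i]])
    expect_gte(boxIoU(seg$box, ds@truthBoxes[[i]]), 0.9)
    tb <- ds@truthBoxes[[i]]
    expect_lte(max(abs(c(seg$box@rowMin - tb@rowMin,
                         seg$box@rowMax - tb@rowMax,
                         seg$box@colMin - tb@colMin,
                         seg$box@colMax - tb@colMax))), 2)
  }
})

test_that("image files round-trip through the loader at 8-bit precision", {
  img <- round(randomRgb(12, 17, seed = 4) * 255) / 255
  path <- withr::local_tempfile(fileext = ".png")
  writeRgbImage(img, path)
  back <- loadRgbImage(path)
  expect_equal(back, img, tolerance = 1e-7)
})
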