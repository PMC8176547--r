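test_that("a lobeless round leaf is a discretized disk", {
  leaf <- renderLeaf(leafClassParams(aspectRatio = 1, lobeCount = 0L,
                                     lobeDepth = 0),
                     jitterSeed = 3, size = c(128, 128))
  area <- sum(leaf$mask)
  # realized radius and aspect (per-image jitter) give the analytic area
  expected <- pi * leaf$radius^2 * leaf$realized$aspectRatio
  expect_lt(abs(area - expected) / expected, 0.05)
})

test_that("rendering is byte-deterministic in parameters and seed", {
  p <- leafClassParams(aspectRatio = 1.2, lobeCount = 5L, lobeDepth = 0.2)
  a <- renderLeaf(p, jitterSeed = 11, size = c(96, 96))
  b <- renderLeaf(p, jitterSeed = 11, size = c(96, 96))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- renderLeaf(p, jitterSeed = 12, size = c(96, 96))
  expect_false(identical(a$mask, c$mask))
})

test_that("the stored box is the tight box of non-background pixels", {
  for (seed in c(2, 9)) {
    leaf <- renderLeaf(leafClassParams(lobeCount = 4L, lobeDepth = 0.25),
                       jitterSeed = seed, size = c(96, 96))
    bg <- leaf$image[1, 1, ]  # corner is always background
    nonBg <- apply(leaf$image, c(1, 2), function(px) any(px != bg)) * 1
    expect_identical(leaf$box, maskBoundingBox(nonBg))
    expect_identical(unname(leaf$mask), unname(nonBg))
  }
})

test_that("leaves are darker than every supported background", {
  for (bgName in c("gray", "red", "white")) {
    leaf <- renderLeaf(leafClassParams(background = bgName),
                       jitterSeed = 5, size = c(96, 96))
    g <- rgbToGray(leaf$image)
    expect_lt(max(g[leaf$mask == 1]), min(g[leaf$mask == 0]))
  }
})

test_that("dataset generation is seeded, counted, and class-separated", {
  ds <- generateLeafDataset(5, 4, seed = 13, size = c(96, 96))
  expect_length(ds@images, 20)
  expect_equal(as.integer(table(ds@labels)), rep(4L, 5))
  ds2 <- generateLeafDataset(5, 4, seed = 13, size = c(96, 96))
  expect_identical(ds@images, ds2@images)
  ds3 <- generateLeafDataset(5, 4, seed = 14, size = c(96, 96))
  expect_false(identical(ds@images, ds3@images))
  # class parameter grids are distinct across classes
  aspects <- vapply(ds@classParams, slot, numeric(1), "aspectRatio")
  lobes <- vapply(ds@classParams, slot, integer(1), "lobeCount")
  expect_equal(anyDuplicated(aspects), 0L)
  expect_equal(anyDuplicated(lobes), 0L)
  expect_error(generateLeafDataset(1, 4, seed = 1), "at least 2")
})

test_that("collapsing class parameters removes the class signal", {
  ds <- generateLeafDataset(3, 8, seed = 21, size = c(96, 96),
                            collapseClasses = TRUE)
  prm <- ds@classParams
  expect_identical(prm[[1]]@aspectRatio, prm[[3]]@aspectRatio)
  cfg <- pipelineConfig(n = 2, kPerTile = 4, folds = 4, seed = 21,
                        targetSize = c(64L, 64L))
  rep <- runPipeline(cfg, ds)
  # accuracy falls toward chance (100/3); far below the separated regime
  expect_lt(accuracy(rep), 70)
})

test_that("written datasets reload as a labeled image folder", {
  ds <- generateLeafDataset(2, 3, seed = 8, size = c(96, 96))
  dir <- withr::local_tempdir()
  truth <- writeLeafDataset(ds, dir)
  expect_equal(nrow(truth), 6)
  folder <- loadImageFolder(dir)
  expect_identical(folder@classes, c("class01", "class02"))
  expect_equal(nrow(folder@samples), 6)
  img <- loadRgbImage(folder@samples$path[1])
  expect_equal(dim(img), c(96L, 96L, 3L))
})
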