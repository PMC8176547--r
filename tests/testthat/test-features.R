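bbTest <- standinBackbone(seed = 42, inputSize = c(64L, 64L))
tileAt <- function(seed) randomRgb(64, 64, seed = seed)

test_that("the stand-in backbone fulfils the extractor contract", {
  v <- bbTest@extractor(tileAt(1))
  expect_length(v, 1000)
  # determinism: same tile, bit-identical features
  expect_identical(v, bbTest@extractor(tileAt(1)))
  # a freshly built backbone with the same seed agrees bit-exactly
  bb2 <- standinBackbone(seed = 42, inputSize = c(64L, 64L))
  expect_identical(v, bb2@extractor(tileAt(1)))
  # zero image maps to the zero vector; the map is linear
  expect_identical(bbTest@extractor(array(0, c(64, 64, 3))), rep(0, 1000))
  half <- bbTest@extractor(0.5 * tileAt(1))
  expect_lt(max(abs(half - 0.5 * v)), 1e-10)
})

test_that("batch extraction stacks rows in input order with raw provenance", {
  tilesIn <- lapply(1:5, tileAt)
  fm <- extractFeatures(tilesIn, bbTest, sampleIds = paste0("s", 1:5),
                        tileCoord = c(1L, 2L))
  expect_equal(dim(featureValues(fm)), c(5L, 1000L))
  expect_equal(featureValues(fm)[3, ], bbTest@extractor(tilesIn[[3]]))
  expect_identical(sampleIds(fm), paste0("s", 1:5))
  expect_identical(provenance(fm)$stage, "raw")
  expect_identical(provenance(fm)$tile, c(1L, 2L))
})

test_that("extraction rejects bad tiles and unknown backbones", {
  expect_error(extractFeatures(list(randomRgb(32, 64, seed = 1)), bbTest),
               "expects 64 x 64")
  expect_error(extractFeatures(list(tileAt(1)), "resnet101"),
               "unknown backbone")
  expect_error(pretrainedBackbone("resnet101"), "extractor")
})

test_that("stand-in features separate synthetic classes by cosine", {
  ds <- generateLeafDataset(2, 20, seed = 17, size = c(96, 96))
  bb <- standinBackbone(seed = 1, inputSize = c(96L, 96L))
  feats <- t(vapply(ds@images, bb@extractor, numeric(1000)))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  a <- which(ds@labels == "class01")
  b <- which(ds@labels == "class02")
  within <- mean(c(
    vapply(1:19, function(i) cosine(feats[a[i], ], feats[a[i + 1], ]),
           numeric(1)),
    vapply(1:19, function(i) cosine(feats[b[i], ], feats[b[i + 1], ]),
           numeric(1))))
  between <- mean(vapply(1:20, function(i)
    cosine(feats[a[i], ], feats[b[i], ]), numeric(1)))
  expect_lt(between, within)
})
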