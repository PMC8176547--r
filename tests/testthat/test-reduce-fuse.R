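test_that("collinear data is captured by a single component", {
  x <- cbind(1:6, 2 * (1:6))
  m <- fitPca(x, 1)
  expect_equal(sum(m@explainedVariance), var(1:6) * 5, tolerance = 1e-10)
  scores <- featureValues(transformPca(m, x))
  recon <- scores %*% m@components + rep(1, 6) %o% m@center
  expect_lt(max(abs(recon - x)), 1e-10)  # k = 1 reconstructs exactly
})

test_that("PCA matches the covariance-eigendecomposition oracle", {
  for (seed in 1:6) {
    dims <- leafgrid:::withSeed(seed, c(sample(5:20, 1), sample(2:20, 1)))
    n <- dims[1]; d <- dims[2]
    x <- leafgrid:::withSeed(100 + seed, matrix(rnorm(n * d), n, d))
    k <- min(n - 1, d)
    m <- fitPca(x, k)
    eig <- eigen(cov(x), symmetric = TRUE)
    expect_equal(m@explainedVariance, eig$values[seq_len(k)],
                 tolerance = 1e-8)
    for (j in seq_len(k)) {
      # sign-invariant comparison of loadings
      expect_lt(min(max(abs(m@components[j, ] - eig$vectors[, j])),
                    max(abs(m@components[j, ] + eig$vectors[, j]))), 1e-8)
    }
    # explained variance is nonincreasing and cumulative capture monotone
    expect_true(all(diff(m@explainedVariance) <= 1e-10))
    expect_true(all(diff(cumsum(m@explainedVariance)) >= -1e-12))
  }
})

test_that("PCA rejects invalid ranks and degenerate data", {
  x <- matrix(rnorm(12), 4, 3)
  expect_error(fitPca(x, 4), "rank error")
  expect_error(fitPca(x[1, , drop = FALSE], 1), "at least 2")
  expect_error(fitPca(matrix(1, 5, 3), 2), "degenerate")
})

test_that("PCA projection centers, preserves distances at full rank, and
           reproduces its explained variance", {
  x <- leafgrid:::withSeed(9, matrix(rnorm(8 * 5), 8, 5))
  m <- fitPca(x, 5 - 1)
  # the training mean projects to zero
  mu <- matrix(colMeans(x), 1)
  expect_lt(max(abs(featureValues(transformPca(m, mu)))), 1e-10)
  # training score variances equal the explained variances
  scores <- featureValues(transformPca(m, x))
  expect_equal(apply(scores, 2, var), m@explainedVariance,
               tolerance = 1e-10)
  # full-rank orthonormal basis preserves pairwise distances
  y <- leafgrid:::withSeed(10, matrix(rnorm(7 * 4), 7, 4))
  mf <- fitPca(y, 4)
  z <- featureValues(transformPca(mf, y))
  expect_equal(as.matrix(dist(z)), as.matrix(dist(y)), tolerance = 1e-8)
  expect_error(transformPca(m, matrix(0, 2, 7)), "shape error")
})

test_that("fusion bookkeeping matches n^2 x sum(k) with stable order", {
  # 2x2 grid, two backbones, k = 30 -> 240 fused dims
  spec2 <- fusionSpec(2, c("resnet101", "densenet201"), 30)
  expect_identical(fusedDim(spec2), 240L)
  blocks2 <- dummyReducedBlocks(8, 4, 30, seed = 2)
  fused2 <- fuseBlocks(blocks2, spec2)
  expect_equal(ncol(featureValues(fused2)), 240L)
  # one backbone -> 120
  spec1 <- fusionSpec(2, "resnet101", 30)
  expect_identical(fusedDim(spec1), 120L)
  fused1 <- fuseBlocks(blocks2[1:4], spec1)
  expect_equal(ncol(featureValues(fused1)), 120L)
  # concatenation preserves block order and values
  expect_equal(unname(featureValues(fused2)[, 1:30]),
               featureValues(blocks2[[1]]))
  expect_equal(unname(featureValues(fused2)[, 211:240]),
               featureValues(blocks2[[8]]))
  expect_identical(provenance(fused2)$stage, "fused")
})

test_that("fusion validates block counts and sample alignment", {
  spec <- fusionSpec(2, "bb", 3)
  blocks <- dummyReducedBlocks(4, 5, 3, seed = 4)
  single <- suppressWarnings(fusionSpec(1, "bb", 3))
  expect_equal(featureValues(fuseBlocks(blocks[1], single)),
               featureValues(blocks[[1]]),
               ignore_attr = TRUE)  # single block: fuse is identity
  expect_error(fuseBlocks(blocks[1:3], spec), "expects 4 blocks")
  misaligned <- blocks
  misaligned[[2]]@sampleIds <- rev(misaligned[[2]]@sampleIds)
  expect_error(fuseBlocks(misaligned, spec), "alignment error")
})

test_that("z-score parameters come from the training split only", {
  train <- leafgrid:::withSeed(5, matrix(rnorm(40 * 6, mean = 3, sd = 2),
                                         40, 6))
  train[, 6] <- 1  # constant column
  heldOut <- leafgrid:::withSeed(6, matrix(rnorm(10 * 6, mean = 5), 10, 6))
  zs <- zscoreFitApply(train, others = list(heldOut))
  expect_lt(max(abs(colMeans(zs$train))), 1e-8)
  expect_lt(max(abs(apply(zs$train[, 1:5], 2, sd) - 1)), 1e-6)
  expect_true(all(zs$train[, 6] == 0))  # epsilon guard on constant column
  # held-out data normalized with frozen training parameters is off-center
  expect_gt(max(abs(colMeans(zs$others[[1]][, 1:5]))), 0.1)
  expect_equal(applyZscore(zs$params, heldOut), zs$others[[1]])
})

test_that("fitted transforms round-trip through the text archive", {
  blocks <- lapply(1:4, function(i)
    featureMatrix(leafgrid:::withSeed(i, matrix(rnorm(12 * 9), 12, 9)),
                  sampleIds = sprintf("s%02d", 1:12),
                  backbone = "standin",
                  tile = c((i - 1L) %/% 2L + 1L, (i - 1L) %% 2L + 1L)))
  fusion <- fusionSpec(2, "standin", 3)
  ft <- fitTransforms(blocks, trainIdx = 1:8, fusion = fusion)
  dir <- withr::local_tempdir()
  writeFittedTransforms(ft, dir)
  back <- readFittedTransforms(dir)
  expect_equal(applyTransforms(back, blocks, rows = 9:12),
               applyTransforms(ft, blocks, rows = 9:12),
               tolerance = 1e-12)
  # training rows are exactly z-scored under their own transforms
  xTrain <- applyTransforms(ft, blocks, rows = 1:8)
  expect_lt(max(abs(colMeans(xTrain))), 1e-8)
})

test_that("feature blocks round-trip through CSV + JSON sidecars", {
  blocks <- lapply(1:2, function(i)
    featureMatrix(leafgrid:::withSeed(20 + i, matrix(rnorm(3 * 4), 3, 4)),
                  sampleIds = c("a", "b", "c"), backbone = "standin",
                  tile = c(1L, i)))
  dir <- withr::local_tempdir()
  writeFeatureBlocks(blocks, dir, divisionSpec(2))
  back <- readFeatureBlocks(dir)
  expect_equal(back$n, 2L)
  expect_equal(featureValues(back$blocks[[2]]),
               featureValues(blocks[[2]]), tolerance = 1e-12)
  expect_identical(sampleIds(back$blocks[[1]]), c("a", "b", "c"))
})
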