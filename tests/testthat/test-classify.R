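toyX <- rbind(c(0, 0), c(0, 1), c(3, 0), c(3, 1))
toyY <- c("A", "A", "B", "B")

test_that("the quadratic kernel evaluates (gamma <x,y> + coef0)^2", {
  ks <- kernelSpec(gamma = 1, coef0 = 0)
  expect_equal(quadraticKernel(c(1, 1), c(2, 0), ks), 4)
  expect_equal(quadraticKernel(c(1, 2), c(3, 4), kernelSpec(gamma = 0.5,
                                                            coef0 = 2)),
               (0.5 * 11 + 2)^2)
  # default gamma resolves to 1/dim
  expect_equal(quadraticKernel(c(2, 2), c(2, 2), kernelSpec(coef0 = 0)),
               16)
  expect_gte(quadraticKernel(rnorm(5), rnorm(5)), 0)  # k(x,x) >= 0 squared
  expect_error(quadraticKernel(1:3, 1:4), "shape error")
})

test_that("quadratic-kernel Gram matrices are positive semidefinite", {
  for (seed in 1:5) {
    x <- leafgrid:::withSeed(seed, matrix(rnorm(3 * 4, sd = 2), 3, 4))
    K <- gramMatrix(x, kernelSpec(gamma = 0.7, coef0 = 1))
    expect_lt(max(abs(K - t(K))), 1e-10)
    expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("the separable toy problem is solved with unit margins", {
  model <- trainOvaSvm(toyX, toyY, kernelSpec(gamma = 1, coef0 = 1,
                                              C = 1000))
  expect_length(model@machines, 2)  # one binary machine per class
  expect_identical(predict(model, toyX), toyY)  # 100% training accuracy
  diag <- dualDiagnostics(model)
  dv <- decisionValues(model, toyX)
  for (cls in names(diag)) {
    d <- diag[[cls]]
    # dual feasibility: 0 <= alpha <= C, sum(alpha * y) = 0
    expect_true(all(abs(d$alphaY) <= d$C + 1e-6))
    expect_lt(abs(d$sumAlphaY), 1e-6)
    # margin constraint y_i f(x_i) >= 1 - tol (hard-margin separable case)
    y <- ifelse(toyY == cls, 1, -1)
    expect_true(all(y * dv[, cls] >= 1 - 1e-3))
    expect_gt(d$marginWidth, 0)
  }
})

test_that("the dual objective matches a coarse grid search on 6 points", {
  x <- rbind(c(0, 0), c(1, 0.5), c(0.5, 1), c(3, 2.5), c(2.5, 3), c(3, 3))
  y <- c(-1, -1, -1, 1, 1, 1)
  ks <- kernelSpec(gamma = 1, coef0 = 1, C = 1)
  model <- trainOvaSvm(x, ifelse(y > 0, "P", "N"), ks)
  # objective of the solved machine for class "P" (y as given)
  d <- dualDiagnostics(model)[["P"]]
  K <- gramMatrix(x, ks)
  svRows <- apply(d$supportVectors, 1, function(sv)
    which.min(colSums((t(x) - sv)^2)))
  alpha <- abs(d$alphaY)
  aFull <- numeric(6); aFull[svRows] <- alpha
  obj <- function(a) sum(a) - 0.5 * sum((a * y) %o% (a * y) * K)
  solved <- obj(aFull)
  # brute-force: all alpha on a coarse grid, equality constraint enforced
  gridVals <- seq(0, 1, by = 0.25)
  grid <- as.matrix(expand.grid(rep(list(gridVals), 6)))
  feas <- grid[abs(grid %*% y) < 1e-9, , drop = FALSE]
  best <- max(apply(feas, 1, obj))
  expect_gte(solved, best - 1e-2)
  # and the solved alphas are feasible
  expect_true(all(aFull >= -1e-9 & aFull <= 1 + 1e-9))
  expect_lt(abs(sum(aFull * y)), 1e-6)
})

test_that("one machine per class, dual-feasible, on a 4-class problem", {
  x <- leafgrid:::withSeed(3, {
    centers <- rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4))
    centers[rep(1:4, each = 6), ] + matrix(rnorm(48, sd = 0.4), 24, 2)
  })
  labs <- rep(c("a", "b", "c", "d"), each = 6)
  model <- trainOvaSvm(x, labs, kernelSpec(C = 10))
  expect_length(model@machines, 4)
  for (d in dualDiagnostics(model)) {
    expect_true(all(abs(d$alphaY) <= d$C + 1e-6))
    expect_lt(abs(d$sumAlphaY), 1e-6)
  }
  expect_error(trainOvaSvm(x, rep("a", 24)), "degenerate labels")
})

test_that("duplicating a consistent sample never hurts training accuracy", {
  # separated clusters, so the margin solution is stable under duplication
  x <- leafgrid:::withSeed(8, {
    centers <- rbind(c(0, 0, 0), c(4, 4, 0))
    centers[rep(1:2, each = 10), ] + matrix(rnorm(60, sd = 0.5), 20, 3)
  })
  labs <- rep(c("u", "v"), each = 10)
  base <- trainOvaSvm(x, labs, kernelSpec(C = 10))
  accBase <- mean(predict(base, x) == labs)
  for (i in c(1, 7, 15)) {
    dup <- trainOvaSvm(rbind(x, x[i, ]), c(labs, labs[i]),
                       kernelSpec(C = 10))
    expect_gte(mean(predict(dup, x) == labs), accBase - 1e-12)
  }
})

test_that("stratified folds balance classes and cover every sample", {
  labs <- rep(c("a", "b", "c"), times = c(23, 17, 10))
  fold <- stratifiedFolds(labs, folds = 5, seed = 3)
  expect_length(fold, 50)
  expect_true(all(fold %in% 1:5))
  tab <- table(labs, fold)
  for (cls in rownames(tab)) {
    # within +/- 1 sample of an even split per class
    expect_lte(diff(range(tab[cls, ])), 1)
  }
  # reproducible under the same seed, different under another
  expect_identical(fold, stratifiedFolds(labs, 5, seed = 3))
  expect_false(identical(fold, stratifiedFolds(labs, 5, seed = 4)))
})

test_that("cross-validation holds out each sample once and counts honestly", {
  x <- leafgrid:::withSeed(12, {
    centers <- rbind(c(0, 0, 0), c(3, 3, 0), c(0, 3, 3))
    centers[rep(1:3, each = 12), ] + matrix(rnorm(108, sd = 0.5), 36, 3)
  })
  labs <- rep(c("a", "b", "c"), each = 12)
  rep1 <- crossValidate(featureMatrix(x, stage = "fused"), labs,
                        folds = 4, seed = 5)
  expect_equal(sort(unique(foldAssignments(rep1))), 1:4)
  expect_equal(unname(rowSums(confusionMatrix(rep1))), rep(12, 3))
  expect_equal(sum(confusionMatrix(rep1)), 36)
  expect_equal(accuracy(rep1),
               100 * sum(diag(confusionMatrix(rep1))) / 36)
  # determinism: identical inputs and seed give identical reports
  rep2 <- crossValidate(featureMatrix(x, stage = "fused"), labs,
                        folds = 4, seed = 5)
  expect_identical(reportAsJson(rep1), reportAsJson(rep2))
  # a class smaller than the fold count reduces folds with a note
  labsSmall <- c(rep("a", 3), rep("b", 33))
  expect_warning(
    repSmall <- crossValidate(featureMatrix(x, stage = "fused"), labsSmall,
                              folds = 10, seed = 1),
    "folds reduced")
  expect_equal(repSmall@folds, 3L)
  expect_error(crossValidate(featureMatrix(x, stage = "fused"), labs,
                             folds = 1, seed = 1), "configuration error")
})
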