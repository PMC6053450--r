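test_that("collinear cells yield a one-component model explaining everything", {
  set.seed(10)
  dir <- c(3, 1, 2) / sqrt(14)
  blocks <- lapply(1:2, function(i) outer(rnorm(200), dir))
  model <- fitSca(pmsFromBlocks(blocks), 1)
  expect_gt(totalExplainedVariance(model), 1 - 1e-12)
  expect_equal(abs(sum(loadings(model)[, 1] * dir)), 1, tolerance = 1e-8)
})

test_that("loadings match a dense eigendecomposition of the weighted covariance", {
  # small printed fixture: 2 blocks x 4 cells, 3 markers
  b1 <- matrix(c(1.2, -0.5, 0.3, 2.2,
                 0.7, 0.1, -1.1, 1.9,
                 -0.4, 0.8, 0.6, -1.5), 4, 3)
  b2 <- matrix(c(0.2, 1.5, -2.0, 0.9,
                 -0.3, 1.1, -1.7, 0.4,
                 1.0, -0.6, 0.5, -0.2), 4, 3)
  model <- fitSca(pmsFromBlocks(list(b1, b2)), 2)
  oracle <- weightedCovLoadings(list(b1, b2), 2)
  for (r in 1:2) {
    a <- loadings(model)[, r]; b <- oracle[, r]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)
  }

  # property: random instances up to 1000 cells, subspace angle < 1e-6
  set.seed(11)
  for (rep in 1:5) {
    blocks <- lapply(sample(50:400, 3), function(n)
      matrix(rnorm(n * 5), n, 5) %*% diag(c(3, 2, 1.5, 1, 0.5)))
    m <- fitSca(pmsFromBlocks(blocks), 3)
    o <- weightedCovLoadings(blocks, 3)
    expect_lt(subspaceAngle(loadings(m), o), 1e-6)
  }
})

test_that("component signs are fixed and errors guard the component count", {
  set.seed(12)
  blocks <- list(matrix(rnorm(300), 100, 3))
  model <- fitSca(pmsFromBlocks(blocks), 3)
  for (r in 1:3) {
    col <- loadings(model)[, r]
    expect_gt(col[which.max(abs(col))], 0)
  }
  expect_error(fitSca(pmsFromBlocks(blocks), 4), "exceeds")
  expect_error(fitSca(pmsFromBlocks(blocks), 0), ">= 1")
  expect_error(fitSca(pmsFromBlocks(list(matrix(rnorm(3), 1, 3))), 2),
               "fewer total cells")
})

test_that("explained variance grows with R and reaches 1 at R = J", {
  set.seed(13)
  blocks <- lapply(1:3, function(i) matrix(rnorm(150 * 4), 150, 4) %*%
                     diag(c(2, 1.5, 1, 0.5)))
  pms <- pmsFromBlocks(blocks)
  ev <- vapply(1:4, function(r) totalExplainedVariance(fitSca(pms, r)),
               numeric(1))
  expect_true(all(diff(ev) > 0))
  expect_equal(ev[4], 1, tolerance = 1e-10)
})

test_that("SPE is the per-cell squared residual distance", {
  P <- diag(3)[, 1:2]
  model <- modelFromLoadings(P)
  # cell (1,2,3): residual (0,0,3), SPE 9
  expect_equal(unname(computeSpe(model, matrix(c(1, 2, 3), 1, 3))), 9)
  # cell inside the model plane: SPE 0
  expect_equal(unname(computeSpe(model, matrix(c(5, -2, 0), 1, 3))), 0)
  # in-span additions leave SPE unchanged
  cell <- matrix(c(1, 2, 3), 1, 3)
  shifted <- cell + matrix(c(4, -7, 0), 1, 3)
  expect_equal(computeSpe(model, cell), computeSpe(model, shifted))
  # full-rank model: all SPE ~ 0
  set.seed(14)
  X <- matrix(rnorm(60), 20, 3)
  full <- fitSca(pmsFromBlocks(list(X)), 3)
  expect_lt(max(computeSpe(full, X)), 1e-10)
})

test_that("SPE limits follow the nearest-rank convention and pool by mean", {
  expect_equal(nearestRankQuantile(sample(1:100), 0.95), 95)
  prof <- speLimits(list(a = as.numeric(1:100)), alpha = 0.05)
  expect_equal(unname(prof@perIndividualLimits), 95)
  # constant SPE: pooled limit equals the constant
  prof2 <- speLimits(list(a = rep(2.5, 10), b = rep(2.5, 7)))
  expect_equal(speLimit(prof2), 2.5)
  # pooled limit is the mean of the individual limits
  prof3 <- speLimits(list(a = rep(10, 20), b = rep(20, 20)), alpha = 0.5)
  expect_equal(speLimit(prof3), 15)
  expect_error(speLimits(list(a = 1:5), alpha = 1.2), "alpha")
  expect_error(speLimits(list(), alpha = 0.05), "at least one")
})

test_that("control SPE exceeds the pooled limit for about alpha of the cells", {
  co <- generateCohort(lpsLikeDefault(spiked = FALSE,
                                      cellsPerIndividual = 2000L), seed = 9)
  pms <- fitPreprocess(co$multiset, preprocessParams())
  model <- fitSca(controls(pms), 2)
  prof <- controlSpeProfile(model, pms)
  allSpe <- unlist(speValues(prof))
  expect_equal(mean(allSpe > speLimit(prof)), 0.05, tolerance = 0.2)
})

test_that("models serialize to JSON and round-trip exactly", {
  set.seed(15)
  raw <- matrix(abs(rnorm(300, 20, 5)), 100, 3,
                dimnames = list(NULL, c("A", "B", "C")))
  ms <- assembleMultiSet(list(eventTable(raw, individualId = "c1")))
  pms <- fitPreprocess(ms, preprocessParams())
  model <- fitSca(pms, 2)
  f <- withr::local_tempfile(fileext = ".json")
  saveScaModel(model, f)
  back <- loadScaModel(f)
  expect_equal(loadings(back), loadings(model))
  expect_equal(back@params@scaleValues, model@params@scaleValues)
  expect_equal(explainedVariance(back), explainedVariance(model))
  expect_equal(back@provenance, model@provenance)
})
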