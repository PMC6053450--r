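test_that("projection reproduces training scores and the dot-product oracle", {
  set.seed(30)
  blocks <- lapply(1:2, function(i) matrix(rnorm(100 * 4), 100, 4))
  pms <- pmsFromBlocks(blocks)
  model <- fitSca(pms, 2)
  ss <- projectMultiSet(model, pms)
  # projecting a training block reproduces its scores bit-for-bit
  expect_identical(projectBlock(model, blocks[[1]])$scores,
                   scores(ss)[[1]])
  # scores * t(loadings) + residuals reconstructs each cell
  recon <- scores(ss)[[2]] %*% t(loadings(model)) + residuals2(ss)[[2]]
  expect_lt(max(abs(recon - blocks[[2]])), 1e-8)
  # a cell equal to loading column r scores as unit vector e_r
  for (r in 1:2) {
    proj <- projectBlock(model, matrix(loadings(model)[, r], 1))
    expect_equal(unname(proj$scores), t(diag(2)[, r]), tolerance = 1e-10)
    expect_lt(max(abs(proj$residuals)), 1e-10)
  }
  # naive per-cell dot-product oracle
  X <- matrix(rnorm(20 * 4), 20, 4)
  proj <- projectBlock(model, X)
  P <- loadings(model)
  for (n in 1:20) for (r in 1:2)
    expect_equal(proj$scores[n, r], sum(X[n, ] * P[, r]), tolerance = 1e-10)
  expect_error(projectBlock(model, matrix(0, 2, 3)), "columns")
})

test_that("SPE flagging uses a strict inequality", {
  expect_equal(flagSpeOutliers(c(0.1, 0.5, 0.9), 1), rep(FALSE, 3))
  expect_false(flagSpeOutliers(1, 1))        # tie is not an outlier
  expect_true(flagSpeOutliers(1 + 1e-12, 1))
  expect_error(flagSpeOutliers(1:3, -1), "positive")
})

test_that("DbD is zero for identical densities and negative on responder-only support", {
  grid <- list(x = seq(-8, 8, length.out = 64),
               y = seq(-8, 8, length.out = 64), bandwidths = c(0.5, 0.5))
  set.seed(31)
  gC <- estimateKde(matrix(rnorm(2000), 1000, 2), grid = grid)
  expect_equal(max(abs(computeDbd(gC, gC)@values)), 0)
  gR <- estimateKde(cbind(rnorm(500, 6), rnorm(500, 6)), grid = grid)
  dbd <- computeDbd(gC, gR)
  corner <- dbd@values[dbd@x > 4, dbd@y > 4]
  expect_true(all(corner[corner != 0] < 0))
  other <- suppressWarnings(estimateKde(matrix(rnorm(20), 10, 2),
                                        gridSize = 64))
  expect_error(computeDbd(gC, other), "identical grid")
})

test_that("DbD sign pattern matches the closed-form difference of two Gaussians", {
  gx <- seq(-5, 5, length.out = 128)
  fC <- outer(dnorm(gx, -1), dnorm(gx))
  fR <- outer(dnorm(gx, +1), dnorm(gx))
  mk <- function(v) new("DensityGrid", x = gx, y = gx,
                        values = v / (sum(v) * (gx[2] - gx[1])^2),
                        bandwidths = c(1, 1), normalized = TRUE,
                        nSourceCells = 1L)
  dbd <- computeDbd(mk(fC), mk(fR))
  ref <- fC / (sum(fC) * (gx[2] - gx[1])^2) - fR / (sum(fR) * (gx[2] - gx[1])^2)
  big <- abs(ref) > 1e-6
  expect_true(all(sign(dbd@values[big]) == sign(ref[big])))
  # offset Gaussians: control-enriched left of the midline, responder right
  expect_true(all(dbd@values[gx < -0.5, abs(gx) < 1] > 0))
  expect_true(all(dbd@values[gx > 0.5, abs(gx) < 1] < 0))
})

test_that("the DbD filter retains only strictly negative bins", {
  gx <- seq(-1, 1, length.out = 21)
  vals <- matrix(0, 21, 21)
  vals[11, 11] <- -0.3
  vals[1, 1] <- 0.4
  dbd <- new("DensityGrid", x = gx, y = gx, values = vals,
             bandwidths = c(NA_real_, NA_real_), normalized = FALSE,
             nSourceCells = 1L)
  expect_true(applyDbdFilter(dbd, matrix(c(0, 0), 1)))        # negative bin
  expect_false(applyDbdFilter(dbd, matrix(c(-1, -1), 1)))     # positive bin
  expect_false(applyDbdFilter(dbd, matrix(c(0.5, 0.5), 1)))   # zero bin
  # all-zero DbD retains nothing
  zero <- new("DensityGrid", x = gx, y = gx, values = matrix(0, 21, 21),
              bandwidths = c(NA_real_, NA_real_), normalized = FALSE,
              nSourceCells = 1L)
  expect_false(any(applyDbdFilter(zero, cbind(runif(50, -1, 1),
                                              runif(50, -1, 1)))))
})

test_that("an off-plane spike is flagged at baseline-plus-abundance rate", {
  # mixture accounting in model space: 85% control-distributed cells plus
  # 15% displaced far along a direction outside the loading span
  set.seed(32)
  J <- 5
  mkBlock <- function(n) matrix(rnorm(n * J), n, J) %*%
    diag(c(3, 2, 0.5, 0.5, 0.5))
  ctrl <- lapply(1:4, function(i) mkBlock(2000))
  pms <- pmsFromBlocks(ctrl)
  model <- fitSca(pms, 2)
  prof <- speLimits(lapply(ctrl, function(b) computeSpe(model, b)))
  offPlane <- qr.Q(qr(cbind(loadings(model),
                            matrix(rnorm(J * 3), J, 3))))[, J]
  n <- 4000
  resp <- mkBlock(n)
  spikeRows <- seq_len(0.15 * n)
  resp[spikeRows, ] <- resp[spikeRows, ] + 6 * rep(offPlane, each =
    length(spikeRows))
  flagged <- flagSpeOutliers(computeSpe(model, resp), speLimit(prof))
  expect_equal(mean(flagged), 0.05 * 0.85 + 0.15, tolerance = 0.1)
  expect_true(all(flagged[spikeRows]))
})

test_that("retention is the union of disjoint SPE and DbD provenances", {
  co <- generateCohort(lpsLikeDefault(cellsPerIndividual = 1500L), seed = 33)
  pms <- fitPreprocess(co$multiset, preprocessParams())
  model <- fitSca(controls(pms), 2)
  prof <- controlSpeProfile(model, pms)
  mask <- suppressMessages(eclipseFilter(model, pms, prof, gridSize = 128))
  for (f in retentionFlags(mask)) {
    expect_equal(f$retained, f$retainedSpe | f$retainedDbd)
    expect_false(any(f$retainedSpe & f$retainedDbd))
  }
  smry <- retentionSummary(mask)
  expect_equal(smry$n_retained, smry$n_spe + smry$n_dbd)
  # every responder retains clearly more than the 5% control baseline
  expect_true(all(smry$pct_retained > 10))
})

test_that("null responders keep the SPE baseline near alpha", {
  co <- generateCohort(lpsLikeDefault(spiked = FALSE,
                                      cellsPerIndividual = 2000L), seed = 34)
  pms <- fitPreprocess(co$multiset, preprocessParams())
  model <- fitSca(controls(pms), 2)
  prof <- controlSpeProfile(model, pms)
  mask <- suppressMessages(eclipseFilter(model, pms, prof, gridSize = 128))
  smry <- retentionSummary(mask)
  expect_equal(mean(smry$pct_spe), 5, tolerance = 0.3)
  # DbD retention on nulls is pure sampling noise around a coin flip;
  # recorded as the calibration floor, bounded loosely
  expect_lt(median(smry$pct_retained), 75)
})

test_that("enlarging a spike never decreases its retained count", {
  counts <- vapply(c(0.05, 0.15), function(ab) {
    spec <- lpsLikeDefault(cellsPerIndividual = 1500L)
    spec@responsePopulations <- lapply(spec@responsePopulations, function(p) {
      p$abundance <- ab
      p
    })
    co <- generateCohort(spec, seed = 35)
    pms <- fitPreprocess(co$multiset, preprocessParams())
    model <- fitSca(controls(pms), 2)
    prof <- controlSpeProfile(model, pms)
    mask <- suppressMessages(eclipseFilter(model, pms, prof, gridSize = 128))
    sum(mapply(function(id, f) sum(f$retained & co$labels[[id]]$spiked),
               names(retentionFlags(mask)), retentionFlags(mask)))
  }, numeric(1))
  expect_gte(counts[2], counts[1])
})
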