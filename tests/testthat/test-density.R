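test_that("diffusion bandwidth approximates the reference rule on normal data", {
  set.seed(20)
  x <- rnorm(1e4)
  h <- selectBandwidth(x)
  silverman <- 1.06 * sd(x) * length(x)^(-1 / 5)
  expect_lt(abs(h - silverman) / silverman, 0.25)
})

test_that("diffusion bandwidth undercuts the reference rule on bimodal data", {
  set.seed(21)
  x <- c(rnorm(5000, -5), rnorm(5000, 5))
  expect_lt(selectBandwidth(x), 1.06 * sd(x) * length(x)^(-1 / 5))
})

test_that("bandwidth selection rejects degenerate input", {
  expect_error(selectBandwidth(rep(2, 10)), "zero spread")
  expect_error(selectBandwidth(3), "two points")
})

test_that("a single cell reproduces the kernel itself", {
  gx <- seq(-4, 4, length.out = 129)
  g <- estimateKde(matrix(c(0, 0), 1, 2),
                   grid = list(x = gx, y = gx, bandwidths = c(1, 1)),
                   normalize = FALSE)
  ref <- outer(dnorm(gx), dnorm(gx))
  expect_lt(max(abs(g@values - ref)), 1e-3)
})

test_that("binned-FFT KDE agrees with direct summation on node-aligned points", {
  gx <- seq(-3, 3, length.out = 64)
  gy <- seq(-2, 2, length.out = 64)
  pts <- cbind(gx[c(10, 30, 47)], gy[c(20, 40, 12)])
  h <- c(0.5, 0.4)
  g <- estimateKde(pts, grid = list(x = gx, y = gy, bandwidths = h),
                   normalize = FALSE)
  oracle <- directKde2d(pts, gx, gy, h)
  expect_lt(max(abs(g@values - oracle)) / max(oracle), 1e-8)
})

test_that("KDE values are nonnegative with exact unit integral", {
  set.seed(22)
  g <- estimateKde(matrix(rnorm(3000), 1500, 2), gridSize = 128)
  expect_true(all(g@values >= 0))
  expect_equal(sum(g@values) * eclipser:::.gridCellArea(g), 1,
               tolerance = 1e-9)
  expect_true(g@normalized)
})

test_that("off-grid cells are clipped to the boundary with a message", {
  gx <- seq(-1, 1, length.out = 32)
  expect_message(
    estimateKde(rbind(c(0, 0), c(5, 5)),
                grid = list(x = gx, y = gx, bandwidths = c(0.2, 0.2))),
    "clipped")
})

test_that("KDE converges to the analytic density on large samples", {
  set.seed(23)
  n <- 1e5
  pts <- cbind(rnorm(n), rnorm(n))
  g <- estimateKde(pts, gridSize = 256L)
  ref <- outer(dnorm(g@x), dnorm(g@y))
  expect_lt(max(abs(g@values - ref)), 0.05 * max(ref))
})

test_that("pooling identical densities is idempotent", {
  set.seed(24)
  grid <- list(x = seq(-4, 4, length.out = 64),
               y = seq(-4, 4, length.out = 64), bandwidths = c(0.4, 0.4))
  g <- estimateKde(matrix(rnorm(1000), 500, 2), grid = grid)
  pooled <- poolDensities(list(g, g))
  expect_equal(pooled@values, g@values, tolerance = 1e-12)
})

test_that("pooling splits mass evenly across disjoint supports", {
  grid <- list(x = seq(-10, 10, length.out = 128),
               y = seq(-10, 10, length.out = 128), bandwidths = c(0.3, 0.3))
  gA <- estimateKde(matrix(c(-6, -6), 1, 2), grid = grid)
  gB <- estimateKde(matrix(c(6, 6), 1, 2), grid = grid)
  pooled <- poolDensities(list(gA, gB))
  area <- eclipser:::.gridCellArea(pooled)
  expect_equal(sum(pooled@values) * area, 1, tolerance = 1e-9)
  left <- pooled@x < 0
  expect_equal(sum(pooled@values[left, ]) * area, 0.5, tolerance = 1e-6)
  other <- estimateKde(matrix(c(0, 0), 1, 2),
                       grid = list(x = seq(-1, 1, length.out = 128),
                                   y = seq(-1, 1, length.out = 128),
                                   bandwidths = c(0.3, 0.3)))
  expect_error(poolDensities(list(gA, other)), "identical grid")
})

test_that("pooled equal-weight KDEs match the KDE of the pooled cells", {
  set.seed(25)
  perInd <- lapply(1:4, function(i)
    cbind(rnorm(800, i / 4), rnorm(800, -i / 4)))
  grid <- scoreGrid(perInd, gridSize = 128)
  pooled <- poolDensities(lapply(perInd, estimateKde, grid = grid))
  union <- estimateKde(do.call(rbind, perInd), grid = grid)
  # equal weights: identical up to per-individual edge-mass renormalization
  expect_lt(max(abs(pooled@values - union@values)), 1e-3 * max(union@values))
})

test_that("density grids round-trip through gzipped JSON", {
  set.seed(26)
  g <- estimateKde(matrix(rnorm(200), 100, 2), gridSize = 32)
  f <- withr::local_tempfile(fileext = ".json.gz")
  writeDensityGrid(g, f)
  back <- readDensityGrid(f)
  expect_equal(back@values, g@values)
  expect_equal(back@bandwidths, g@bandwidths)
  expect_equal(back@nSourceCells, g@nSourceCells)
})
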