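mkRetained <- function(popList, ids, markers = paste0("M", 1:4)) {
  # one block per id, same populations
  blocks <- lapply(ids, function(id) rawBlockFromPops(popList, markers))
  tabs <- Map(function(b, id) eventTable(b, individualId = id, group = 1L),
              blocks, ids)
  # bypass assembleMultiSet's control requirement: retained sets are all
  # responders by construction
  new("CytoMultiSet", blocks = lapply(tabs, function(t) t$events),
      individualIds = ids, groups = rep(1L, length(ids)),
      markerNames = markers)
}

test_that("the response model picks up the discriminating markers", {
  set.seed(40)
  # two retained populations differing only in markers M1 and M2
  pops <- list(list(mean = c(2, 4, 3, 3), sd = 0.2, n = 400),
               list(mean = c(4, 2, 3, 3), sd = 0.2, n = 400))
  ms <- mkRetained(pops, c("r1", "r2"))
  res <- buildEclipseModel(ms, params = preprocessParams(), nComponents = 2)
  lead <- abs(loadings(res@model)[, 1])
  expect_setequal(names(sort(lead, decreasing = TRUE))[1:2], c("M1", "M2"))
})

test_that("a single responder with full rank explains all variance", {
  set.seed(41)
  pops <- list(list(mean = c(2, 3, 4, 3), sd = 0.5, n = 300))
  ms <- mkRetained(pops, "r1")
  res <- buildEclipseModel(ms, params = preprocessParams(), nComponents = 4)
  expect_equal(totalExplainedVariance(res@model), 1, tolerance = 1e-10)
})

test_that("zero-variance markers under per-individual scaling fall back to pooled", {
  set.seed(42)
  blocks <- list(cbind(M1 = rnorm(50, 10, 2), M2 = rep(5, 50)),
                 cbind(M1 = rnorm(50, 10, 2), M2 = rnorm(50, 5, 1)))
  ms <- new("CytoMultiSet", blocks = blocks, individualIds = c("r1", "r2"),
            groups = c(1L, 1L), markerNames = c("M1", "M2"))
  expect_warning(
    res <- buildEclipseModel(ms, params = preprocessParams(),
                             nComponents = 2),
    "falling back to over_all")
  expect_equal(res@model@params@scaling, "over_all")
})

test_that("retained-cell provenance traces back to original event indices", {
  co <- generateCohort(lpsLikeDefault(cellsPerIndividual = 1000L), seed = 43)
  pms <- fitPreprocess(co$multiset, preprocessParams())
  model <- fitSca(controls(pms), 2)
  prof <- controlSpeProfile(model, pms)
  mask <- suppressMessages(eclipseFilter(model, pms, prof, gridSize = 96))
  rs <- retainedMultiSet(co$multiset, mask)
  tab <- rs$provenance
  expect_equal(nrow(tab), sum(retentionSummary(mask)$n_retained))
  id <- tab$individual_id[1]
  idx <- tab$event_index[tab$individual_id == id]
  expect_equal(eventBlocks(rs$multiset)[[id]],
               eventBlocks(co$multiset)[[id]][idx, , drop = FALSE])
})

test_that("binned densities are unit-mass vectors with expected structure", {
  set.seed(44)
  pops <- list(list(mean = c(2, 4, 3, 3), sd = 0.3, n = 200),
               list(mean = c(4, 2, 3, 3), sd = 0.3, n = 200))
  ms <- mkRetained(pops, c("r1", "r2"))
  res <- buildEclipseModel(ms, params = preprocessParams(), nComponents = 2)
  dens <- binnedDensities(res, gridSize = 16)
  expect_equal(dim(dens), c(2L, 256L))
  expect_equal(unname(rowSums(dens)), c(1, 1))
  # a responder whose cells all score identically gives a one-hot vector
  one <- res
  one@scores@scores[[1]][] <- 0.25
  oh <- binnedDensities(one, gridSize = 8)
  expect_equal(unname(max(oh[1, ])), 1)
  expect_equal(sum(oh[1, ] > 0), 1L)
  # identical responders give identical vectors
  two <- res
  two@scores@scores[[2]] <- two@scores@scores[[1]]
  tw <- binnedDensities(two, gridSize = 8)
  expect_equal(tw[1, ], tw[2, ])
})

test_that("identical responders sit at distance zero and merge first", {
  set.seed(45)
  pops <- list(list(mean = c(2, 4, 3, 3), sd = 0.3, n = 300))
  b <- rawBlockFromPops(pops, paste0("M", 1:4))
  b3 <- rawBlockFromPops(list(list(mean = c(2, 4, 3, 3), sd = 0.3, n = 150),
                              list(mean = c(5, 1, 3, 3), sd = 0.3, n = 150)),
                         paste0("M", 1:4))
  ms <- new("CytoMultiSet", blocks = list(b, b, b3),
            individualIds = c("r1", "r2", "r3"), groups = rep(1L, 3),
            markerNames = paste0("M", 1:4))
  res <- buildEclipseModel(ms, params = preprocessParams(), nComponents = 2)
  st <- stratify(res, k = 2)
  D <- as.matrix(st@distances)
  expect_equal(D["r1", "r2"], 0)
  expect_equal(st@tree$height[1], 0)
  expect_equal(unname(clusterLabels(st)[c("r1", "r2")]), c(1L, 1L))
  expect_error(stratify(res, k = 5), "exceeds")
})

test_that("jensen-shannon distances are a valid metric option", {
  dens <- rbind(r1 = c(0.5, 0.5, 0, 0), r2 = c(0.5, 0.5, 0, 0),
                r3 = c(0, 0, 0.5, 0.5))
  st <- stratify(dens, k = 2, metric = "jensen_shannon")
  D <- as.matrix(st@distances)
  expect_equal(D["r1", "r2"], 0)
  expect_equal(D["r1", "r3"], sqrt(log(2)), tolerance = 1e-10)
  expect_equal(unname(clusterLabels(st)), c(1L, 1L, 2L))
})

test_that("a one-cluster cut reproduces the general model", {
  set.seed(46)
  pops <- list(list(mean = c(2, 4, 3, 3), sd = 0.3, n = 200),
               list(mean = c(4, 2, 3, 3), sd = 0.3, n = 200))
  ms <- mkRetained(pops, c("r1", "r2"))
  res <- buildEclipseModel(ms, params = preprocessParams(), nComponents = 2)
  pm <- fitPartialModels(res, c(r1 = 1L, r2 = 1L))
  expect_length(pm, 1L)
  expect_equal(loadings(pm[["1"]]@model), loadings(res@model),
               tolerance = 1e-10)
  expect_equal(pm[["1"]]@model@provenance, "eclipse_partial")
})

test_that("clusters with orthogonal response axes yield distant partial models", {
  set.seed(47)
  mkPair <- function(d) list(list(mean = c(3, 3, 3, 3) + d, sd = 0.2, n = 300),
                             list(mean = c(3, 3, 3, 3) - d, sd = 0.2, n = 300))
  dA <- c(1.5, -1.5, 0, 0)   # cluster A varies along M1-M2
  dB <- c(0, 0, 1.5, -1.5)   # cluster B varies along M3-M4
  msA <- mkRetained(mkPair(dA), c("a1", "a2"))
  msB <- mkRetained(mkPair(dB), c("b1", "b2"))
  ms <- new("CytoMultiSet", blocks = c(msA@blocks, msB@blocks),
            individualIds = c("a1", "a2", "b1", "b2"),
            groups = rep(1L, 4), markerNames = paste0("M", 1:4))
  res <- buildEclipseModel(ms, params = preprocessParams(), nComponents = 1)
  labels <- c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L)
  pm <- fitPartialModels(res, labels, nComponents = 1)
  ang <- subspaceAngle(loadings(pm[["1"]]@model), loadings(pm[["2"]]@model))
  expect_gt(ang, 45 * pi / 180)
})
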