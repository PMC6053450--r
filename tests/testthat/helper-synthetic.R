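# Shared fixtures and independent oracles, all built in code.

# PreprocessedMultiSet straight from a list of numeric matrices (no
# transform), for exercising the decomposition machinery in isolation.
pmsFromBlocks <- function(blocks, groups = rep(0L, length(blocks)),
                          ids = sprintf("ind%02d", seq_along(blocks))) {
  J <- ncol(blocks[[1]])
  mk <- paste0("M", seq_len(J))
  blocks <- lapply(blocks, function(b) { colnames(b) <- mk; b })
  params <- new("PreprocessParams", transform = "arcsinh",
                arcsinhCofactor = 5, logShift = NA_real_,
                scaling = "over_controls", scaleValues = rep(1, J),
                centers = list(), scales = list(), markerNames = mk,
                fitted = TRUE)
  new("PreprocessedMultiSet", blocks = blocks, individualIds = ids,
      groups = as.integer(groups), markerNames = mk, params = params,
      normalized = FALSE)
}

# ScaModel with prescribed orthonormal loadings (for SPE hand examples).
modelFromLoadings <- function(P) {
  colnames(P) <- NULL
  rn <- rownames(P)
  if (is.null(rn)) rn <- paste0("M", seq_len(nrow(P)))
  rownames(P) <- rn
  new("ScaModel", loadings = P, nComponents = ncol(P),
      params = new("PreprocessParams", transform = "arcsinh",
                   arcsinhCofactor = 5, logShift = NA_real_,
                   scaling = "over_controls", scaleValues = numeric(0),
                   centers = list(), scales = list(),
                   markerNames = rn, fitted = TRUE),
      explainedVariance = numeric(0), totalExplainedVariance = 0,
      provenance = "control")
}

# Brute-force oracle: eigenvectors of the block-weighted covariance
# sum_i X_i' X_i / N_i (each individual equal weight).
weightedCovLoadings <- function(blocks, R) {
  J <- ncol(blocks[[1]])
  S <- matrix(0, J, J)
  for (X in blocks) S <- S + crossprod(X) / nrow(X)
  eigen(S, symmetric = TRUE)$vectors[, seq_len(R), drop = FALSE]
}

# Naive double-loop KDE oracle (direct summation of product Gaussians).
directKde2d <- function(pts, x, y, h) {
  out <- matrix(0, length(x), length(y))
  for (k in seq_len(nrow(pts)))
    out <- out + outer(stats::dnorm(x, pts[k, 1], h[1]),
                       stats::dnorm(y, pts[k, 2], h[2]))
  out / nrow(pts)
}

# Raw-intensity multiset with prescribed populations in arcsinh space:
# popList entries are list(mean, sd, n) (isotropic); one block.
rawBlockFromPops <- function(popList, markers, cofactor = 5) {
  z <- do.call(rbind, lapply(popList, function(p)
    matrix(stats::rnorm(p$n * length(markers), mean = rep(p$mean,
      each = p$n), sd = p$sd), nrow = p$n)))
  raw <- sinh(z) * cofactor
  colnames(raw) <- markers
  raw
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
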