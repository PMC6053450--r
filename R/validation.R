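#' @include AllClasses.R control_model.R
NULL

#' Largest principal angle between two loading subspaces
#'
#' Computed from the singular values of `t(Pa) %*% Pb` (clamped to [0, 1]
#' before arccos); the largest angle is the most conservative measure of
#' subspace dissimilarity and is invariant to component sign flips and to
#' rotations within either subspace.
#'
#' @param Pa,Pb J x R matrices with orthonormal columns.
#' @return angle in radians, in [0, pi/2].
#' @export
subspaceAngle <- function(Pa, Pb) {
  Pa <- as.matrix(Pa); Pb <- as.matrix(Pb)
  if (!all(dim(Pa) == dim(Pb)))
    stop("subspaces must have equal dimensions")
  s <- svd(crossprod(Pa, Pb), nu = 0, nv = 0)$d
  acos(min(pmax(pmin(s, 1), 0)))
}

#' Bootstrap stability of the loading subspaces
#'
#' For each bootstrap replicate, cells are resampled with replacement within
#' each individual (block sizes preserved, so the multiset structure is
#' intact), the simultaneous decomposition is refitted, and for every
#' candidate component count R <= `rMax` the largest principal angle between
#' the replicate's first R loadings and the full-data reference loadings is
#' recorded. Components that describe systematic cohort-wide variability
#' reproduce under resampling (small angles); noise directions do not.
#'
#' @param pms [PreprocessedMultiSet] (un-normalized blocks).
#' @param rMax largest candidate R (<= number of markers).
#' @param nBoot number of replicates (>= 10).
#' @param seed RNG seed; results are reproducible given the seed.
#' @return a [StabilityProfile].
#' @export
bootstrapStability <- function(pms, rMax, nBoot = 100L, seed = 1L) {
  stopifnot(is(pms, "PreprocessedMultiSet"))
  rMax <- as.integer(rMax)
  J <- length(pms@markerNames)
  if (rMax > J) stop("rMax exceeds the number of markers")
  if (rMax < 1L) stop("rMax must be >= 1")
  if (nBoot < 10L) stop("at least 10 bootstrap replicates are required")
  ref <- fitSca(pms, rMax)@loadings
  set.seed(seed)
  angles <- lapply(seq_len(rMax), function(r) numeric(nBoot))
  for (b in seq_len(nBoot)) {
    boot <- pms
    boot@blocks <- lapply(pms@blocks, function(X)
      X[sample.int(nrow(X), replace = TRUE), , drop = FALSE])
    Pb <- fitSca(boot, rMax)@loadings
    for (r in seq_len(rMax))
      angles[[r]][b] <- subspaceAngle(ref[, seq_len(r), drop = FALSE],
                                      Pb[, seq_len(r), drop = FALSE])
  }
  new("StabilityProfile", angles = angles, nBoot = as.integer(nBoot),
      seed = as.integer(seed))
}

#' Summary table of a stability profile
#'
#' @param profile a [StabilityProfile].
#' @return data.frame with per-R median and 95th-percentile angles (radians).
#' @export
stabilityTable <- function(profile) {
  stopifnot(is(profile, "StabilityProfile"))
  data.frame(
    R = seq_along(profile@angles),
    median_angle = vapply(profile@angles, stats::median, numeric(1)),
    q95_angle = vapply(profile@angles, function(a)
      unname(stats::quantile(a, 0.95)), numeric(1)))
}

#' Choose the number of components from bootstrap stability
#'
#' Returns the largest R whose 95th-percentile bootstrap angle stays at or
#' below `angleThreshold` (default 0.35 rad, about 20 degrees). If no R
#' qualifies, 1 is returned with a warning. The threshold is a pragmatic
#' numeric reading of 'the stability of the angle should be high' and can be
#' overridden; the final choice remains the analyst's.
#'
#' @param profile a [StabilityProfile].
#' @param angleThreshold radians.
#' @return integer R.
#' @export
chooseComponents <- function(profile, angleThreshold = 0.35) {
  tab <- stabilityTable(profile)
  ok <- which(tab$q95_angle <= angleThreshold)
  if (!length(ok)) {
    warning("no component count met the stability threshold; returning R = 1")
    return(1L)
  }
  max(ok)
}
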