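#' @include AllClasses.R preprocess.R
NULL

.fixLoadingSigns <- function(P) {
  for (r in seq_len(ncol(P))) {
    j <- which.max(abs(P[, r]))
    if (P[j, r] < 0) P[, r] <- -P[, r]
  }
  P
}

#' Fit a simultaneous component (SCA-P) model
#'
#' Stacks the block-normalized events of all blocks in `pms` and takes the
#' first `nComponents` right singular directions as the loading matrix common
#' to every individual. Scores and residuals are then computed per individual
#' on the un-normalized blocks, so the model is the multiset PCA in which
#' each individual contributed equal weight to the loadings while keeping its
#' own cells' coordinates. SVD of the stacked data is used rather than an
#' eigendecomposition of the covariance for numerical stability; the two
#' agree up to the span of the loadings.
#'
#' Per component, the largest-magnitude loading entry is made positive so
#' models are reproducible across platforms.
#'
#' @param pms a [PreprocessedMultiSet] (block normalization is applied
#'   internally for the decomposition if it has not been already).
#' @param nComponents number of components R (1 <= R <= J).
#' @param provenance model provenance tag.
#' @return an [ScaModel]; obtain scores via [projectMultiSet()].
#' @export
fitSca <- function(pms, nComponents,
                   provenance = c("control", "eclipse_general",
                                  "eclipse_partial")) {
  stopifnot(is(pms, "PreprocessedMultiSet"))
  provenance <- match.arg(provenance)
  J <- length(pms@markerNames)
  R <- as.integer(nComponents)
  if (R < 1L) stop("nComponents must be >= 1")
  if (R > J) stop("nComponents (", R, ") exceeds the number of markers (", J, ")")
  ntot <- sum(vapply(pms@blocks, nrow, integer(1)))
  if (ntot < R) stop("fewer total cells than components")
  if (pms@normalized)
    stop("pass the un-normalized PreprocessedMultiSet; block normalization ",
         "is applied internally for the decomposition only")
  norm <- blockNormalize(pms)
  stacked <- do.call(rbind, norm@blocks)
  sv <- svd(stacked, nu = 0L, nv = R)
  P <- .fixLoadingSigns(sv$v[, seq_len(R), drop = FALSE])
  rownames(P) <- pms@markerNames

  raw <- pms@blocks
  ev <- vapply(raw, function(X) {
    Tm <- X %*% P
    E <- X - Tm %*% t(P)
    1 - sum(E^2) / sum(X^2)
  }, numeric(1))
  evTot <- 1 - (sum(stacked^2) - sum((stacked %*% P)^2)) / sum(stacked^2)
  new("ScaModel", loadings = P, nComponents = R, params = pms@params,
      explainedVariance = stats::setNames(ev, pms@individualIds),
      totalExplainedVariance = evTot, provenance = provenance)
}

#' Project a preprocessed block onto a fitted model
#'
#' Orthogonal projection: `T = X P`, `E = X - T t(P)`. Projecting a control
#' training block reproduces its training scores exactly, since scores are
#' defined by the same product.
#'
#' @param model an [ScaModel].
#' @param block preprocessed event matrix (same panel and recipe as the
#'   model's training data).
#' @return list with elements `scores` (N x R) and `residuals` (N x J).
#' @export
projectBlock <- function(model, block) {
  stopifnot(is(model, "ScaModel"))
  block <- as.matrix(block)
  if (ncol(block) != nrow(model@loadings))
    stop("block has ", ncol(block), " columns; model expects ",
         nrow(model@loadings))
  Tm <- block %*% model@loadings
  list(scores = Tm, residuals = block - Tm %*% t(model@loadings))
}

#' Project every block of a multiset
#'
#' @param model an [ScaModel].
#' @param pms a [PreprocessedMultiSet] (un-normalized blocks).
#' @return a [ScoreSet] aligned with the blocks of `pms`.
#' @export
projectMultiSet <- function(model, pms) {
  stopifnot(is(pms, "PreprocessedMultiSet"))
  proj <- lapply(pms@blocks, projectBlock, model = model)
  new("ScoreSet",
      scores = lapply(proj, `[[`, "scores"),
      residuals = lapply(proj, `[[`, "residuals"),
      individualIds = pms@individualIds)
}

#' Per-cell squared prediction error
#'
#' SPE of cell n is the squared distance of its preprocessed event vector
#' from the model plane: the row sum of squared residuals. Cells lying inside
#' the loading span have SPE 0; adding any in-span vector to a cell leaves
#' its SPE unchanged.
#'
#' @param model an [ScaModel].
#' @param block preprocessed event matrix, or a residual matrix via
#'   `residuals =`.
#' @param residuals optional precomputed residual matrix.
#' @return nonnegative numeric vector of length N.
#' @export
computeSpe <- function(model, block, residuals = NULL) {
  if (is.null(residuals)) residuals <- projectBlock(model, block)$residuals
  rowSums(residuals^2)
}

#' Nearest-rank (type 1) empirical quantile
#'
#' @param x numeric vector.
#' @param p probability in (0, 1].
#' @return the `ceiling(p * length(x))`-th order statistic.
#' @export
nearestRankQuantile <- function(x, p) {
  stopifnot(length(x) >= 1, p > 0, p <= 1)
  sort(x)[ceiling(p * length(x))]
}

#' SPE control limits
#'
#' The per-individual limit at level `alpha` is the empirical (1 - alpha)
#' quantile of that individual's SPE values (nearest-rank by default, i.e.
#' the value exceeded by alpha of the cells); the pooled limit is the
#' arithmetic mean of the per-individual limits and serves as the cohort-wide
#' reference for flagging non-normal cells.
#'
#' @param spe named list of per-individual SPE vectors (see [computeSpe()]),
#'   or an [SpeProfile] to re-evaluate at a new alpha.
#' @param alpha tail fraction in (0, 1); default 0.05.
#' @param quantileType `"nearest_rank"` (default) or `"interpolated"`
#'   (type 7).
#' @return an [SpeProfile].
#' @export
speLimits <- function(spe, alpha = 0.05, quantileType = c("nearest_rank",
                                                          "interpolated")) {
  quantileType <- match.arg(quantileType)
  if (is(spe, "SpeProfile")) spe <- stats::setNames(spe@spe, spe@individualIds)
  if (!length(spe)) stop("at least one individual is required")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly inside (0, 1)")
  ids <- names(spe)
  if (is.null(ids)) ids <- paste0("ind", seq_along(spe))
  lims <- vapply(spe, function(v) {
    if (quantileType == "nearest_rank") nearestRankQuantile(v, 1 - alpha)
    else unname(stats::quantile(v, 1 - alpha, type = 7))
  }, numeric(1))
  new("SpeProfile", spe = unname(spe), individualIds = ids,
      perIndividualLimits = stats::setNames(lims, ids),
      pooledLimit = mean(lims), alpha = alpha)
}

#' SPE profile of the control individuals under a control model
#'
#' Convenience wrapper: projects the control blocks, computes per-cell SPE
#' and derives the per-individual and pooled control limits.
#'
#' @param model the control [ScaModel].
#' @param pms the [PreprocessedMultiSet] (controls are selected by group 0).
#' @param alpha tail fraction; default 0.05.
#' @return an [SpeProfile].
#' @export
controlSpeProfile <- function(model, pms, alpha = 0.05) {
  ctrl <- controls(pms)
  spe <- lapply(ctrl@blocks, function(b) computeSpe(model, b))
  speLimits(stats::setNames(spe, ctrl@individualIds), alpha = alpha)
}

#' Serialize / restore an ScaModel as JSON
#'
#' The full model (loadings, preprocessing recipe with fitted scale vectors,
#' explained variance, provenance) round-trips exactly through a plain-text
#' JSON file.
#'
#' @param model an [ScaModel].
#' @param path file path.
#' @return `loadScaModel` returns the restored [ScaModel].
#' @export
saveScaModel <- function(model, path) {
  p <- model@params
  obj <- list(
    loadings = model@loadings, markerNames = rownames(model@loadings),
    nComponents = model@nComponents,
    explainedVariance = as.list(model@explainedVariance),
    totalExplainedVariance = model@totalExplainedVariance,
    provenance = model@provenance,
    params = list(transform = p@transform, arcsinhCofactor = p@arcsinhCofactor,
                  logShift = p@logShift, scaling = p@scaling,
                  scaleValues = p@scaleValues, centers = p@centers,
                  scales = p@scales, markerNames = p@markerNames,
                  fitted = p@fitted))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

.namedBy <- function(v, nm) {
  v <- as.numeric(v)
  if (length(v) == length(nm)) names(v) <- as.character(nm)
  v
}

#' @rdname saveScaModel
#' @export
loadScaModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pp <- obj$params
  lsh <- pp$logShift
  if (is.null(lsh)) lsh <- NA_real_
  params <- new("PreprocessParams",
    transform = pp$transform, arcsinhCofactor = pp$arcsinhCofactor,
    logShift = lsh, scaling = pp$scaling,
    scaleValues = .namedBy(pp$scaleValues, pp$markerNames),
    centers = lapply(pp$centers, .namedBy, nm = pp$markerNames),
    scales = lapply(pp$scales, .namedBy, nm = pp$markerNames),
    markerNames = as.character(pp$markerNames), fitted = isTRUE(pp$fitted))
  P <- matrix(as.numeric(obj$loadings), ncol = obj$nComponents,
              byrow = FALSE)
  if (is.matrix(obj$loadings)) P <- obj$loadings
  rownames(P) <- obj$markerNames
  new("ScaModel", loadings = P, nComponents = as.integer(obj$nComponents),
      params = params,
      explainedVariance = unlist(obj$explainedVariance),
      totalExplainedVariance = obj$totalExplainedVariance,
      provenance = obj$provenance)
}
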