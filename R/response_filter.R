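#' @include AllClasses.R control_model.R density.R
NULL

#' Flag SPE outliers against a control limit
#'
#' A cell is flagged when its SPE strictly exceeds the limit; ties are not
#' flagged. Flagged cells are the ones the control model cannot explain
#' ('non-normal' marker expression).
#'
#' @param spe numeric vector of per-cell SPE values.
#' @param limit positive pooled control limit (see [speLimits()]).
#' @return logical vector.
#' @export
flagSpeOutliers <- function(spe, limit) {
  if (!is.numeric(limit) || length(limit) != 1L || limit <= 0)
    stop("limit must be a single positive number")
  spe > limit
}

#' Difference between Densities (DbD)
#'
#' Bin-wise difference `control - responder` of two normalized densities on
#' one grid. Positive bins mark score regions where a cell is more likely in
#' control individuals; negative bins mark responder-enriched regions. The
#' responder density must be built from its SPE-inlier cells only, since SPE
#' outliers are removed before this comparison and reintroduced afterwards.
#'
#' @param controlKde pooled control [DensityGrid] (normalized).
#' @param responderKde responder [DensityGrid] (normalized, same grid).
#' @return a signed (unnormalized) [DensityGrid].
#' @export
computeDbd <- function(controlKde, responderKde) {
  stopifnot(is(controlKde, "DensityGrid"), is(responderKde, "DensityGrid"))
  if (!isTRUE(all.equal(controlKde@x, responderKde@x)) ||
      !isTRUE(all.equal(controlKde@y, responderKde@y)))
    stop("both densities must live on an identical grid")
  if (!controlKde@normalized || !responderKde@normalized)
    stop("both densities must be normalized to unit probability")
  new("DensityGrid", x = controlKde@x, y = controlKde@y,
      values = controlKde@values - responderKde@values,
      bandwidths = c(NA_real_, NA_real_), normalized = FALSE,
      nSourceCells = responderKde@nSourceCells)
}

.nearestNodeIndex <- function(v, nodes) {
  d <- nodes[2] - nodes[1]
  pmin(pmax(round((v - nodes[1]) / d) + 1L, 1L), length(nodes))
}

#' Retain cells falling in responder-enriched DbD bins
#'
#' Each cell is assigned to its nearest grid node (cells outside the bounds
#' are clipped to the boundary); it is retained iff the DbD value at that
#' node is strictly negative. Cells in bins with DbD exactly zero (no cells
#' anywhere, or equal control and responder intensity) are eliminated.
#'
#' @param dbd signed [DensityGrid] from [computeDbd()].
#' @param scores N x 2 matrix of responder cell scores.
#' @return logical retention vector.
#' @export
applyDbdFilter <- function(dbd, scores) {
  stopifnot(is(dbd, "DensityGrid"))
  scores <- as.matrix(scores)
  i <- .nearestNodeIndex(scores[, 1], dbd@x)
  j <- .nearestNodeIndex(scores[, 2], dbd@y)
  dbd@values[cbind(i, j)] < 0
}

#' Run the elimination filter over all responder individuals
#'
#' Orchestrates the projection and elimination stages: responder blocks are
#' projected into the control model; cells whose SPE exceeds the pooled
#' control limit are flagged (and set aside); each responder's SPE-inlier
#' score density is estimated on the common control grid and subtracted from
#' the pooled control density; inlier cells in strictly negative DbD bins
#' are retained. The final retained set is the union of the SPE outliers and
#' the DbD-negative cells, with disjoint provenance flags.
#'
#' @param model the control [ScaModel].
#' @param pms [PreprocessedMultiSet] covering controls and responders
#'   (un-normalized blocks).
#' @param profile the control [SpeProfile] (pooled limit and alpha).
#' @param gridSize density grid size per dimension (default 256).
#' @param grid optional precomputed grid (see [scoreGrid()]); defaults to the
#'   pooled-control-score grid.
#' @return a [ResponseMask]; per-responder DbD grids and the pooled control
#'   density ride along for plotting and export.
#' @export
eclipseFilter <- function(model, pms, profile, gridSize = 256L, grid = NULL) {
  stopifnot(is(model, "ScaModel"), is(pms, "PreprocessedMultiSet"),
            is(profile, "SpeProfile"))
  if (model@nComponents < 2L)
    stop("the density filter operates in a 2-component score plane; ",
         "fit the control model with at least 2 components")
  ctrl <- controls(pms)
  resp <- responders(pms)
  if (nBlocks(resp) == 0L) stop("no responder blocks to filter")
  ctrlScores <- lapply(ctrl@blocks,
                       function(b) projectBlock(model, b)$scores[, 1:2])
  if (is.null(grid)) grid <- scoreGrid(ctrlScores, gridSize = gridSize)
  ctrlKdes <- lapply(ctrlScores, estimateKde, grid = grid)
  controlKde <- poolDensities(ctrlKdes)
  limit <- profile@pooledLimit

  flags <- list(); dbds <- list(); rows <- list()
  for (i in seq_len(nBlocks(resp))) {
    id <- resp@individualIds[i]
    proj <- projectBlock(model, resp@blocks[[i]])
    spe <- computeSpe(model, residuals = proj$residuals)
    speFlag <- flagSpeOutliers(spe, limit)
    sc2 <- proj$scores[, 1:2, drop = FALSE]
    dbdFlag <- logical(length(spe))
    if (any(!speFlag)) {
      respKde <- estimateKde(sc2[!speFlag, , drop = FALSE], grid = grid)
      dbd <- computeDbd(controlKde, respKde)
      dbdFlag[!speFlag] <- applyDbdFilter(dbd, sc2[!speFlag, , drop = FALSE])
      dbds[[id]] <- dbd
    } else {
      dbds[[id]] <- computeDbd(controlKde, controlKde)
    }
    retained <- speFlag | dbdFlag
    flags[[id]] <- data.frame(retainedSpe = speFlag, retainedDbd = dbdFlag,
                              retained = retained)
    rows[[id]] <- data.frame(
      individual_id = id, n_cells = length(spe), n_spe = sum(speFlag),
      n_dbd = sum(dbdFlag), n_retained = sum(retained),
      pct_spe = 100 * mean(speFlag), pct_retained = 100 * mean(retained))
  }
  new("ResponseMask", flags = flags,
      summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      dbd = dbds, controlDensity = controlKde)
}

#' Write the per-responder filter report as CSV
#'
#' @param mask a [ResponseMask].
#' @param path output CSV path.
#' @export
writeFilterReport <- function(mask, path) {
  utils::write.csv(mask@summary, path, row.names = FALSE)
  invisible(path)
}
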