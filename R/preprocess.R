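#' @include AllClasses.R
NULL

#' Create a pre-processing recipe
#'
#' The recipe fixes the variance-stabilizing transform, the (always
#' per-individual) centering and the scaling convention applied before any
#' component model is fitted. Fitting ([fitPreprocess()]) freezes the
#' per-variable scale vector so the identical recipe can be re-applied to new
#' blocks (projection of responders reuses the control scale).
#'
#' @param transform `"arcsinh"` (asinh(x / cofactor), cytometry standard for
#'   compensated data) or `"log"` (log10(x + shift)).
#' @param cofactor arcsinh cofactor; 5 is the usual choice for compensated
#'   fluorescence intensities.
#' @param logShift shift added before log10; `NA` selects
#'   `1 - min(0, min(data))` at fit time so nonpositive compensated values
#'   stay finite.
#' @param scaling `"over_controls"` (per-variable sd of the pooled centered
#'   control events; the control-model convention), `"per_individual"`
#'   (autoscaling within each block; the response-model convention) or
#'   `"over_all"` (pooled over every individual).
#' @return an unfitted [PreprocessParams].
#' @export
preprocessParams <- function(transform = c("arcsinh", "log"), cofactor = 5,
                             logShift = NA_real_,
                             scaling = c("over_controls", "per_individual",
                                         "over_all")) {
  new("PreprocessParams",
      transform = match.arg(transform),
      arcsinhCofactor = cofactor,
      logShift = logShift,
      scaling = match.arg(scaling),
      scaleValues = numeric(0),
      centers = list(), scales = list(),
      markerNames = character(0), fitted = FALSE)
}

# Population (1/n) standard deviation per column.
.colSdsPop <- function(x) {
  apply(x, 2L, function(v) sqrt(mean((v - mean(v))^2)))
}

.applyVst <- function(x, params) {
  if (params@transform == "arcsinh") asinh(x / params@arcsinhCofactor)
  else log10(x + params@logShift)
}

.invertVst <- function(z, transform, cofactor, logShift) {
  if (transform == "arcsinh") sinh(z) * cofactor else 10^z - logShift
}

#' Fit the pre-processing recipe and transform a multiset
#'
#' Each block is transformed, centered by its own per-variable mean (so
#' per-individual location offsets are removed), and every variable is
#' divided by the scale vector the recipe prescribes. For `over_controls`
#' scaling the scale is the per-variable standard deviation of the pooled,
#' per-individual-centered control events; it is frozen into the returned
#' params and reused verbatim when responder blocks are processed.
#'
#' @param ms a [CytoMultiSet] of raw event blocks.
#' @param params a [PreprocessParams] recipe (unfitted).
#' @return a [PreprocessedMultiSet] covering all blocks of `ms`, with the
#'   fitted recipe in its `params` slot.
#' @export
fitPreprocess <- function(ms, params = preprocessParams()) {
  stopifnot(is(ms, "CytoMultiSet"), is(params, "PreprocessParams"))
  if (params@scaling == "over_controls" && !any(ms@groups == 0L))
    stop("over_controls scaling requires at least one control block")
  if (params@transform == "log" && is.na(params@logShift)) {
    gmin <- min(vapply(ms@blocks, min, numeric(1)))
    params@logShift <- 1 - min(0, gmin)
  }
  transformed <- lapply(ms@blocks, .applyVst, params = params)
  centers <- lapply(transformed, colMeans)
  centered <- Map(function(b, ctr) sweep(b, 2L, ctr, "-"), transformed, centers)

  refIdx <- switch(params@scaling,
    over_controls = which(ms@groups == 0L),
    over_all = seq_along(centered),
    per_individual = integer(0))
  if (params@scaling %in% c("over_controls", "over_all")) {
    pooled <- do.call(rbind, centered[refIdx])
    scaleVec <- .colSdsPop(pooled)
    bad <- which(scaleVec <= .Machine$double.eps)
    if (length(bad))
      stop("zero variance in reference events for marker(s): ",
           paste(ms@markerNames[bad], collapse = ", "))
    params@scaleValues <- scaleVec
    scaled <- lapply(centered, function(b) sweep(b, 2L, scaleVec, "/"))
    params@scales <- list()
  } else {
    perScales <- lapply(centered, .colSdsPop)
    for (i in seq_along(perScales)) {
      bad <- which(perScales[[i]] <= .Machine$double.eps)
      if (length(bad))
        stop("zero variance within individual '", ms@individualIds[i],
             "' for marker(s): ", paste(ms@markerNames[bad], collapse = ", "))
    }
    scaled <- Map(function(b, s) sweep(b, 2L, s, "/"), centered, perScales)
    params@scales <- stats::setNames(perScales, ms@individualIds)
  }
  params@centers <- stats::setNames(centers, ms@individualIds)
  params@markerNames <- ms@markerNames
  params@fitted <- TRUE
  new("PreprocessedMultiSet",
      blocks = scaled, individualIds = ms@individualIds, groups = ms@groups,
      markerNames = ms@markerNames, params = params, normalized = FALSE)
}

#' Apply a fitted recipe to a new block
#'
#' The transform and the frozen scale vector are those of the fit stage;
#' centering always uses the new block's own per-variable mean (centering is
#' per individual by definition, so adding a constant offset to all events of
#' an individual leaves its preprocessed block unchanged).
#'
#' @param params a fitted [PreprocessParams].
#' @param table an `EventTable` or a raw event matrix with the fitted panel.
#' @return the preprocessed numeric matrix.
#' @export
applyPreprocess <- function(params, table) {
  stopifnot(is(params, "PreprocessParams"))
  if (!params@fitted) stop("params must be fitted first (see fitPreprocess)")
  mat <- if (inherits(table, "EventTable")) table$events else as.matrix(table)
  if (!identical(colnames(mat), params@markerNames)) {
    if (!setequal(colnames(mat), params@markerNames))
      stop("marker panel mismatch; fitted panel: ",
           paste(params@markerNames, collapse = ", "))
    mat <- mat[, params@markerNames, drop = FALSE]
  }
  z <- .applyVst(mat, params)
  z <- sweep(z, 2L, colMeans(z), "-")
  scl <- if (params@scaling == "per_individual") .colSdsPop(z)
         else params@scaleValues
  if (any(scl <= .Machine$double.eps))
    stop("zero variance in block for marker(s): ",
         paste(params@markerNames[scl <= .Machine$double.eps], collapse = ", "))
  sweep(z, 2L, scl, "/")
}

#' Equalize block weights before the simultaneous decomposition
#'
#' Multiplies each block by 1/sqrt(N_i), so every individual contributes the
#' same total sum of squares to the stacked decomposition regardless of how
#' many cells were measured. Scores are always computed afterwards on the
#' un-normalized blocks.
#'
#' @param pms a [PreprocessedMultiSet].
#' @return the block-normalized [PreprocessedMultiSet] (`normalized = TRUE`).
#' @export
blockNormalize <- function(pms) {
  stopifnot(is(pms, "PreprocessedMultiSet"))
  if (pms@normalized) return(pms)
  pms@blocks <- lapply(pms@blocks, function(b) b / sqrt(nrow(b)))
  pms@normalized <- TRUE
  pms
}
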