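#' @include AllClasses.R
NULL

#' Accessors for CytoMultiSet and derived objects
#'
#' @param x a [CytoMultiSet] (or subclass).
#' @param ... unused.
#' @return `nBlocks`: number of individuals; `blockSizes`: named integer event
#'   counts; `eventBlocks`: list of event matrices; `markerNames`: the shared
#'   marker panel; `individualIds` / `groupLabels`: per-block metadata.
#' @name CytoMultiSet-accessors
#' @aliases nBlocks blockSizes eventBlocks markerNames individualIds groupLabels
NULL

#' @rdname CytoMultiSet-accessors
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))
#' @rdname CytoMultiSet-accessors
#' @export
setMethod("nBlocks", "CytoMultiSet", function(x) length(x@blocks))

#' @rdname CytoMultiSet-accessors
#' @export
setGeneric("blockSizes", function(x) standardGeneric("blockSizes"))
#' @rdname CytoMultiSet-accessors
#' @export
setMethod("blockSizes", "CytoMultiSet", function(x) {
  stats::setNames(vapply(x@blocks, nrow, integer(1)), x@individualIds)
})

#' @rdname CytoMultiSet-accessors
#' @export
setGeneric("eventBlocks", function(x) standardGeneric("eventBlocks"))
#' @rdname CytoMultiSet-accessors
#' @export
setMethod("eventBlocks", "CytoMultiSet", function(x) {
  stats::setNames(x@blocks, x@individualIds)
})

#' @rdname CytoMultiSet-accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
#' @rdname CytoMultiSet-accessors
#' @export
setMethod("markerNames", "CytoMultiSet", function(x) x@markerNames)

#' @rdname CytoMultiSet-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname CytoMultiSet-accessors
#' @export
setMethod("individualIds", "CytoMultiSet", function(x) x@individualIds)

#' @rdname CytoMultiSet-accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname CytoMultiSet-accessors
#' @export
setMethod("groupLabels", "CytoMultiSet", function(x) {
  stats::setNames(x@groups, x@individualIds)
})

#' Subset a multiset by block
#'
#' `ms[i]` keeps the selected blocks (logical, integer or id-character index)
#' with their metadata; `controls(ms)` and `responders(ms)` select by group
#' label.
#'
#' @param x a [CytoMultiSet] or [PreprocessedMultiSet].
#' @param i block index.
#' @param j,drop unused.
#' @param ... unused.
#' @export
setMethod("[", "CytoMultiSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@individualIds)
  if (anyNA(i)) stop("unknown individual id in subset")
  out <- x
  out@blocks <- x@blocks[i]
  out@individualIds <- x@individualIds[i]
  out@groups <- x@groups[i]
  validObject(out)
  out
})

#' @rdname sub-CytoMultiSet-ANY-ANY-ANY-method
#' @export
controls <- function(x) x[x@groups == 0L]

#' @rdname sub-CytoMultiSet-ANY-ANY-ANY-method
#' @export
responders <- function(x) x[x@groups >= 1L]

#' Accessors for fitted models and profiles
#'
#' @param x a fitted object.
#' @return `loadings`: the J x R loading matrix; `nComponents`: R;
#'   `explainedVariance`: per-individual fractions; `speValues`: per-cell SPE
#'   list; `speLimit`: pooled control limit; `clusterLabels`: stratification
#'   labels.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))
#' @rdname model-accessors
#' @export
setMethod("loadings", "ScaModel", function(x) x@loadings)

#' @rdname model-accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname model-accessors
#' @export
setMethod("nComponents", "ScaModel", function(x) x@nComponents)

#' @rdname model-accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
#' @rdname model-accessors
#' @export
setMethod("explainedVariance", "ScaModel", function(x) x@explainedVariance)

#' @rdname model-accessors
#' @export
setGeneric("totalExplainedVariance",
           function(x) standardGeneric("totalExplainedVariance"))
#' @rdname model-accessors
#' @export
setMethod("totalExplainedVariance", "ScaModel",
          function(x) x@totalExplainedVariance)

#' @rdname model-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname model-accessors
#' @export
setMethod("scores", "ScoreSet", function(x) {
  stats::setNames(x@scores, x@individualIds)
})
#' @rdname model-accessors
#' @export
setMethod("scores", "EclipseResult", function(x) scores(x@scores))

#' @rdname model-accessors
#' @export
setGeneric("residuals2", function(x) standardGeneric("residuals2"))
#' @rdname model-accessors
#' @export
setMethod("residuals2", "ScoreSet", function(x) {
  stats::setNames(x@residuals, x@individualIds)
})

#' @rdname model-accessors
#' @export
setGeneric("speValues", function(x) standardGeneric("speValues"))
#' @rdname model-accessors
#' @export
setMethod("speValues", "SpeProfile", function(x) {
  stats::setNames(x@spe, x@individualIds)
})

#' @rdname model-accessors
#' @export
setGeneric("speLimit", function(x) standardGeneric("speLimit"))
#' @rdname model-accessors
#' @export
setMethod("speLimit", "SpeProfile", function(x) x@pooledLimit)

#' @rdname model-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname model-accessors
#' @export
setMethod("clusterLabels", "StratificationResult", function(x) x@labels)

#' @rdname model-accessors
#' @export
setGeneric("retentionSummary", function(x) standardGeneric("retentionSummary"))
#' @rdname model-accessors
#' @export
setMethod("retentionSummary", "ResponseMask", function(x) x@summary)

#' @rdname model-accessors
#' @export
setGeneric("retentionFlags", function(x) standardGeneric("retentionFlags"))
#' @rdname model-accessors
#' @export
setMethod("retentionFlags", "ResponseMask", function(x) x@flags)

setMethod("show", "CytoMultiSet", function(object) {
  g <- object@groups
  cat(sprintf("%s with %d blocks (%d control, %d responder), %d markers\n",
              class(object), length(object@blocks), sum(g == 0L),
              sum(g >= 1L), length(object@markerNames)))
  cat("  markers:", paste(object@markerNames, collapse = ", "), "\n")
  cat("  events per block:",
      paste(sprintf("%s=%d", object@individualIds,
                    vapply(object@blocks, nrow, integer(1))),
            collapse = ", "), "\n")
})

setMethod("show", "ScaModel", function(object) {
  cat(sprintf("ScaModel (%s): %d markers, %d components, total EV %.1f%%\n",
              object@provenance, nrow(object@loadings), object@nComponents,
              100 * object@totalExplainedVariance))
})

setMethod("show", "SpeProfile", function(object) {
  cat(sprintf("SpeProfile over %d individuals, alpha = %.3f, pooled limit %.4g\n",
              length(object@spe), object@alpha, object@pooledLimit))
})

setMethod("show", "DensityGrid", function(object) {
  cat(sprintf("DensityGrid %d x %d, %s, bandwidths (%s), from %d cells\n",
              length(object@x), length(object@y),
              if (object@normalized) "normalized" else "unnormalized",
              paste(signif(object@bandwidths, 3), collapse = ", "),
              object@nSourceCells))
})

setMethod("show", "ResponseMask", function(object) {
  cat("ResponseMask\n")
  print(object@summary, row.names = FALSE)
})

setMethod("show", "EclipseResult", function(object) {
  cat(sprintf("EclipseResult: %d retained cells from %d responders\n",
              nrow(object@provenanceTable), nBlocks(object@retained)))
  show(object@model)
})

setMethod("show", "StratificationResult", function(object) {
  cat(sprintf("StratificationResult: %d responders in %d clusters\n",
              length(object@labels), object@k))
  print(object@labels)
})

setMethod("show", "StabilityProfile", function(object) {
  med <- vapply(object@angles, stats::median, numeric(1))
  cat(sprintf("StabilityProfile (%d bootstrap replicates)\n", object@nBoot))
  for (r in seq_along(object@angles))
    cat(sprintf("  R = %d: median angle %.3f rad\n", r, med[r]))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d control + %d responder individuals, %d cells each, %d markers, %d spiked populations\n",
    object@nControl, object@nResponder, object@cellsPerIndividual,
    length(object@markerNames), length(object@responsePopulations)))
})
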