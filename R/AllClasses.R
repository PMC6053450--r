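#' @import methods
NULL

#' CytoMultiSet: per-individual flow cytometry event blocks
#'
#' Ordered collection of single-cell event matrices (rows = cells/events,
#' columns = markers), one block per individual, sharing one marker panel.
#' Group labels distinguish control individuals (group 0) from responder
#' individuals (group >= 1).
#'
#' @slot blocks list of numeric matrices, one per individual; each of
#'   dimension N_i x J with identical column names (the marker panel).
#' @slot individualIds character vector of unique individual identifiers.
#' @slot groups integer vector; 0 for control, >= 1 for responder groups.
#' @slot markerNames character vector, the shared marker panel in order.
#'
#' @export
setClass("CytoMultiSet",
  representation(
    blocks = "list",
    individualIds = "character",
    groups = "integer",
    markerNames = "character"
  )
)

setValidity("CytoMultiSet", function(object) {
  msg <- character()
  nb <- length(object@blocks)
  if (nb == 0L) msg <- c(msg, "at least one block is required")
  if (length(object@individualIds) != nb || length(object@groups) != nb)
    msg <- c(msg, "individualIds and groups must match the number of blocks")
  if (anyDuplicated(object@individualIds))
    msg <- c(msg, "individual ids must be unique")
  if (length(object@markerNames) < 2L)
    msg <- c(msg, "at least two markers are required")
  if (anyDuplicated(object@markerNames))
    msg <- c(msg, "marker names must be unique")
  if (any(object@groups < 0L)) msg <- c(msg, "group labels must be >= 0")
  for (b in object@blocks) {
    if (!is.matrix(b) || !is.numeric(b)) {
      msg <- c(msg, "all blocks must be numeric matrices"); break
    }
    if (nrow(b) < 1L) { msg <- c(msg, "each block needs >= 1 event"); break }
    if (anyNA(b)) { msg <- c(msg, "blocks must not contain missing values"); break }
    if (!identical(colnames(b), object@markerNames)) {
      msg <- c(msg, "all blocks must share the marker panel in order"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' PreprocessParams: frozen pre-processing recipe
#'
#' Records the variance-stabilizing transform, the centering convention
#' (always per individual) and the scaling convention, together with the
#' fitted per-variable scale vector so the identical recipe can be re-applied
#' to new blocks.
#'
#' @slot transform `"arcsinh"` or `"log"`.
#' @slot arcsinhCofactor positive divisor applied before asinh (cytometry
#'   convention; 5 for compensated fluorescence data).
#' @slot logShift nonnegative shift added before log10 to avoid nonpositive
#'   arguments; `NA` until fitted when the default (data-driven) is used.
#' @slot scaling `"over_controls"`, `"per_individual"` or `"over_all"`.
#' @slot scaleValues fitted per-variable scale (positive), length J; empty
#'   until fitted. For `per_individual` scaling this slot stays empty and
#'   scales live in `centers`' sibling `scales`.
#' @slot centers list of per-block centering vectors recorded at fit time.
#' @slot scales list of per-block scale vectors (per_individual scaling only).
#' @slot markerNames marker panel the recipe was fitted on.
#' @slot fitted logical.
#' @export
setClass("PreprocessParams",
  representation(
    transform = "character",
    arcsinhCofactor = "numeric",
    logShift = "numeric",
    scaling = "character",
    scaleValues = "numeric",
    centers = "list",
    scales = "list",
    markerNames = "character",
    fitted = "logical"
  )
)

setValidity("PreprocessParams", function(object) {
  msg <- character()
  if (!object@transform %in% c("arcsinh", "log"))
    msg <- c(msg, "transform must be 'arcsinh' or 'log'")
  if (!object@scaling %in% c("over_controls", "per_individual", "over_all"))
    msg <- c(msg, "unknown scaling convention")
  if (object@arcsinhCofactor <= 0)
    msg <- c(msg, "arcsinh cofactor must be positive")
  if (length(object@scaleValues) && any(object@scaleValues <= 0))
    msg <- c(msg, "scale values must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' PreprocessedMultiSet: transformed, centered, scaled event blocks
#'
#' A [CytoMultiSet] after applying a fitted [PreprocessParams] recipe; the
#' `normalized` flag records whether the per-block 1/sqrt(N_i) weighting
#' (which equalizes each individual's contribution to the decomposition) has
#' been applied.
#'
#' @slot params the fitted [PreprocessParams].
#' @slot normalized logical, whether block normalization was applied.
#' @export
setClass("PreprocessedMultiSet",
  contains = "CytoMultiSet",
  representation(params = "PreprocessParams", normalized = "logical")
)

#' ScaModel: simultaneous component (multiset PCA) model
#'
#' Loadings common to all individuals of a multiset, with explained-variance
#' bookkeeping. Fitted on block-normalized data; scores are computed on the
#' un-normalized blocks.
#'
#' @slot loadings J x R matrix with orthonormal columns; per component the
#'   largest-magnitude entry is positive (sign convention).
#' @slot nComponents integer R.
#' @slot params the [PreprocessParams] the training data used.
#' @slot explainedVariance named numeric, per-individual explained-variance
#'   fraction (1 - |E_i|^2 / |X_i|^2).
#' @slot totalExplainedVariance numeric scalar over all training cells.
#' @slot provenance `"control"`, `"eclipse_general"` or `"eclipse_partial"`.
#' @export
setClass("ScaModel",
  representation(
    loadings = "matrix",
    nComponents = "integer",
    params = "PreprocessParams",
    explainedVariance = "numeric",
    totalExplainedVariance = "numeric",
    provenance = "character"
  )
)

setValidity("ScaModel", function(object) {
  msg <- character()
  P <- object@loadings
  if (ncol(P) != object@nComponents)
    msg <- c(msg, "loadings must have nComponents columns")
  if (ncol(P) > nrow(P)) msg <- c(msg, "more components than variables")
  orth <- crossprod(P)
  if (max(abs(orth - diag(ncol(P)))) > 1e-8)
    msg <- c(msg, "loadings columns must be orthonormal")
  if (!object@provenance %in% c("control", "eclipse_general", "eclipse_partial"))
    msg <- c(msg, "unknown provenance")
  if (length(msg)) msg else TRUE
})

#' ScoreSet: per-block scores and residuals under an ScaModel
#'
#' @slot scores list of N_i x R matrices (component scores per cell).
#' @slot residuals list of N_i x J matrices.
#' @slot individualIds character, aligned with the score list.
#' @export
setClass("ScoreSet",
  representation(
    scores = "list",
    residuals = "list",
    individualIds = "character"
  )
)

#' SpeProfile: squared prediction error statistics and control limits
#'
#' Per-cell SPE (row sums of squared residuals) per individual, the
#' per-individual empirical (1 - alpha) limits (nearest-rank), and the pooled
#' limit defined as the arithmetic mean of the per-individual limits.
#'
#' @slot spe list of nonnegative numeric vectors, one per individual.
#' @slot individualIds character.
#' @slot perIndividualLimits named numeric.
#' @slot pooledLimit numeric scalar.
#' @slot alpha numeric in (0, 1).
#' @export
setClass("SpeProfile",
  representation(
    spe = "list",
    individualIds = "character",
    perIndividualLimits = "numeric",
    pooledLimit = "numeric",
    alpha = "numeric"
  )
)

setValidity("SpeProfile", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie strictly inside (0, 1)")
  if (any(vapply(object@spe, function(v) any(v < 0), logical(1))))
    msg <- c(msg, "SPE values must be nonnegative")
  if (length(object@perIndividualLimits) &&
      abs(object@pooledLimit - mean(object@perIndividualLimits)) > 1e-8)
    msg <- c(msg, "pooled limit must be the mean of per-individual limits")
  if (length(msg)) msg else TRUE
})

#' DensityGrid: 2-D density (or density-difference) on a rectangular grid
#'
#' @slot x,y grid node coordinates (increasing, equally spaced).
#' @slot values length(x) x length(y) matrix; nonnegative for densities,
#'   signed for differences between densities.
#' @slot bandwidths per-dimension kernel bandwidths (NA for differences).
#' @slot normalized logical; TRUE when values integrate to one.
#' @slot nSourceCells number of cells the estimate was built from.
#' @export
setClass("DensityGrid",
  representation(
    x = "numeric",
    y = "numeric",
    values = "matrix",
    bandwidths = "numeric",
    normalized = "logical",
    nSourceCells = "integer"
  )
)

setValidity("DensityGrid", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@x) ||
      ncol(object@values) != length(object@y))
    msg <- c(msg, "values must be length(x) x length(y)")
  if (length(object@x) > 1 && any(diff(object@x) <= 0))
    msg <- c(msg, "x must be strictly increasing")
  if (length(object@y) > 1 && any(diff(object@y) <= 0))
    msg <- c(msg, "y must be strictly increasing")
  if (isTRUE(object@normalized)) {
    if (min(object@values) < -1e-12)
      msg <- c(msg, "a normalized density cannot be negative")
    area <- .gridCellArea(object)
    tot <- sum(object@values) * area
    if (abs(tot - 1) > 1e-6)
      msg <- c(msg, sprintf("normalized density must integrate to 1 (got %.8f)", tot))
  }
  if (length(msg)) msg else TRUE
})

#' ResponseMask: per-cell retention flags for responder individuals
#'
#' For each responder, `retainedSpe` marks cells whose projection SPE exceeds
#' the pooled control limit; `retainedDbd` marks SPE-inlier cells falling in
#' strictly negative Difference-between-Densities bins. The final mask is
#' their union; the two provenance flags are disjoint by construction.
#'
#' @slot flags named list (per responder) of data.frames with logical columns
#'   `retainedSpe`, `retainedDbd`, `retained`.
#' @slot summary data.frame with one row per responder: individual id, cell
#'   counts and retention percentages.
#' @slot dbd named list of signed [DensityGrid] objects (the per-responder
#'   Difference between Densities), kept for plotting and export.
#' @slot controlDensity the pooled control [DensityGrid] the differences were
#'   taken against.
#' @export
setClass("ResponseMask",
  representation(flags = "list", summary = "data.frame",
                 dbd = "list", controlDensity = "ANY")
)

#' EclipseResult: response-specific component model over retained cells
#'
#' @slot model [ScaModel] with provenance `eclipse_general` / `eclipse_partial`.
#' @slot scores [ScoreSet] over retained cells per responder.
#' @slot retained [CytoMultiSet] of retained raw events.
#' @slot provenanceTable data.frame (individual_id, event_index) tracing every
#'   retained cell to its original event.
#' @export
setClass("EclipseResult",
  representation(
    model = "ScaModel",
    scores = "ScoreSet",
    retained = "CytoMultiSet",
    provenanceTable = "data.frame"
  )
)

#' StratificationResult: responder subgroups by response-cell density
#'
#' @slot densities matrix, one row per responder: unit-mass binned density of
#'   that responder's cells in the response component space.
#' @slot distances `dist` object of pairwise distances between responders.
#' @slot tree `hclust` average-linkage tree.
#' @slot labels named integer cluster labels at the requested cut.
#' @slot k integer number of clusters.
#' @slot partialModels list of [EclipseResult], one per cluster (possibly
#'   empty when partial models were not requested).
#' @export
setClass("StratificationResult",
  representation(
    densities = "matrix",
    distances = "ANY",
    tree = "ANY",
    labels = "integer",
    k = "integer",
    partialModels = "list"
  )
)

#' StabilityProfile: bootstrap stability of loading subspaces
#'
#' For each candidate component number R, the largest principal angles
#' (radians) between the full-data loadings and each bootstrap replicate's
#' loadings.
#'
#' @slot angles list (per R) of numeric vectors of angles in [0, pi/2].
#' @slot nBoot integer.
#' @slot seed integer.
#' @export
setClass("StabilityProfile",
  representation(angles = "list", nBoot = "integer", seed = "integer")
)

#' CohortSpec: generative description of a synthetic cytometry cohort
#'
#' Populations are specified in transformed (arcsinh or log) space, where the
#' component models operate, and back-transformed to raw-intensity-like values
#' on output.
#'
#' @slot nControl,nResponder integer counts of individuals.
#' @slot cellsPerIndividual integer (events per individual).
#' @slot markerNames character of length J.
#' @slot controlPopulations list of populations; each a list with `mean`
#'   (J-vector), `cov` (J x J positive-definite), `weight`.
#' @slot individualShiftSd nonnegative; sd of the per-individual mean offset.
#' @slot responsePopulations list of spiked populations; each a list with
#'   `mean`, `cov`, `abundance`, `phenotype` (which responder phenotype
#'   carries it).
#' @slot phenotypeOf integer vector (length nResponder) assigning each
#'   responder a phenotype id; 0 means no spiked populations.
#' @slot transform,arcsinhCofactor,logShift back-transform applied on output.
#' @slot seed integer default seed.
#' @export
setClass("CohortSpec",
  representation(
    nControl = "integer",
    nResponder = "integer",
    cellsPerIndividual = "integer",
    markerNames = "character",
    controlPopulations = "list",
    individualShiftSd = "numeric",
    responsePopulations = "list",
    phenotypeOf = "integer",
    transform = "character",
    arcsinhCofactor = "numeric",
    logShift = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  w <- vapply(object@controlPopulations, function(p) p$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8)
    msg <- c(msg, "control population weights must sum to 1")
  ab <- vapply(object@responsePopulations, function(p) p$abundance, numeric(1))
  if (length(ab) && (any(ab < 0) || any(ab >= 1)))
    msg <- c(msg, "spike abundances must lie in [0, 1)")
  if (length(object@phenotypeOf) != object@nResponder)
    msg <- c(msg, "phenotypeOf must have one entry per responder")
  for (p in c(object@controlPopulations, object@responsePopulations)) {
    ev <- eigen(p$cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) { msg <- c(msg, "population covariances must be positive-definite"); break }
  }
  if (length(msg)) msg else TRUE
})
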