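#' @include AllClasses.R preprocess.R control_model.R response_filter.R
NULL

#' Extract retained raw events as a new multiset
#'
#' Selects, per responder, the raw events the elimination filter retained,
#' preserving the multiset structure and recording each cell's original event
#' index.
#'
#' @param ms the raw [CytoMultiSet] the filter was run on.
#' @param mask the [ResponseMask].
#' @return list with `multiset` (a [CytoMultiSet] of retained cells) and
#'   `provenance` (data.frame individual_id, event_index). Responders with no
#'   retained cells are dropped with a warning.
#' @export
retainedMultiSet <- function(ms, mask) {
  stopifnot(is(ms, "CytoMultiSet"), is(mask, "ResponseMask"))
  ids <- names(mask@flags)
  blocks <- list(); keepIds <- character(); groups <- integer()
  prov <- list()
  for (id in ids) {
    keep <- which(mask@flags[[id]]$retained)
    if (!length(keep)) {
      warning("responder '", id, "' has no retained cells and is dropped")
      next
    }
    bi <- match(id, ms@individualIds)
    if (is.na(bi)) stop("mask references unknown individual '", id, "'")
    blocks[[length(blocks) + 1L]] <- ms@blocks[[bi]][keep, , drop = FALSE]
    keepIds <- c(keepIds, id)
    groups <- c(groups, ms@groups[bi])
    prov[[length(prov) + 1L]] <- data.frame(individual_id = id,
                                            event_index = keep)
  }
  if (!length(blocks)) stop("no retained cells in any responder")
  list(
    multiset = new("CytoMultiSet", blocks = blocks, individualIds = keepIds,
                   groups = groups, markerNames = ms@markerNames),
    provenance = do.call(rbind, prov))
}

#' Fit the response-specific (ECLIPSE) component model
#'
#' The retained raw events are re-processed from scratch with the transform
#' of the original recipe but response-side centering/scaling: per-individual
#' autoscaling by default (each responder's own mean and sd), or pooled
#' scaling over all retained individuals. The re-processed multiset is block
#' normalized and decomposed simultaneously; the resulting loadings describe
#' marker co-expression of response-specific cells only.
#'
#' If any responder has a zero-variance marker among its retained cells,
#' per-individual scaling falls back to pooled (`over_all`) scaling with a
#' warning.
#'
#' @param ms raw [CytoMultiSet] (all individuals) when `mask` is supplied,
#'   or a multiset of already-retained responder cells.
#' @param mask optional [ResponseMask] selecting the retained cells.
#' @param params [PreprocessParams] carrying the transform settings of the
#'   original recipe (scaling is overridden by `scaling`).
#' @param nComponents number of response components R_E.
#' @param scaling `"per_individual"` (default) or `"over_all"`.
#' @param provenance model provenance tag.
#' @return an [EclipseResult].
#' @export
buildEclipseModel <- function(ms, mask = NULL, params = preprocessParams(),
                              nComponents = 2L,
                              scaling = c("per_individual", "over_all"),
                              provenance = c("eclipse_general",
                                             "eclipse_partial")) {
  scaling <- match.arg(scaling)
  provenance <- match.arg(provenance)
  if (!is.null(mask)) {
    rs <- retainedMultiSet(ms, mask)
    retained <- rs$multiset
    provTab <- rs$provenance
  } else {
    retained <- ms
    provTab <- do.call(rbind, Map(function(id, n)
      data.frame(individual_id = id, event_index = seq_len(n)),
      ms@individualIds, vapply(ms@blocks, nrow, integer(1))))
    rownames(provTab) <- NULL
  }
  p5 <- preprocessParams(transform = params@transform,
                         cofactor = params@arcsinhCofactor,
                         logShift = params@logShift,
                         scaling = scaling)
  pms <- tryCatch(fitPreprocess(retained, p5), error = function(e) {
    if (scaling == "per_individual" &&
        grepl("zero variance within individual", conditionMessage(e))) {
      warning("zero-variance marker within a responder's retained cells; ",
              "falling back to over_all scaling")
      p5@scaling <- "over_all"
      fitPreprocess(retained, p5)
    } else stop(e)
  })
  model <- fitSca(pms, nComponents, provenance = provenance)
  new("EclipseResult", model = model, scores = projectMultiSet(model, pms),
      retained = retained, provenanceTable = provTab)
}

#' Per-responder binned score densities in the response component space
#'
#' Cells of each responder are binned onto a common grid over the pooled
#' first-two response-component scores (plain histogram, nearest node);
#' each responder's bin vector is normalized to unit mass and flattened.
#' Optionally a kernel estimate replaces the raw histogram.
#'
#' @param result an [EclipseResult].
#' @param gridSize bins per dimension (default 64).
#' @param method `"histogram"` (default) or `"kde"`.
#' @return matrix, one row per responder (unit row sums).
#' @export
binnedDensities <- function(result, gridSize = 64L,
                            method = c("histogram", "kde")) {
  method <- match.arg(method)
  stopifnot(is(result, "EclipseResult"))
  sc <- lapply(result@scores@scores, function(s) s[, 1:2, drop = FALSE])
  pooled <- do.call(rbind, sc)
  span <- function(v) {
    r <- range(v)
    if (diff(r) <= 0) r <- r + c(-0.5, 0.5)  # degenerate: all cells equal
    seq(r[1], r[2], length.out = gridSize)
  }
  gx <- span(pooled[, 1])
  gy <- span(pooled[, 2])
  out <- t(vapply(sc, function(s) {
    if (method == "histogram") {
      i <- .nearestNodeIndex(s[, 1], gx)
      j <- .nearestNodeIndex(s[, 2], gy)
      W <- matrix(0, gridSize, gridSize)
      tab <- table(factor(i + gridSize * (j - 1L),
                          levels = seq_len(gridSize^2)))
      W[] <- as.numeric(tab)
    } else {
      g <- estimateKde(s, grid = list(x = gx, y = gy, bandwidths = NULL))
      W <- g@values
    }
    as.numeric(W / sum(W))
  }, numeric(gridSize^2)))
  rownames(out) <- result@scores@individualIds
  out
}

.jensenShannonDist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  kl <- function(p, q) {
    i <- p > 0
    sum(p[i] * log(p[i] / q[i]))
  }
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    mid <- (m[a, ] + m[b, ]) / 2
    d[a, b] <- d[b, a] <- sqrt(0.5 * kl(m[a, ], mid) + 0.5 * kl(m[b, ], mid))
  }
  stats::as.dist(d)
}

#' Stratify responders by their response-cell density distributions
#'
#' Pairwise distances between the responders' binned density vectors are
#' clustered with average-linkage hierarchical clustering; labels are
#' obtained by cutting the tree at `k` clusters (chosen by the analyst from
#' the dendrogram).
#'
#' @param x an [EclipseResult] or a density matrix from [binnedDensities()].
#' @param k number of clusters (2 <= k <= number of responders).
#' @param metric `"euclidean"` (default) or `"jensen_shannon"`.
#' @param gridSize,method forwarded to [binnedDensities()] when `x` is an
#'   [EclipseResult].
#' @return a [StratificationResult] (without partial models; see
#'   [fitPartialModels()]).
#' @export
stratify <- function(x, k, metric = c("euclidean", "jensen_shannon"),
                     gridSize = 64L, method = "histogram") {
  metric <- match.arg(metric)
  dens <- if (is(x, "EclipseResult"))
    binnedDensities(x, gridSize = gridSize, method = method) else as.matrix(x)
  if (nrow(dens) < 2L) stop("at least two responders are required")
  k <- as.integer(k)
  if (k > nrow(dens)) stop("k exceeds the number of responders")
  if (k < 1L) stop("k must be >= 1")
  d <- if (metric == "euclidean") stats::dist(dens)
       else .jensenShannonDist(dens)
  tree <- stats::hclust(d, method = "average")
  labels <- stats::cutree(tree, k = k)
  new("StratificationResult", densities = dens, distances = d, tree = tree,
      labels = labels, k = k, partialModels = list())
}

#' Fit cluster-specific partial response models
#'
#' Re-runs the response-model pipeline independently on each cluster's
#' retained cells (its own scaling, its own loadings).
#'
#' @param result the general [EclipseResult].
#' @param labels named cluster labels (e.g. [clusterLabels()] of a
#'   [StratificationResult]), or the [StratificationResult] itself.
#' @param nComponents components per partial model; default the general
#'   model's.
#' @param scaling response-side scaling, as in [buildEclipseModel()].
#' @return list of [EclipseResult], one per cluster (named by label).
#' @export
fitPartialModels <- function(result, labels, nComponents = NULL,
                             scaling = c("per_individual", "over_all")) {
  scaling <- match.arg(scaling)
  stopifnot(is(result, "EclipseResult"))
  if (is(labels, "StratificationResult")) labels <- labels@labels
  if (is.null(nComponents)) nComponents <- result@model@nComponents
  ids <- result@retained@individualIds
  if (!all(ids %in% names(labels)))
    stop("labels must cover every retained responder")
  out <- list()
  for (cl in sort(unique(labels[ids]))) {
    members <- ids[labels[ids] == cl]
    sub <- result@retained[members]
    out[[as.character(cl)]] <- buildEclipseModel(
      sub, mask = NULL, params = result@model@params,
      nComponents = nComponents, scaling = scaling,
      provenance = "eclipse_partial")
  }
  out
}

#' Write the retained-cell table (id, original index, response scores)
#'
#' @param result an [EclipseResult].
#' @param path CSV path.
#' @param labels optional cluster labels to append.
#' @export
writeRetainedCells <- function(result, path, labels = NULL) {
  tab <- result@provenanceTable
  sc <- do.call(rbind, result@scores@scores)
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  tab <- cbind(tab, as.data.frame(sc))
  if (!is.null(labels)) {
    if (is(labels, "StratificationResult")) labels <- labels@labels
    tab$cluster <- labels[tab$individual_id]
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
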