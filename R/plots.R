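#' @include AllClasses.R
NULL

.gridToDf <- function(g) {
  data.frame(x = rep(g@x, times = length(g@y)),
             y = rep(g@y, each = length(g@x)),
             value = as.vector(g@values))
}

.loadingArrows <- function(model, scale) {
  P <- model@loadings[, 1:2, drop = FALSE]
  data.frame(marker = rownames(P),
             xend = P[, 1] * scale, yend = P[, 2] * scale)
}

.axisLabels <- function(model) {
  ev <- model@explainedVariance
  tot <- 100 * model@totalExplainedVariance
  sprintf("PC%d (model total EV %.1f%%)", 1:2, tot)
}

#' Biplot of a component model: score density plus loading vectors
#'
#' Scores (or a precomputed density) are drawn in the first two components,
#' with the marker loadings superimposed as labelled vectors: vector length
#' is the marker's contribution to cell-to-cell variability, mutual direction
#' its co-expression with other markers. Axes are annotated with the model's
#' explained variance.
#'
#' @param model an [ScaModel].
#' @param scores N x 2 score matrix (a subsample is drawn for display), or
#'   `NULL` when `density` is given.
#' @param density optional [DensityGrid] underlay.
#' @param maxPoints subsample size for the scatter underlay.
#' @return a ggplot object.
#' @export
plotBiplot <- function(model, scores = NULL, density = NULL,
                       maxPoints = 20000L) {
  stopifnot(is(model, "ScaModel"))
  p <- ggplot2::ggplot()
  if (!is.null(density)) {
    df <- .gridToDf(density)
    p <- p + ggplot2::geom_raster(
      data = df[df$value > 0, ],
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(name = "density")
    arrowScale <- 0.8 * max(abs(c(density@x, density@y)))
  } else if (!is.null(scores)) {
    scores <- as.matrix(scores)[, 1:2, drop = FALSE]
    if (nrow(scores) > maxPoints)
      scores <- scores[sample.int(nrow(scores), maxPoints), ]
    df <- data.frame(x = scores[, 1], y = scores[, 2])
    p <- p + ggplot2::geom_point(
      data = df, ggplot2::aes(x = .data$x, y = .data$y),
      alpha = 0.15, size = 0.3, colour = "steelblue")
    arrowScale <- 0.8 * max(abs(scores))
  } else stop("provide scores or a density")
  arr <- .loadingArrows(model, arrowScale)
  lab <- .axisLabels(model)
  p + ggplot2::geom_segment(
        data = arr,
        ggplot2::aes(x = 0, y = 0, xend = .data$xend, yend = .data$yend),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
        colour = "black") +
    ggplot2::geom_text(
      data = arr,
      ggplot2::aes(x = .data$xend * 1.08, y = .data$yend * 1.08,
                   label = .data$marker), size = 3) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' Signed Difference-between-Densities map
#'
#' Diverging colour map with white at zero: negative (responder-enriched)
#' regions in red, positive (control-enriched) regions in blue; white marks
#' bins with no cells or equal intensity. Loadings of the control model can
#' be superimposed.
#'
#' @param dbd signed [DensityGrid] from [computeDbd()].
#' @param model optional control [ScaModel] whose loadings to draw.
#' @return a ggplot object.
#' @export
plotDbd <- function(dbd, model = NULL) {
  stopifnot(is(dbd, "DensityGrid"))
  df <- .gridToDf(dbd)
  lim <- max(abs(df$value))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  midpoint = 0, limits = c(-lim, lim),
                                  name = "DbD") +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    arr <- .loadingArrows(model, 0.8 * max(abs(c(dbd@x, dbd@y))))
    p <- p + ggplot2::geom_segment(
      data = arr,
      ggplot2::aes(x = 0, y = 0, xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      inherit.aes = FALSE) +
      ggplot2::geom_text(
        data = arr,
        ggplot2::aes(x = .data$xend * 1.08, y = .data$yend * 1.08,
                     label = .data$marker), size = 3, inherit.aes = FALSE)
  }
  p
}

#' Dendrogram of a responder stratification
#'
#' Base-graphics dendrogram with the k-cluster cut outlined.
#'
#' @param strat a [StratificationResult].
#' @param file optional path; when given the plot is written there as PDF.
#' @export
plotDendrogram <- function(strat, file = NULL) {
  stopifnot(is(strat, "StratificationResult"))
  draw <- function() {
    plot(strat@tree, main = "Responder stratification",
         xlab = "", sub = "", ylab = "distance")
    if (strat@k > 1L && strat@k < length(strat@labels))
      stats::rect.hclust(strat@tree, k = strat@k,
                         border = seq_len(strat@k) + 1L)
  }
  if (!is.null(file)) {
    grDevices::pdf(file, width = 7, height = 5)
    on.exit(grDevices::dev.off())
    draw()
    return(invisible(file))
  }
  draw()
  invisible(NULL)
}
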