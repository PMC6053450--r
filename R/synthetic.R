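#' @include AllClasses.R preprocess.R
NULL

#' Describe a synthetic cytometry cohort
#'
#' Populations are Gaussian components specified in transformed (arcsinh or
#' log10) space — the space the component models operate in — and samples are
#' back-transformed to raw-intensity-like values on output, so the generator
#' exercises the full pre-processing honestly. Each individual receives its
#' own Gaussian mean offset (emulating sample-to-sample location variation,
#' which per-individual centering later removes); responders additionally
#' receive the spiked populations of their phenotype at the stated abundance.
#'
#' @param nControl,nResponder number of individuals per group.
#' @param cellsPerIndividual events per individual.
#' @param markerNames marker panel (J >= 2).
#' @param controlPopulations list of `list(mean, cov, weight)`; weights sum
#'   to 1.
#' @param individualShiftSd sd of the per-individual mean offset (same in
#'   every marker).
#' @param responsePopulations list of `list(mean, cov, abundance,
#'   phenotype)`; a responder with phenotype id p carries every population
#'   with `phenotype == p`.
#' @param phenotypeOf integer vector assigning each responder a phenotype
#'   (0 = no spikes); recycled to `nResponder`.
#' @param transform,cofactor,logShift back-transform of the output.
#' @param seed default RNG seed for [generateCohort()].
#' @return a [CohortSpec].
#' @export
cohortSpec <- function(nControl, nResponder, cellsPerIndividual,
                       markerNames, controlPopulations,
                       individualShiftSd = 0.15,
                       responsePopulations = list(),
                       phenotypeOf = rep(1L, nResponder),
                       transform = c("arcsinh", "log"), cofactor = 5,
                       logShift = 1, seed = 1234L) {
  new("CohortSpec",
      nControl = as.integer(nControl), nResponder = as.integer(nResponder),
      cellsPerIndividual = as.integer(cellsPerIndividual),
      markerNames = markerNames,
      controlPopulations = controlPopulations,
      individualShiftSd = individualShiftSd,
      responsePopulations = responsePopulations,
      phenotypeOf = as.integer(rep_len(phenotypeOf, nResponder)),
      transform = match.arg(transform), arcsinhCofactor = cofactor,
      logShift = logShift, seed = as.integer(seed))
}

.rmvn <- function(n, mean, cov) {
  L <- chol(cov)
  sweep(matrix(stats::rnorm(n * length(mean)), n) %*% L, 2L, mean, "+")
}

#' Generate a cohort with ground-truth labels
#'
#' Deterministic given the seed. Per individual: draw the mean offset, draw
#' each cell's population (controls: the control mixture; responders: the
#' phenotype's spiked populations at their abundances, the control mixture
#' filling the rest), sample the cell in transformed space and invert the
#' transform so the output is raw-intensity-like.
#'
#' @param spec a [CohortSpec].
#' @param seed RNG seed; defaults to the spec's frozen seed.
#' @return list with `multiset` (a [CytoMultiSet]), `labels` (per-individual
#'   data.frame with columns `population` and `spiked`), and `phenotypes`
#'   (named integer per responder).
#' @export
generateCohort <- function(spec, seed = spec@seed) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(seed)
  J <- length(spec@markerNames)
  nInd <- spec@nControl + spec@nResponder
  ids <- c(sprintf("control%02d", seq_len(spec@nControl)),
           sprintf("responder%02d", seq_len(spec@nResponder)))
  groups <- c(rep(0L, spec@nControl), rep(1L, spec@nResponder))
  ctrlW <- vapply(spec@controlPopulations, `[[`, numeric(1), "weight")
  blocks <- vector("list", nInd)
  labels <- vector("list", nInd)
  for (i in seq_len(nInd)) {
    shift <- stats::rnorm(J, 0, spec@individualShiftSd)
    pops <- spec@controlPopulations
    w <- ctrlW
    popNames <- sprintf("control%d", seq_along(pops))
    spiked <- rep(FALSE, length(pops))
    if (groups[i] >= 1L) {
      ph <- spec@phenotypeOf[i - spec@nControl]
      sel <- which(vapply(spec@responsePopulations, `[[`, numeric(1),
                          "phenotype") == ph)
      if (length(sel)) {
        ab <- vapply(spec@responsePopulations[sel], `[[`, numeric(1),
                     "abundance")
        if (sum(ab) >= 1) stop("total spike abundance must be < 1")
        w <- c(ctrlW * (1 - sum(ab)), ab)
        pops <- c(pops, spec@responsePopulations[sel])
        popNames <- c(popNames, sprintf("spike%d", sel))
        spiked <- c(spiked, rep(TRUE, length(sel)))
      }
    }
    N <- spec@cellsPerIndividual
    popIdx <- sample.int(length(pops), N, replace = TRUE, prob = w)
    X <- matrix(0, N, J)
    for (p in unique(popIdx)) {
      rows <- popIdx == p
      X[rows, ] <- .rmvn(sum(rows), pops[[p]]$mean + shift, pops[[p]]$cov)
    }
    raw <- .invertVst(X, spec@transform, spec@arcsinhCofactor, spec@logShift)
    colnames(raw) <- spec@markerNames
    blocks[[i]] <- raw
    labels[[i]] <- data.frame(population = popNames[popIdx],
                              spiked = spiked[popIdx])
  }
  ms <- new("CytoMultiSet", blocks = blocks, individualIds = ids,
            groups = groups, markerNames = spec@markerNames)
  respIds <- ids[groups >= 1L]
  list(multiset = ms, labels = stats::setNames(labels, ids),
       phenotypes = stats::setNames(spec@phenotypeOf, respIds))
}

# Shared geometry of the neutrophil-challenge-like cohort: two orthogonal
# in-plane co-expression axes (the directions the control model should
# recover) and one off-plane axis (marker variation outside the control
# component plane, invisible to the score densities but caught by SPE).
.lpsGeometry <- function() {
  markers <- c("CD62L", "CD11b", "CD11c", "CD64", "CD32", "CD69", "CD16")
  unit <- function(v) v / sqrt(sum(v^2))
  v1 <- unit(c(0, 0.60, 0.55, 0.25, 0, 0, 0.50))    # CD11b/CD11c/CD16 axis
  v2 <- unit(c(0.60, 0, 0, 0, 0.55, 0.50, 0))       # CD62L/CD32/CD69 axis
  wRaw <- c(0, 0.50, -0.50, 0.60, 0, 0, -0.35)
  w <- unit(wRaw - v1 * sum(wRaw * v1) - v2 * sum(wRaw * v2))
  base <- c(2.2, 2.6, 2.4, 1.8, 2.0, 1.5, 2.8)
  cov <- 0.16 * diag(7) + 1.44 * tcrossprod(v1) + 0.64 * tcrossprod(v2)
  list(markers = markers, v1 = v1, v2 = v2, w = w, base = base, cov = cov)
}

#' Frozen default cohort emulating an endotoxin-challenge study
#'
#' Seven neutrophil surface markers, eight control and eight responder
#' individuals. Control cells come from a bimodal mixture whose two dominant
#' co-expression axes (a CD11b/CD11c/CD16 axis and a CD62L/CD32/CD69 axis)
#' define the control component plane. Responders carry two spiked
#' populations at 15% abundance each, with opposite displacement signs on
#' the two leading axes (one CD16-high/CD62L-low, one CD62L-high/CD16-low):
#' one population sits mostly off the control component plane, so the
#' residual (SPE) limit flags it; the other lies inside the plane but far
#' from the control score density, so the density-difference filter catches
#' it. With the 5% baseline of the SPE limit this geometry puts per-responder
#' SPE-flagged fractions near one sixth of the cells.
#'
#' @param spiked with `FALSE` the spiked populations are omitted (a null,
#'   homogeneous cohort for calibration).
#' @param cellsPerIndividual events per individual; the default 17500 mirrors
#'   the event depth of the endotoxin study the design emulates (about 2.8e5
#'   events over 16 individuals).
#' @param seed frozen default seed.
#' @return a [CohortSpec].
#' @export
lpsLikeDefault <- function(spiked = TRUE, cellsPerIndividual = 17500L,
                           seed = 1234L) {
  g <- .lpsGeometry()
  ctrl <- list(
    list(mean = g$base + 0.8 * g$v1, cov = g$cov, weight = 0.55),
    list(mean = g$base - 0.8 * g$v1, cov = g$cov, weight = 0.45))
  spikes <- if (spiked) list(
    list(mean = g$base + 2.75 * g$v1 - 2.25 * g$v2 + 2.0 * g$w,
         cov = 0.09 * diag(7), abundance = 0.15, phenotype = 1),
    list(mean = g$base - 2.75 * g$v1 + 2.25 * g$v2,
         cov = 0.09 * diag(7), abundance = 0.15, phenotype = 1))
  else list()
  cohortSpec(
    nControl = 8L, nResponder = 8L,
    cellsPerIndividual = cellsPerIndividual,
    markerNames = g$markers, controlPopulations = ctrl,
    individualShiftSd = 0.15, responsePopulations = spikes,
    phenotypeOf = rep(1L, 8L), transform = "arcsinh", cofactor = 5,
    seed = seed)
}

#' Frozen three-phenotype cohort for stratification
#'
#' Same control design as [lpsLikeDefault()]; nine responders carry one of
#' three response phenotypes (three responders each). Each phenotype consists
#' of two spiked populations at 15% abundance placed symmetrically about the
#' control bulk along a phenotype-specific in-plane direction, so after
#' per-individual centering the phenotypes remain distinguishable by the
#' geometry of their response-cell score distributions.
#'
#' @param cellsPerIndividual events per individual (default 3000).
#' @param seed frozen default seed.
#' @return a [CohortSpec].
#' @export
threePhenotypeDefault <- function(cellsPerIndividual = 3000L, seed = 5678L) {
  g <- .lpsGeometry()
  ctrl <- list(
    list(mean = g$base + 0.8 * g$v1, cov = g$cov, weight = 0.55),
    list(mean = g$base - 0.8 * g$v1, cov = g$cov, weight = 0.45))
  dirs <- list(g$v1, g$v2, (g$v1 + g$v2) / sqrt(2))
  dist <- c(3.5, 3.0, 3.5)
  spikes <- list()
  for (p in 1:3) for (s in c(-1, 1))
    spikes[[length(spikes) + 1L]] <- list(
      mean = g$base + s * dist[p] * dirs[[p]], cov = 0.09 * diag(7),
      abundance = 0.15, phenotype = p)
  cohortSpec(
    nControl = 8L, nResponder = 9L,
    cellsPerIndividual = cellsPerIndividual,
    markerNames = g$markers, controlPopulations = ctrl,
    individualShiftSd = 0.15, responsePopulations = spikes,
    phenotypeOf = rep(1:3, each = 3L), transform = "arcsinh", cofactor = 5,
    seed = seed)
}

#' Write a generated cohort to per-individual CSV files
#'
#' Writes one CSV per individual plus `truth_labels.csv` (individual_id,
#' event_index, population, spiked) and `group_map.csv`.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ms <- cohort$multiset
  for (i in seq_len(nBlocks(ms))) {
    utils::write.csv(as.data.frame(ms@blocks[[i]]),
                     file.path(dir, paste0(ms@individualIds[i], ".csv")),
                     row.names = FALSE)
  }
  truth <- do.call(rbind, Map(function(id, lab)
    cbind(individual_id = id, event_index = seq_len(nrow(lab)), lab),
    ms@individualIds, cohort$labels))
  utils::write.csv(truth, file.path(dir, "truth_labels.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(individual_id = ms@individualIds, group = ms@groups),
    file.path(dir, "group_map.csv"), row.names = FALSE)
  invisible(dir)
}
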