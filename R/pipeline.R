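#' @include AllClasses.R io.R preprocess.R control_model.R density.R
#' @include response_filter.R eclipse_model.R validation.R synthetic.R plots.R
#' @importFrom rlang .data
NULL

.defaultConfig <- function() {
  list(
    inputDir = NULL,          # directory of per-individual CSVs + group_map.csv
    cohort = NULL,            # "lps_like" | "three_phenotype" (simulated input)
    cells = NULL,             # override simulated cells per individual
    transform = "arcsinh", cofactor = 5, logShift = NA,
    scaling = "over_controls",
    alpha = 0.05,
    nComponents = 2,          # integer or "auto"
    nBoot = 50, angleThreshold = 0.35,
    gridSize = 256,
    eclipseScaling = "per_individual", eclipseComponents = 2,
    k = NULL, metric = "euclidean", stratGridSize = 64,
    partialModels = FALSE,
    figures = TRUE,
    seed = 1L)
}

.readConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the yaml package; use JSON instead")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- .defaultConfig()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  cfg
}

.loadInput <- function(cfg) {
  if (!is.null(cfg$inputDir)) {
    files <- list.files(cfg$inputDir, pattern = "\\.(csv|tsv|txt|fcs)$",
                        full.names = TRUE, ignore.case = TRUE)
    files <- files[!grepl("group_map|truth_labels", basename(files))]
    if (!length(files)) stop("no event files found in ", cfg$inputDir)
    gm <- file.path(cfg$inputDir, "group_map.csv")
    if (!file.exists(gm)) stop("group_map.csv not found in ", cfg$inputDir)
    groups <- readGroupMap(gm)
    tables <- lapply(files, readEvents)
    return(assembleMultiSet(tables, groups = groups))
  }
  if (!is.null(cfg$cohort)) {
    spec <- switch(cfg$cohort,
      lps_like = lpsLikeDefault(),
      three_phenotype = threePhenotypeDefault(),
      stop("unknown cohort preset: ", cfg$cohort))
    if (!is.null(cfg$cells)) spec@cellsPerIndividual <- as.integer(cfg$cells)
    return(generateCohort(spec, seed = cfg$seed)$multiset)
  }
  stop("config must name either inputDir or a cohort preset")
}

#' Run the full elimination pipeline
#'
#' Orchestrates, in order: pre-processing (fit on controls), the control
#' component model (with optional bootstrap-based component choice), SPE
#' control limits, score densities and the pooled control density, the
#' per-responder Difference-between-Densities filter, the response-specific
#' model on the retained cells and (when `k` is configured) stratification
#' with optional cluster-specific partial models. All stage artifacts are
#' written under `outDir` together with a manifest of the resolved
#' configuration; rerunning with the same manifest reproduces every artifact.
#'
#' If the input contains no responder individuals the pipeline writes the
#' control model and densities, then stops with a message.
#'
#' @param config named list, or path to a JSON/YAML file; see the package
#'   vignette for keys. Unknown keys are an error.
#' @param outDir output directory.
#' @return (invisibly) a list of the in-memory stage results.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("eclipse_run")) {
  cfg <- .readConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  res <- list()
  tryCatch({
    ms <- .loadInput(cfg)
    res$multiset <- ms

    stage <- "preprocess"
    params <- preprocessParams(transform = cfg$transform,
                               cofactor = cfg$cofactor,
                               logShift = if (is.null(cfg$logShift)) NA_real_
                                          else as.numeric(cfg$logShift),
                               scaling = cfg$scaling)
    pms <- fitPreprocess(ms, params)
    res$preprocessed <- pms

    stage <- "control_model"
    nComp <- cfg$nComponents
    if (identical(nComp, "auto")) {
      prof <- bootstrapStability(controls(pms),
                                 rMax = length(markerNames(ms)),
                                 nBoot = cfg$nBoot, seed = cfg$seed)
      nComp <- chooseComponents(prof, cfg$angleThreshold)
      res$stability <- prof
      utils::write.csv(stabilityTable(prof),
                       file.path(outDir, "stability.csv"), row.names = FALSE)
    }
    nComp <- max(2L, as.integer(nComp))
    ctrlPms <- controls(pms)
    model <- fitSca(ctrlPms, nComp, provenance = "control")
    res$controlModel <- model
    saveScaModel(model, file.path(outDir, "control_model.json"))

    stage <- "spe"
    profile <- controlSpeProfile(model, pms, alpha = cfg$alpha)
    res$speProfile <- profile
    utils::write.csv(
      data.frame(individual_id = profile@individualIds,
                 limit = profile@perIndividualLimits,
                 pooled_limit = profile@pooledLimit, alpha = profile@alpha),
      file.path(outDir, "spe_report.csv"), row.names = FALSE)

    if (!any(groupLabels(ms) >= 1L)) {
      ctrlScores <- lapply(ctrlPms@blocks,
                           function(b) projectBlock(model, b)$scores[, 1:2])
      grid <- scoreGrid(ctrlScores, gridSize = cfg$gridSize)
      ctrlKde <- poolDensities(lapply(ctrlScores, estimateKde, grid = grid))
      writeDensityGrid(ctrlKde, file.path(outDir, "control_density.json.gz"))
      .writeManifest(cfg, nComp, outDir)
      message("no responder individuals: pipeline stopped after the ",
              "control density stage")
      return(invisible(res))
    }

    stage <- "filter"
    mask <- eclipseFilter(model, pms, profile, gridSize = cfg$gridSize)
    res$mask <- mask
    writeFilterReport(mask, file.path(outDir, "filter_report.csv"))
    writeDensityGrid(mask@controlDensity,
                     file.path(outDir, "control_density.json.gz"))
    for (id in names(mask@dbd))
      writeDensityGrid(mask@dbd[[id]],
                       file.path(outDir, sprintf("dbd_%s.json.gz", id)))
    maskTab <- do.call(rbind, Map(function(id, f)
      cbind(individual_id = id, event_index = seq_len(nrow(f)), f),
      names(mask@flags), mask@flags))
    utils::write.csv(maskTab, file.path(outDir, "masks.csv"),
                     row.names = FALSE)

    stage <- "eclipse_model"
    eclipse <- buildEclipseModel(ms, mask, params = pms@params,
                                 nComponents = cfg$eclipseComponents,
                                 scaling = cfg$eclipseScaling)
    res$eclipse <- eclipse
    saveScaModel(eclipse@model, file.path(outDir, "eclipse_model.json"))

    strat <- NULL
    if (!is.null(cfg$k) && nBlocks(eclipse@retained) >= 2L) {
      stage <- "stratify"
      strat <- stratify(eclipse, k = cfg$k, metric = cfg$metric,
                        gridSize = cfg$stratGridSize)
      res$stratification <- strat
      utils::write.csv(
        data.frame(individual_id = names(strat@labels),
                   cluster = strat@labels),
        file.path(outDir, "clusters.csv"), row.names = FALSE)
      ape::write.tree(ape::as.phylo(strat@tree),
                      file.path(outDir, "linkage.nwk"))
      if (isTRUE(cfg$partialModels))
        res$partialModels <- fitPartialModels(eclipse, strat)
    }
    writeRetainedCells(eclipse, file.path(outDir, "retained_cells.csv"),
                       labels = strat)

    if (isTRUE(cfg$figures)) {
      stage <- "figures"
      ggplot2::ggsave(file.path(outDir, "control_biplot.pdf"),
                      plotBiplot(model, density = mask@controlDensity),
                      width = 7, height = 6)
      firstId <- names(mask@dbd)[1]
      ggplot2::ggsave(file.path(outDir, sprintf("dbd_%s.pdf", firstId)),
                      plotDbd(mask@dbd[[firstId]], model = model),
                      width = 7, height = 6)
      if (!is.null(strat))
        plotDendrogram(strat, file.path(outDir, "dendrogram.pdf"))
    }

    .writeManifest(cfg, nComp, outDir)
    invisible(res)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.writeManifest <- function(cfg, nComp, outDir) {
  cfg$resolvedComponents <- nComp
  cfg$packageVersion <- as.character(utils::packageVersion("eclipser"))
  jsonlite::write_json(cfg, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}
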