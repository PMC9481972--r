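#' Read a tissue series from a directory
#'
#' Reads the per-step graph JSONs and lineage CSVs written by
#' \code{\link{writeTissueSeries}} (or any conforming exporter); ground-truth
#' pair classes are recomputed from the graphs and lineages. Polygon geometry
#' is not stored on disk and comes back empty.
#'
#' @param dir directory with \code{graph_t<k>.json} and
#'   \code{lineage_t<k>.csv}.
#' @return a \linkS4class{TissueSeries}.
#' @export
readTissueSeries <- function(dir) {
  if (!dir.exists(dir)) stopInput("no such directory: %s", dir)
  gf <- sort(list.files(dir, "^graph_t[0-9]+\\.json$", full.names = TRUE))
  lf <- sort(list.files(dir, "^lineage_t[0-9]+\\.csv$", full.names = TRUE))
  if (!length(gf)) stopInput("no graph files in %s", dir)
  ord <- order(as.integer(sub(".*_t([0-9]+)\\.json$", "\\1", gf)))
  gf <- gf[ord]
  lf <- lf[order(as.integer(sub(".*_t([0-9]+)\\.csv$", "\\1", lf)))]
  graphs <- lapply(gf, readTissueGraph)
  lineages <- lapply(lf, readLineageMap)
  pairClasses <- lapply(seq_along(lineages), function(t) {
    pairs <- enumeratePairs(graphs[[t]], lineages[[t]],
                            includeDividingNeighbors = TRUE)
    if (nrow(pairs))
      pairs$label <- labelPairClasses(pairs, graphs[[t + 1]], lineages[[t]])
    else pairs$label <- integer(0)
    pairs
  })
  params <- if (file.exists(file.path(dir, "manifest.json")))
    do.call(simParams, jsonlite::fromJSON(file.path(dir, "manifest.json")))
  else simParams()
  methods::new("TissueSeries", graphs = graphs,
               polygons = rep(list(list()), length(graphs)),
               lineages = lineages, pairClasses = pairClasses,
               params = params, seed = params$seed)
}

#' Read a pipeline run configuration
#'
#' @param path YAML file; fields mirror the arguments resolved by
#'   \code{\link{runPipeline}}.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  yaml::read_yaml(path)
}

resolveConfig <- function(config) {
  defaults <- list(outDir = NULL, seed = 1L, nPlants = 5, nTestPlants = 2,
                   radius = 30, divisionFeatureSet = "topo+area",
                   pairFeatureSet = "topo+bio", cGrid = defaultCGrid(),
                   baselineReps = 20, propagate = TRUE, cohortDirs = NULL,
                   sim = list())
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$outDir)) stopInput("config requires an outDir")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> feature assembly -> division training -> rewiring
#' training -> propagation -> evaluation, writing every artifact (series
#' files, feature tables, model JSONs, metrics, per-feature correlations) and
#' the resolved configuration into the output directory. All randomness flows
#' through the configured seed, so a rerun with the same configuration
#' reproduces identical reports. Instead of simulating, an existing cohort
#' can be loaded via \code{cohortDirs} (named list of series directories).
#'
#' @param config named list or YAML path (see \code{\link{readRunConfig}}).
#' @return (invisibly) list with the trained models, metrics and output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- resolveConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg[setdiff(names(cfg), "cGrid")],
                   file.path(cfg$outDir, "config_resolved.yaml"))

  cohort <- if (!is.null(cfg$cohortDirs)) {
    out <- lapply(cfg$cohortDirs, readTissueSeries)
    if (is.null(names(out)) || any(!nzchar(names(out))))
      names(out) <- paste0("plant", seq_along(out))
    out
  } else {
    params <- do.call(simParams, utils::modifyList(cfg$sim,
                                                   list(seed = cfg$seed)))
    simulateCohort(params, nPlants = cfg$nPlants, seed = cfg$seed)
  }
  for (pl in names(cohort))
    writeTissueSeries(cohort[[pl]], file.path(cfg$outDir, "series", pl))

  divFT <- assembleDivisionDataset(cohort, featureSet = cfg$divisionFeatureSet,
                                   radius = cfg$radius)
  pairFT <- assemblePairDataset(cohort, featureSet = cfg$pairFeatureSet,
                                radius = cfg$radius)
  writeFeatureTable(divFT, file.path(cfg$outDir, "division_features.csv"))
  writeFeatureTable(pairFT, file.path(cfg$outDir, "pair_features.csv"))

  splits <- makeSplits(sampleData(divFT)$plant, nTestPlants = cfg$nTestPlants,
                       seed = cfg$seed)
  divFit <- trainDivisionClassifier(divFT, splits, cGrid = cfg$cGrid,
                                    featureSet = cfg$divisionFeatureSet)
  pairFit <- trainPairClassifier(pairFT, splits, cGrid = cfg$cGrid,
                                 seed = cfg$seed,
                                 featureSet = cfg$pairFeatureSet)
  writeClassifier(divFit$model, file.path(cfg$outDir, "division_model.json"))
  writeClassifier(pairFit$model, file.path(cfg$outDir, "pair_model.json"))

  testRows <- sampleData(divFT)$plant %in% splits$testPlants
  report <- list(
    selectedC = list(division = divFit$C, pair = pairFit$C),
    divisionValidation = lapply(divFit$foldMetrics, function(f)
      f$validation[c("accuracy", "balancedAccuracy")]),
    pairValidation = lapply(pairFit$foldMetrics, function(f)
      f$validation[c("accuracy", "balancedAccuracy")]))
  if (any(testRows)) {
    report$divisionTest <- evaluateClassifier(
      divFit$model, subsetRowsFT(divFT, testRows))[
        c("accuracy", "balancedAccuracy", "tpr", "fpr", "f1", "auc")]
  }

  if (isTRUE(cfg$propagate)) {
    pl <- splits$testPlants[1]
    ser <- cohort[[pl]]
    tg <- ser@graphs[[1]]
    prop <- propagateTissue(tg, divFit$model, pairFit$model,
                            seed = cfg$seed, radius = cfg$radius)
    cmp <- compareTopologies(prop, ser@graphs[[2]], ser@lineages[[1]])
    utils::write.csv(cmp$perFeature[order(-cmp$perFeature$r), ],
                     file.path(cfg$outDir, "propagation_correlations.csv"),
                     row.names = FALSE)
    central <- selectCentralCells(tg, cfg$radius)
    dividers <- names(prop@divisionClasses)
    poolLabels <- sampleData(pairFT)$label[
      sampleData(pairFT)$plant %in% splits$trainPlants]
    classDist <- table(factor(poolLabels, levels = c("0", "1", "2")))
    base <- randomPropagationBaseline(
      tg, dividers, central, classDist / sum(classDist),
      ser@graphs[[2]], ser@lineages[[1]], reps = cfg$baselineReps,
      seed = cfg$seed,
      modelR = stats::setNames(cmp$perFeature$r, cmp$perFeature$feature))
    report$propagation <- list(
      nCoNonDividing = cmp$n,
      meanModelR = mean(cmp$perFeature$r, na.rm = TRUE),
      meanBaselineR = mean(base$mean, na.rm = TRUE))
    acc <- tryCatch(localRewiringAccuracy(prop, ser@graphs[[2]],
                                          ser@lineages[[1]], seed = cfg$seed),
                    error = function(e) NULL)
    if (!is.null(acc))
      report$propagation$meanNeighborAccuracy <- acc$meanAccuracy
  }
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(cohort = cohort, divisionFit = divFit, pairFit = pairFit,
                 report = report, outDir = cfg$outDir))
}

# internal: row-subset of a FeatureTable (rows = samples)
subsetRowsFT <- function(ft, rows) {
  methods::new("FeatureTable", methods::as(ft[, rows], "SummarizedExperiment"))
}
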