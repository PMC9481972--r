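#' Read / write tissue graphs
#'
#' The canonical on-disk form is node-link JSON with schema
#' \code{{"time": int, "center": id, "cells": [{"id", "centroid": [x,y,z],
#' "area", "perimeter"}], "walls": [{"u", "v", "shared_wall"}]}}. A two-file
#' CSV dialect mirroring segmentation-tool exports is also supported
#' (\code{readTissueGraphCSV}): \code{cells.csv} with columns
#' \code{id,x,y,z,area,perimeter} and \code{walls.csv} with
#' \code{u,v,shared_wall}.
#'
#' @param path JSON file path.
#' @param tg a \linkS4class{TissueGraph}.
#' @return \code{readTissueGraph*}: a \linkS4class{TissueGraph};
#'   the writers return their path invisibly.
#' @export
readTissueGraph <- function(path) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cells <- as.data.frame(j$cells)
  ctr <- do.call(rbind, if (is.list(cells$centroid)) cells$centroid else
    asplit(cells$centroid, 1))
  cells <- data.frame(id = cells$id, x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                      area = cells$area, perimeter = cells$perimeter)
  walls <- as.data.frame(j$walls)
  names(walls)[names(walls) == "shared_wall"] <- "sharedWall"
  buildTissueGraph(cells, walls, centerCell = j$center,
                   timeIndex = j$time %||% 0L)
}

#' @rdname readTissueGraph
#' @export
writeTissueGraph <- function(tg, path) {
  cd <- cellData(tg)
  wd <- wallData(tg)
  obj <- list(
    time = timeIndex(tg),
    center = centerCell(tg),
    cells = lapply(seq_len(nrow(cd)), function(i) list(
      id = cd$id[i], centroid = c(cd$x[i], cd$y[i], cd$z[i]),
      area = cd$area[i], perimeter = cd$perimeter[i])),
    walls = lapply(seq_len(nrow(wd)), function(i) list(
      u = wd$u[i], v = wd$v[i], shared_wall = wd$sharedWall[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname readTissueGraph
#' @param cellsFile,wallsFile CSV paths of the two-file dialect.
#' @param centerCell,timeIndex as in \code{\link{buildTissueGraph}}.
#' @export
readTissueGraphCSV <- function(cellsFile, wallsFile, centerCell, timeIndex = 0L) {
  for (f in c(cellsFile, wallsFile))
    if (!file.exists(f)) stopInput("no such file: %s", f)
  cells <- utils::read.csv(cellsFile, stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
  walls <- utils::read.csv(wallsFile, stringsAsFactors = FALSE,
                           colClasses = c(u = "character", v = "character"))
  names(walls)[names(walls) == "shared_wall"] <- "sharedWall"
  buildTissueGraph(cells, walls, centerCell = centerCell, timeIndex = timeIndex)
}

#' Export a tissue graph as GraphML
#'
#' Writes the underlying igraph (with all cell and wall attributes) in GraphML
#' for interoperability with external network tools.
#'
#' @param tg a \linkS4class{TissueGraph}.
#' @param path output path.
#' @export
exportGraphML <- function(tg, path) {
  igraph::write_graph(asIgraph(tg), path, format = "graphml")
  invisible(path)
}

#' Read / write lineage maps
#'
#' CSV with columns \code{parent_id, daughterA_id, daughterB_id}; survivor rows
#' carry the time-t id in \code{parent_id}, the time-t+1 id in
#' \code{daughterA_id} and an empty \code{daughterB_id}.
#'
#' @param path CSV file path.
#' @param lineage a \linkS4class{LineageMap}.
#' @export
readLineageMap <- function(path) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  d[is.na(d)] <- ""
  isDiv <- nzchar(d$daughterB_id)
  LineageMap(
    divisions = data.frame(parent = d$parent_id[isDiv],
                           daughterA = d$daughterA_id[isDiv],
                           daughterB = d$daughterB_id[isDiv]),
    survivors = stats::setNames(d$daughterA_id[!isDiv], d$parent_id[!isDiv]))
}

#' @rdname readLineageMap
#' @export
writeLineageMap <- function(lineage, path) {
  d <- divisions(lineage)
  s <- survivors(lineage)
  out <- rbind(
    data.frame(parent_id = d$parent, daughterA_id = d$daughterA,
               daughterB_id = d$daughterB),
    data.frame(parent_id = names(s), daughterA_id = unname(s),
               daughterB_id = ""))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write feature tables
#'
#' The matrix is written as CSV (rows = cells/pairs, columns = features, the
#' row metadata prepended as leading columns) with a JSON sidecar
#' (\code{<path>.meta.json}) recording each column's provenance: feature name,
#' weighting scenario and scope.
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @param path CSV file path.
#' @export
writeFeatureTable <- function(ft, path) {
  X <- featureMatrix(ft)
  meta <- as.data.frame(SummarizedExperiment::colData(ft))
  utils::write.csv(cbind(meta, as.data.frame(X)), path, row.names = FALSE)
  side <- list(metaColumns = names(meta),
               columns = as.data.frame(SummarizedExperiment::rowData(ft)))
  jsonlite::write_json(side, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  side <- jsonlite::fromJSON(paste0(path, ".meta.json"), simplifyVector = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- d[, side$metaColumns, drop = FALSE]
  X <- as.matrix(d[, setdiff(names(d), side$metaColumns), drop = FALSE])
  makeFeatureTable(X, rowInfo = as.data.frame(side$columns), colMeta = meta)
}

#' Serialize / restore a trained classifier
#'
#' The model artifact is JSON holding the feature column names, z-normalization
#' statistics, weight vectors, intercepts, class labels, class weights and the
#' selected C. A restored model reproduces its predictions exactly.
#'
#' @param model a \linkS4class{LinearTissueClassifier}.
#' @param path JSON file path.
#' @export
writeClassifier <- function(model, path) {
  # doubles are stored as %.17g strings: every IEEE double round-trips
  # exactly, so a restored model reproduces predictions bit-identically
  num <- function(x) sprintf("%.17g", x)
  obj <- list(featureNames = model@featureNames,
              center = num(unname(model@center)),
              scale = num(unname(model@scale)),
              weights = lapply(unname(asplit(model@weights, 2)), num),
              intercepts = num(unname(model@intercepts)),
              classes = model@classes, C = num(model@cost),
              classWeights = as.list(num(model@classWeights)),
              classWeightNames = names(model@classWeights),
              featureSet = model@featureSet)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  W <- if (is.matrix(obj$weights)) {
    # one row per class column (JSON array-of-arrays)
    t(matrix(as.numeric(obj$weights), nrow = nrow(obj$weights)))
  } else {
    matrix(as.numeric(unlist(obj$weights)), ncol = 1)
  }
  methods::new("LinearTissueClassifier",
    featureNames = obj$featureNames,
    center = stats::setNames(as.numeric(obj$center), obj$featureNames),
    scale = stats::setNames(as.numeric(obj$scale), obj$featureNames),
    weights = W, intercepts = as.numeric(obj$intercepts),
    classes = obj$classes, cost = as.numeric(obj$C),
    classWeights = stats::setNames(as.numeric(unlist(obj$classWeights)),
                                   obj$classWeightNames),
    featureSet = obj$featureSet)
}
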