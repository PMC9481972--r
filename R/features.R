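#' The per-cell topological feature catalogue
#'
#' Seventeen features per cell: ten whole-network properties (degree i.e.
#' summed edge weight, clustering coefficient, average neighbor degree,
#' harmonic centrality, closeness, betweenness, current-flow closeness /
#' information centrality, Katz centrality, eigenvector centrality and
#' current-flow betweenness) and seven neighborhood-subgraph properties
#' (first neighborhood: size, absolute and relative graph density; second
#' neighborhood: size, absolute and relative density, and mean internal
#' shortest-path length).
#'
#' \code{weightRole} declares, per feature, how the scenario's edge weight
#' enters: \code{strength} features consume the weight directly (walk and flow
#' measures), \code{length} features convert it to a path length of
#' \code{1/weight} so that "heavier = closer" holds uniformly, and \code{none}
#' features are pure counts, identical across scenarios. The catalogue is a
#' registry: the pipeline consumes whatever it returns.
#'
#' @return data.frame with columns \code{name}, \code{scope},
#'   \code{weightSensitive}, \code{weightRole}.
#' @export
featureCatalogue <- function() {
  data.frame(
    name = c("degree", "clustering", "avgNeighborDegree", "harmonic",
             "closeness", "betweenness", "currentFlowCloseness", "katz",
             "eigenvector", "currentFlowBetweenness",
             "nbSize1", "nbAbsDensity1", "nbRelDensity1",
             "nbSize2", "nbAbsDensity2", "nbRelDensity2", "nbMeanPath2"),
    scope = c(rep("whole_network", 10), rep("neighborhood_k1", 3),
              rep("neighborhood_k2", 4)),
    weightSensitive = c(rep(TRUE, 10), rep(FALSE, 6), TRUE),
    weightRole = c("strength", "strength", "strength", "length", "length",
                   "length", "strength", "strength", "strength", "strength",
                   rep("none", 6), "length"),
    stringsAsFactors = FALSE)
}

# memo of per-graph scenario feature matrices, keyed by the graph's cache id
# (graphs are immutable once constructed); bounded FIFO
.featCache <- new.env(parent = emptyenv())
.featCache$keys <- character(0)

featCacheGet <- function(key) .featCache[[key]]

featCacheSet <- function(key, value) {
  if (is.null(.featCache[[key]])) {
    .featCache$keys <- c(.featCache$keys, key)
    if (length(.featCache$keys) > 60) {
      rm(list = .featCache$keys[1], envir = .featCache)
      .featCache$keys <- .featCache$keys[-1]
    }
  }
  .featCache[[key]] <- value
}

# all 17 catalogue features for every node, for one or several weighting
# scenarios at once (the count-based parts are shared across scenarios).
# Features are computed on the FULL tissue graph. Returns a named list of
# cells x 17 matrices, one per requested scenario.
allScenarioFeatures <- function(tg, scenarios, inverseDistance = TRUE) {
  cid <- igraph::graph_attr(tg@graph, ".cacheId")
  key <- if (!is.null(cid)) paste0(cid, ".", inverseDistance) else NULL
  if (!is.null(key)) {
    hit <- featCacheGet(key)
    if (!is.null(hit) && all(scenarios %in% names(hit)))
      return(hit[scenarios])
    miss <- setdiff(scenarios, names(hit))
    res <- c(hit, computeScenarioFeatures(tg, miss, inverseDistance))
    featCacheSet(key, res)
    return(res[scenarios])
  }
  computeScenarioFeatures(tg, scenarios, inverseDistance)
}

computeScenarioFeatures <- function(tg, scenarios, inverseDistance = TRUE) {
  g <- asIgraph(tg)
  if (!igraph::is_connected(g))
    stopInput("feature computation requires a connected tissue graph")
  ids <- igraph::V(g)$name

  deg0 <- igraph::degree(g)
  tri <- igraph::count_triangles(g)
  egos <- igraph::make_ego_graph(g, order = 2, mindist = 1)
  n2 <- vapply(egos, igraph::vcount, numeric(1))
  e2 <- vapply(egos, igraph::ecount, numeric(1))
  ekey <- apply(igraph::as_edgelist(g), 1, function(r)
    paste(sort(r), collapse = "\r"))
  egoKeys <- lapply(egos, function(h) {
    if (igraph::ecount(h) == 0) return(character(0))
    apply(igraph::as_edgelist(h), 1, function(r) paste(sort(r), collapse = "\r"))
  })

  out <- lapply(scenarios, function(s)
    oneScenarioFeatures(tg, g, s, inverseDistance, ids, deg0, tri, n2, e2,
                        ekey, egoKeys, egos))
  names(out) <- scenarios
  out
}

oneScenarioFeatures <- function(tg, g, scenario, inverseDistance, ids, deg0,
                                tri, n2, e2, ekey, egoKeys, egos) {
  w <- edgeWeights(tg, scenario, inverseDistance)
  len <- 1 / w
  lenOf <- stats::setNames(len, ekey)

  meanPath2 <- vapply(seq_along(egos), function(i) {
    h <- egos[[i]]
    if (igraph::vcount(h) < 2) return(0)
    D <- igraph::distances(h, weights = lenOf[egoKeys[[i]]])
    d <- D[upper.tri(D)]
    d <- d[is.finite(d)]
    if (length(d)) mean(d) else 0
  }, numeric(1))

  # ARPACK draws its starting vector from the RNG; pin it so that feature
  # values are bit-reproducible regardless of ambient RNG state
  evFull <- withSeed(1L, igraph::eigen_centrality(g, weights = w))
  ev <- evFull$vector

  out <- cbind(
    degree = as.numeric(igraph::strength(g, weights = w)),
    clustering = {
      cc <- igraph::transitivity(g, type = "barrat", weights = w, isolates = "zero")
      cc[!is.finite(cc)] <- 0
      cc
    },
    avgNeighborDegree = {
      ann <- igraph::knn(g, weights = w)$knn
      ann[!is.finite(ann)] <- 0
      ann
    },
    harmonic = as.numeric(igraph::harmonic_centrality(g, weights = len,
                                                      normalized = FALSE)),
    closeness = as.numeric(igraph::closeness(g, weights = len,
                                             normalized = FALSE)),
    betweenness = as.numeric(igraph::betweenness(g, weights = len)),
    currentFlowCloseness = as.numeric(currentFlowCloseness(g, w)),
    katz = as.numeric(katzCentrality(g, w, lambdaMax = evFull$value)),
    eigenvector = as.numeric(ev),
    currentFlowBetweenness = as.numeric(currentFlowBetweenness(g, w)),
    nbSize1 = deg0,
    nbAbsDensity1 = ifelse(deg0 > 1, tri / (deg0 * (deg0 - 1) / 2), 0),
    nbRelDensity1 = ifelse(deg0 > 0, 2 * tri / deg0, 0),
    nbSize2 = n2,
    nbAbsDensity2 = ifelse(n2 > 1, 2 * e2 / (n2 * (n2 - 1)), 0),
    nbRelDensity2 = ifelse(n2 > 0, 2 * e2 / n2, 0),
    nbMeanPath2 = meanPath2)
  rownames(out) <- ids
  out
}

scenarioNodeFeatures <- function(tg, scenario, inverseDistance = TRUE) {
  allScenarioFeatures(tg, scenario, inverseDistance)[[scenario]]
}

#' Topological features of one cell
#'
#' Evaluates the full 17-feature catalogue (see \code{\link{featureCatalogue}})
#' for a single cell under one weighting scenario. Features are computed on
#' the full tissue graph, including peripheral cells and cells outside the
#' central region.
#'
#' @param tg a \linkS4class{TissueGraph} (must be connected).
#' @param cell a cell id.
#' @param scenario one of \code{\link{weightScenarios}()}.
#' @param inverseDistance see \code{\link{edgeWeight}}.
#' @return named numeric vector of length 17.
#' @export
nodeFeatures <- function(tg, cell, scenario = "unweighted",
                         inverseDistance = TRUE) {
  cell <- as.character(cell)
  if (!cell %in% cellIds(tg)) stopInput("unknown cell '%s'", cell)
  scenarioNodeFeatures(tg, scenario, inverseDistance)[cell, ]
}

#' Neighborhood-subgraph features of one cell
#'
#' Features of the subgraph induced by all cells within \code{k} hops of the
#' focal cell (the focal cell itself is excluded): node count ("size"),
#' absolute density \code{2E/(N(N-1))}, relative density (mean induced degree,
#' \code{2E/N}) and, for \code{k = 2}, the mean pairwise shortest-path length
#' within the subgraph (edge lengths \code{1/weight}).
#'
#' @inheritParams nodeFeatures
#' @param k neighborhood order, 1 or 2.
#' @return named numeric vector (3 values for k = 1, 4 for k = 2).
#' @export
neighborhoodFeatures <- function(tg, cell, k = 1, scenario = "unweighted",
                                 inverseDistance = TRUE) {
  if (!k %in% c(1, 2)) stopInput("k must be 1 or 2")
  cell <- as.character(cell)
  if (!cell %in% cellIds(tg)) stopInput("unknown cell '%s'", cell)
  f <- scenarioNodeFeatures(tg, scenario, inverseDistance)[cell, ]
  if (k == 1) f[c("nbSize1", "nbAbsDensity1", "nbRelDensity1")]
  else f[c("nbSize2", "nbAbsDensity2", "nbRelDensity2", "nbMeanPath2")]
}

# internal FeatureTable constructor (X: samples x features)
makeFeatureTable <- function(X, rowInfo, colMeta) {
  stopifnot(nrow(rowInfo) == ncol(X), nrow(colMeta) == nrow(X))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X)),
    rowData = S4Vectors::DataFrame(rowInfo, row.names = colnames(X)),
    colData = S4Vectors::DataFrame(colMeta, row.names = rownames(X)))
  methods::new("FeatureTable", se)
}

#' Accessors for FeatureTable objects
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param ... unused.
#' @return \code{featureMatrix}: numeric matrix, samples (cells/pairs) in rows
#'   and features in columns; \code{featureInfo}: data.frame of per-column
#'   provenance; \code{sampleData}: data.frame of per-row metadata.
#' @name FeatureTable-accessors
NULL

#' @rdname FeatureTable-accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(x, ...)
  t(SummarizedExperiment::assay(x, "features")))

#' @rdname FeatureTable-accessors
#' @export
setMethod("featureInfo", "FeatureTable", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname FeatureTable-accessors
#' @export
sampleData <- function(x) as.data.frame(SummarizedExperiment::colData(x))

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d rows x %d feature columns (%s)\n",
              ncol(object), nrow(object),
              paste(unique(SummarizedExperiment::rowData(object)$scope),
                    collapse = ", ")))
})

#' The per-cell feature sets
#'
#' Expands the feature catalogue across weighting scenarios into the named
#' feature sets used for division prediction: \code{unweighted} (17 columns,
#' unweighted scenario only), \code{topo} (17 unweighted + the
#' weight-sensitive features under the area, wall and distance scenarios; 50
#' columns for the default catalogue), \code{area} (the cell surface area
#' alone), and \code{topo+area} (51). The reduced set \code{r<0.3} is obtained
#' by \code{\link{reduceByCorrelation}} on a \code{topo+area} table.
#'
#' @param tg a connected \linkS4class{TissueGraph}; features are computed on
#'   the full graph.
#' @param cells row cells (typically the central non-peripheral cells);
#'   default: all cells.
#' @param featureSet one of \code{"unweighted"}, \code{"topo"}, \code{"area"},
#'   \code{"topo+area"}.
#' @param inverseDistance see \code{\link{edgeWeight}}.
#' @param plant,time row metadata recorded in the table (default: plant NA,
#'   time from the graph).
#' @return a \linkS4class{FeatureTable} with one row per requested cell.
#' @export
cellFeatureTable <- function(tg, cells = NULL,
                             featureSet = c("topo", "unweighted", "area", "topo+area"),
                             inverseDistance = TRUE, plant = NA_character_,
                             time = timeIndex(tg)) {
  featureSet <- match.arg(featureSet)
  cells <- if (is.null(cells)) cellIds(tg) else as.character(cells)
  unknown <- setdiff(cells, cellIds(tg))
  if (length(unknown)) stopInput("unknown cell id(s): %s", paste(unknown, collapse = ", "))

  blocks <- list(); info <- list()
  if (featureSet %in% c("unweighted", "topo", "topo+area")) {
    cat <- featureCatalogue()
    scen <- if (featureSet == "unweighted") "unweighted" else weightScenarios()
    allF <- allScenarioFeatures(tg, scen, inverseDistance)
    for (s in scen) {
      F <- allF[[s]][cells, , drop = FALSE]
      keep <- if (s == "unweighted") cat$name else cat$name[cat$weightSensitive]
      F <- F[, keep, drop = FALSE]
      colnames(F) <- paste0(keep, "@", s)
      blocks[[paste0("scen.", s)]] <- F
      info[[paste0("scen.", s)]] <- data.frame(feature = keep, scenario = s,
                              scope = cat$scope[match(keep, cat$name)],
                              weightRole = cat$weightRole[match(keep, cat$name)])
    }
  }
  if (featureSet %in% c("area", "topo+area")) {
    cd <- cellData(tg)
    ar <- matrix(cd$area[match(cells, cd$id)], ncol = 1,
                 dimnames = list(NULL, "area@bio"))
    blocks$bioArea <- ar
    info$bioArea <- data.frame(feature = "area", scenario = "bio",
                            scope = "biological", weightRole = "none")
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- cells
  makeFeatureTable(X, do.call(rbind, info),
                   data.frame(cell = cells, plant = plant, time = time))
}

#' Correlation-based feature screening
#'
#' Reports, for every candidate column, the Pearson correlation with each
#' reference column, and keeps the candidates whose absolute correlation with
#' every reference stays below the threshold. Zero-variance candidates have
#' undefined correlation and are excluded with a warning. Two-sided p-values
#' accompany the correlation matrix.
#'
#' @param x a \linkS4class{FeatureTable} or a numeric matrix (samples x
#'   columns).
#' @param referenceColumns column names to screen against (e.g.
#'   \code{"area@bio"} for the division task, the six biological pair features
#'   for the rewiring task).
#' @param threshold absolute-correlation cutoff (default 0.3).
#' @return list with \code{kept}, \code{removed} (column names),
#'   \code{correlation} and \code{p} (candidates x references matrices).
#' @export
correlationScreen <- function(x, referenceColumns, threshold = 0.3) {
  X <- if (methods::is(x, "FeatureTable")) featureMatrix(x) else as.matrix(x)
  miss <- setdiff(referenceColumns, colnames(X))
  if (length(miss)) stopInput("missing reference column(s): %s", paste(miss, collapse = ", "))
  cand <- setdiff(colnames(X), referenceColumns)
  sds <- apply(X[, cand, drop = FALSE], 2, stats::sd)
  bad <- cand[sds == 0 | !is.finite(sds)]
  if (length(bad))
    warning(sprintf("excluding zero-variance column(s): %s", paste(bad, collapse = ", ")))
  cand <- setdiff(cand, bad)
  R <- stats::cor(X[, cand, drop = FALSE], X[, referenceColumns, drop = FALSE])
  n <- nrow(X)
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tstat), df = n - 2)
  kept <- cand[apply(abs(R) < threshold, 1, all)]
  list(kept = kept, removed = c(setdiff(cand, kept), bad),
       correlation = R, p = P)
}

#' Reduce a feature table by the correlation screen
#'
#' Applies \code{\link{correlationScreen}} and returns the table restricted to
#' the surviving (non-reference) columns — the \code{r<0.3} feature set when
#' applied to a \code{topo+area} (division task) or topological+biological
#' (rewiring task) table.
#'
#' @inheritParams correlationScreen
#' @param ft a \linkS4class{FeatureTable}.
#' @return a reduced \linkS4class{FeatureTable}.
#' @export
reduceByCorrelation <- function(ft, referenceColumns = "area@bio",
                                threshold = 0.3) {
  scr <- correlationScreen(ft, referenceColumns, threshold)
  subsetFeatureColumns(ft, scr$kept)
}

# internal: restrict a FeatureTable to named columns (i.e. assay rows)
subsetFeatureColumns <- function(ft, columns) {
  keep <- match(columns, rownames(ft))
  if (anyNA(keep)) stopInput("unknown feature column(s)")
  methods::new("FeatureTable", methods::as(ft[keep, ], "SummarizedExperiment"))
}
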