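#' Build a cell-connectivity tissue graph
#'
#' Constructs a \linkS4class{TissueGraph} from per-cell records and shared-wall
#' records, as exported by surface segmentation tools. Two cells are connected
#' by an edge exactly when they share a cell wall.
#'
#' @param cells data.frame with columns \code{id}, \code{x}, \code{y}, \code{z}
#'   (centroid, um), \code{area} (outer surface area, um^2, > 0) and
#'   \code{perimeter} (um, > 0).
#' @param walls data.frame with columns \code{u}, \code{v} and
#'   \code{sharedWall} (shared wall area, um^2, > 0). Each unordered pair may
#'   appear at most once; self-pairs are rejected.
#' @param centerCell id of the tissue-center cell.
#' @param timeIndex integer time-point index (default 0).
#' @return a \linkS4class{TissueGraph}.
#' @examples
#' cells <- data.frame(id = c("a", "b", "c"), x = c(0, 1, 2), y = 0, z = 0,
#'                     area = 10, perimeter = 12)
#' walls <- data.frame(u = c("a", "b"), v = c("b", "c"), sharedWall = 3)
#' tg <- buildTissueGraph(cells, walls, centerCell = "b")
#' @export
buildTissueGraph <- function(cells, walls, centerCell, timeIndex = 0L) {
  cells <- as.data.frame(cells)
  walls <- as.data.frame(walls)
  need <- c("id", "x", "y", "z", "area", "perimeter")
  if (!all(need %in% names(cells)))
    stopInput("cells must have columns %s", paste(need, collapse = ", "))
  if (!all(c("u", "v", "sharedWall") %in% names(walls)))
    stopInput("walls must have columns u, v, sharedWall")
  cells$id <- as.character(cells$id)
  if (anyDuplicated(cells$id)) stopInput("duplicate cell ids")
  if (any(!is.finite(as.matrix(cells[, c("x", "y", "z")]))))
    stopInput("cell centroids must be finite")
  if (any(cells$area <= 0) || any(cells$perimeter <= 0))
    stopInput("cell area and perimeter must be positive")
  u <- as.character(walls$u); v <- as.character(walls$v)
  if (any(u == v)) stopInput("self-adjacency (a cell sharing a wall with itself)")
  unknown <- setdiff(c(u, v), cells$id)
  if (length(unknown))
    stopInput("wall record references unknown cell id(s): %s",
              paste(utils::head(unknown, 5), collapse = ", "))
  key <- paste(pmin(u, v), pmax(u, v))
  if (anyDuplicated(key)) stopInput("duplicate wall record for the same cell pair")
  if (any(!is.finite(walls$sharedWall) | walls$sharedWall <= 0))
    stopInput("shared wall areas must be positive")
  g <- igraph::graph_from_data_frame(
    data.frame(from = u, to = v, sharedWall = walls$sharedWall),
    directed = FALSE,
    vertices = cells[, need])
  newTissueGraph(g, timeIndex, centerCell)
}

# internal: wrap an igraph (already attribute-complete) into a TissueGraph.
# Each graph gets a unique cache id so that expensive per-scenario feature
# matrices can be memoised (graphs are treated as immutable once built).
.tgCounter <- new.env(parent = emptyenv())
.tgCounter$n <- 0L

newTissueGraph <- function(g, timeIndex, centerCell) {
  .tgCounter$n <- .tgCounter$n + 1L
  g <- igraph::set_graph_attr(g, ".cacheId", sprintf("tg%d", .tgCounter$n))
  methods::new("TissueGraph", graph = g, timeIndex = as.integer(timeIndex),
               centerCell = as.character(centerCell))
}

#' Accessors for TissueGraph objects
#'
#' @param x a \linkS4class{TissueGraph}.
#' @return \code{asIgraph}: the underlying igraph; \code{cellIds}: character
#'   vector of cell ids; \code{cellData} / \code{wallData}: data.frames of
#'   per-cell and per-wall attributes; \code{centerCell}, \code{timeIndex}:
#'   the respective slots.
#' @name TissueGraph-accessors
NULL

#' @rdname TissueGraph-accessors
#' @export
setMethod("asIgraph", "TissueGraph", function(x) x@graph)

#' @rdname TissueGraph-accessors
#' @export
setMethod("cellIds", "TissueGraph", function(x) igraph::V(x@graph)$name)

#' @rdname TissueGraph-accessors
#' @export
setMethod("cellData", "TissueGraph", function(x) {
  g <- x@graph
  data.frame(id = igraph::V(g)$name, x = igraph::V(g)$x, y = igraph::V(g)$y,
             z = igraph::V(g)$z, area = igraph::V(g)$area,
             perimeter = igraph::V(g)$perimeter, row.names = NULL)
})

#' @rdname TissueGraph-accessors
#' @export
setMethod("wallData", "TissueGraph", function(x) {
  el <- igraph::as_edgelist(x@graph)
  data.frame(u = el[, 1], v = el[, 2],
             sharedWall = if (nrow(el)) igraph::E(x@graph)$sharedWall else numeric(0))
})

#' @rdname TissueGraph-accessors
#' @export
setMethod("centerCell", "TissueGraph", function(x) x@centerCell)

#' @rdname TissueGraph-accessors
#' @export
setMethod("timeIndex", "TissueGraph", function(x) x@timeIndex)

setMethod("show", "TissueGraph", function(object) {
  cat(sprintf("TissueGraph: %d cells, %d walls, t = %d, center = '%s'\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              object@timeIndex, object@centerCell))
})

#' The four edge-weighting scenarios
#'
#' @return character vector \code{c("unweighted", "area", "wall", "distance")}.
#' @export
weightScenarios <- function() c("unweighted", "area", "wall", "distance")

#' Edge weight under a weighting scenario
#'
#' Computes the weight of the edge between two adjacent cells. Weights encode
#' closeness: a larger weight means the two cells are closer in the topological
#' representation. \code{unweighted}: 1; \code{area}: inverse of the mean of
#' the two cell areas; \code{wall}: inverse of the shared wall area;
#' \code{distance}: inverse Euclidean centroid distance (set
#' \code{inverseDistance = FALSE} for the raw-distance variant).
#'
#' @param scenario one of \code{\link{weightScenarios}()}.
#' @param cellU,cellV lists/rows with \code{area} and centroid \code{x,y,z}.
#' @param sharedWall shared wall area (um^2).
#' @param inverseDistance logical; use 1/distance (default) or the raw distance.
#' @return a positive scalar weight.
#' @export
edgeWeight <- function(scenario, cellU, cellV, sharedWall = NA_real_,
                       inverseDistance = TRUE) {
  scenario <- match.arg(scenario, weightScenarios())
  switch(scenario,
    unweighted = 1,
    area = {
      if (cellU$area <= 0 || cellV$area <= 0) stopInput("cell areas must be positive")
      1 / ((cellU$area + cellV$area) / 2)
    },
    wall = {
      if (is.na(sharedWall) || sharedWall <= 0) stopInput("shared wall must be positive")
      1 / sharedWall
    },
    distance = {
      d <- sqrt((cellU$x - cellV$x)^2 + (cellU$y - cellV$y)^2 + (cellU$z - cellV$z)^2)
      if (d == 0) stopInput("coincident centroids under the distance scenario")
      if (inverseDistance) 1 / d else d
    })
}

#' Edge weights for all walls of a tissue graph
#'
#' @param tg a \linkS4class{TissueGraph}.
#' @inheritParams edgeWeight
#' @return numeric vector of weights aligned with the graph's edges.
#' @export
edgeWeights <- function(tg, scenario, inverseDistance = TRUE) {
  scenario <- match.arg(scenario, weightScenarios())
  g <- asIgraph(tg)
  m <- igraph::ecount(g)
  if (m == 0) return(numeric(0))
  if (scenario == "unweighted") return(rep(1, m))
  el <- igraph::as_edgelist(g, names = FALSE)
  if (scenario == "area") {
    ar <- igraph::V(g)$area
    w <- 2 / (ar[el[, 1]] + ar[el[, 2]])
  } else if (scenario == "wall") {
    w <- 1 / igraph::E(g)$sharedWall
  } else {
    xyz <- cbind(igraph::V(g)$x, igraph::V(g)$y, igraph::V(g)$z)
    d <- sqrt(rowSums((xyz[el[, 1], , drop = FALSE] - xyz[el[, 2], , drop = FALSE])^2))
    if (any(d == 0)) stopInput("coincident centroids under the distance scenario")
    w <- if (inverseDistance) 1 / d else d
  }
  if (any(!is.finite(w) | w <= 0))
    stopInput("scenario '%s' produced non-positive or non-finite weights", scenario)
  w
}

#' Identify peripheral cells
#'
#' A cell is peripheral when the subgraph induced by its neighbors does not
#' close into a ring around it: the neighbors must form a connected subgraph,
#' each with induced degree >= 2, containing a cycle through all of them.
#' Cells with fewer than three neighbors are always peripheral. Peripheral
#' cells sit on the tissue boundary (or next to unsegmented regions) and are
#' excluded from analysis because their neighborhoods are incomplete.
#'
#' @param tg a \linkS4class{TissueGraph}.
#' @param cells cell ids to test (default: all cells).
#' @return named logical vector.
#' @export
isPeripheral <- function(tg, cells = NULL) {
  g <- asIgraph(tg)
  ids <- cellIds(tg)
  cells <- if (is.null(cells)) ids else as.character(cells)
  unknown <- setdiff(cells, ids)
  if (length(unknown)) stopInput("unknown cell id(s): %s", paste(unknown, collapse = ", "))
  res <- vapply(cells, function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) < 3) return(TRUE)
    sub <- igraph::induced_subgraph(g, nb)
    if (!igraph::is_connected(sub)) return(TRUE)
    deg <- igraph::degree(sub)
    if (any(deg < 2)) return(TRUE)
    !hasHamiltonianCycle(igraph::as_adjacency_matrix(sub, sparse = FALSE) > 0)
  }, logical(1))
  names(res) <- cells
  res
}

# exhaustive Hamiltonian-cycle check; epidermal degrees keep n small (<= 12)
hasHamiltonianCycle <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(FALSE)
  visited <- rep(FALSE, n)
  visited[1] <- TRUE
  recurse <- function(v, count) {
    if (count == n) return(adj[v, 1])
    for (u in which(adj[v, ] & !visited)) {
      visited[u] <<- TRUE
      if (recurse(u, count + 1)) return(TRUE)
      visited[u] <<- FALSE
    }
    FALSE
  }
  recurse(1, 1)
}

#' Select the cells of the central zone
#'
#' Returns the ids of cells whose centroid lies within \code{radius}
#' micrometres (closed interval) of the center cell's centroid, optionally with
#' peripheral cells removed. Typical radii are 30 um for the shoot
#' apical meristem and 15 um for floral meristems.
#'
#' @param tg a \linkS4class{TissueGraph}.
#' @param radius zone radius in micrometres (> 0).
#' @param filterPeripheral drop peripheral cells (default TRUE).
#' @return character vector of cell ids.
#' @export
selectCentralCells <- function(tg, radius = 30, filterPeripheral = TRUE) {
  if (!is.finite(radius) || radius <= 0) stopInput("radius must be positive")
  cd <- cellData(tg)
  ctr <- cd[cd$id == centerCell(tg), ]
  if (nrow(ctr) != 1) stopInput("center cell '%s' missing from graph", centerCell(tg))
  d <- sqrt((cd$x - ctr$x)^2 + (cd$y - ctr$y)^2 + (cd$z - ctr$z)^2)
  sel <- cd$id[d <= radius]
  if (filterPeripheral && length(sel)) sel <- sel[!isPeripheral(tg, sel)]
  sel
}

#' Construct a lineage map
#'
#' @param divisions data.frame with columns \code{parent}, \code{daughterA},
#'   \code{daughterB} (daughter A is the daughter nearer the tissue center).
#' @param survivors named character vector: time-t id -> time-t+1 id.
#' @return a \linkS4class{LineageMap}.
#' @export
LineageMap <- function(divisions = data.frame(parent = character(0),
                                              daughterA = character(0),
                                              daughterB = character(0)),
                       survivors = character(0)) {
  divisions <- as.data.frame(divisions)
  for (cl in c("parent", "daughterA", "daughterB"))
    divisions[[cl]] <- as.character(divisions[[cl]])
  survivors <- stats::setNames(as.character(survivors), names(survivors))
  methods::new("LineageMap", divisions = divisions, survivors = survivors)
}

#' Accessors for LineageMap objects
#'
#' @param x a \linkS4class{LineageMap}.
#' @param ids cell ids at time t.
#' @name LineageMap-accessors
NULL

#' @rdname LineageMap-accessors
#' @export
setMethod("divisions", "LineageMap", function(x) x@divisions)

#' @rdname LineageMap-accessors
#' @export
setMethod("survivors", "LineageMap", function(x) x@survivors)

#' @rdname LineageMap-accessors
#' @export
setMethod("isDividing", "LineageMap", function(x, ids)
  stats::setNames(as.character(ids) %in% x@divisions$parent, ids))

setMethod("show", "LineageMap", function(object) {
  cat(sprintf("LineageMap: %d divisions, %d survivors\n",
              nrow(object@divisions), length(object@survivors)))
})

# daughters of a parent, as c(A = ..., B = ...)
lineageDaughters <- function(lineage, parent) {
  d <- lineage@divisions
  i <- match(parent, d$parent)
  if (is.na(i)) stopInput("'%s' is not a dividing cell", parent)
  c(A = d$daughterA[i], B = d$daughterB[i])
}
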