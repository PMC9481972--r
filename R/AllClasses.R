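#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' TissueGraph: one time point's cell-connectivity network
#'
#' A simple undirected graph whose nodes are epidermal cells and whose edges
#' connect cells sharing a cell wall. Vertices carry the cell id (\code{name}),
#' the 3D centroid in micrometres (\code{x}, \code{y}, \code{z}), the outer
#' periclinal surface area (\code{area}, um^2) and the cell perimeter
#' (\code{perimeter}, um); edges carry the shared wall area
#' (\code{sharedWall}, um^2). Graphs predicted by \code{\link{propagateTissue}}
#' are topology-only: their daughter cells have \code{NA} geometry.
#'
#' @slot graph an \pkg{igraph} object holding topology and attributes.
#' @slot timeIndex integer time-point index.
#' @slot centerCell id of the (manually chosen) central cell.
#' @seealso \code{\link{buildTissueGraph}}, \code{\link{selectCentralCells}}
#' @exportClass TissueGraph
setClass("TissueGraph",
  representation(graph = "ANY", timeIndex = "integer", centerCell = "character"))

setValidity("TissueGraph", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("@graph must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (!igraph::is_simple(g)) return("graph must be simple (no loops/multi-edges)")
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyDuplicated(nm)) return("vertices must carry unique cell ids")
  for (a in c("x", "y", "z", "area", "perimeter"))
    if (is.null(igraph::vertex_attr(g, a))) return(sprintf("missing vertex attribute '%s'", a))
  ar <- igraph::V(g)$area
  if (any(!is.na(ar) & ar <= 0)) return("cell areas must be positive")
  pe <- igraph::V(g)$perimeter
  if (any(!is.na(pe) & pe <= 0)) return("cell perimeters must be positive")
  if (igraph::ecount(g) > 0) {
    sw <- igraph::E(g)$sharedWall
    if (is.null(sw)) return("missing edge attribute 'sharedWall'")
    if (any(!is.na(sw) & sw <= 0)) return("shared wall areas must be positive")
  }
  if (length(object@centerCell) != 1 || !(object@centerCell %in% nm))
    return("centerCell must name an existing cell")
  TRUE
})

#' LineageMap: cell correspondence between consecutive time points
#'
#' Records which cells divided between time t and t+1 (parent to daughter pair)
#' and how non-dividing cells map forward (survivors). Daughter 'A' is, by
#' convention, the daughter closer to the tissue center at t+1.
#'
#' @slot divisions data.frame with character columns \code{parent},
#'   \code{daughterA}, \code{daughterB}; each parent appears once.
#' @slot survivors named character vector mapping surviving cell ids at time t
#'   to their ids at time t+1 (injective).
#' @exportClass LineageMap
setClass("LineageMap",
  representation(divisions = "data.frame", survivors = "character"))

setValidity("LineageMap", function(object) {
  d <- object@divisions
  if (!all(c("parent", "daughterA", "daughterB") %in% names(d)))
    return("divisions needs columns parent, daughterA, daughterB")
  if (anyDuplicated(d$parent)) return("a cell may appear as parent at most once")
  s <- object@survivors
  if (length(s) && (is.null(names(s)) || anyDuplicated(names(s))))
    return("survivors must be uniquely named by time-t cell id")
  if (anyDuplicated(s[nzchar(s)])) return("survivor mapping must be injective")
  if (any(d$parent %in% names(s))) return("a parent cannot also be a survivor")
  TRUE
})

#' FeatureTable: feature-by-cell matrix with provenance
#'
#' A \linkS4class{SummarizedExperiment} whose single assay holds feature values
#' (rows = features, columns = cells or neighbor-parent pairs). \code{rowData}
#' records each feature's provenance (\code{feature}, \code{scenario},
#' \code{scope}, \code{weightRole}); \code{colData} carries the row metadata
#' (cell/pair ids, plant, time and, for labeled datasets, \code{label}).
#' Use \code{\link{featureMatrix}} to obtain the samples-by-features matrix
#' used for classification.
#'
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  a <- SummarizedExperiment::assay(object)
  if (!is.numeric(a)) return("assay must be numeric")
  if (any(!is.finite(a))) return("feature values must be finite")
  if (!all(c("feature", "scenario", "scope") %in%
           names(SummarizedExperiment::rowData(object))))
    return("rowData must record feature, scenario and scope")
  TRUE
})

#' LinearTissueClassifier: trained linear max-margin model
#'
#' A linear support-vector classifier together with the z-normalization
#' statistics of its training data, the class-weight scheme and the selected
#' regularization constant C. Binary models (division events, classes -1/+1)
#' store a single weight vector; the 3-class rewiring model stores one
#' one-vs-rest weight vector per class. The decision rule is
#' sign(w . x_normalized + b) (binary) or argmax of the per-class decision
#' values (multiclass).
#'
#' @slot featureNames character, training column names (order matters).
#' @slot center,scale numeric, per-column z-normalization statistics.
#' @slot weights numeric matrix, features x classes.
#' @slot intercepts numeric, one per class column.
#' @slot classes character class labels (binary: c("-1","1")).
#' @slot cost selected regularization constant C.
#' @slot classWeights named numeric, weights used during training.
#' @slot featureSet name of the feature set the model was trained on.
#' @exportClass LinearTissueClassifier
setClass("LinearTissueClassifier",
  representation(featureNames = "character", center = "numeric", scale = "numeric",
                 weights = "matrix", intercepts = "numeric", classes = "character",
                 cost = "numeric", classWeights = "numeric", featureSet = "character"))

setValidity("LinearTissueClassifier", function(object) {
  p <- length(object@featureNames)
  if (nrow(object@weights) != p) return("weights rows must match featureNames")
  if (length(object@center) != p || length(object@scale) != p)
    return("normalization statistics must match featureNames")
  k <- ncol(object@weights)
  if (length(object@intercepts) != k) return("one intercept per class column")
  if (length(object@classes) < 2) return("need at least two classes")
  if (length(object@classes) == 2 && k != 1)
    return("binary model stores a single weight column")
  if (length(object@classes) > 2 && k != length(object@classes))
    return("multiclass model stores one column per class")
  if (any(object@scale <= 0)) return("scale must be positive")
  TRUE
})

#' PropagationResult: predicted next-time-point topology
#'
#' Output of \code{\link{propagateTissue}}: the predicted tissue graph
#' (topology only; daughters carry no geometry), the mapping from time-t cells
#' to their surviving node or daughter pair, and the predicted neighbor classes
#' for every executed division.
#'
#' @slot graph predicted \linkS4class{TissueGraph}.
#' @slot nodeMap named list: time-t cell id -> character vector of length 1
#'   (survivor) or 2 (daughters A, B).
#' @slot divisionClasses named list: parent id -> named integer vector of
#'   predicted classes (0/1/2) per time-t neighbor.
#' @slot seed integer seed that fixed the division processing order.
#' @exportClass PropagationResult
setClass("PropagationResult",
  representation(graph = "TissueGraph", nodeMap = "list",
                 divisionClasses = "list", seed = "integer"))

setValidity("PropagationResult", function(object) {
  len <- lengths(object@nodeMap)
  if (any(len < 1 | len > 2)) return("nodeMap entries must have length 1 or 2")
  nDiv <- sum(len == 2)
  if (length(object@divisionClasses) != nDiv)
    return("one class vector per division")
  TRUE
})

#' TissueSeries: a simulated growing tissue
#'
#' A time series of synthetic tissues: per-step \linkS4class{TissueGraph}s with
#' matching polygon geometry, the \linkS4class{LineageMap} of every transition,
#' and the ground-truth neighbor rewiring classes derived from the geometry.
#'
#' @slot graphs list of \linkS4class{TissueGraph}, one per time point.
#' @slot polygons list (per time point) of named lists of vertex matrices.
#' @slot lineages list of \linkS4class{LineageMap}, one per transition.
#' @slot pairClasses list (per transition) of data.frames with columns
#'   \code{parent}, \code{neighbor}, \code{label}.
#' @slot params the \code{\link{simParams}} list used.
#' @slot seed integer seed.
#' @exportClass TissueSeries
setClass("TissueSeries",
  representation(graphs = "list", polygons = "list", lineages = "list",
                 pairClasses = "list", params = "list", seed = "integer"))

setValidity("TissueSeries", function(object) {
  if (length(object@graphs) != length(object@lineages) + 1L)
    return("need one more graph than lineage maps")
  if (length(object@pairClasses) != length(object@lineages))
    return("one pair-class table per transition")
  TRUE
})
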