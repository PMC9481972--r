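# ---- polygon helpers ------------------------------------------------------
# polygons are 2-column vertex matrices (closed implicitly), convex by
# construction: Voronoi tiles of a disk, split recursively by straight chords

polyArea <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polyPerimeter <- function(P) {
  d <- P - P[c(2:nrow(P), 1), ]
  sum(sqrt(rowSums(d^2)))
}

polyCentroid <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(P))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# total length of shared boundary between two convex polygons: sum of
# collinear overlaps between their edges (tolerance in um)
sharedBoundaryLength <- function(P, Q, tol = 1e-6) {
  total <- 0
  nP <- nrow(P); nQ <- nrow(Q)
  Qn <- Q[c(2:nQ, 1), , drop = FALSE]
  for (i in seq_len(nP)) {
    a1 <- P[i, ]; a2 <- P[if (i == nP) 1 else i + 1, ]
    u <- a2 - a1; L <- sqrt(sum(u^2))
    if (L < tol) next
    u <- u / L
    r1x <- Q[, 1] - a1[1]; r1y <- Q[, 2] - a1[2]
    r2x <- Qn[, 1] - a1[1]; r2y <- Qn[, 2] - a1[2]
    col <- abs(u[1] * r1y - u[2] * r1x) <= tol &
           abs(u[1] * r2y - u[2] * r2x) <= tol
    if (!any(col)) next
    t1 <- r1x[col] * u[1] + r1y[col] * u[2]
    t2 <- r2x[col] * u[1] + r2y[col] * u[2]
    ov <- pmin(L, pmax(t1, t2)) - pmax(0, pmin(t1, t2))
    total <- total + sum(ov[ov > 0])
  }
  total
}

# split a convex polygon by the chord through `point` with direction angle
# `theta`; returns list(left, right) or NULL when degenerate
splitConvexPolygon <- function(P, point, theta) {
  dir <- c(cos(theta), sin(theta))
  nrm <- c(-dir[2], dir[1])
  s <- as.numeric((P - matrix(point, nrow(P), 2, byrow = TRUE)) %*% nrm)
  n <- nrow(P)
  left <- list(); right <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (s[i] >= 0) left[[length(left) + 1]] <- P[i, ]
    if (s[i] <= 0) right[[length(right) + 1]] <- P[i, ]
    if (s[i] * s[j] < 0) {
      t <- s[i] / (s[i] - s[j])
      X <- P[i, ] + t * (P[j, ] - P[i, ])
      left[[length(left) + 1]] <- X
      right[[length(right) + 1]] <- X
    }
  }
  A <- do.call(rbind, left); B <- do.call(rbind, right)
  if (is.null(A) || is.null(B) || nrow(A) < 3 || nrow(B) < 3) return(NULL)
  if (polyArea(A) < 1e-9 || polyArea(B) < 1e-9) return(NULL)
  list(A, B)
}

# chord length of the line through `point` at angle `theta` inside convex P
chordLength <- function(P, point, theta) {
  nrm <- c(-sin(theta), cos(theta))
  s <- (P[, 1] - point[1]) * nrm[1] + (P[, 2] - point[2]) * nrm[2]
  sn <- c(s[-1], s[1])
  cross <- which(s * sn < 0)
  if (length(cross) != 2) return(NA_real_)
  pts <- vapply(cross, function(i) {
    j <- if (i == nrow(P)) 1 else i + 1
    t <- s[i] / (s[i] - s[j])
    P[i, ] + t * (P[j, ] - P[i, ])
  }, numeric(2))
  sqrt(sum((pts[, 1] - pts[, 2])^2))
}

# shortest straight wall through the centroid (ties by smaller angle)
shortestWallSplit <- function(P, nAngles = 90) {
  ctr <- polyCentroid(P)
  angles <- seq(0, pi, length.out = nAngles + 1)[-(nAngles + 1)]
  lens <- vapply(angles, function(th) chordLength(P, ctr, th), numeric(1))
  ord <- order(lens, angles)
  for (k in ord) {
    sp <- splitConvexPolygon(P, ctr, angles[k])
    if (!is.null(sp)) return(sp)
  }
  stopInput("polygon split failed for every candidate wall")
}

# ---- tissue construction --------------------------------------------------

# adjacency + attributes from a named list of polygons
polygonsToTissueGraph <- function(polys, timeIndex = 0L, centerId = NULL,
                                  minWall = 1e-6) {
  ids <- names(polys)
  n <- length(ids)
  ctr <- t(vapply(polys, polyCentroid, numeric(2)))
  rad <- vapply(seq_len(n), function(i) {
    P <- polys[[i]]
    sqrt(max(rowSums((P - matrix(ctr[i, ], nrow(P), 2, byrow = TRUE))^2)))
  }, numeric(1))
  cells <- data.frame(id = ids, x = ctr[, 1], y = ctr[, 2], z = 0,
                      area = vapply(polys, polyArea, numeric(1)),
                      perimeter = vapply(polys, polyPerimeter, numeric(1)))
  D <- as.matrix(stats::dist(ctr))
  lim <- outer(rad, rad, "+") * 1.001
  cand <- which(upper.tri(D) & D <= lim, arr.ind = TRUE)
  sw <- vapply(seq_len(nrow(cand)), function(k)
    sharedBoundaryLength(polys[[cand[k, 1]]], polys[[cand[k, 2]]]),
    numeric(1))
  keep <- sw > minWall
  walls <- data.frame(u = ids[cand[keep, 1]], v = ids[cand[keep, 2]],
                      sharedWall = sw[keep])
  if (is.null(centerId))
    centerId <- ids[which.min(rowSums(ctr^2))]
  buildTissueGraph(cells, walls, centerCell = centerId, timeIndex = timeIndex)
}

#' Simulation parameters for the synthetic tissue generator
#'
#' Defaults emulate the tissue statistics the analysis assumes: a planar
#' tissue of a few hundred cells with mean interior degree about 6, roughly
#' 29 percent of central-zone cells dividing per 24 h step, and a
#' division propensity rising with cell area and harmonic centrality. The
#' division rule is logistic: p = plogis(beta0 + betaArea * z(area) +
#' betaTopo * z(harmonic)), with z-scores taken over the tissue at each step,
#' which makes the rule invariant to tissue dilation. beta0 is a build-time
#' calibration constant fixing the central-zone division fraction at the
#' observed 28.9 percent per step; betaArea and betaTopo set the planted
#' signal strength, chosen so division predictability sits at the level the
#' tissue-scale analysis reports (about three quarters of events).
#'
#' @param nCellsInit initial cell count (>= 20).
#' @param diskRadius tissue radius, um.
#' @param growthMean,growthSd mean and s.d. (log scale) of the per-step
#'   multiplicative tissue area growth.
#' @param beta0,betaArea,betaTopo division-rule coefficients.
#' @param steps number of 24 h steps to simulate.
#' @param centralRadius central-zone radius, um.
#' @param lloydIterations Lloyd relaxation sweeps of the initial tessellation.
#' @param wallRule wall placement rule id (only \code{"shortest"} is
#'   implemented: shortest straight wall through the centroid).
#' @param seed integer seed (mandatory for the simulation entry points).
#' @return named list of parameters.
#' @export
simParams <- function(nCellsInit = 220, diskRadius = 60,
                      growthMean = 1.28, growthSd = 0.05,
                      beta0 = -1.97, betaArea = 1.5, betaTopo = 1.0,
                      steps = 4, centralRadius = 30, lloydIterations = 3,
                      wallRule = "shortest", seed = 1L) {
  stopifnot(nCellsInit >= 20, diskRadius > 0, steps >= 1)
  if (wallRule != "shortest") stopInput("unknown wall rule '%s'", wallRule)
  list(nCellsInit = nCellsInit, diskRadius = diskRadius,
       growthMean = growthMean, growthSd = growthSd, beta0 = beta0,
       betaArea = betaArea, betaTopo = betaTopo, steps = steps,
       centralRadius = centralRadius, lloydIterations = lloydIterations,
       wallRule = wallRule, seed = as.integer(seed))
}

diskPolygon <- function(R, n = 128) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(x = R * cos(th), y = R * sin(th))
}

voronoiPolygons <- function(pts, R) {
  rw <- c(-R, R, -R, R) * 1.05
  dd <- deldir::deldir(pts[, 1], pts[, 2], rw = rw, suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  disk <- diskPolygon(R)
  lapply(tl, function(tile) {
    cl <- polyclip::polyclip(list(x = tile$x, y = tile$y), disk,
                             op = "intersection")
    if (!length(cl)) return(NULL)
    cbind(cl[[1]]$x, cl[[1]]$y)
  })
}

#' Generate the initial synthetic tissue
#'
#' Lloyd-relaxed Voronoi tessellation of a disk. Cell attributes derive from
#' the polygon geometry: polygon area stands in for the outer surface area,
#' polygon perimeter for the cell perimeter, the polygon centroid (z = 0) for
#' the cell centroid and the shared boundary length for the shared wall.
#' The center cell is the cell nearest the origin.
#'
#' @param params a \code{\link{simParams}} list.
#' @param seed integer seed (default: \code{params$seed}).
#' @return list with \code{polygons} (named list of vertex matrices) and
#'   \code{graph} (a \linkS4class{TissueGraph}).
#' @export
generateInitialTissue <- function(params = simParams(), seed = params$seed) {
  R <- params$diskRadius
  n <- params$nCellsInit
  for (try in 0:4) {
    pts <- withSeed(deriveSeed(seed, try), {
      r <- R * sqrt(stats::runif(n))
      a <- stats::runif(n, 0, 2 * pi)
      cbind(r * cos(a), r * sin(a))
    })
    ok <- TRUE
    for (it in seq_len(params$lloydIterations)) {
      polys <- voronoiPolygons(pts, R)
      if (any(vapply(polys, is.null, logical(1)))) { ok <- FALSE; break }
      pts <- t(vapply(polys, polyCentroid, numeric(2)))
    }
    if (!ok) { message("degenerate tessellation; regenerating with perturbed seed"); next }
    polys <- voronoiPolygons(pts, R)
    if (any(vapply(polys, is.null, logical(1)))) { ok <- FALSE; next }
    names(polys) <- as.character(seq_len(n))
    return(list(polygons = polys,
                graph = polygonsToTissueGraph(polys, timeIndex = 0L)))
  }
  stopInput("failed to generate a non-degenerate tessellation")
}

#' Advance the synthetic tissue by one 24 h step
#'
#' Dilates the tissue by a noisy multiplicative growth factor, draws division
#' events from the logistic size-and-centrality rule, splits each dividing
#' cell by the shortest straight wall through its centroid (ties broken by
#' angle), recomputes the daughters' adjacency geometrically and derives the
#' ground-truth neighbor rewiring classes. Daughter 'A' is the daughter
#' nearer the new tissue center.
#'
#' @param tissue list with \code{polygons} and \code{graph} (as produced by
#'   \code{\link{generateInitialTissue}} or a previous step).
#' @param params a \code{\link{simParams}} list.
#' @param seed integer seed for this step.
#' @return list with \code{tissue} (next-step polygons + graph),
#'   \code{lineage} (\linkS4class{LineageMap}) and \code{pairClasses}
#'   (data.frame parent, neighbor, label, neighborDivides).
#' @export
stepTissue <- function(tissue, params, seed) {
  tg <- tissue$graph
  polys <- tissue$polygons
  ids <- names(polys)
  cd <- cellData(tg)
  harm <- as.numeric(igraph::harmonic_centrality(asIgraph(tg), normalized = FALSE))
  zA <- as.numeric(scale(cd$area[match(ids, cd$id)]))
  zH <- as.numeric(scale(harm[match(ids, cellIds(tg))]))
  p <- stats::plogis(params$beta0 + params$betaArea * zA + params$betaTopo * zH)

  rng <- withSeed(seed, list(growth = stats::rnorm(1, log(params$growthMean),
                                                   params$growthSd),
                             u = stats::runif(length(ids))))
  scaleF <- sqrt(exp(rng$growth))
  polys <- lapply(polys, function(P) P * scaleF)
  dividers <- ids[rng$u < p]

  nextId <- max(as.integer(ids))
  newPolys <- list()
  divTab <- list()
  for (id in ids) {
    if (id %in% dividers) {
      sp <- shortestWallSplit(polys[[id]])
      d1 <- as.character(nextId + 1); d2 <- as.character(nextId + 2)
      nextId <- nextId + 2
      newPolys[[d1]] <- sp[[1]]; newPolys[[d2]] <- sp[[2]]
      divTab[[id]] <- c(d1, d2)
    } else {
      newPolys[[id]] <- polys[[id]]
    }
  }
  tgNext <- polygonsToTissueGraph(newPolys, timeIndex = timeIndex(tg) + 1L)

  # daughter A = nearer the new tissue center (tie: smaller id)
  cdN <- cellData(tgNext)
  ctrI <- match(centerCell(tgNext), cdN$id)
  ctr <- c(cdN$x[ctrI], cdN$y[ctrI], cdN$z[ctrI])
  divisions <- do.call(rbind, lapply(names(divTab), function(par) {
    d <- divTab[[par]]
    i <- match(d, cdN$id)
    dist <- sqrt((cdN$x[i] - ctr[1])^2 + (cdN$y[i] - ctr[2])^2)
    ord <- order(dist, d)
    data.frame(parent = par, daughterA = d[ord[1]], daughterB = d[ord[2]])
  }))
  if (is.null(divisions))
    divisions <- data.frame(parent = character(0), daughterA = character(0),
                            daughterB = character(0))
  surv <- setdiff(ids, divisions$parent)
  lineage <- LineageMap(divisions, stats::setNames(surv, surv))

  pairs <- enumeratePairs(tg, lineage, includeDividingNeighbors = TRUE)
  pairClasses <- if (nrow(pairs)) {
    pairs$label <- labelPairClasses(pairs, tgNext, lineage)
    pairs
  } else cbind(pairs, label = integer(0))

  list(tissue = list(polygons = newPolys, graph = tgNext),
       lineage = lineage, pairClasses = pairClasses)
}

#' Simulate a growing, dividing tissue series
#'
#' Iterates \code{\link{stepTissue}} from a fresh initial tissue, collecting
#' per-step graphs, polygon geometry, lineage maps and ground-truth rewiring
#' classes.
#'
#' @param params a \code{\link{simParams}} list (its \code{seed} drives all
#'   randomness).
#' @return a \linkS4class{TissueSeries}.
#' @export
simulateSeries <- function(params = simParams()) {
  params$seed <- as.integer(params$seed)
  tis <- generateInitialTissue(params)
  graphs <- list(tis$graph)
  polys <- list(tis$polygons)
  lineages <- list()
  pairClasses <- list()
  for (s in seq_len(params$steps)) {
    st <- stepTissue(tis, params, seed = deriveSeed(params$seed, 1000 + s))
    tis <- st$tissue
    graphs[[s + 1]] <- tis$graph
    polys[[s + 1]] <- tis$polygons
    lineages[[s]] <- st$lineage
    pairClasses[[s]] <- st$pairClasses
  }
  methods::new("TissueSeries", graphs = graphs, polygons = polys,
               lineages = lineages, pairClasses = pairClasses,
               params = params, seed = params$seed)
}

#' Accessors for TissueSeries objects
#' @param x a \linkS4class{TissueSeries}.
#' @name TissueSeries-accessors
NULL

#' @rdname TissueSeries-accessors
#' @export
setMethod("tissueGraphs", "TissueSeries", function(x) x@graphs)

#' @rdname TissueSeries-accessors
#' @export
setMethod("lineageMaps", "TissueSeries", function(x) x@lineages)

setMethod("show", "TissueSeries", function(object) {
  cat(sprintf("TissueSeries: %d time points, %d -> %d cells (seed %d)\n",
              length(object@graphs),
              igraph::vcount(asIgraph(object@graphs[[1]])),
              igraph::vcount(asIgraph(object@graphs[[length(object@graphs)]])),
              object@seed))
})

#' Write a tissue series to disk
#'
#' Emits one graph JSON per time point, one lineage CSV per transition and a
#' manifest (JSON) holding the parameters and seed; a series regenerated from
#' the manifest via \code{simulateSeries(manifestParams(dir))} is identical.
#'
#' @param series a \linkS4class{TissueSeries}.
#' @param dir output directory (created if needed).
#' @export
writeTissueSeries <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(series@graphs))
    writeTissueGraph(series@graphs[[i]],
                     file.path(dir, sprintf("graph_t%d.json", i - 1)))
  for (i in seq_along(series@lineages))
    writeLineageMap(series@lineages[[i]],
                    file.path(dir, sprintf("lineage_t%d.csv", i - 1)))
  jsonlite::write_json(series@params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeTissueSeries
#' @return \code{manifestParams}: the \code{\link{simParams}} list stored in
#'   a series directory's manifest.
#' @export
manifestParams <- function(dir) {
  m <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  do.call(simParams, m)
}

#' Simulate a cohort of plants
#'
#' Runs \code{\link{simulateSeries}} once per plant with derived seeds,
#' yielding the multi-plant data the plant-wise cross-validation design
#' needs.
#'
#' @param params shared \code{\link{simParams}}.
#' @param nPlants number of plants.
#' @param seed cohort seed.
#' @return named list of \linkS4class{TissueSeries} ("plant1", ...).
#' @export
simulateCohort <- function(params = simParams(), nPlants = 5, seed = 1) {
  out <- lapply(seq_len(nPlants), function(i) {
    pi <- params; pi$seed <- deriveSeed(seed, 5000 + i)
    simulateSeries(pi)
  })
  names(out) <- paste0("plant", seq_len(nPlants))
  out
}

# ---- dataset assembly -----------------------------------------------------

#' Assemble the labeled division dataset from a cohort
#'
#' For every plant and transition, computes the chosen feature set on the full
#' time-t graph, restricts rows to the central non-peripheral cells and labels
#' them +1/-1 from the lineage.
#'
#' @param cohort named list of \linkS4class{TissueSeries} (names = plant ids).
#' @param featureSet see \code{\link{cellFeatureTable}}.
#' @param radius central-zone radius, um.
#' @param inverseDistance see \code{\link{edgeWeight}}.
#' @param transitions indices of the t -> t+1 transitions to use (default:
#'   all).
#' @return a labeled \linkS4class{FeatureTable}.
#' @export
assembleDivisionDataset <- function(cohort, featureSet = "topo+area",
                                    radius = 30, inverseDistance = TRUE,
                                    transitions = NULL) {
  Xs <- list(); metas <- list(); rowInfo <- NULL
  for (pl in names(cohort)) {
    ser <- cohort[[pl]]
    trans <- transitions %||% seq_along(ser@lineages)
    for (t in intersect(trans, seq_along(ser@lineages))) {
      tg <- ser@graphs[[t]]
      cells <- selectCentralCells(tg, radius)
      if (!length(cells)) next
      ft <- cellFeatureTable(tg, cells, featureSet = featureSet,
                             inverseDistance = inverseDistance,
                             plant = pl, time = t - 1L)
      X <- featureMatrix(ft)
      rownames(X) <- paste(pl, t - 1L, cells, sep = ":")
      Xs[[length(Xs) + 1]] <- X
      meta <- sampleData(ft)
      meta$label <- as.character(labelDivisions(tg, ser@lineages[[t]], cells))
      metas[[length(metas) + 1]] <- meta
      if (is.null(rowInfo)) rowInfo <- featureInfo(ft)
    }
  }
  if (!length(Xs)) stopInput("cohort produced no central cells")
  makeFeatureTable(do.call(rbind, Xs), rowInfo, do.call(rbind, metas))
}

#' Assemble the labeled neighbor-parent pair dataset from a cohort
#'
#' Enumerates, per plant and transition, the neighbor-parent pairs of central
#' non-peripheral dividing cells, labels them 0/1/2 from the observed t+1
#' graph and computes the chosen pair feature set on the time-t graph.
#' Exact-duplicate and zero-variance feature columns are dropped at assembly
#' (with a message recording the final width).
#'
#' @inheritParams assembleDivisionDataset
#' @param featureSet see \code{\link{pairFeatureTable}}.
#' @param includeDividingNeighbors keep pairs whose neighbor also divides.
#' @param dropDegenerate drop duplicate/zero-variance columns (default TRUE).
#' @return a labeled pair \linkS4class{FeatureTable}.
#' @export
assemblePairDataset <- function(cohort, featureSet = "topo+bio", radius = 30,
                                includeDividingNeighbors = FALSE,
                                inverseDistance = TRUE, dropDegenerate = TRUE,
                                transitions = NULL) {
  Xs <- list(); metas <- list(); rowInfo <- NULL
  for (pl in names(cohort)) {
    ser <- cohort[[pl]]
    trans <- transitions %||% seq_along(ser@lineages)
    for (t in intersect(trans, seq_along(ser@lineages))) {
      tg <- ser@graphs[[t]]
      lin <- ser@lineages[[t]]
      parents <- selectCentralCells(tg, radius)
      pairs <- enumeratePairs(tg, lin, includeDividingNeighbors, parents)
      if (!nrow(pairs)) next
      labels <- labelPairClasses(pairs, ser@graphs[[t + 1]], lin)
      ft <- pairFeatureTable(tg, pairs, featureSet = featureSet,
                             inverseDistance = inverseDistance,
                             labels = labels, plant = pl, time = t - 1L)
      X <- featureMatrix(ft)
      rownames(X) <- paste(pl, t - 1L, rownames(X), sep = ":")
      Xs[[length(Xs) + 1]] <- X
      metas[[length(metas) + 1]] <- sampleData(ft)
      if (is.null(rowInfo)) rowInfo <- featureInfo(ft)
    }
  }
  if (!length(Xs)) stopInput("cohort produced no neighbor-parent pairs")
  X <- do.call(rbind, Xs)
  if (dropDegenerate) {
    sds <- apply(X, 2, stats::sd)
    dup <- duplicated(t(X))
    drop <- sds == 0 | dup
    if (any(drop)) {
      message(sprintf("dropping %d degenerate pair column(s); %d remain",
                      sum(drop), sum(!drop)))
      X <- X[, !drop, drop = FALSE]
      rowInfo <- rowInfo[!drop, , drop = FALSE]
    }
  }
  makeFeatureTable(X, rowInfo, do.call(rbind, metas))
}
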