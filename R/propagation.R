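# core graph-rewriting step shared by model propagation and the random
# baseline: divide the given parents in seeded random order, daughters A/B
# adjacent, each former neighbor reconnected per its class (0 -> A, 1 -> B,
# 2 -> both). A neighbor that divided earlier in the sequence is represented
# by whichever of its daughters inherited the adjacency; each representative
# is rewired according to the processed parent's class for the original
# neighbor.
rewireTissue <- function(tg, classList, seed) {
  g <- asIgraph(tg)
  igraph::V(g)$origin <- igraph::V(g)$name
  parents <- names(classList)
  missing <- setdiff(parents, igraph::V(g)$name)
  if (length(missing)) stopInput("divider(s) not in graph: %s",
                                 paste(missing, collapse = ", "))
  order <- withSeed(seed, sample(seq_along(parents)))
  for (k in order) {
    p <- parents[k]
    cls <- classList[[k]]
    nA <- paste0(p, ".A"); nB <- paste0(p, ".B")
    if (any(c(nA, nB) %in% igraph::V(g)$name))
      stopInput("daughter id collision for parent '%s'", p)
    nbIdx <- igraph::neighbors(g, p)
    nbName <- igraph::V(g)$name[nbIdx]
    nbOrigin <- igraph::V(g)$origin[nbIdx]
    nbClass <- cls[nbOrigin]
    if (anyNA(nbClass))
      stopInput("no class prediction for neighbor(s) of '%s': %s", p,
                paste(unique(nbOrigin[is.na(nbClass)]), collapse = ", "))
    g <- igraph::add_vertices(g, 2, name = c(nA, nB),
                              origin = c(p, p),
                              x = NA_real_, y = NA_real_, z = NA_real_,
                              area = NA_real_, perimeter = NA_real_)
    newEdges <- c(nA, nB)
    for (i in seq_along(nbName)) {
      tgt <- switch(as.character(nbClass[i]),
                    "0" = nA, "1" = nB, "2" = c(nA, nB),
                    stopInput("invalid class %s", nbClass[i]))
      newEdges <- c(newEdges, as.vector(rbind(nbName[i], tgt)))
    }
    g <- igraph::add_edges(g, newEdges, sharedWall = NA_real_)
    g <- igraph::delete_vertices(g, p)
  }
  g
}

#' Propagate a tissue graph one time step forward
#'
#' Applies the division classifier to the central non-peripheral cells, then
#' rewrites the graph: every predicted divider is removed and replaced by two
#' adjacent daughters A (semantically the daughter nearer the tissue center)
#' and B, and each former neighbor is reconnected according to the rewiring
#' classifier's predicted class for that neighbor-parent pair (0: A only,
#' 1: B only, 2: both). All pair features are computed on the time-t graph;
#' predicted dividers are processed in seeded random order. Daughters carry no
#' geometry, so the predicted graph supports unweighted features only. A
#' single forward step (one 24 h interval) is produced; longer horizons would
#' require forecasting the biological attributes.
#'
#' @param tg the time-t \linkS4class{TissueGraph} (attribute-complete).
#' @param divisionModel binary \linkS4class{LinearTissueClassifier}.
#' @param pairModel 3-class \linkS4class{LinearTissueClassifier}.
#' @param seed integer seed fixing the processing order.
#' @param radius central-zone radius in um (default 30).
#' @param inverseDistance see \code{\link{edgeWeight}}.
#' @return a \linkS4class{PropagationResult}.
#' @export
propagateTissue <- function(tg, divisionModel, pairModel, seed = 1,
                            radius = 30, inverseDistance = TRUE) {
  central <- selectCentralCells(tg, radius)
  if (!length(central)) stopInput("no central non-peripheral cells")
  divFT <- cellFeatureTable(tg, central, featureSet = "topo+area",
                            inverseDistance = inverseDistance)
  dividers <- central[predict(divisionModel, divFT) == "1"]

  classList <- list()
  if (length(dividers)) {
    g <- asIgraph(tg)
    pairs <- do.call(rbind, lapply(dividers, function(p) {
      nb <- igraph::V(g)$name[igraph::neighbors(g, p)]
      data.frame(parent = p, neighbor = nb)
    }))
    pairFT <- pairFeatureTable(tg, pairs, featureSet = "topo+bio",
                               inverseDistance = inverseDistance)
    cls <- predict(pairModel, pairFT)
    classList <- lapply(dividers, function(p) {
      i <- pairs$parent == p
      stats::setNames(as.integer(cls[i]), pairs$neighbor[i])
    })
    names(classList) <- dividers
  }

  gNew <- rewireTissue(tg, classList, seed)
  ctr <- centerCell(tg)
  newCenter <- if (ctr %in% names(classList)) paste0(ctr, ".A") else ctr
  out <- newTissueGraph(gNew, timeIndex(tg) + 1L, newCenter)

  nodeMap <- lapply(cellIds(tg), function(v)
    if (v %in% names(classList)) c(paste0(v, ".A"), paste0(v, ".B")) else v)
  names(nodeMap) <- cellIds(tg)
  methods::new("PropagationResult", graph = out, nodeMap = nodeMap,
               divisionClasses = classList, seed = as.integer(seed))
}

setMethod("show", "PropagationResult", function(object) {
  cat(sprintf("PropagationResult: %d divisions -> %d cells (seed %d)\n",
              length(object@divisionClasses),
              igraph::vcount(asIgraph(object@graph)), object@seed))
})

# cells non-dividing in BOTH the predicted and the observed topology,
# as (time-t id, observed t+1 id) pairs
coNonDividingCells <- function(nodeMap, lineage) {
  surv <- survivors(lineage)
  keep <- names(nodeMap)[lengths(nodeMap) == 1]
  keep <- intersect(keep, names(surv))
  data.frame(old = keep, observed = unname(surv[keep]))
}

#' Compare a predicted topology with the observed one
#'
#' Restricted to the cells that divide in neither topology, computes the 17
#' unweighted topological features on the full predicted and observed graphs
#' and returns the per-feature Pearson correlation together with the best
#' linear fit. Only the unweighted scenario is used: predicted daughters have
#' no geometry from which weighted scenarios could be formed.
#'
#' @param predicted a \linkS4class{PropagationResult} (or a list with
#'   \code{graph} and \code{nodeMap}).
#' @param observed the observed t+1 \linkS4class{TissueGraph}.
#' @param lineage the observed \linkS4class{LineageMap} for t -> t+1.
#' @return list with \code{perFeature} (data.frame: feature, r, slope,
#'   intercept) and \code{n} (number of co-non-dividing cells).
#' @export
compareTopologies <- function(predicted, observed, lineage) {
  nodeMap <- if (methods::is(predicted, "PropagationResult"))
    predicted@nodeMap else predicted$nodeMap
  gPred <- if (methods::is(predicted, "PropagationResult"))
    predicted@graph else predicted$graph
  common <- coNonDividingCells(nodeMap, lineage)
  common <- common[common$old %in% cellIds(gPred) &
                   common$observed %in% cellIds(observed), , drop = FALSE]
  if (nrow(common) < 3) stopInput("fewer than 3 co-non-dividing cells")
  Fp <- scenarioNodeFeatures(gPred, "unweighted")[common$old, , drop = FALSE]
  Fo <- scenarioNodeFeatures(observed, "unweighted")[common$observed, , drop = FALSE]
  perFeature <- do.call(rbind, lapply(colnames(Fp), function(f) {
    xo <- Fo[, f]; xp <- Fp[, f]
    if (stats::sd(xo) == 0 || stats::sd(xp) == 0)
      return(data.frame(feature = f, r = NA_real_, slope = NA_real_,
                        intercept = NA_real_))
    fit <- stats::lm.fit(cbind(1, xp), xo)
    data.frame(feature = f, r = stats::cor(xp, xo),
               slope = fit$coefficients[2], intercept = fit$coefficients[1])
  }))
  rownames(perFeature) <- NULL
  list(perFeature = perFeature, n = nrow(common))
}

#' Random-propagation baseline
#'
#' The null counterpart of \code{\link{propagateTissue}}: the complement cell
#' set (by default every evaluated cell predicted to be non-dividing) is
#' divided instead, with each neighbor's class drawn from the empirical class
#' distribution of the training pairs (redrawn, up to 100 times, until both
#' daughters receive at least one neighbor connection whenever the
#' distribution allows it). Each repetition is rebuilt and compared against
#' the observed topology; per-feature one-sample t-tests (Benjamini-Hochberg
#' corrected) compare the baseline correlations with the model's.
#'
#' @param tg the time-t \linkS4class{TissueGraph}.
#' @param predictedDividers cell ids the model predicted to divide.
#' @param evaluatedCells the cell set the division model scored (central
#'   non-peripheral cells).
#' @param classDistribution probabilities of classes "0", "1", "2" (e.g. the
#'   training-pool class frequencies).
#' @param observed,lineage observed t+1 graph and lineage.
#' @param reps repetitions (default 100).
#' @param seed integer seed.
#' @param modelR optional named per-feature correlations of the model
#'   propagation (enables the t-tests).
#' @param variant \code{"methods"} (default) divides all predicted
#'   non-dividers; \code{"results"} divides only the observed non-dividers
#'   among the predicted dividers.
#' @return list with \code{r} (reps x features matrix), \code{mean},
#'   \code{sd}, and, when \code{modelR} is given, \code{tests} (t statistic,
#'   p, BH-adjusted p per feature).
#' @export
randomPropagationBaseline <- function(tg, predictedDividers, evaluatedCells,
                                      classDistribution, observed, lineage,
                                      reps = 100, seed = 1, modelR = NULL,
                                      variant = c("methods", "results")) {
  variant <- match.arg(variant)
  baseDividers <- if (variant == "methods")
    setdiff(evaluatedCells, predictedDividers)
  else intersect(predictedDividers, names(survivors(lineage)))
  if (!length(baseDividers)) stopInput("empty complement divider set")
  p <- classDistribution[c("0", "1", "2")]
  if (anyNA(p)) stopInput("classDistribution needs entries '0', '1', '2'")
  p <- p / sum(p)
  g <- asIgraph(tg)
  nbList <- lapply(baseDividers, function(v) igraph::V(g)$name[igraph::neighbors(g, v)])
  canA <- p[["0"]] + p[["2"]] > 0
  canB <- p[["1"]] + p[["2"]] > 0

  drawClasses <- function(nn) {
    for (try in 1:100) {
      cl <- sample(0:2, nn, replace = TRUE, prob = p)
      okA <- !canA || any(cl %in% c(0, 2))
      okB <- !canB || any(cl %in% c(1, 2))
      if (okA && okB) return(cl)
    }
    cl
  }

  featNames <- featureCatalogue()$name
  R <- matrix(NA_real_, reps, length(featNames),
              dimnames = list(NULL, featNames))
  for (rep in seq_len(reps)) {
    classList <- withSeed(deriveSeed(seed, rep), lapply(nbList, function(nb)
      stats::setNames(drawClasses(length(nb)), nb)))
    names(classList) <- baseDividers
    gNew <- rewireTissue(tg, classList, deriveSeed(seed, 10000 + rep))
    nodeMap <- lapply(cellIds(tg), function(v)
      if (v %in% baseDividers) paste0(v, c(".A", ".B")) else v)
    names(nodeMap) <- cellIds(tg)
    ctr <- centerCell(tg)
    if (ctr %in% baseDividers) ctr <- paste0(ctr, ".A")
    cmp <- compareTopologies(
      list(graph = newTissueGraph(gNew, timeIndex(tg) + 1L, ctr),
           nodeMap = nodeMap),
      observed, lineage)
    R[rep, cmp$perFeature$feature] <- cmp$perFeature$r
  }
  out <- list(r = R, mean = colMeans(R, na.rm = TRUE),
              sd = apply(R, 2, stats::sd, na.rm = TRUE))
  if (!is.null(modelR)) {
    tests <- do.call(rbind, lapply(featNames, function(f) {
      x <- R[, f]; x <- x[!is.na(x)]
      if (length(x) < 2 || is.na(modelR[f]) || stats::sd(x) == 0)
        return(data.frame(feature = f, t = NA_real_, p = NA_real_))
      tt <- stats::t.test(x, mu = modelR[[f]])
      data.frame(feature = f, t = unname(tt$statistic), p = tt$p.value)
    }))
    tests$pAdjusted <- stats::p.adjust(tests$p, method = "BH")
    out$tests <- tests
  }
  out
}

#' Per-division local rewiring accuracy
#'
#' For every cell dividing in both the predicted and the observed tissue,
#' computes the fraction of its neighbors whose predicted rewiring class
#' (0/1/2) matches the observed class, and tests the distribution of these
#' per-division accuracies against random class assignment with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param result a \linkS4class{PropagationResult}.
#' @param observed observed t+1 \linkS4class{TissueGraph}.
#' @param lineage observed \linkS4class{LineageMap}.
#' @param classDistribution probabilities used for the random labels
#'   (default: empirical distribution of the observed classes).
#' @param randomReps repetitions of the random labeling (default 100).
#' @param seed integer seed.
#' @return list with \code{perDivision} (parent, nNeighbors, accuracy),
#'   \code{meanAccuracy}, \code{randomAccuracies} and \code{ks} (the test).
#' @export
localRewiringAccuracy <- function(result, observed, lineage,
                                  classDistribution = NULL, randomReps = 100,
                                  seed = 1) {
  commonDiv <- intersect(names(result@divisionClasses),
                         divisions(lineage)$parent)
  if (!length(commonDiv)) stopInput("no divisions common to predicted and observed")
  obsClasses <- list(); predClasses <- list()
  for (par in commonDiv) {
    prd <- result@divisionClasses[[par]]
    nb <- names(prd)[names(prd) %in% c(names(survivors(lineage)),
                                       divisions(lineage)$parent)]
    pairs <- data.frame(parent = par, neighbor = nb)
    obsClasses[[par]] <- stats::setNames(
      labelPairClasses(pairs, observed, lineage), nb)
    predClasses[[par]] <- prd[nb]
  }
  perDivision <- do.call(rbind, lapply(commonDiv, function(par)
    data.frame(parent = par, nNeighbors = length(predClasses[[par]]),
               accuracy = mean(predClasses[[par]] == obsClasses[[par]]))))
  allObs <- unlist(obsClasses)
  if (is.null(classDistribution))
    classDistribution <- table(factor(allObs, levels = 0:2)) / length(allObs)
  pcl <- as.numeric(classDistribution[c("0", "1", "2")] /
                    sum(classDistribution[c("0", "1", "2")]))
  randomAcc <- withSeed(deriveSeed(seed, 77), unlist(lapply(
    seq_len(randomReps), function(i)
      vapply(commonDiv, function(par) {
        nn <- length(obsClasses[[par]])
        mean(sample(0:2, nn, replace = TRUE, prob = pcl) == obsClasses[[par]])
      }, numeric(1)))))
  ks <- suppressWarnings(stats::ks.test(perDivision$accuracy, randomAcc))
  list(perDivision = perDivision, meanAccuracy = mean(perDivision$accuracy),
       randomAccuracies = unname(randomAcc), ks = ks)
}
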