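#' Enumerate neighbor-parent pairs of dividing cells
#'
#' One record per (dividing parent, neighbor) pair at time t. Peripheral
#' neighbors are excluded; pairs whose neighbor itself divides are excluded
#' unless \code{includeDividingNeighbors} is set (both regimes are analyzed).
#'
#' @param tg the time-t \linkS4class{TissueGraph}.
#' @param lineage \linkS4class{LineageMap} for t -> t+1.
#' @param includeDividingNeighbors keep pairs with dividing neighbors
#'   (default FALSE).
#' @param parents restrict to these parent cells (default: all dividing cells
#'   present in the graph; pass the central non-peripheral selection to mirror
#'   the tissue-scale analysis).
#' @return data.frame with columns \code{parent}, \code{neighbor},
#'   \code{neighborDivides}.
#' @export
enumeratePairs <- function(tg, lineage, includeDividingNeighbors = FALSE,
                           parents = NULL) {
  div <- divisions(lineage)$parent
  if (is.null(parents)) parents <- intersect(div, cellIds(tg))
  else {
    parents <- as.character(parents)
    missing <- setdiff(parents, cellIds(tg))
    if (length(missing)) stopInput("parent(s) not in graph: %s",
                                   paste(missing, collapse = ", "))
    parents <- intersect(parents, div)
  }
  if (!length(parents))
    return(data.frame(parent = character(0), neighbor = character(0),
                      neighborDivides = logical(0)))
  g <- asIgraph(tg)
  periph <- isPeripheral(tg)
  out <- lapply(parents, function(p) {
    nb <- igraph::V(g)$name[igraph::neighbors(g, p)]
    nb <- nb[!periph[nb]]
    data.frame(parent = rep(p, length(nb)), neighbor = nb,
               neighborDivides = nb %in% div)
  })
  out <- do.call(rbind, out)
  if (!includeDividingNeighbors) out <- out[!out$neighborDivides, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Post-division adjacency class of a neighbor-parent pair
#'
#' Of the two daughters of a divided cell, daughter 'A' is the one whose
#' centroid at t+1 lies nearer the tissue center (ties broken by the smaller
#' cell id). A neighbor is class 0 when adjacent only to daughter A, class 1
#' when adjacent only to daughter B, and class 2 when adjacent to both. A
#' neighbor that itself divided is represented by the union of its daughters'
#' adjacencies.
#'
#' @param pairs data.frame with columns \code{parent}, \code{neighbor} (e.g.
#'   from \code{\link{enumeratePairs}}).
#' @param tgNext the observed time-t+1 \linkS4class{TissueGraph}.
#' @param lineage \linkS4class{LineageMap} for t -> t+1.
#' @param center tissue center: a t+1 cell id or a numeric xyz position;
#'   default the t+1 graph's center cell.
#' @return integer vector of classes (0/1/2), one per pair row.
#' @export
labelPairClasses <- function(pairs, tgNext, lineage, center = NULL) {
  cd <- cellData(tgNext)
  if (is.null(center)) center <- centerCell(tgNext)
  ctr <- if (is.character(center)) {
    i <- match(center, cd$id)
    if (is.na(i)) stopInput("center cell '%s' not in t+1 graph", center)
    c(cd$x[i], cd$y[i], cd$z[i])
  } else as.numeric(center)
  g1 <- asIgraph(tgNext)
  surv <- survivors(lineage)
  divTab <- divisions(lineage)
  adjOf <- function(id) igraph::V(g1)$name[igraph::neighbors(g1, id)]

  vapply(seq_len(nrow(pairs)), function(k) {
    p <- pairs$parent[k]; nb <- pairs$neighbor[k]
    d <- lineageDaughters(lineage, p)
    i <- match(d, cd$id)
    if (anyNA(i)) stopInput("daughter(s) of '%s' missing from t+1 graph", p)
    dist <- sqrt((cd$x[i] - ctr[1])^2 + (cd$y[i] - ctr[2])^2 + (cd$z[i] - ctr[3])^2)
    ord <- order(dist, d)           # nearer first; tie -> smaller id
    A <- d[ord[1]]; B <- d[ord[2]]
    image <- if (nb %in% names(surv)) surv[[nb]]
      else if (nb %in% divTab$parent) unname(lineageDaughters(lineage, nb))
      else stopInput("neighbor '%s' absent from lineage", nb)
    adj <- unique(unlist(lapply(image, adjOf)))
    hitA <- A %in% adj; hitB <- B %in% adj
    if (!hitA && !hitB)
      stopInput("neighbor '%s' adjacent to neither daughter of '%s'", nb, p)
    if (hitA && hitB) 2L else if (hitA) 0L else 1L
  }, integer(1))
}

#' Feature vectors for neighbor-parent pairs
#'
#' Assembles, per pair and on the time-t graph, the topological block (the
#' parent's features followed by the neighbor-minus-parent differences, which
#' disambiguate neighbors adjacent to several dividing cells) and/or the
#' biological block of exactly six cellular features: parent area, neighbor
#' area, parent perimeter, neighbor perimeter, shared wall area and centroid
#' distance.
#'
#' @param tg the time-t \linkS4class{TissueGraph}.
#' @param pairs data.frame with \code{parent}, \code{neighbor}.
#' @param featureSet \code{"topo+bio"}, \code{"topo"}, \code{"bio"} or
#'   \code{"unweighted"}. The reduced \code{r<0.3} set is obtained with
#'   \code{\link{reduceByCorrelation}} using the six biological columns as
#'   references on a \code{"topo+bio"} table.
#' @param inverseDistance see \code{\link{edgeWeight}}.
#' @param labels optional per-pair classes recorded as \code{label}.
#' @param plant,time row metadata.
#' @return a \linkS4class{FeatureTable} with one row per pair.
#' @export
pairFeatureTable <- function(tg, pairs,
                             featureSet = c("topo+bio", "topo", "bio", "unweighted"),
                             inverseDistance = TRUE, labels = NULL,
                             plant = NA_character_, time = timeIndex(tg)) {
  featureSet <- match.arg(featureSet)
  np <- nrow(pairs)
  blocks <- list(); info <- list()
  if (featureSet %in% c("topo+bio", "topo", "unweighted")) {
    cat <- featureCatalogue()
    scen <- if (featureSet == "unweighted") "unweighted" else weightScenarios()
    allF <- allScenarioFeatures(tg, scen, inverseDistance)
    for (s in scen) {
      F <- allF[[s]]
      keep <- if (s == "unweighted") cat$name else cat$name[cat$weightSensitive]
      P <- F[pairs$parent, keep, drop = FALSE]
      Dp <- F[pairs$neighbor, keep, drop = FALSE] - P
      colnames(P) <- paste0("parent.", keep, "@", s)
      colnames(Dp) <- paste0("diff.", keep, "@", s)
      blocks[[paste0("p", s)]] <- P
      blocks[[paste0("d", s)]] <- Dp
      sc <- cat$scope[match(keep, cat$name)]
      wr <- cat$weightRole[match(keep, cat$name)]
      info[[paste0("p", s)]] <- data.frame(feature = paste0("parent.", keep),
                                           scenario = s, scope = sc, weightRole = wr)
      info[[paste0("d", s)]] <- data.frame(feature = paste0("diff.", keep),
                                           scenario = s, scope = sc, weightRole = wr)
    }
  }
  if (featureSet %in% c("topo+bio", "bio")) {
    cd <- cellData(tg)
    ip <- match(pairs$parent, cd$id); inb <- match(pairs$neighbor, cd$id)
    wd <- wallData(tg)
    wkey <- paste(pmin(wd$u, wd$v), pmax(wd$u, wd$v))
    pkey <- paste(pmin(pairs$parent, pairs$neighbor),
                  pmax(pairs$parent, pairs$neighbor))
    sw <- wd$sharedWall[match(pkey, wkey)]
    if (anyNA(sw)) stopInput("pair without a shared wall at time t")
    B <- cbind(parentArea = cd$area[ip], neighborArea = cd$area[inb],
               parentPerimeter = cd$perimeter[ip],
               neighborPerimeter = cd$perimeter[inb],
               sharedWall = sw,
               centroidDistance = sqrt((cd$x[ip] - cd$x[inb])^2 +
                                       (cd$y[ip] - cd$y[inb])^2 +
                                       (cd$z[ip] - cd$z[inb])^2))
    colnames(B) <- paste0(colnames(B), "@bio")
    blocks$bio <- B
    info$bio <- data.frame(feature = sub("@bio$", "", colnames(B)),
                           scenario = "bio", scope = "biological",
                           weightRole = "none")
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- paste(pairs$parent, pairs$neighbor, sep = "|")
  meta <- data.frame(parent = pairs$parent, neighbor = pairs$neighbor,
                     plant = plant, time = time)
  if (!is.null(labels)) meta$label <- as.character(labels)
  makeFeatureTable(X, do.call(rbind, info), meta)
}

#' Biological pair feature names
#' @return the six column names of the biological pair block.
#' @export
bioPairColumns <- function()
  paste0(c("parentArea", "neighborArea", "parentPerimeter",
           "neighborPerimeter", "sharedWall", "centroidDistance"), "@bio")

# one-vs-rest linear SVM over k classes; X already normalized
ovrFit <- function(X, y, C, classes) {
  W <- matrix(0, ncol(X), length(classes),
              dimnames = list(colnames(X), classes))
  b <- numeric(length(classes))
  for (j in seq_along(classes)) {
    cl <- classes[j]
    yb <- ifelse(y == cl, cl, ".rest")
    if (length(unique(yb)) < 2) stopInput("class '%s' absent from a training fold", cl)
    fit <- fitLinearSVM(X, yb, C, balancedClassWeights(yb), cl)
    W[, j] <- fit$w; b[j] <- fit$b
  }
  list(W = W, b = b)
}

ovrPredict <- function(Xz, fit, classes) {
  D <- sweep(Xz %*% fit$W, 2, fit$b, "+")
  classes[max.col(D, ties.method = "first")]
}

#' Seeded class balancing by downsampling
#'
#' Downsamples every class to the smallest class count (the tissue-scale datasets
#' were balanced to equal class representation before training).
#'
#' @param y class labels.
#' @param seed integer seed.
#' @return integer vector of retained row indices.
#' @export
balanceClasses <- function(y, seed = 1) {
  idx <- split(seq_along(y), y)
  nmin <- min(lengths(idx))
  sort(unlist(lapply(seq_along(idx), function(j)
    withSeed(deriveSeed(seed, j), sample(idx[[j]], nmin)))))
}

#' Train the 3-class neighbor-rewiring classifier
#'
#' One-vs-rest linear max-margin model over the rewiring classes 0/1/2 with
#' nested plant-aware cross-validation: within each outer fold, the
#' regularization C is chosen on the remaining folds (inner grid search by
#' balanced accuracy) before the outer fold's validation plants are scored.
#' Classes are balanced in the train-validation pool by seeded downsampling
#' (\code{balance = "downsample"}) or by class weights alone
#' (\code{"weights"}). The final model refits all pool rows with the C that
#' maximizes the mean outer-validation balanced accuracy.
#'
#' @param ft labeled pair \linkS4class{FeatureTable} (labels "0"/"1"/"2").
#' @param splits a \code{\link{makeSplits}} plan (use \code{nFolds = 5} when
#'   enough plants are available).
#' @param cGrid candidate C values.
#' @param balance class balancing mode.
#' @param seed integer seed for the downsampling.
#' @param featureSet name recorded in the model.
#' @return list with \code{model}, \code{C}, \code{foldMetrics} (outer-fold
#'   train/validation metrics under the nested-selected C), \code{innerC}
#'   (per outer fold), \code{gridValidation}.
#' @export
trainPairClassifier <- function(ft, splits, cGrid = defaultCGrid(),
                                balance = c("downsample", "weights"),
                                seed = 1, featureSet = "custom") {
  balance <- match.arg(balance)
  dp <- datasetParts(ft)
  pool <- which(dp$plant %in% splits$trainPlants)
  if (balance == "downsample") pool <- pool[balanceClasses(dp$y[pool], seed)]
  X <- dp$X[pool, , drop = FALSE]
  y <- dp$y[pool]
  plant <- dp$plant[pool]
  classes <- sort(unique(y))
  if (length(classes) < 3) stopInput("expected 3 rewiring classes, got %d",
                                     length(classes))

  evalFold <- function(f, C, Xs, ys, plants) {
    tr <- plants %in% f$train; va <- plants %in% f$validation
    st <- zStats(Xs[tr, , drop = FALSE])
    fit <- ovrFit(zApply(Xs[tr, , drop = FALSE], st), ys[tr], C, classes)
    pr <- ovrPredict(zApply(Xs[va, , drop = FALSE], st), fit, classes)
    classificationMetrics(ys[va], pr)$balancedAccuracy
  }

  gridVal <- vapply(cGrid, function(C) mean(vapply(splits$folds, evalFold,
    numeric(1), C = C, Xs = X, ys = y, plants = plant)), numeric(1))
  flatC <- cGrid[which.max(gridVal)]

  nestedPick <- function(outer) {
    # the inner grid search needs at least two inner folds, i.e. three
    # training plant groups; below that the flat selection is used
    inner <- lapply(splits$folds[-outer], function(f)
      list(train = setdiff(f$train, splits$folds[[outer]]$validation),
           validation = f$validation))
    inner <- inner[vapply(inner, function(f) length(f$train) > 0, logical(1))]
    if (length(inner) < 2) return(flatC)
    keep <- plant %in% splits$folds[[outer]]$train
    val <- vapply(cGrid, function(C) mean(vapply(inner, evalFold, numeric(1),
      C = C, Xs = X[keep, , drop = FALSE], ys = y[keep],
      plants = plant[keep])), numeric(1))
    cGrid[which.max(val)]
  }

  innerC <- vapply(seq_along(splits$folds), nestedPick, numeric(1))
  foldMetrics <- lapply(seq_along(splits$folds), function(j) {
    f <- splits$folds[[j]]
    tr <- plant %in% f$train; va <- plant %in% f$validation
    st <- zStats(X[tr, , drop = FALSE])
    fit <- ovrFit(zApply(X[tr, , drop = FALSE], st), y[tr], innerC[j], classes)
    list(train = classificationMetrics(
           y[tr], ovrPredict(zApply(X[tr, , drop = FALSE], st), fit, classes)),
         validation = classificationMetrics(
           y[va], ovrPredict(zApply(X[va, , drop = FALSE], st), fit, classes)))
  })

  C <- flatC
  st <- zStats(X)
  fit <- ovrFit(zApply(X, st), y, C, classes)
  model <- newLinearClassifier(colnames(X), st, fit$W, fit$b, classes, C,
                               balancedClassWeights(y), featureSet)
  list(model = model, C = C, foldMetrics = foldMetrics, innerC = innerC,
       gridValidation = stats::setNames(gridVal, signif(cGrid, 6)))
}
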