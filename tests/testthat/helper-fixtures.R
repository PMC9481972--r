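# fixtures built in code, shared across test files

# hexagonal patch: center cell surrounded by a closed ring of 6 cells
hexPatch <- function() {
  ring <- paste0("r", 1:6)
  cells <- data.frame(
    id = c("c", ring),
    x = c(0, 2 * cos(2 * pi * (0:5) / 6)),
    y = c(0, 2 * sin(2 * pi * (0:5) / 6)),
    z = 0, area = 10, perimeter = 12)
  walls <- rbind(
    data.frame(u = "c", v = ring, sharedWall = 2),
    data.frame(u = ring, v = ring[c(2:6, 1)], sharedWall = 2))
  buildTissueGraph(cells, walls, centerCell = "c")
}

# path a - b - c with unit attributes
pathTissue <- function() {
  cells <- data.frame(id = c("a", "b", "c"), x = c(0, 1, 2), y = 0, z = 0,
                      area = 10, perimeter = 12)
  walls <- data.frame(u = c("a", "b"), v = c("b", "c"), sharedWall = 3)
  buildTissueGraph(cells, walls, centerCell = "b")
}

# random connected tissue graph with random positive attributes
randomTissue <- function(n, seed, pEdge = 0.35) {
  withr::with_seed(seed, {
    repeat {
      A <- matrix(stats::runif(n * n) < pEdge, n, n)
      A[lower.tri(A, diag = TRUE)] <- FALSE
      g <- igraph::graph_from_adjacency_matrix(A | t(A), mode = "undirected")
      if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
    }
    ids <- paste0("v", seq_len(n))
    cells <- data.frame(id = ids,
                        x = stats::rnorm(n) * 10, y = stats::rnorm(n) * 10,
                        z = stats::rnorm(n), area = stats::runif(n, 2, 30),
                        perimeter = stats::runif(n, 5, 25))
    el <- igraph::as_edgelist(g)
    walls <- data.frame(u = ids[el[, 1]], v = ids[el[, 2]],
                        sharedWall = stats::runif(nrow(el), 0.5, 8))
    buildTissueGraph(cells, walls, centerCell = ids[1])
  })
}

# small simulated cohort + trained models, computed once per test run
.fixtureCache <- new.env(parent = emptyenv())

smallCohort <- function() {
  if (is.null(.fixtureCache$cohort)) {
    p <- simParams(nCellsInit = 110, diskRadius = 42, steps = 2)
    .fixtureCache$cohort <- simulateCohort(p, nPlants = 4, seed = 42)
  }
  .fixtureCache$cohort
}

smallDivisionData <- function() {
  if (is.null(.fixtureCache$divFT))
    .fixtureCache$divFT <- assembleDivisionDataset(smallCohort(), radius = 25)
  .fixtureCache$divFT
}

smallPairData <- function() {
  if (is.null(.fixtureCache$pairFT))
    .fixtureCache$pairFT <- suppressMessages(
      assemblePairDataset(smallCohort(), radius = 25))
  .fixtureCache$pairFT
}

smallSplits <- function() {
  if (is.null(.fixtureCache$splits))
    .fixtureCache$splits <- makeSplits(sampleData(smallDivisionData())$plant,
                                       nTestPlants = 1, seed = 2)
  .fixtureCache$splits
}

smallDivisionFit <- function() {
  if (is.null(.fixtureCache$divFit))
    .fixtureCache$divFit <- trainDivisionClassifier(
      smallDivisionData(), smallSplits(), cGrid = c(0.01, 0.1, 1),
      featureSet = "topo+area")
  .fixtureCache$divFit
}

smallPairFit <- function() {
  if (is.null(.fixtureCache$pairFit))
    .fixtureCache$pairFit <- trainPairClassifier(
      smallPairData(), smallSplits(), cGrid = c(0.01, 0.1, 1),
      seed = 7, featureSet = "topo+bio")
  .fixtureCache$pairFit
}
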