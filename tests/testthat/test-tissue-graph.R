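test_that("graph construction attaches attributes and rejects bad input", {
  cells <- data.frame(id = c("a", "b", "c"), x = c(0, 1, 2), y = 0, z = 0,
                      area = 10, perimeter = 12)
  walls <- data.frame(u = c("a", "b"), v = c("b", "c"), sharedWall = 3)
  tg <- buildTissueGraph(cells, walls, centerCell = "b")
  expect_equal(length(cellIds(tg)), 3)
  expect_equal(nrow(wallData(tg)), 2)
  expect_equal(unname(igraph::degree(asIgraph(tg))[2]), 2)

  expect_error(buildTissueGraph(cells,
    data.frame(u = "a", v = "a", sharedWall = 1), "b"), "self-adjacency")
  expect_error(buildTissueGraph(cells,
    data.frame(u = "a", v = "zz", sharedWall = 1), "b"), "unknown cell")
  expect_error(buildTissueGraph(cells,
    data.frame(u = c("a", "b"), v = c("b", "a"), sharedWall = 1), "b"),
    "duplicate wall")
  expect_error(buildTissueGraph(cells,
    data.frame(u = "a", v = "b", sharedWall = -1), "b"), "positive")
  cells2 <- cells; cells2$area[1] <- 0
  expect_error(buildTissueGraph(cells2, walls, "b"), "positive")
})

test_that("hexagonal patch has the expected degrees", {
  tg <- hexPatch()
  deg <- igraph::degree(asIgraph(tg))
  expect_equal(unname(deg[cellIds(tg) == "c"]), 6)
  expect_true(all(deg[cellIds(tg) != "c"] == 3))
})

test_that("edge weights follow the four scenario definitions", {
  u <- list(area = 2, x = 0, y = 0, z = 0)
  v <- list(area = 4, x = 0, y = 0, z = 2)
  expect_identical(edgeWeight("unweighted", u, v), 1)
  expect_equal(edgeWeight("area", u, v), 1 / 3)
  expect_equal(edgeWeight("wall", u, v, sharedWall = 4), 0.25)
  expect_equal(edgeWeight("distance", u, v), 0.5)
  expect_equal(edgeWeight("distance", u, v, inverseDistance = FALSE), 2)
  expect_error(edgeWeight("distance", u, u), "coincident")
  expect_error(edgeWeight("wall", u, v, sharedWall = 0), "positive")

  tg <- hexPatch()
  for (s in weightScenarios()) {
    w <- edgeWeights(tg, s)
    expect_true(all(is.finite(w) & w > 0), info = s)
  }
  expect_true(all(edgeWeights(tg, "unweighted") == 1))
})

test_that("peripheral test recognizes ring closure around a cell", {
  tg <- hexPatch()
  p <- isPeripheral(tg)
  expect_false(p[["c"]])                 # neighbors close into a 6-cycle
  expect_true(all(p[paste0("r", 1:6)]))  # ring cells' neighbors form a path
  expect_error(isPeripheral(tg, "nope"), "unknown cell")

  # two mutually non-adjacent neighbors: no cycle possible
  cells <- data.frame(id = c("m", "l", "r"), x = c(0, -1, 1), y = 0, z = 0,
                      area = 1, perimeter = 1)
  walls <- data.frame(u = "m", v = c("l", "r"), sharedWall = 1)
  tg2 <- buildTissueGraph(cells, walls, "m")
  expect_true(isPeripheral(tg2, "m")[[1]])
})

test_that("peripheral status is invariant under cell relabeling", {
  tg <- randomTissue(12, seed = 5)
  base <- isPeripheral(tg)
  cd <- cellData(tg); wd <- wallData(tg)
  perm <- withr::with_seed(9, sample(cd$id))
  map <- stats::setNames(perm, cd$id)
  cd$id <- map[cd$id]; wd$u <- map[wd$u]; wd$v <- map[wd$v]
  names(wd)[3] <- "sharedWall"
  tg2 <- buildTissueGraph(cd, wd, centerCell = map[[centerCell(tg)]])
  expect_equal(unname(isPeripheral(tg2)[map[names(base)]]), unname(base))
})

test_that("central-zone selection uses a closed radius and drops peripherals", {
  ring <- paste0("r", 1:6)
  cells <- data.frame(
    id = c("c", ring, "far", "edge"),
    x = c(0, 2 * cos(2 * pi * (0:5) / 6), 30.1, 29.9),
    y = 0, z = 0, area = 10, perimeter = 12)
  walls <- rbind(
    data.frame(u = "c", v = ring, sharedWall = 2),
    data.frame(u = ring, v = ring[c(2:6, 1)], sharedWall = 2),
    data.frame(u = "r1", v = c("far", "edge"), sharedWall = 2))
  tg <- buildTissueGraph(cells, walls, centerCell = "c")
  selAll <- selectCentralCells(tg, 30, filterPeripheral = FALSE)
  expect_true("edge" %in% selAll)     # 29.9 <= 30: included
  expect_false("far" %in% selAll)     # 30.1 > 30: excluded
  sel <- selectCentralCells(tg, 30)
  expect_identical(sel, "c")          # everything else is peripheral

  # monotone inclusion before peripheral filtering
  tg2 <- randomTissue(14, seed = 3)
  s1 <- selectCentralCells(tg2, 5, filterPeripheral = FALSE)
  s2 <- selectCentralCells(tg2, 12, filterPeripheral = FALSE)
  expect_true(all(s1 %in% s2))
  expect_error(selectCentralCells(tg2, -1), "positive")
})

test_that("lineage map enforces its invariants", {
  lm <- LineageMap(data.frame(parent = "p", daughterA = "d1", daughterB = "d2"),
                   survivors = c(s1 = "s1b"))
  expect_true(isDividing(lm, c("p", "s1"))[["p"]])
  expect_false(isDividing(lm, c("p", "s1"))[["s1"]])
  expect_error(LineageMap(
    data.frame(parent = c("p", "p"), daughterA = c("a", "b"),
               daughterB = c("c", "d")), character(0)), "at most once")
  expect_error(LineageMap(
    data.frame(parent = "p", daughterA = "a", daughterB = "b"),
    survivors = c(p = "x")), "cannot also be")
})

test_that("graph and lineage files round-trip through their formats", {
  tg <- randomTissue(10, seed = 21)
  tmp <- tempfile(fileext = ".json")
  writeTissueGraph(tg, tmp)
  tg2 <- readTissueGraph(tmp)
  expect_equal(sort(cellIds(tg2)), sort(cellIds(tg)))
  expect_equal(cellData(tg2)[order(cellData(tg2)$id), ],
               cellData(tg)[order(cellData(tg)$id), ],
               ignore_attr = TRUE)
  w1 <- wallData(tg); w2 <- wallData(tg2)
  key <- function(w) paste(pmin(w$u, w$v), pmax(w$u, w$v))
  expect_equal(w2$sharedWall[order(key(w2))], w1$sharedWall[order(key(w1))])
  expect_identical(centerCell(tg2), centerCell(tg))

  # CSV dialect
  cf <- tempfile(fileext = ".csv"); wf <- tempfile(fileext = ".csv")
  utils::write.csv(cellData(tg), cf, row.names = FALSE)
  wd <- wallData(tg); names(wd)[3] <- "shared_wall"
  utils::write.csv(wd, wf, row.names = FALSE)
  tg3 <- readTissueGraphCSV(cf, wf, centerCell = centerCell(tg))
  expect_equal(sort(cellIds(tg3)), sort(cellIds(tg)))
  expect_error(readTissueGraphCSV("no/such.csv", wf, "a"), "no such file")

  lm <- LineageMap(data.frame(parent = "p", daughterA = "d1", daughterB = "d2"),
                   survivors = c(a = "a", b = "b2"))
  lf <- tempfile(fileext = ".csv")
  writeLineageMap(lm, lf)
  lm2 <- readLineageMap(lf)
  expect_equal(divisions(lm2), divisions(lm))
  expect_equal(survivors(lm2), survivors(lm))
})
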