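# a small hand-built division fixture: parent "p" with two daughters and
# four neighbors at known positions, so every pair class is known
divisionFixture <- function() {
  # time t: p surrounded by n1..n4 (ring), plus outer cells to keep the
  # neighbors non-peripheral is unnecessary here -- pairs are passed directly
  cellsT <- data.frame(
    id = c("p", "n1", "n2", "n3", "n4"),
    x = c(0, 0, 2, 0, -2), y = c(0, 2, 0, -2, 0), z = 0,
    area = 10, perimeter = 12)
  wallsT <- rbind(
    data.frame(u = "p", v = c("n1", "n2", "n3", "n4"), sharedWall = 2),
    data.frame(u = c("n1", "n2", "n3", "n4"),
               v = c("n2", "n3", "n4", "n1"), sharedWall = 1))
  tgT <- buildTissueGraph(cellsT, wallsT, centerCell = "p")
  # time t+1: p -> dA (nearer center cell n1') and dB; n1 touches only dA,
  # n3 only dB, n2 and n4 touch both
  cellsT1 <- data.frame(
    id = c("dA", "dB", "m1", "m2", "m3", "m4"),
    x = c(0, 0, 0, 2, 0, -2), y = c(1, -1, 2, 0, -2, 0), z = 0,
    area = 5, perimeter = 9)
  wallsT1 <- rbind(
    data.frame(u = "dA", v = c("dB", "m1", "m2", "m4"), sharedWall = 1),
    data.frame(u = "dB", v = c("m2", "m3", "m4"), sharedWall = 1),
    data.frame(u = c("m1", "m2", "m3", "m4"),
               v = c("m2", "m3", "m4", "m1"), sharedWall = 1))
  tgT1 <- buildTissueGraph(cellsT1, wallsT1, centerCell = "m1")
  lineage <- LineageMap(
    data.frame(parent = "p", daughterA = "dA", daughterB = "dB"),
    survivors = c(n1 = "m1", n2 = "m2", n3 = "m3", n4 = "m4"))
  list(tgT = tgT, tgT1 = tgT1, lineage = lineage)
}

test_that("pair enumeration respects the dividing-neighbor flag", {
  ser <- smallCohort()[[2]]
  tg <- tissueGraphs(ser)[[1]]
  lin <- lineageMaps(ser)[[1]]
  pairsOff <- enumeratePairs(tg, lin, includeDividingNeighbors = FALSE)
  pairsOn <- enumeratePairs(tg, lin, includeDividingNeighbors = TRUE)
  expect_true(all(!pairsOff$neighborDivides))
  expect_gt(nrow(pairsOn), nrow(pairsOff))
  expect_true(all(pairsOn$parent %in% divisions(lin)$parent))
  # no dividing cells -> empty enumeration
  linNone <- LineageMap(survivors = stats::setNames(cellIds(tg), cellIds(tg)))
  expect_equal(nrow(enumeratePairs(tg, linNone)), 0)
  expect_error(enumeratePairs(tg, lin, parents = "not-a-cell"), "not in graph")
})

test_that("pair classes follow daughter adjacency with the stated tie-break", {
  fx <- divisionFixture()
  pairs <- data.frame(parent = "p", neighbor = c("n1", "n2", "n3", "n4"))
  cls <- labelPairClasses(pairs, fx$tgT1, fx$lineage)
  # center m1 sits at (0,2): dA (0,1) is nearer than dB (0,-1)
  expect_equal(cls, c(0L, 2L, 1L, 2L))
  # moving the reference center below flips the A/B roles: 0 <-> 1
  cls2 <- labelPairClasses(pairs, fx$tgT1, fx$lineage, center = "m3")
  expect_equal(cls2, c(1L, 2L, 0L, 2L))
  # equidistant daughters: tie broken by the smaller cell id ("dA" < "dB")
  cls3 <- labelPairClasses(pairs, fx$tgT1, fx$lineage, center = c(10, 0, 0))
  expect_equal(cls3[1], 0L)
})

test_that("pair feature blocks have the documented shapes", {
  fx <- divisionFixture()
  pairs <- data.frame(parent = "p", neighbor = c("n1", "n2"))
  bio <- pairFeatureTable(fx$tgT, pairs, featureSet = "bio")
  expect_equal(rownames(bio), bioPairColumns())
  expect_equal(nrow(featureMatrix(bio)), 2)
  topo <- pairFeatureTable(fx$tgT, pairs, featureSet = "topo")
  expect_equal(nrow(topo), 100)        # 2 x 50
  both <- pairFeatureTable(fx$tgT, pairs, featureSet = "topo+bio")
  expect_equal(nrow(both), 106)
  unw <- pairFeatureTable(fx$tgT, pairs, featureSet = "unweighted")
  expect_equal(nrow(unw), 34)
  # a neighbor topologically identical to the parent zeroes the diff block
  X <- featureMatrix(unw)
  diffCols <- grepl("^diff\\.", colnames(X))
  sym <- pairFeatureTable(fx$tgT, data.frame(parent = "n1", neighbor = "n3"),
                          featureSet = "unweighted")
  expect_true(all(abs(featureMatrix(sym)[, diffCols]) < 1e-10))
})

test_that("biological pair features equal their geometric definitions", {
  fx <- divisionFixture()
  X <- featureMatrix(pairFeatureTable(fx$tgT,
    data.frame(parent = "p", neighbor = "n2"), featureSet = "bio"))
  expect_equal(unname(X[1, ]), c(10, 10, 12, 12, 2, 2))
})

test_that("three separable clusters are classified perfectly one-vs-rest", {
  withr::with_seed(19, {
    X <- rbind(matrix(rnorm(80, 0), ncol = 2),
               matrix(rnorm(80, 6), ncol = 2),
               cbind(rnorm(40, 6), rnorm(40, -6)))
    colnames(X) <- c("f1", "f2")
    y <- rep(c("0", "1", "2"), each = 40)
  })
  st <- meristemNet:::zStats(X)
  fit <- meristemNet:::ovrFit(meristemNet:::zApply(X, st), y, C = 10,
                              classes = c("0", "1", "2"))
  pred <- meristemNet:::ovrPredict(meristemNet:::zApply(X, st), fit,
                                   c("0", "1", "2"))
  expect_equal(mean(pred == y), 1)
})

test_that("per-class AUC equals the brute-force rank-sum oracle", {
  fit <- smallPairFit()$model
  ft <- smallPairData()
  te <- sampleData(ft)$plant %in% smallSplits()$testPlants
  fte <- meristemNet:::subsetRowsFT(ft, te)
  ev <- evaluateClassifier(fit, fte)
  D <- decisionValues(fit, fte)
  y <- sampleData(fte)$label
  for (cl in fit@classes)
    expect_equal(ev$classAUC[[cl]], oracleAUC(y, D[, cl], cl),
                 tolerance = 1e-12)
  expect_equal(ev$macroAUC, mean(ev$classAUC))
})

test_that("class balancing downsamples to the smallest class", {
  y <- c(rep("0", 30), rep("1", 12), rep("2", 20))
  idx <- balanceClasses(y, seed = 4)
  expect_equal(unname(table(y[idx])), rep(12L, 3), ignore_attr = TRUE)
  expect_identical(balanceClasses(y, seed = 4), idx)   # seeded determinism
})

test_that("the rewiring classifier learns the geometric ground truth", {
  fit <- smallPairFit()
  vba <- sapply(fit$foldMetrics, function(f) f$validation$balancedAccuracy)
  expect_gt(mean(vba), 1 / 3 + 0.05)
  expect_length(fit$innerC, length(smallSplits()$folds))
  # multiclass model round-trips through JSON
  tmp <- tempfile(fileext = ".json")
  writeClassifier(fit$model, tmp)
  back <- readClassifier(tmp)
  expect_identical(predict(back, smallPairData()),
                   predict(fit$model, smallPairData()))
})

test_that("pair labels are recomputable from graphs and lineage alone", {
  ser <- smallCohort()[[1]]
  pc <- ser@pairClasses[[1]]
  relab <- labelPairClasses(pc, tissueGraphs(ser)[[2]], lineageMaps(ser)[[1]])
  expect_equal(relab, pc$label)
})

test_that("reflecting the center exchanges class 0 and class 1 counts", {
  ser <- smallCohort()[[3]]
  tg1 <- tissueGraphs(ser)[[2]]
  lin <- lineageMaps(ser)[[1]]
  pairs <- enumeratePairs(tissueGraphs(ser)[[1]], lin,
                          includeDividingNeighbors = TRUE)
  # two reference points far away in opposite directions: distance ordering
  # becomes a projection, so the mirrored reference reverses every A/B call
  d <- c(1, 0.37, 0)
  a <- labelPairClasses(pairs, tg1, lin, center = 1e7 * d)
  b <- labelPairClasses(pairs, tg1, lin, center = -1e7 * d)
  expect_equal(sum(a == 2), sum(b == 2))
  expect_equal(sum(a == 0), sum(b == 1))
  expect_true(all((a == 2) == (b == 2)))
  expect_true(all(a[a != 2] != b[a != 2]))
})
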