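test_that("division labels come from the lineage and orphans are rejected", {
  tg <- hexPatch()
  lm <- LineageMap(data.frame(parent = "c", daughterA = "cA", daughterB = "cB"),
                   survivors = stats::setNames(paste0("r", 1:6), paste0("r", 1:6)))
  lab <- labelDivisions(tg, lm)
  expect_equal(unname(lab[["c"]]), 1)
  expect_true(all(lab[paste0("r", 1:6)] == -1))
  lm2 <- LineageMap(survivors = c(c = "c"))
  expect_error(labelDivisions(tg, lm2), "absent from both")
})

test_that("generated lineages round-trip through the division labels", {
  ser <- smallCohort()[[1]]
  tg <- tissueGraphs(ser)[[1]]
  lin <- lineageMaps(ser)[[1]]
  lab <- labelDivisions(tg, lin)
  expect_identical(names(lab)[lab == 1], intersect(cellIds(tg), divisions(lin)$parent))
})

test_that("plant-wise splits partition plants into leave-one-plant folds", {
  sp <- makeSplits(paste0("p", 1:8), nTestPlants = 2, seed = 1)
  expect_length(sp$testPlants, 2)
  expect_length(sp$folds, 6)
  vals <- unlist(lapply(sp$folds, `[[`, "validation"))
  expect_setequal(vals, sp$trainPlants)          # each fold validates one plant
  for (f in sp$folds) {
    expect_length(intersect(f$train, f$validation), 0)
    expect_setequal(c(f$train, f$validation), sp$trainPlants)
    expect_length(intersect(f$train, sp$testPlants), 0)
  }
  expect_error(makeSplits("p1"), "at least 3")
  expect_error(makeSplits(paste0("p", 1:4), nFolds = 5, nTestPlants = 1),
               "fewer training plants")
})

test_that("a separable toy problem is fitted perfectly", {
  withr::with_seed(11, {
    X <- rbind(matrix(rnorm(60, 3), ncol = 2), matrix(rnorm(60, -3), ncol = 2))
    colnames(X) <- c("f1", "f2")
    y <- rep(c("1", "-1"), each = 30)
  })
  st <- meristemNet:::zStats(X)
  fit <- meristemNet:::fitLinearSVM(meristemNet:::zApply(X, st), y, C = 1,
    classWeights = c("-1" = 1, "1" = 1), positiveClass = "1")
  pred <- ifelse(meristemNet:::zApply(X, st) %*% fit$w + fit$b > 0, "1", "-1")
  expect_equal(mean(pred == y), 1)
})

test_that("class weighting rescues balanced accuracy under 90/10 imbalance", {
  withr::with_seed(13, {
    nMaj <- 180; nMin <- 20
    X <- rbind(matrix(rnorm(nMaj * 2, 0), ncol = 2),
               matrix(rnorm(nMin * 2, 1.2), ncol = 2))
    colnames(X) <- c("f1", "f2")
    y <- c(rep("-1", nMaj), rep("1", nMin))
  })
  majority <- rep("-1", length(y))
  expect_equal(classificationMetrics(y, majority)$balancedAccuracy, 0.5)
  st <- meristemNet:::zStats(X)
  fit <- meristemNet:::fitLinearSVM(meristemNet:::zApply(X, st), y, C = 1,
    classWeights = meristemNet:::balancedClassWeights(y), positiveClass = "1")
  pred <- ifelse(meristemNet:::zApply(X, st) %*% fit$w + fit$b > 0, "1", "-1")
  expect_gt(classificationMetrics(y, pred)$balancedAccuracy, 0.5)
})

test_that("metrics equal hand-computed confusion-matrix arithmetic", {
  truth <- c(rep("1", 8), rep("-1", 12))
  pred  <- c(rep("1", 6), rep("-1", 2),   # 6 TP, 2 FN
             rep("1", 3), rep("-1", 9))   # 3 FP, 9 TN
  m <- classificationMetrics(truth, pred)
  expect_equal(m$accuracy, 15 / 20)
  expect_equal(m$tpr, 6 / 8)
  expect_equal(m$fpr, 3 / 12)
  expect_equal(m$balancedAccuracy, (6 / 8 + 9 / 12) / 2)
  expect_equal(m$f1, 2 * 6 / (2 * 6 + 3 + 2))
  # constant scores give AUC 1/2; the package AUC matches a rank-sum oracle
  scores <- withr::with_seed(3, rnorm(20))
  m2 <- classificationMetrics(truth, pred, scores = scores)
  expect_equal(m2$auc, oracleAUC(truth, scores, "1"))
  expect_equal(classificationMetrics(truth, pred, scores = rep(0, 20))$auc, 0.5)
})

test_that("training on the synthetic cohort recovers the planted signal", {
  fit <- smallDivisionFit()
  vba <- sapply(fit$foldMetrics, function(f) f$validation$balancedAccuracy)
  expect_gt(mean(vba), 0.6)
  # the trained model beats chance on the held-out plant
  ft <- smallDivisionData()
  te <- sampleData(ft)$plant %in% smallSplits()$testPlants
  ev <- evaluateClassifier(fit$model, meristemNet:::subsetRowsFT(ft, te))
  expect_gt(ev$balancedAccuracy, 0.55)
  expect_gt(ev$auc, 0.6)
  expect_true(all(ev$roc$tpr >= 0 & ev$roc$tpr <= 1))
})

test_that("trained weights emphasize the planted area and centrality signal", {
  m <- smallDivisionFit()$model
  w <- stats::setNames(as.numeric(m@weights), m@featureNames)
  # group columns into feature families (collinear scenario variants share
  # the planted signal, so the family mean is the stable quantity)
  fam <- sub("@.*$", "", names(w))
  famW <- tapply(w, fam, mean)         # signed mean weight per family
  famA <- tapply(abs(w), fam, mean)    # magnitude per family
  expect_gt(famW[["area"]], 0)
  expect_gt(famW[["harmonic"]], 0)
  topFam <- names(sort(famA, decreasing = TRUE))
  expect_true(all(c("area", "harmonic") %in% topFam[1:6]),
              label = paste("top families:", paste(topFam[1:6], collapse = ", ")))
})

test_that("z-normalization comes from training rows only", {
  fit <- smallDivisionFit()$model
  ft <- smallDivisionData()
  tr <- sampleData(ft)$plant %in% smallSplits()$trainPlants
  X <- featureMatrix(ft)[tr, fit@featureNames]
  Z <- meristemNet:::zApply(X, list(center = fit@center, scale = fit@scale))
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  sds <- apply(Z, 2, sd)
  expect_lt(max(abs(sds[fit@scale != 1] - 1)), 1e-9)
  # normalizing an already-normalized matrix with the stored stats is not the
  # identity (the stats belong to the raw training data)
  Z2 <- meristemNet:::zApply(Z, list(center = fit@center, scale = fit@scale))
  expect_gt(max(abs(Z2 - Z)), 1e-6)
})

test_that("label flip symmetry: negated model yields identical accuracy", {
  fit <- smallDivisionFit()$model
  ft <- smallDivisionData()
  y <- sampleData(ft)$label
  pred <- predict(fit, ft)
  flipped <- fit
  flipped@weights <- -fit@weights
  flipped@intercepts <- -fit@intercepts
  predF <- predict(flipped, ft)
  yF <- as.character(-as.numeric(y))
  expect_equal(mean(pred == y), mean(predF == yF))
})

test_that("serialized models reproduce their predictions exactly", {
  fit <- smallDivisionFit()$model
  ft <- smallDivisionData()
  tmp <- tempfile(fileext = ".json")
  writeClassifier(fit, tmp)
  back <- readClassifier(tmp)
  expect_identical(decisionValues(back, ft), decisionValues(fit, ft))
  expect_identical(predict(back, ft), predict(fit, ft))
  expect_identical(back@cost, fit@cost)
})

test_that("permuted labels bring validation accuracy to chance", {
  ft <- smallDivisionData()
  null <- permutationControl(ft, smallSplits(), n = 15, seed = 5)
  expect_equal(nrow(null), 15)
  expect_lt(abs(mean(null$validationBalancedAccuracy) - 0.5), 0.07)
  # observed performance clears the null distribution
  obs <- mean(sapply(smallDivisionFit()$foldMetrics,
                     function(f) f$validation$balancedAccuracy))
  expect_gt(obs, quantile(null$validationBalancedAccuracy, 0.95))
})

test_that("learning curve at fraction 1 reproduces the full-data fit", {
  ft <- smallDivisionData()
  lc <- learningCurve(ft, smallSplits(), fractions = c(0.4, 1),
                      C = smallDivisionFit()$C, seed = 3)
  full <- mean(sapply(smallDivisionFit()$foldMetrics,
                      function(f) f$train$balancedAccuracy))
  expect_equal(lc$train[lc$fraction == 1], full, tolerance = 1e-12)
  expect_equal(nrow(lc), 2)
})
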