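#' Label cells as dividing or non-dividing
#'
#' A cell gets label +1 when it appears as a parent in the lineage map between
#' this time point and the next, and -1 when it survives undivided.
#'
#' @param tg the time-t \linkS4class{TissueGraph}.
#' @param lineage the \linkS4class{LineageMap} for the t -> t+1 transition.
#' @param cells cells to label (typically the central non-peripheral cells);
#'   default: all cells of the graph.
#' @return named numeric vector of +1/-1 labels.
#' @export
labelDivisions <- function(tg, lineage, cells = NULL) {
  cells <- if (is.null(cells)) cellIds(tg) else as.character(cells)
  div <- divisions(lineage)$parent
  surv <- names(survivors(lineage))
  orphan <- setdiff(cells, c(div, surv))
  if (length(orphan))
    stopInput("cell(s) absent from both divisions and survivors: %s",
              paste(utils::head(orphan, 5), collapse = ", "))
  stats::setNames(ifelse(cells %in% div, 1, -1), cells)
}

#' Plant-wise train/validation/test split plan
#'
#' Holds out \code{nTestPlants} whole plants as the test set and partitions the
#' remaining plants into cross-validation folds in which each fold's
#' validation set is exactly one plant (leave-one-plant-out; the full study
#' design of 8 plants with 2 test plants yields six folds). With
#' \code{nFolds} set, plants are instead grouped into that many folds
#' (seeded), each fold validating on its plant group.
#'
#' @param plants character vector of plant ids (per-sample or unique).
#' @param nTestPlants number of plants held out for testing (default 2).
#' @param nFolds number of CV folds; NULL (default) = one fold per training
#'   plant.
#' @param seed integer seed for the test-plant draw and fold assignment.
#' @return list with \code{testPlants}, \code{trainPlants} and \code{folds}
#'   (each fold a list with \code{train} and \code{validation} plant ids).
#' @export
makeSplits <- function(plants, nTestPlants = 2, nFolds = NULL, seed = 1) {
  ids <- unique(as.character(plants))
  if (length(ids) < 3) stopInput("need at least 3 plants, got %d", length(ids))
  if (nTestPlants < 1 || length(ids) - nTestPlants < 2)
    stopInput("need at least 2 training plants after holding out %d", nTestPlants)
  testPlants <- withSeed(seed, sort(sample(ids, nTestPlants)))
  trainPlants <- setdiff(ids, testPlants)
  if (is.null(nFolds)) {
    groups <- as.list(trainPlants)
  } else {
    if (nFolds > length(trainPlants))
      stopInput("fewer training plants (%d) than folds (%d)",
                length(trainPlants), nFolds)
    perm <- withSeed(seed + 1, sample(trainPlants))
    groups <- split(perm, rep_len(seq_len(nFolds), length(perm)))
  }
  folds <- lapply(groups, function(v)
    list(train = setdiff(trainPlants, v), validation = v))
  names(folds) <- NULL
  list(testPlants = testPlants, trainPlants = trainPlants, folds = folds)
}

# ---- low-level linear SVM fit (libsvm via e1071) -------------------------

# X already normalized; returns weight vector/intercept with decision value
# oriented so that positive means `positiveClass`
fitLinearSVM <- function(X, y, C, classWeights, positiveClass) {
  yf <- factor(y)
  if (nlevels(yf) < 2) stopInput("training data contains a single class")
  m <- e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE,
                  class.weights = classWeights[levels(yf)])
  w <- as.numeric(t(m$coefs) %*% m$SV)
  b <- -m$rho
  if (m$levels[m$labels[1]] != positiveClass) { w <- -w; b <- -b }
  list(w = w, b = b)
}

newLinearClassifier <- function(featureNames, stats, W, b, classes, C,
                                classWeights, featureSet) {
  methods::new("LinearTissueClassifier",
    featureNames = featureNames,
    center = stats::setNames(as.numeric(stats$center), featureNames),
    scale = stats::setNames(as.numeric(stats$scale), featureNames),
    weights = W, intercepts = b, classes = classes, cost = C,
    classWeights = classWeights, featureSet = featureSet)
}

# ---- prediction -----------------------------------------------------------

asModelMatrix <- function(model, newdata) {
  X <- if (methods::is(newdata, "FeatureTable")) featureMatrix(newdata)
       else as.matrix(newdata)
  miss <- setdiff(model@featureNames, colnames(X))
  if (length(miss))
    stopInput("newdata lacks training column(s): %s",
              paste(utils::head(miss, 5), collapse = ", "))
  X[, model@featureNames, drop = FALSE]
}

#' Decision values of a linear tissue classifier
#'
#' @param object a \linkS4class{LinearTissueClassifier}.
#' @param newdata a \linkS4class{FeatureTable} or matrix with the training
#'   columns.
#' @param normalization \code{"train"} (default) z-normalizes with the stored
#'   training statistics; \code{"self"} uses the new data's own statistics
#'   (for external datasets such as mutants).
#' @return numeric matrix, samples x classes (binary: one column; positive
#'   favors the positive class).
#' @name decisionValues
#' @aliases decisionValues,LinearTissueClassifier-method
#' @export
setMethod("decisionValues", "LinearTissueClassifier",
  function(object, newdata, normalization = c("train", "self")) {
    normalization <- match.arg(normalization)
    X <- asModelMatrix(object, newdata)
    st <- if (normalization == "train")
      list(center = object@center, scale = object@scale) else zStats(X)
    Z <- zApply(X, st)
    D <- Z %*% object@weights
    D <- sweep(D, 2, object@intercepts, "+")
    colnames(D) <- if (ncol(D) == 1) utils::tail(object@classes, 1) else object@classes
    D
  })

#' Predict with a linear tissue classifier
#'
#' Binary models return the sign rule sign(w.x + b) mapped to the class
#' labels; multiclass (one-vs-rest) models return the class with the largest
#' decision value.
#'
#' @param object a \linkS4class{LinearTissueClassifier}.
#' @param newdata feature table or matrix.
#' @param normalization see \code{\link{decisionValues}}.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
setMethod("predict", "LinearTissueClassifier",
  function(object, newdata, normalization = c("train", "self"), ...) {
    D <- decisionValues(object, newdata, match.arg(normalization))
    if (length(object@classes) == 2) {
      ifelse(D[, 1] > 0, utils::tail(object@classes, 1), object@classes[1])
    } else {
      object@classes[max.col(D, ties.method = "first")]
    }
  })

setMethod("show", "LinearTissueClassifier", function(object) {
  cat(sprintf("LinearTissueClassifier: %d features (%s), classes {%s}, C = %g\n",
              length(object@featureNames), object@featureSet,
              paste(object@classes, collapse = ", "), object@cost))
})

# ---- metrics --------------------------------------------------------------

#' Classifier performance metrics
#'
#' Computes, from labels and decision scores, the accuracy (raw), balanced
#' accuracy (mean of per-class recall; the class-weighted "accuracy" used
#' throughout, matching the class-weighted training), F1-score of the positive
#' class, true/false positive rates and the ROC AUC (decision value as score).
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param scores decision values for the positive class (binary only; NULL
#'   skips the AUC).
#' @param positiveClass label treated as positive (default "1").
#' @return list of metrics; binary input also gets \code{tpr}, \code{fpr},
#'   \code{f1}, \code{auc}.
#' @export
classificationMetrics <- function(truth, predicted, scores = NULL,
                                  positiveClass = "1") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- sort(unique(truth))
  acc <- mean(truth == predicted)
  recall <- vapply(classes, function(cl) mean(predicted[truth == cl] == cl),
                   numeric(1))
  out <- list(accuracy = acc, balancedAccuracy = mean(recall))
  if (length(classes) == 2 && positiveClass %in% classes) {
    pos <- truth == positiveClass
    tp <- sum(pos & predicted == positiveClass)
    fp <- sum(!pos & predicted == positiveClass)
    fn <- sum(pos & predicted != positiveClass)
    tn <- sum(!pos & predicted != positiveClass)
    out$tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    out$fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
    out$f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    if (!is.null(scores)) {
      out$auc <- as.numeric(pROC::auc(pROC::roc(
        response = factor(truth, levels = c(setdiff(classes, positiveClass),
                                            positiveClass)),
        predictor = as.numeric(scores), direction = "<", quiet = TRUE)))
    }
  }
  out
}

#' Evaluate a classifier on labeled data
#'
#' @param model a \linkS4class{LinearTissueClassifier}.
#' @param ft a labeled \linkS4class{FeatureTable} (\code{label} in its sample
#'   metadata) or a matrix together with \code{labels}.
#' @param labels labels when \code{ft} is a matrix.
#' @param normalization see \code{\link{decisionValues}}.
#' @return for binary models: metrics list plus \code{roc} curve points; for
#'   multiclass: accuracy, balanced accuracy, per-class one-vs-rest AUC and
#'   macro AUC.
#' @export
evaluateClassifier <- function(model, ft, labels = NULL,
                               normalization = c("train", "self")) {
  normalization <- match.arg(normalization)
  if (is.null(labels)) {
    if (!methods::is(ft, "FeatureTable") || is.null(sampleData(ft)$label))
      stopInput("provide labels or a labeled FeatureTable")
    labels <- sampleData(ft)$label
  }
  labels <- as.character(labels)
  D <- decisionValues(model, ft, normalization)
  pred <- predict(model, ft, normalization)
  if (length(model@classes) == 2) {
    met <- classificationMetrics(labels, pred, scores = D[, 1],
                                 positiveClass = utils::tail(model@classes, 1))
    r <- pROC::roc(response = factor(labels, levels = model@classes),
                   predictor = as.numeric(D[, 1]), direction = "<", quiet = TRUE)
    met$roc <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
    met
  } else {
    met <- classificationMetrics(labels, pred)
    aucs <- vapply(model@classes, function(cl) {
      as.numeric(pROC::auc(pROC::roc(
        response = factor(ifelse(labels == cl, cl, "rest"),
                          levels = c("rest", cl)),
        predictor = D[, cl], direction = "<", quiet = TRUE)))
    }, numeric(1))
    met$classAUC <- aucs
    met$macroAUC <- mean(aucs)
    met
  }
}

# ---- training -------------------------------------------------------------

#' Regularization grids
#'
#' \code{defaultCGrid}: 13 log-spaced values covering 1e-4..1e1 (the default).
#' \code{paperCGrid}: 100 linearly spaced values inside each decade of
#' 1e-4..1e1 (500 candidates), the fully literal grid.
#'
#' @return numeric vector of C values.
#' @export
defaultCGrid <- function() 10^seq(-4, 1, length.out = 13)

#' @rdname defaultCGrid
#' @export
paperCGrid <- function()
  unlist(lapply(-4:0, function(k) seq(10^k, 10^(k + 1), length.out = 101)[-101]))

# pull matrix/labels/plants out of a labeled FeatureTable
datasetParts <- function(ft) {
  sd <- sampleData(ft)
  if (is.null(sd$label)) stopInput("FeatureTable carries no 'label' metadata")
  list(X = featureMatrix(ft), y = as.character(sd$label),
       plant = as.character(sd$plant))
}

#' Train the class-weighted linear division classifier
#'
#' Grid-searches the regularization constant C by plant-wise cross-validation:
#' within each fold the features are z-normalized on the fold's training rows
#' only, a hinge-loss linear SVM with inverse-class-frequency weights is
#' fitted, and the fold's one-plant validation set is scored by balanced
#' accuracy. The C maximizing the mean validation balanced accuracy is
#' selected (ties to the smaller C) and the final model is refitted on all
#' train-validation rows.
#'
#' @param ft labeled \linkS4class{FeatureTable} (label +1/-1, plant metadata).
#' @param splits a \code{\link{makeSplits}} plan.
#' @param cGrid candidate C values (default \code{\link{defaultCGrid}()}).
#' @param featureSet name recorded in the model (default: attr or "custom").
#' @return list with \code{model} (\linkS4class{LinearTissueClassifier}),
#'   \code{C}, \code{foldMetrics} (per-fold train/validation metrics at the
#'   selected C), \code{gridValidation} (mean validation balanced accuracy per
#'   C).
#' @export
trainDivisionClassifier <- function(ft, splits, cGrid = defaultCGrid(),
                                    featureSet = "custom") {
  dp <- datasetParts(ft)
  trainRows <- dp$plant %in% splits$trainPlants
  X <- dp$X[trainRows, , drop = FALSE]
  y <- dp$y[trainRows]
  plant <- dp$plant[trainRows]
  if (any(!is.finite(X))) stopInput("non-finite feature values")
  classes <- sort(unique(y))  # "-1" < "1"
  pos <- utils::tail(classes, 1)

  foldEval <- function(C) {
    vapply(splits$folds, function(f) {
      tr <- plant %in% f$train; va <- plant %in% f$validation
      st <- zStats(X[tr, , drop = FALSE])
      cw <- balancedClassWeights(y[tr])
      fit <- fitLinearSVM(zApply(X[tr, , drop = FALSE], st), y[tr], C, cw, pos)
      dv <- zApply(X[va, , drop = FALSE], st) %*% fit$w + fit$b
      pr <- ifelse(dv > 0, pos, classes[1])
      classificationMetrics(y[va], pr)$balancedAccuracy
    }, numeric(1))
  }
  gridVal <- vapply(cGrid, function(C) mean(foldEval(C)), numeric(1))
  C <- cGrid[which.max(gridVal)]

  foldMetrics <- lapply(splits$folds, function(f) {
    tr <- plant %in% f$train; va <- plant %in% f$validation
    st <- zStats(X[tr, , drop = FALSE])
    cw <- balancedClassWeights(y[tr])
    fit <- fitLinearSVM(zApply(X[tr, , drop = FALSE], st), y[tr], C, cw, pos)
    scoreOf <- function(rows) {
      dv <- zApply(X[rows, , drop = FALSE], st) %*% fit$w + fit$b
      classificationMetrics(y[rows], ifelse(dv > 0, pos, classes[1]),
                            scores = dv, positiveClass = pos)
    }
    list(train = scoreOf(tr), validation = scoreOf(va))
  })

  st <- zStats(X)
  cw <- balancedClassWeights(y)
  fit <- fitLinearSVM(zApply(X, st), y, C, cw, pos)
  model <- newLinearClassifier(colnames(X), st, matrix(fit$w, ncol = 1),
                               fit$b, classes, C, cw, featureSet)
  list(model = model, C = C, foldMetrics = foldMetrics,
       gridValidation = stats::setNames(gridVal, signif(cGrid, 6)))
}

#' Permutation control for the division classifier
#'
#' Shuffles the labels within the train-validation pool, retrains the
#' classifier with the default regularization, and records train, validation
#' and (optionally) test metrics per repetition, yielding the null
#' distribution against which the observed performance is judged.
#'
#' @param ft labeled \linkS4class{FeatureTable}.
#' @param splits a \code{\link{makeSplits}} plan.
#' @param n number of label permutations (default 100).
#' @param seed integer seed.
#' @param C regularization used for every permuted fit (default 1, the
#'   library default).
#' @return data.frame with one row per repetition: train/validation (fold
#'   means) and test balanced accuracy and raw accuracy.
#' @export
permutationControl <- function(ft, splits, n = 100, seed = 1, C = 1) {
  dp <- datasetParts(ft)
  trainRows <- dp$plant %in% splits$trainPlants
  X <- dp$X[trainRows, , drop = FALSE]
  y0 <- dp$y[trainRows]
  plant <- dp$plant[trainRows]
  Xte <- dp$X[!trainRows, , drop = FALSE]
  yte <- dp$y[!trainRows]
  classes <- sort(unique(y0)); pos <- utils::tail(classes, 1)
  res <- lapply(seq_len(n), function(i) {
    y <- withSeed(deriveSeed(seed, i), sample(y0))
    fm <- vapply(splits$folds, function(f) {
      tr <- plant %in% f$train; va <- plant %in% f$validation
      if (length(unique(y[tr])) < 2) return(c(NA_real_, NA_real_))
      st <- zStats(X[tr, , drop = FALSE])
      fit <- fitLinearSVM(zApply(X[tr, , drop = FALSE], st), y[tr], C,
                          balancedClassWeights(y[tr]), pos)
      prOf <- function(rows) {
        dv <- zApply(X[rows, , drop = FALSE], st) %*% fit$w + fit$b
        classificationMetrics(y[rows], ifelse(dv > 0, pos, classes[1]))$balancedAccuracy
      }
      c(prOf(tr), prOf(va))
    }, numeric(2))
    st <- zStats(X)
    fit <- fitLinearSVM(zApply(X, st), y, C, balancedClassWeights(y), pos)
    dvTe <- zApply(Xte, st) %*% fit$w + fit$b
    teBA <- if (nrow(Xte))
      classificationMetrics(yte, ifelse(dvTe > 0, pos, classes[1]))$balancedAccuracy
    else NA_real_
    data.frame(rep = i, trainBalancedAccuracy = mean(fm[1, ], na.rm = TRUE),
               validationBalancedAccuracy = mean(fm[2, ], na.rm = TRUE),
               testBalancedAccuracy = teBA)
  })
  do.call(rbind, res)
}

#' Learning curve of the division classifier
#'
#' Retrains the classifier on stratified subsamples of each fold's training
#' rows (hyperparameters fixed) and reports the train and validation balanced
#' accuracy per training fraction, averaged over folds.
#'
#' @param ft labeled \linkS4class{FeatureTable}.
#' @param splits a \code{\link{makeSplits}} plan.
#' @param fractions training fractions in (0, 1].
#' @param C fixed regularization (the selected C).
#' @param seed integer seed for the subsampling.
#' @return data.frame with columns \code{fraction}, \code{train},
#'   \code{validation} (balanced accuracy, fold means) and \code{n} (mean
#'   training rows used).
#' @export
learningCurve <- function(ft, splits, fractions = seq(0.2, 1, by = 0.2),
                          C = 1, seed = 1) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  dp <- datasetParts(ft)
  trainRows <- dp$plant %in% splits$trainPlants
  X <- dp$X[trainRows, , drop = FALSE]
  y <- dp$y[trainRows]
  plant <- dp$plant[trainRows]
  classes <- sort(unique(y)); pos <- utils::tail(classes, 1)
  rows <- lapply(seq_along(fractions), function(k) {
    fr <- fractions[k]
    fm <- vapply(seq_along(splits$folds), function(j) {
      f <- splits$folds[[j]]
      tr <- which(plant %in% f$train); va <- which(plant %in% f$validation)
      sub <- if (fr < 1) {
        unlist(lapply(split(tr, y[tr]), function(ix)
          withSeed(deriveSeed(seed, k * 1000 + j),
                   sample(ix, max(1, round(fr * length(ix)))))))
      } else tr
      if (length(unique(y[sub])) < 2) return(c(NA_real_, NA_real_, NA_real_))
      st <- zStats(X[sub, , drop = FALSE])
      fit <- fitLinearSVM(zApply(X[sub, , drop = FALSE], st), y[sub], C,
                          balancedClassWeights(y[sub]), pos)
      baOf <- function(ix) {
        dv <- zApply(X[ix, , drop = FALSE], st) %*% fit$w + fit$b
        classificationMetrics(y[ix], ifelse(dv > 0, pos, classes[1]))$balancedAccuracy
      }
      c(baOf(sub), baOf(va), length(sub))
    }, numeric(3))
    if (all(is.na(fm[1, ])))
      warning(sprintf("fraction %.2f produced single-class subsamples; skipped", fr))
    data.frame(fraction = fr, train = mean(fm[1, ], na.rm = TRUE),
               validation = mean(fm[2, ], na.rm = TRUE),
               n = mean(fm[3, ], na.rm = TRUE))
  })
  do.call(rbind, rows)
}
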