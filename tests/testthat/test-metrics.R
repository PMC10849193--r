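test_that("confusion counts follow the score >= threshold rule", {
  cc <- confusionCounts(c(0.9, 0.1), c(1, 0))
  expect_equal(c(cc@TP, cc@TN, cc@FP, cc@FN), c(1L, 1L, 0L, 0L))
  # boundary: a score exactly at the threshold counts as predicted positive
  cc2 <- confusionCounts(0.5, 0)
  expect_equal(cc2@FP, 1L)
  withr::with_seed(30, {
    scores <- runif(50)
    labels <- rbinom(50, 1, 0.5)
  })
  cc3 <- confusionCounts(scores, labels, 0.4)
  expect_equal(cc3@TP, sum(scores >= 0.4 & labels == 1))
  expect_equal(cc3@TN, sum(scores < 0.4 & labels == 0))
  expect_equal(cc3@TP + cc3@TN + cc3@FP + cc3@FN, 50L)
  expect_error(confusionCounts(numeric(0), integer(0)), "empty")
})

test_that("confusion metrics reproduce closed-form cases", {
  perfect <- confusionCountsFrom(25, 25, 0, 0)
  m <- confusionMetrics(perfect)
  expect_equal(unname(m[c("Acc", "Sens", "Spec", "Prec", "MCC")]),
               c(100, 100, 100, 100, 100))
  allPos <- confusionCountsFrom(50, 0, 50, 0)
  expect_warning(m2 <- confusionMetrics(allPos), "zero denominator")
  expect_equal(unname(m2["Spec"]), 0)
  expect_equal(unname(m2["Sens"]), 100)
  expect_equal(unname(m2["MCC"]), 0)
})

test_that("balanced-fold identities reproduce the reported 5-fold table", {
  # printed per-fold sensitivity/specificity, balanced classes; the remaining
  # columns follow from the metric definitions
  printed <- data.frame(
    Acc = c(84.95, 84.65, 83.23, 83.18, 83.94),
    Sens = c(86.26, 87.88, 81.21, 84.24, 85.86),
    Spec = c(83.64, 81.41, 85.25, 82.12, 82.02),
    Prec = c(84.06, 82.54, 84.63, 82.49, 82.68),
    MCC = c(69.92, 69.44, 66.52, 66.38, 67.93)
  )
  for (i in seq_len(nrow(printed))) {
    TP <- round(printed$Sens[i] * 100)
    TN <- round(printed$Spec[i] * 100)
    cc <- confusionCountsFrom(TP, TN, 10000 - TN, 10000 - TP)
    m <- confusionMetrics(cc)
    expect_equal(circMiRCAE:::roundHalfUp(m[["Acc"]], 2), printed$Acc[i])
    expect_equal(circMiRCAE:::roundHalfUp(m[["Prec"]], 2), printed$Prec[i])
    # the published MCC column carries the rounding of the underlying fold
    # counts, so reconstruction from 2-decimal Sens/Spec agrees to 0.01
    expect_lte(abs(circMiRCAE:::roundHalfUp(m[["MCC"]], 2) - printed$MCC[i]),
               0.011)
    # balanced classes: accuracy is the sensitivity/specificity midpoint
    expect_equal(m[["Acc"]], (printed$Sens[i] + printed$Spec[i]) / 2,
                 tolerance = 1e-12)
  }
  # the first fold matches every printed column exactly
  cc1 <- confusionCountsFrom(8626, 8364, 1636, 1374)
  m1 <- circMiRCAE:::roundHalfUp(confusionMetrics(cc1), 2)
  expect_equal(unname(m1[c("Acc", "Prec", "MCC")]), c(84.95, 84.06, 69.92))
})

test_that("MCC is a bounded symmetric correlation over random tables", {
  withr::with_seed(31, {
    for (rep in 1:2000) {
      counts <- sample(0:40, 4, replace = TRUE)
      if (sum(counts) == 0) next
      cc <- confusionCountsFrom(counts[1], counts[2], counts[3], counts[4])
      m <- suppressWarnings(confusionMetrics(cc))
      expect_gte(m[["MCC"]], -100)
      expect_lte(m[["MCC"]], 100)
      # class swap: TP<->TN, FP<->FN leaves MCC unchanged
      swapped <- confusionCountsFrom(counts[2], counts[1], counts[4],
                                     counts[3])
      expect_equal(suppressWarnings(confusionMetrics(swapped))[["MCC"]],
                   m[["MCC"]])
    }
  })
})

test_that("ROC AUC equals the pair-counting oracle and handles ties", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAUC(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(rocAUC(runif(5), rep(1, 5)), "both classes")
  withr::with_seed(32, {
    for (rep in 1:10) {
      scores <- sample(seq(0, 1, 0.1), 30, replace = TRUE) # force ties
      labels <- rbinom(30, 1, 0.5)
      if (length(unique(labels)) < 2) next
      expect_equal(rocAUC(scores, labels), aucOracle(scores, labels))
    }
  })
})

test_that("ROC AUC is invariant to monotone transforms and anti-symmetric", {
  withr::with_seed(33, {
    scores <- rnorm(40)
    labels <- rbinom(40, 1, 0.5)
  })
  a <- rocAUC(scores, labels)
  expect_equal(rocAUC(exp(scores), labels), a)
  expect_equal(rocAUC(qlogis(plogis(scores)), labels), a)
  expect_equal(rocAUC(-scores, labels), 1 - a)
})

test_that("ROC AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(34, {
    scores <- runif(60)
    labels <- rbinom(60, 1, 0.4)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAUC(scores, labels), ref)
})

test_that("AUPR follows step-wise average precision", {
  expect_equal(prAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # constant scores: precision is the prevalence
  expect_equal(prAUC(rep(0.3, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_error(prAUC(runif(4), rep(0, 4)), "positive")
  withr::with_seed(35, {
    for (rep in 1:10) {
      scores <- sample(seq(0, 1, 0.2), 30, replace = TRUE)
      labels <- rbinom(30, 1, 0.4)
      if (sum(labels) == 0) next
      expect_equal(prAUC(scores, labels), aprOracle(scores, labels))
    }
  })
})

test_that("fold aggregation uses the mean and the sample SD", {
  aucs <- c(0.9166, 0.9147, 0.9102, 0.9131, 0.9142)
  accs <- c(84.95, 84.65, 83.23, 83.18, 83.94)
  agg <- aggregateFolds(data.frame(Acc = accs, AUC = aucs))
  expect_equal(circMiRCAE:::roundHalfUp(agg["Average", "AUC"], 4), 0.9138)
  expect_equal(circMiRCAE:::roundHalfUp(agg["SD", "AUC"], 4), 0.0024)
  expect_equal(circMiRCAE:::roundHalfUp(agg["Average", "Acc"], 2), 83.99)
  # population SD would NOT reproduce the printed dispersion
  expect_false(isTRUE(all.equal(
    circMiRCAE:::roundHalfUp(sqrt(mean((aucs - mean(aucs))^2)), 4), 0.0024)))
  same <- aggregateFolds(data.frame(AUC = rep(0.9, 5)))
  expect_equal(same["SD", "AUC"], 0)
})

test_that("report formatting rounds half away from zero", {
  expect_equal(circMiRCAE:::roundHalfUp(84.645, 2), 84.65)
  expect_equal(circMiRCAE:::roundHalfUp(-84.645, 2), -84.65)
  expect_equal(circMiRCAE:::roundHalfUp(0.91376, 4), 0.9138)
  folds <- data.frame(Acc = c(84.645, 50), Sens = c(1, 2), Spec = c(1, 2),
                      Prec = c(1, 2), MCC = c(1, 2), AUC = c(0.91376, 0.5),
                      AUPR = c(0.5, 0.5))
  rep <- new("FoldReport", folds = folds, summary = aggregateFolds(folds),
             k = 2L, seed = 1L, metadata = list())
  tab <- formatFoldReport(rep)
  expect_identical(tab$Fold, c("Fold1", "Fold2", "Average", "SD"))
  expect_equal(tab$Acc[1], 84.65)
  expect_equal(tab$AUC[1], 0.9138)
})

test_that("curve points sweep thresholds over distinct scores", {
  pts <- curvePoints(c(0.9, 0.7, 0.7, 0.2), c(1, 1, 0, 0))
  expect_equal(pts$roc$tpr[length(pts$roc$tpr)], 1)
  expect_equal(pts$roc$fpr[length(pts$roc$fpr)], 1)
  expect_true(all(diff(pts$roc$fpr) >= 0))
  expect_true(all(pts$pr$precision >= 0 & pts$pr$precision <= 1))
})
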