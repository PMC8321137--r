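test_that("mRMR ranks a label copy first and penalizes duplicates", {
  set.seed(1)
  y <- factor(rep(c("a", "b", "c", "d"), each = 10))
  X <- cbind(copy = as.numeric(y) + rnorm(40, sd = 1e-3),
             noise1 = rnorm(40), noise2 = rnorm(40))
  sel <- mrmrSelect(X, y, 2)
  expect_equal(sel[1], 1L)

  # 3-feature MI-arithmetic toy: f2 is an exact duplicate of f1 (so its
  # redundancy equals its relevance), f3 is a noisier label copy that still
  # carries information beyond f1's duplication penalty
  y2 <- factor(rep(c(0, 1), each = 16))
  f1 <- as.numeric(y2 == 1); f1[c(1, 2, 17, 18)] <- 1 - f1[c(1, 2, 17, 18)]
  f3 <- as.numeric(y2 == 1); f3[c(5, 6, 21, 22)] <- 1 - f3[c(5, 6, 21, 22)]
  X2 <- cbind(f1 = f1, f2 = f1, f3 = f3)
  sel2 <- mrmrSelect(X2, y2, 2)
  expect_equal(sel2, c(1L, 3L))  # duplicate skipped by the redundancy term

  # first pick matches an exhaustive MI oracle
  D <- apply(X, 2, mbRadiomics:::.binEqFreq, nbins = 4L)
  rel <- apply(D, 2, function(col) {
    jt <- table(col, y); p <- jt / sum(jt)
    px <- rowSums(p); py <- colSums(p); nz <- p > 0
    sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  })
  expect_equal(which.max(rel), 1L, ignore_attr = TRUE)
  # constant feature never beats informative ones
  Xc <- cbind(X, const = rep(1, 40))
  expect_false(4L %in% mrmrSelect(Xc, y, 2))
})

test_that("sequential selection finds separating features and drops noise", {
  set.seed(2)
  y <- factor(rep(c("a", "b"), each = 12))
  sep1 <- ifelse(y == "a", -2, 2) + rnorm(24, sd = 0.2)
  sep2 <- ifelse(y == "a", 2, -2) + rnorm(24, sd = 0.2)
  X <- cbind(n1 = rnorm(24), sep1 = sep1, n2 = rnorm(24), sep2 = sep2)
  Xs <- scale(X)
  sel <- sfsSelect(Xs, y, 2)
  expect_lte(length(sel), 2L)
  expect_true(sel[1] %in% c(2L, 4L))  # a separating feature enters first
  acc <- mbRadiomics:::.innerCvAccuracy(Xs[, sel, drop = FALSE], y, 1)
  expect_equal(acc, 1.0)              # perfect within two steps

  # SBE eliminates the pure-noise column first: the two informative
  # directions are individually weak (classes separated along u + v), so
  # dropping either costs accuracy while dropping the noise does not
  set.seed(4)
  y3 <- factor(rep(c("a", "b"), each = 14))
  u <- ifelse(y3 == "a", 0, 1.1) + rnorm(28, sd = 0.5)
  v <- ifelse(y3 == "a", 0, 1.1) + rnorm(28, sd = 0.5)
  Xb <- cbind(u = u, noise = rnorm(28, sd = 1), v = v)
  selB <- sbeSelect(scale(Xb), y3, 2)
  expect_setequal(selB, c(1L, 3L))

  # m = total features returns everything
  expect_setequal(sfsSelect(Xs, y, 4), 1:4)
})

test_that("the one-vs-rest SVM separates, scores, and is deterministic", {
  set.seed(5)
  n <- 10
  centers <- rbind(c(4, 0), c(-4, 0), c(0, 4), c(0, -4))
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(2 * n, sd = 0.5), n), 2, centers[k, ], "+")))
  colnames(X) <- c("u", "v")
  y <- factor(rep(c("WNT", "SHH", "Group3", "Group4"), each = n))
  clf <- svmTrainOvR(X, y, C = 1)
  sc <- svmScore(clf, X)
  pred <- colnames(sc)[max.col(sc)]
  expect_gte(mean(pred == as.character(y)), 0.95)
  clf2 <- svmTrainOvR(X, y, C = 1)
  expect_identical(svmScore(clf2, X), sc)
  expect_error(svmTrainOvR(X, factor(rep("WNT", 40)), 1), "single class")
})

test_that("rank AUC handles perfect, constant and tied scorers", {
  pos <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(aucRank(c(6:10, 1:5), pos), 1)
  expect_equal(aucRank(rep(2, 10), pos), 0.5)
  expect_equal(aucRank(c(1:5, 6:10), pos), 0)
  set.seed(6)
  sc <- rnorm(30); lab <- runif(30) < 0.4
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(aucRank(sc, lab), ref, tolerance = 1e-12)
  }
})

test_that("nested LOOCV is deterministic and rejects degenerate cohorts", {
  tab <- simulateFeatureCohort(nPerSubgroup = rep(4L, 4),
                               effectModality = "CET1", effectSize = 2,
                               seed = 8)
  r1 <- nestedLOOCV(tab, algorithm = "mrmr", maxFeatures = 3,
                    Cgrid = c(0.1, 1))
  r2 <- nestedLOOCV(tab, algorithm = "mrmr", maxFeatures = 3,
                    Cgrid = c(0.1, 1))
  expect_identical(r1$predictions, r2$predictions)
  expect_true(all(r1$auc >= 0 & r1$auc <= 1))
  expect_equal(nrow(r1$predictions), 16L)
  X <- featureMatrix(tab)
  expect_error(nestedLOOCV(X, labels = rep("WNT", 16)), "single class")
  expect_error(nestedLOOCV(X[1:6, ], labels = rep(c("a", "b"), 3)),
               "n >= 8")
})

test_that("singleton-class outer folds are flagged, not dropped", {
  tab <- simulateFeatureCohort(nPerSubgroup = c(1L, 5L, 5L, 5L),
                               effectModality = "CET1", effectSize = 2,
                               seed = 9)
  r <- nestedLOOCV(tab, algorithm = "mrmr", maxFeatures = 2,
                   Cgrid = 1)
  expect_equal(length(r$flagged), 1L)
  expect_equal(nrow(r$predictions), 16L)
})

test_that("strong planted effects yield high AUC; permuted labels are at chance", {
  tab <- simulateFeatureCohort(nPerSubgroup = rep(6L, 4),
                               effectModality = "CET1", effectSize = 3,
                               nEffectFeatures = 12L, seed = 10)
  r <- nestedLOOCV(tab, algorithm = "mrmr", maxFeatures = 6,
                   Cgrid = c(0.1, 1, 10), modality = "CET1")
  expect_true(all(r$auc >= 0.9))
  y <- clinicalData(tab)$subgroup
  set.seed(11)
  accs <- replicate(5, {
    nestedLOOCV(featureMatrix(tab)[, 1:40], labels = sample(y),
                algorithm = "mrmr", maxFeatures = 3, Cgrid = 1)$accuracy
  })
  # mean permuted accuracy near chance for 4 balanced classes
  expect_lt(abs(mean(accs) - 0.25), 0.15)
})

test_that("the model grid recovers the modality carrying the effect", {
  tab <- simulateFeatureCohort(nPerSubgroup = rep(5L, 4),
                               effectModality = "T2WI", effectSize = 3,
                               nEffectFeatures = 12L, seed = 12)
  mg <- modelGrid(tab, algorithms = "mrmr",
                  modalities = c("CET1", "T2WI", "ADC"),
                  maxFeatures = 4, Cgrid = 1)
  expect_equal(dim(mg$accuracy), c(3L, 1L))
  expect_equal(mg$winner$modality, "T2WI")
})
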