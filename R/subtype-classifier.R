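# Molecular-subtype prediction: feature selection (mRMR / sequential
# forward / sequential backward) x linear SVM, evaluated by nested
# leave-one-out cross-validation. Every data-dependent step (standardization,
# pre-filtering, selection, regularization choice) runs inside the decoding
# set of each outer fold.

# equal-frequency discretization into (up to) nbins levels
.binEqFreq <- function(x, nbins = 4L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = nbins + 1L),
                        names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  findInterval(x, br, all.inside = TRUE)
}

# plug-in mutual information (bits) between two discrete vectors
.mutualInfo <- function(a, b) {
  jt <- table(a, b)
  p <- jt / sum(jt)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy mRMR (MID difference variant): at each step pick the feature
#' maximizing `I(f; y) - mean(I(f; s))` over the already-selected set `s`,
#' with mutual information estimated on 4 equal-frequency bins per feature.
#' Deterministic: ties are broken by column order; constant features have
#' zero MI and are never preferred over informative ones.
#'
#' @param X subjects x features numeric matrix.
#' @param y class labels (factor or vector).
#' @param m number of features to select.
#' @param nbins discretization bins.
#' @return Integer vector of selected column indices, in selection order.
#' @export
mrmrSelect <- function(X, y, m, nbins = 4L) {
  m <- min(m, ncol(X))
  if (length(unique(y)) < 2) stop("labels must have >= 2 classes")
  D <- apply(X, 2, .binEqFreq, nbins = nbins)
  rel <- apply(D, 2, .mutualInfo, b = y)
  sel <- integer(0)
  red <- rep(0, ncol(X))
  for (step in seq_len(m)) {
    score <- rel - if (length(sel)) red / length(sel) else 0
    score[sel] <- -Inf
    pick <- unname(which.max(score))
    sel <- c(sel, pick)
    if (step < m)
      red <- red + apply(D, 2, .mutualInfo, b = D[, pick])
  }
  sel
}

# inner-LOOCV accuracy of a linear SVM on (pre-standardized) X. Explicit
# R-level leave-one-out: deterministic for a fixed subject order (libsvm's
# built-in cross-validation shuffles folds with an unseedable RNG).
.innerCvAccuracy <- function(X, y, C) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) return(0)
  n <- nrow(X)
  correct <- 0L
  for (i in seq_len(n)) {
    yt <- droplevels(y[-i])
    if (nlevels(yt) < 2) next
    fit <- suppressWarnings(
      e1071::svm(x = X[-i, , drop = FALSE], y = yt, kernel = "linear",
                 cost = C, scale = FALSE))
    pr <- predict(fit, X[i, , drop = FALSE])
    correct <- correct + (as.character(pr) == as.character(y[i]))
  }
  correct / n
}

#' Sequential forward / backward feature selection
#'
#' `sfsSelect()` greedily adds the feature that maximizes the inner-LOOCV
#' accuracy of a linear SVM on the candidate subset, up to `m` features
#' (with `m` = all features it exhausts the set, returning an ordering);
#' `sbeSelect()` starts from all
#' features and removes the feature whose removal keeps accuracy highest,
#' down to `m` features (stopping early if every removal strictly hurts).
#' Ties are broken by column order.
#'
#' @param X subjects x features matrix (standardized).
#' @param y class labels.
#' @param m target feature count.
#' @param C SVM cost used for the inner evaluations.
#' @return Integer vector of selected column indices.
#' @export
sfsSelect <- function(X, y, m, C = 1) {
  m <- min(m, ncol(X))
  sel <- integer(0)
  while (length(sel) < m) {
    cand <- setdiff(seq_len(ncol(X)), sel)
    acc <- vapply(cand, function(f)
      .innerCvAccuracy(X[, c(sel, f), drop = FALSE], y, C), numeric(1))
    sel <- c(sel, cand[which.max(acc)])
  }
  sel
}

#' @rdname sfsSelect
#' @export
sbeSelect <- function(X, y, m, C = 1) {
  sel <- seq_len(ncol(X))
  cur <- .innerCvAccuracy(X, y, C)
  while (length(sel) > max(m, 1L)) {
    acc <- vapply(seq_along(sel), function(r)
      .innerCvAccuracy(X[, sel[-r], drop = FALSE], y, C), numeric(1))
    top <- which.max(acc)
    if (acc[top] + 1e-12 < cur) break   # every removal strictly hurts
    cur <- acc[top]
    sel <- sel[-top]
  }
  sel
}

#' One-vs-rest linear SVM
#'
#' Trains four binary soft-margin linear SVMs (one per subgroup) on features
#' standardized by the supplied (training-fold) statistics; `svmScore()`
#' returns the four decision values for new subjects, oriented so that larger
#' means more like the class.
#'
#' @param X training subjects x features matrix (raw scale).
#' @param y class labels.
#' @param C cost parameter.
#' @param center,scale standardization statistics (defaults: from `X`).
#' @return An `ovr_svm` classifier.
#' @export
svmTrainOvR <- function(X, y, C = 1, center = NULL, scale = NULL) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("training fold has a single class")
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, sd)
    scale[scale < 1e-12] <- 1
  }
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  models <- lapply(levels(y), function(cls) {
    yb <- factor(ifelse(y == cls, "pos", "rest"), levels = c("pos", "rest"))
    suppressWarnings(
      e1071::svm(x = Xs, y = yb, kernel = "linear", cost = C, scale = FALSE))
  })
  structure(list(models = setNames(models, levels(y)), classes = levels(y),
                 center = center, scale = scale), class = "ovr_svm")
}

#' @rdname svmTrainOvR
#' @param object an `ovr_svm`.
#' @param newX matrix of new subjects (raw scale).
#' @return `svmScore()`: subjects x classes matrix of decision values.
#' @export
svmScore <- function(object, newX) {
  Xs <- sweep(sweep(newX, 2, object$center, "-"), 2, object$scale, "/")
  sc <- vapply(object$classes, function(cls) {
    pr <- predict(object$models[[cls]], Xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    if (grepl("^pos/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
  }, numeric(nrow(Xs)))
  matrix(sc, nrow = nrow(Xs), dimnames = list(rownames(newX), object$classes))
}

#' Rank-based (trapezoidal) ROC AUC
#'
#' Mann-Whitney AUC with ties counted half, so a constant scorer gives 0.5
#' and a perfect scorer 1.
#'
#' @param scores numeric decision values.
#' @param positive logical, TRUE for the positive class.
#' @return AUC in [0, 1] (`NA` if a class is absent).
#' @export
aucRank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Kruskal-Wallis p-value pre-filter: top q columns within the decoding set
.kwPreFilter <- function(X, y, q) {
  if (ncol(X) <= q) return(seq_len(ncol(X)))
  p <- apply(X, 2, function(v) {
    if (sd(v) < 1e-12) return(1)
    suppressWarnings(kruskal.test(v, factor(y))$p.value)
  })
  order(p)[seq_len(q)]
}

.selectFeatures <- function(Xs, y, algorithm, m, C = 1, preFilter = 30L) {
  pool <- seq_len(ncol(Xs))
  if (algorithm %in% c("sfs", "sbe") && ncol(Xs) > preFilter)
    pool <- .kwPreFilter(Xs, y, preFilter)
  Xp <- Xs[, pool, drop = FALSE]
  sel <- switch(algorithm,
    mrmr = mrmrSelect(Xp, y, m),
    sfs  = sfsSelect(Xp, y, m, C),
    sbe  = sbeSelect(Xp, y, m, C),
    stop("unknown selection algorithm: ", algorithm))
  pool[sel]
}

#' Nested leave-one-out cross-validation of the subtype classifier
#'
#' The outer loop holds out one subject; on the remaining decoding set only,
#' features are standardized, optionally pre-filtered (Kruskal-Wallis, for
#' the sequential algorithms), selected by the chosen algorithm, and the SVM
#' cost is picked from `Cgrid` by inner leave-one-out accuracy. The held-out
#' subject is then scored by a one-vs-rest linear SVM trained on the decoding
#' set. Outer predictions are pooled into the overall accuracy and a
#' one-vs-rest AUC per class. Deterministic for a fixed subject order.
#'
#' @param table [RadiomicsFeatureTable-class] or subjects x features matrix
#'   (complete).
#' @param labels subgroup labels (defaults to the table's clinical data).
#' @param algorithm `"mrmr"`, `"sfs"` or `"sbe"`.
#' @param maxFeatures features to select per outer fold.
#' @param Cgrid SVM cost grid for the inner loop.
#' @param modality feature scope: one of CET1, T1WI, T2WI, FLAIR, ADC
#'   (that modality's 49 features) or `"all"` (all 253).
#' @param preFilter decoding-set pre-filter width for sfs/sbe.
#' @return A `nested_cv_report`: list with `accuracy`, `auc` (per class),
#'   `predictions` (per-subject predicted label + 4 scores), `folds`
#'   (selected features and C per outer fold), `flagged` (outer folds whose
#'   class was a singleton).
#' @export
nestedLOOCV <- function(table, labels = NULL, algorithm = "mrmr",
                        maxFeatures = 5L, Cgrid = c(0.01, 0.1, 1, 10, 100),
                        modality = "all", preFilter = 30L) {
  X <- if (is(table, "RadiomicsFeatureTable")) featureMatrix(table) else table
  if (is.null(labels)) labels <- clinicalData(table)$subgroup
  if (nrow(X) < 8) stop("need n >= 8 subjects for nested LOOCV")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("degenerate cohort: a single class label")
  if (modality != "all") {
    cat0 <- featureCatalog()
    X <- X[, intersect(cat0$qualified[cat0$modality == modality],
                       colnames(X)), drop = FALSE]
  }
  if (anyNA(X))
    stop("feature table must be complete within the requested scope ",
         "(impute first)")
  n <- nrow(X)
  classes <- levels(y)
  scores <- matrix(NA_real_, n, length(classes),
                   dimnames = list(rownames(X), classes))
  pred <- character(n)
  folds <- vector("list", n)
  flagged <- integer(0)
  for (i in seq_len(n)) {
    Xd <- X[-i, , drop = FALSE]; yd <- droplevels(y[-i])
    if (sum(y == y[i]) == 1L) flagged <- c(flagged, i)
    ctr <- colMeans(Xd)
    scl <- apply(Xd, 2, sd); scl[scl < 1e-12] <- 1
    Xs <- sweep(sweep(Xd, 2, ctr, "-"), 2, scl, "/")
    sel <- .selectFeatures(Xs, yd, algorithm, maxFeatures,
                           C = 1, preFilter = preFilter)
    accs <- vapply(Cgrid, function(C)
      .innerCvAccuracy(Xs[, sel, drop = FALSE], yd, C), numeric(1))
    C <- Cgrid[which.max(accs)]
    clf <- svmTrainOvR(Xd[, sel, drop = FALSE], yd, C,
                       center = ctr[sel], scale = scl[sel])
    sc <- svmScore(clf, X[i, sel, drop = FALSE])
    scores[i, colnames(sc)] <- sc
    pred[i] <- colnames(sc)[which.max(sc)]
    folds[[i]] <- list(features = colnames(X)[sel], C = C)
  }
  auc <- vapply(classes, function(cls) {
    s <- scores[, cls]
    ok <- !is.na(s)
    aucRank(s[ok], (y == cls)[ok])
  }, numeric(1))
  structure(list(
    accuracy = mean(pred == as.character(y)),
    auc = auc,
    predictions = data.frame(subject = rownames(X) %||% seq_len(n),
                             truth = as.character(y), predicted = pred,
                             scores, check.names = FALSE),
    folds = folds, flagged = flagged,
    algorithm = algorithm, modality = modality),
    class = "nested_cv_report")
}

#' Selection-algorithm x modality model grid
#'
#' Runs [nestedLOOCV()] for every combination of feature scope (five
#' modalities + all) and selection algorithm, and reports the accuracy
#' matrix, the winning cell and the winner's per-class AUCs.
#'
#' @param table,labels,maxFeatures,Cgrid,preFilter as in [nestedLOOCV()].
#' @param algorithms selection algorithms to evaluate.
#' @param modalities feature scopes to evaluate.
#' @return list with `accuracy` (modalities x algorithms matrix), `winner`
#'   (`modality`, `algorithm`, `accuracy`), `winnerAUC`, `reports`.
#' @export
modelGrid <- function(table, labels = NULL,
                      algorithms = c("mrmr", "sfs", "sbe"),
                      modalities = c(MODALITIES, "all"),
                      maxFeatures = 5L, Cgrid = c(0.01, 0.1, 1, 10, 100),
                      preFilter = 30L) {
  acc <- matrix(NA_real_, length(modalities), length(algorithms),
                dimnames = list(modalities, algorithms))
  reports <- list()
  for (mo in modalities) for (al in algorithms) {
    rep0 <- nestedLOOCV(table, labels, algorithm = al, modality = mo,
                        maxFeatures = maxFeatures, Cgrid = Cgrid,
                        preFilter = preFilter)
    acc[mo, al] <- rep0$accuracy
    reports[[paste(mo, al, sep = ".")]] <- rep0
  }
  best <- which(acc == max(acc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  winner <- list(modality = modalities[best[1]],
                 algorithm = algorithms[best[2]],
                 accuracy = acc[best[1], best[2]])
  list(accuracy = acc, winner = winner,
       winnerAUC = reports[[paste(winner$modality, winner$algorithm,
                                  sep = ".")]]$auc,
       reports = reports)
}
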