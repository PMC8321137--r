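#' k-nearest-neighbour imputation of missing features
#'
#' Fills each missing cell with the unweighted mean (optionally
#' inverse-distance weighted) of the k nearest subjects observed at that
#' column. Distance between two subjects is Euclidean over the columns
#' observed in both, with each column z-scored by its observed mean/SD, and
#' rescaled by `sqrt(p / shared)` (p = total columns) so that subjects
#' sharing few columns are not artificially close. Ties are broken by
#' subject order, so imputation is deterministic. Observed cells are never
#' altered; a complete table is returned unchanged.
#'
#' @param table a [RadiomicsFeatureTable-class] or a subjects x features
#'   numeric matrix with `NA` for missing values.
#' @param k number of donors (default 3).
#' @param weighted if `TRUE`, donors are weighted by 1/(distance + eps).
#' @return The completed table, same class as the input.
#' @examples
#' tab <- simulateFeatureCohort(c(2, 2, 2, 2), missingProb = 0.3, seed = 2)
#' comp <- knnImpute(tab, k = 3)
#' anyNA(featureMatrix(comp))
#' @export
knnImpute <- function(table, k = 3L, weighted = FALSE) {
  isS4tab <- is(table, "RadiomicsFeatureTable")
  X <- if (isS4tab) featureMatrix(table) else table
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(X); p <- ncol(X)
  obs <- !is.na(X)
  nObs <- colSums(obs)
  short <- which(nObs < k)
  if (length(short) > 0)
    stop("column(s) observed in fewer than k subjects: ",
         paste(colnames(X)[short], collapse = ", "))
  if (!anyNA(X)) return(table)
  mu <- colMeans(X, na.rm = TRUE)
  sg <- apply(X, 2, sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sg, "/")
  out <- X
  for (s in which(rowSums(!obs) > 0)) {
    shared <- obs & matrix(obs[s, ], n, p, byrow = TRUE)
    nsh <- rowSums(shared)
    d2 <- rowSums((Z - matrix(Z[s, ], n, p, byrow = TRUE))^2 * shared,
                  na.rm = TRUE)
    dist <- sqrt(d2 * p / pmax(nsh, 1))
    dist[s] <- Inf
    dist[nsh == 0] <- Inf
    for (col in which(!obs[s, ])) {
      donors <- which(obs[, col] & is.finite(dist))
      if (length(donors) == 0)
        stop("subject ", rownames(X)[s] %||% s,
             " shares no observed columns with any donor for ",
             colnames(X)[col])
      donors <- donors[order(dist[donors], donors)][seq_len(min(k, length(donors)))]
      if (weighted) {
        w <- 1 / (dist[donors] + 1e-8)
        out[s, col] <- sum(w * X[donors, col]) / sum(w)
      } else {
        out[s, col] <- mean(X[donors, col])
      }
    }
  }
  if (isS4tab) {
    SummarizedExperiment::assay(table, "features") <- t(out)
    table
  } else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Column-mean imputation (baseline)
#'
#' Reference method for benchmarking [knnImpute()]: each missing cell gets
#' its column's observed mean.
#'
#' @inheritParams knnImpute
#' @return The completed table, same class as the input.
#' @export
meanImpute <- function(table) {
  isS4tab <- is(table, "RadiomicsFeatureTable")
  X <- if (isS4tab) featureMatrix(table) else table
  mu <- colMeans(X, na.rm = TRUE)
  for (col in seq_len(ncol(X))) X[is.na(X[, col]), col] <- mu[col]
  if (isS4tab) {
    SummarizedExperiment::assay(table, "features") <- t(X)
    table
  } else X
}
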