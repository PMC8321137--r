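# Gray-level co-occurrence and run-length texture. Both matrices pool counts
# across the 13 unique 3D voxel-index offsets at Chebyshev distance 1 before
# normalization (robust on thin masks), with runs/pairs restricted to masked
# voxels.

# the 13 unique direction offsets (first nonzero component positive)
OFFSETS13 <- matrix(c(
  1, 0, 0,   0, 1, 0,   0, 0, 1,
  1, 1, 0,   1, -1, 0,  1, 0, 1,   1, 0, -1,
  0, 1, 1,   0, 1, -1,
  1, 1, 1,   1, 1, -1,  1, -1, 1,  1, -1, -1), ncol = 3, byrow = TRUE)

# index ranges such that both (r) and (r + d) are in bounds along one axis
.pairRange <- function(n, d) {
  if (d >= 0) seq_len(n - d) else seq(1 - d, n)
}

#' Build the gray-level co-occurrence matrix
#'
#' Co-occurrence counts of discretized gray-level pairs over the 13 unique
#' 3D offsets at Chebyshev distance 1 (voxel-index offsets), both pair orders
#' counted (the matrix is symmetric), pooled across offsets and normalized to
#' sum to 1. Only pairs with both voxels inside the mask contribute.
#'
#' @param dvol a `discretized_volume` from [discretizeVolume()].
#' @param offsets optional m x 3 matrix of direction offsets (defaults to all
#'   13).
#' @return A `glcm_matrix`: list with `P` (ng x ng probabilities) and `ng`.
#' @export
glcmBuild <- function(dvol, offsets = OFFSETS13) {
  lev <- dvol$levels
  ng <- dvol$ng
  dm <- dim(lev)
  counts <- matrix(0, ng, ng)
  for (o in seq_len(nrow(offsets))) {
    d <- offsets[o, ]
    rx <- .pairRange(dm[1], d[1]); ry <- .pairRange(dm[2], d[2])
    rz <- .pairRange(dm[3], d[3])
    a <- lev[rx, ry, rz, drop = FALSE]
    b <- lev[rx + d[1], ry + d[2], rz + d[3], drop = FALSE]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    counts <- counts + matrix(tabulate(a[ok] + ng * (b[ok] - 1L),
                                       nbins = ng * ng), ng, ng)
  }
  counts <- counts + t(counts)   # count both pair orders -> symmetric
  tot <- sum(counts)
  if (tot == 0) stop("no co-occurring voxel pairs inside the mask")
  structure(list(P = counts / tot, ng = ng), class = "glcm_matrix")
}

.entropy2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

#' GLCM texture features
#'
#' The 22 co-occurrence features (Aerts-style definitions; all logs base 2,
#' with the convention 0 log 0 = 0): autocorrelation, cluster prominence /
#' shade / tendency, contrast, correlation, difference entropy,
#' dissimilarity, energy, entropy, homogeneity1, homogeneity2, the two
#' informational measures of correlation, IDMN, IDN, inverse variance,
#' maximum probability, sum average, sum entropy, sum variance, variance.
#' IDN and IDMN use `ng` in their normalizing denominators.
#'
#' @param M a `glcm_matrix` from [glcmBuild()].
#' @return Named numeric(22).
#' @export
glcmFeatures <- function(M) {
  P <- M$P; ng <- M$ng
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal and cross-diagonal marginals
  pxmy <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  pxpy <- vapply(2:(2 * ng), function(k) sum(P[(i + j) == k]), numeric(1))
  ks <- 2:(2 * ng)
  sumAvg <- sum(ks * pxpy)
  HXY <- .entropy2(P)
  pxyOuter <- outer(px, py)
  nz <- P > 0 & pxyOuter > 0
  HXY1 <- -sum(P[nz] * log2(pxyOuter[nz]))
  HXY2 <- .entropy2(pxyOuter)
  HX <- .entropy2(px)
  corr <- if (sdx < 1e-12 || sdy < 1e-12) 1 else
    (sum(i * j * P) - mux * muy) / (sdx * sdy)
  offdiag <- i != j
  c(autocorrelation = sum(i * j * P),
    cluster.prominence = sum((i + j - mux - muy)^4 * P),
    cluster.shade = sum((i + j - mux - muy)^3 * P),
    cluster.tendency = sum((i + j - mux - muy)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference.entropy = .entropy2(pxmy),
    dissimilarity = sum(abs(i - j) * P),
    energy = sum(P^2),
    entropy = HXY,
    homogeneity1 = sum(P / (1 + abs(i - j))),
    homogeneity2 = sum(P / (1 + (i - j)^2)),
    imc1 = if (HX < 1e-12) 0 else (HXY - HXY1) / HX,
    imc2 = sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0)),
    idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    idn = sum(P / (1 + abs(i - j) / ng)),
    inverse.variance = if (any(offdiag & P > 0))
      sum(P[offdiag] / (i[offdiag] - j[offdiag])^2) else 0,
    max.probability = max(P),
    sum.average = sumAvg,
    sum.entropy = .entropy2(pxpy),
    sum.variance = sum((ks - sumAvg)^2 * pxpy),
    variance = sum((i - mux)^2 * P))
}

#' Build the gray-level run-length matrix
#'
#' Maximal runs of equal gray level along each of the 13 unique 3D
#' directions, masked voxels only (a masked-out voxel breaks a run), pooled
#' across directions.
#'
#' @param dvol a `discretized_volume`.
#' @param offsets optional m x 3 matrix of directions (defaults to all 13).
#' @return A `glrlm_matrix`: list with `R` (ng x maxRunLength counts), `ng`,
#'   `nRuns`, `nDirections`, `nVoxels`.
#' @export
glrlmBuild <- function(dvol, offsets = OFFSETS13) {
  lev <- dvol$levels
  ng <- dvol$ng
  dm <- dim(lev)
  idx <- which(lev > 0L, arr.ind = TRUE)
  nvox <- nrow(idx)
  if (nvox == 0) stop("mask is empty")
  maxlen <- max(dm)
  R <- matrix(0, ng, maxlen)
  g0 <- lev[lev > 0L]
  off <- max(dm) + 2L
  big <- 4L * off
  for (o in seq_len(nrow(offsets))) {
    d <- offsets[o, ]
    # parameter t advances by 1 per step along d; key identifies the line
    ax <- which(d != 0)[1]
    t <- idx[, ax] * d[ax]            # d[ax] is +1 for the chosen axis
    keyc <- idx - tcrossprod(t, d)    # base point of the line
    key <- (keyc[, 1] + off) + (keyc[, 2] + off) * big +
           (keyc[, 3] + off) * big * big
    ord <- order(key, t)
    k <- key[ord]; tt <- t[ord]; g <- g0[ord]
    n <- length(k)
    newrun <- c(TRUE, k[-1] != k[-n] | tt[-1] != tt[-n] + 1L |
                        g[-1] != g[-n])
    runid <- cumsum(newrun)
    rl <- tabulate(runid)
    rg <- g[newrun]
    cnt <- tabulate(rg + ng * (rl - 1L), nbins = ng * maxlen)
    R <- R + matrix(cnt, ng, maxlen)
  }
  structure(list(R = R, ng = ng, nRuns = sum(R),
                 nDirections = nrow(offsets), nVoxels = nvox),
            class = "glrlm_matrix")
}

#' GLRLM texture features
#'
#' The 11 run-length features: short/long run emphasis (SRE, LRE), gray-level
#' and run-length non-uniformity (GLN, RLN), run percentage (RP = runs per
#' traversed voxel: `nRuns / (nDirections * nVoxels)`), low/high gray-level
#' run emphasis (LGLRE, HGLRE) and the four joint emphases (SRLGLE, SRHGLE,
#' LRLGLE, LRHGLE).
#'
#' @param RL a `glrlm_matrix` from [glrlmBuild()].
#' @return Named numeric(11).
#' @export
glrlmFeatures <- function(RL) {
  R <- RL$R
  Nr <- RL$nRuns
  if (Nr <= 0) stop("empty run-length matrix")
  i <- row(R); j <- col(R)
  c(SRE = sum(R / j^2) / Nr,
    LRE = sum(R * j^2) / Nr,
    GLN = sum(rowSums(R)^2) / Nr,
    RLN = sum(colSums(R)^2) / Nr,
    RP = Nr / (RL$nDirections * RL$nVoxels),
    LGLRE = sum(R / i^2) / Nr,
    HGLRE = sum(R * i^2) / Nr,
    SRLGLE = sum(R / (i^2 * j^2)) / Nr,
    SRHGLE = sum(R * i^2 / j^2) / Nr,
    LRLGLE = sum(R * j^2 / i^2) / Nr,
    LRHGLE = sum(R * i^2 * j^2) / Nr)
}

#' Extract the full feature vector for one harmonized subject
#'
#' 49 features (16 first-order + 22 GLCM + 11 GLRLM) per present modality
#' plus the 8 shape features from the mask; features of absent modalities are
#' `NA`. The result always has length 253, ordered as [featureCatalog()].
#'
#' @param study a harmonized [SubjectStudy-class] (see [prepareSubject()]).
#' @param ng gray levels for discretization.
#' @return Named numeric(253) with `NA` for missing-modality features.
#' @export
extractSubject <- function(study, ng = 32L) {
  cat0 <- featureCatalog()
  out <- setNames(rep(NA_real_, nrow(cat0)), cat0$qualified)
  mask <- study@mask
  for (mod in MODALITIES) {
    if (!mod %in% names(study@volumes)) next
    vol <- study@volumes[[mod]]
    fo <- firstOrderFeatures(vol, mask, ng)
    dv <- discretizeVolume(vol, mask, ng)
    gc <- glcmFeatures(glcmBuild(dv))
    gr <- glrlmFeatures(glrlmBuild(dv))
    out[paste(mod, "fo", names(fo), sep = ".")] <- fo
    out[paste(mod, "glcm", names(gc), sep = ".")] <- gc
    out[paste(mod, "glrlm", names(gr), sep = ".")] <- gr
  }
  sf <- shapeFeatures(mask)
  out[paste("shape", names(sf), sep = ".")] <- sf
  out
}

#' Extract features for a harmonized cohort
#'
#' @param cohort an [MBCohort-class] of harmonized studies.
#' @param ng gray levels.
#' @return A [RadiomicsFeatureTable-class].
#' @export
extractCohortFeatures <- function(cohort, ng = 32L) {
  rows <- t(vapply(cohort@subjects, extractSubject,
                   numeric(nrow(featureCatalog())), ng = ng))
  rownames(rows) <- cohort@clinical$subject_id
  RadiomicsFeatureTable(rows, cohort@clinical)
}
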