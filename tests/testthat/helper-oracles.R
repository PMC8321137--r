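# Independent naive-loop oracles for the texture engine, plus small fixture
# builders. These deliberately use plain element-wise loops and their own
# conventions so they share no code with the implementation.

log2z <- function(x) ifelse(x > 0, log2(x), 0)

# naive GLCM build: visit every voxel, every offset, count ordered pairs
naiveGlcmBuild <- function(lev, ng, offsets) {
  dm <- dim(lev)
  P <- matrix(0, ng, ng)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    a <- lev[x, y, z]
    if (a == 0) next
    for (o in seq_len(nrow(offsets))) {
      for (sgn in c(1, -1)) {
        xx <- x + sgn * offsets[o, 1]; yy <- y + sgn * offsets[o, 2]
        zz <- z + sgn * offsets[o, 3]
        if (xx < 1 || xx > dm[1] || yy < 1 || yy > dm[2] ||
            zz < 1 || zz > dm[3]) next
        b <- lev[xx, yy, zz]
        if (b == 0) next
        P[a, b] <- P[a, b] + 1
      }
    }
  }
  P / sum(P)
}

# naive GLCM feature formulas, direct double sums
naiveGlcmFeatures <- function(P) {
  ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- sqrt(sum((1:ng - mux)^2 * px)); sy <- sqrt(sum((1:ng - muy)^2 * py))
  pxy <- rep(0, 2 * ng); pd <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    pxy[i + j] <- pxy[i + j] + P[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
  }
  out <- c(autocorrelation = 0, cluster.prominence = 0, cluster.shade = 0,
           cluster.tendency = 0, contrast = 0, correlation = 0,
           difference.entropy = 0, dissimilarity = 0, energy = 0,
           entropy = 0, homogeneity1 = 0, homogeneity2 = 0, imc1 = 0,
           imc2 = 0, idmn = 0, idn = 0, inverse.variance = 0,
           max.probability = 0, sum.average = 0, sum.entropy = 0,
           sum.variance = 0, variance = 0)
  HXY <- 0; HXY1 <- 0; HXY2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    out["autocorrelation"] <- out["autocorrelation"] + i * j * p
    out["cluster.prominence"] <- out["cluster.prominence"] +
      (i + j - mux - muy)^4 * p
    out["cluster.shade"] <- out["cluster.shade"] + (i + j - mux - muy)^3 * p
    out["cluster.tendency"] <- out["cluster.tendency"] +
      (i + j - mux - muy)^2 * p
    out["contrast"] <- out["contrast"] + (i - j)^2 * p
    out["dissimilarity"] <- out["dissimilarity"] + abs(i - j) * p
    out["energy"] <- out["energy"] + p^2
    out["homogeneity1"] <- out["homogeneity1"] + p / (1 + abs(i - j))
    out["homogeneity2"] <- out["homogeneity2"] + p / (1 + (i - j)^2)
    out["idmn"] <- out["idmn"] + p / (1 + (i - j)^2 / ng^2)
    out["idn"] <- out["idn"] + p / (1 + abs(i - j) / ng)
    if (i != j) out["inverse.variance"] <- out["inverse.variance"] +
        p / (i - j)^2
    out["variance"] <- out["variance"] + (i - mux)^2 * p
    HXY <- HXY - p * log2z(p)
    if (p > 0 && px[i] * py[j] > 0) HXY1 <- HXY1 - p * log2(px[i] * py[j])
    HXY2 <- HXY2 - px[i] * py[j] * log2z(px[i] * py[j])
  }
  out["entropy"] <- HXY
  out["max.probability"] <- max(P)
  out["correlation"] <- if (sx < 1e-12 || sy < 1e-12) 1 else
    (out[["autocorrelation"]] - mux * muy) / (sx * sy)
  HX <- -sum(px * log2z(px))
  out["imc1"] <- if (HX < 1e-12) 0 else (HXY - HXY1) / HX
  out["imc2"] <- sqrt(max(1 - exp(-2 * (HXY2 - HXY)), 0))
  sa <- 0
  for (k in 2:(2 * ng)) sa <- sa + k * pxy[k]
  out["sum.average"] <- sa
  for (k in 2:(2 * ng)) {
    out["sum.entropy"] <- out["sum.entropy"] - pxy[k] * log2z(pxy[k])
    out["sum.variance"] <- out["sum.variance"] + (k - sa)^2 * pxy[k]
  }
  for (k in 1:ng) out["difference.entropy"] <- out["difference.entropy"] -
      pd[k] * log2z(pd[k])
  out
}

# naive GLRLM build: walk every line voxel by voxel in each direction
naiveGlrlmBuild <- function(lev, ng, offsets) {
  dm <- dim(lev)
  maxlen <- max(dm)
  R <- matrix(0, ng, maxlen)
  inb <- function(p) all(p >= 1) && all(p <= dm)
  for (o in seq_len(nrow(offsets))) {
    d <- offsets[o, ]
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
      p <- c(x, y, z)
      g <- lev[x, y, z]
      if (g == 0) next
      prev <- p - d
      # run starts here iff the previous voxel is out of grid, out of mask,
      # or a different level
      if (inb(prev) && lev[prev[1], prev[2], prev[3]] == g) next
      len <- 1
      nxt <- p + d
      while (inb(nxt) && lev[nxt[1], nxt[2], nxt[3]] == g) {
        len <- len + 1
        nxt <- nxt + d
      }
      R[g, len] <- R[g, len] + 1
    }
  }
  R
}

naiveGlrlmFeatures <- function(R, nDirections, nVoxels) {
  ng <- nrow(R); ml <- ncol(R)
  Nr <- sum(R)
  out <- c(SRE = 0, LRE = 0, GLN = 0, RLN = 0, RP = 0, LGLRE = 0,
           HGLRE = 0, SRLGLE = 0, SRHGLE = 0, LRLGLE = 0, LRHGLE = 0)
  for (i in 1:ng) for (j in 1:ml) {
    r <- R[i, j]
    out["SRE"] <- out["SRE"] + r / j^2
    out["LRE"] <- out["LRE"] + r * j^2
    out["LGLRE"] <- out["LGLRE"] + r / i^2
    out["HGLRE"] <- out["HGLRE"] + r * i^2
    out["SRLGLE"] <- out["SRLGLE"] + r / (i^2 * j^2)
    out["SRHGLE"] <- out["SRHGLE"] + r * i^2 / j^2
    out["LRLGLE"] <- out["LRLGLE"] + r * j^2 / i^2
    out["LRHGLE"] <- out["LRHGLE"] + r * i^2 * j^2
  }
  for (i in 1:ng) out["GLN"] <- out["GLN"] + sum(R[i, ])^2
  for (j in 1:ml) out["RLN"] <- out["RLN"] + sum(R[, j])^2
  out <- out / Nr
  out["RP"] <- Nr / (nDirections * nVoxels)
  out
}

# random discretized test volume: dims, ng levels, with a random mask
randomDiscretizedVolume <- function(dm = c(6, 6, 3), ng = 4,
                                    maskFrac = 0.85) {
  vol <- MRVolume(array(runif(prod(dm)), dm))
  mask <- MRVolume(array(as.numeric(runif(prod(dm)) < maskFrac), dm))
  if (sum(voxels(mask)) < 2) mask <- MRVolume(array(1, dm))
  discretizeVolume(vol, mask, ng)
}

# small harmonized study built directly on one grid (no registration needed)
makeHarmonizedStudy <- function(mods = c("CET1", "T1WI", "T2WI", "FLAIR",
                                         "ADC"),
                                dm = c(12, 12, 6), seed = 1,
                                subgroup = "WNT", id = "T01") {
  set.seed(seed)
  mask <- array(0, dm)
  mask[4:9, 4:9, 2:5] <- 1
  vols <- lapply(setNames(mods, mods), function(m)
    MRVolume(array(runif(prod(dm)), dm), c(0.75, 0.75, 3)))
  SubjectStudy(id, vols, MRVolume(mask, c(0.75, 0.75, 3)), subgroup,
               survivalDays = 100, event = 1L)
}
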