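# Low-level array geometry helpers shared by the generator, resampling and
# registration code. All coordinates are world mm under the cell-centred
# convention: voxel (i,j,k) sits at origin + (c(i,j,k) - 0.5) * spacing.

# World coordinates (n x 3) of every voxel centre of a volume grid.
voxelCenters <- function(dm, spacing, origin) {
  g <- expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]), k = seq_len(dm[3]))
  cbind(origin[1] + (g$i - 0.5) * spacing[1],
        origin[2] + (g$j - 0.5) * spacing[2],
        origin[3] + (g$k - 0.5) * spacing[3])
}

# Sample a 3D array at continuous voxel coordinates (matrix n x 3, 1-based,
# cell-centred so the value of voxel i lives at coordinate i).
# interpolation: "trilinear" or "nearest". Points outside the grid get
# `fill`; fill = NULL clamps to the nearest edge value instead (used when
# resampling, so e.g. a constant volume stays exactly constant).
sampleArray <- function(arr, pts, interpolation = c("trilinear", "nearest"),
                        fill = 0) {
  interpolation <- match.arg(interpolation)
  dm <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  if (interpolation == "nearest") {
    i <- pmin(pmax(round(x), 1), dm[1])
    j <- pmin(pmax(round(y), 1), dm[2])
    k <- pmin(pmax(round(z), 1), dm[3])
    out <- arr[cbind(i, j, k)]
    if (!is.null(fill)) {
      ok <- x >= 0.5 & x <= dm[1] + 0.5 & y >= 0.5 & y <= dm[2] + 0.5 &
            z >= 0.5 & z <= dm[3] + 0.5
      out[!ok] <- fill
    }
    return(out)
  }
  ok <- x >= 0.5 & x <= dm[1] + 0.5 & y >= 0.5 & y <= dm[2] + 0.5 &
        z >= 0.5 & z <= dm[3] + 0.5
  xc <- pmin(pmax(x, 1), dm[1]); yc <- pmin(pmax(y, 1), dm[2])
  zc <- pmin(pmax(z, 1), dm[3])
  i0 <- pmin(floor(xc), dm[1] - 1L); i0 <- pmax(i0, 1L)
  j0 <- pmin(floor(yc), dm[2] - 1L); j0 <- pmax(j0, 1L)
  k0 <- pmin(floor(zc), dm[3] - 1L); k0 <- pmax(k0, 1L)
  if (dm[1] == 1L) i0 <- rep(1L, length(xc))
  if (dm[2] == 1L) j0 <- rep(1L, length(yc))
  if (dm[3] == 1L) k0 <- rep(1L, length(zc))
  fx <- xc - i0; fy <- yc - j0; fz <- zc - k0
  i1 <- pmin(i0 + 1L, dm[1]); j1 <- pmin(j0 + 1L, dm[2]); k1 <- pmin(k0 + 1L, dm[3])
  v <- arr[cbind(i0, j0, k0)] * (1 - fx) * (1 - fy) * (1 - fz) +
       arr[cbind(i1, j0, k0)] * fx       * (1 - fy) * (1 - fz) +
       arr[cbind(i0, j1, k0)] * (1 - fx) * fy       * (1 - fz) +
       arr[cbind(i1, j1, k0)] * fx       * fy       * (1 - fz) +
       arr[cbind(i0, j0, k1)] * (1 - fx) * (1 - fy) * fz +
       arr[cbind(i1, j0, k1)] * fx       * (1 - fy) * fz +
       arr[cbind(i0, j1, k1)] * (1 - fx) * fy       * fz +
       arr[cbind(i1, j1, k1)] * fx       * fy       * fz
  if (!is.null(fill)) v[!ok] <- fill
  v
}

# Sample a volume at world coordinates (n x 3, mm).
sampleVolumeWorld <- function(vol, world, interpolation = "trilinear",
                              fill = 0) {
  vc <- sweep(sweep(world, 2, vol@origin, "-"), 2, vol@spacing, "/") + 0.5
  sampleArray(vol@voxels, vc, interpolation, fill)
}

# Separable Gaussian smoothing with sigma given per axis in voxels.
# Truncated at 3 sigma; kernel rows renormalised at the edges (replicate-free
# boundary handling that preserves the local mean).
gaussianSmooth3D <- function(arr, sigmaVox) {
  dm <- dim(arr)
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s < 1e-8) next
    r <- max(1L, ceiling(3 * s))
    kern <- exp(-0.5 * ((-r:r) / s)^2)
    n <- dm[ax]
    # banded n x n convolution matrix with edge renormalisation
    K <- matrix(0, n, n)
    for (d in -r:r) {
      idx <- seq_len(n)
      src <- idx + d
      okr <- src >= 1 & src <= n
      K[cbind(idx[okr], src[okr])] <- K[cbind(idx[okr], src[okr])] + kern[d + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = dm[ax])
    m <- K %*% m
    a <- array(m, dim = dm[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

# 26-connected component containing seed voxels, by iterated dilation within
# the mask (logical 3D array). Returns a logical array.
connectedComponent <- function(mask, seed) {
  comp <- seed & mask
  repeat {
    grown <- dilate26(comp) & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# One-step 26-neighbourhood dilation of a logical 3D array.
dilate26 <- function(m) {
  dm <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- seq_len(dm[1]); sy <- seq_len(dm[2]); sz <- seq_len(dm[3])
    tx <- sx + dx; ty <- sy + dy; tz <- sz + dz
    okx <- tx >= 1 & tx <= dm[1]; oky <- ty >= 1 & ty <= dm[2]
    okz <- tz >= 1 & tz <= dm[3]
    out[sx[okx], sy[oky], sz[okz]] <-
      out[sx[okx], sy[oky], sz[okz]] | m[tx[okx], ty[oky], tz[okz]]
  }
  out
}

# Number of 26-connected components of a logical 3D array.
countComponents26 <- function(mask) {
  n <- 0L
  left <- mask
  while (any(left)) {
    idx <- which(left)[1]
    seed <- array(FALSE, dim(mask)); seed[idx] <- TRUE
    comp <- connectedComponent(left, seed)
    left <- left & !comp
    n <- n + 1L
  }
  n
}
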