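# 3D shape features from the binary tumour mask. The surface is meshed by
# marching tetrahedra on the binary field at iso-level 0.5 (each lattice cube
# split into 6 tetrahedra; surface vertices at edge midpoints), which tracks
# the iso-surface far more faithfully than counting exposed voxel faces.

# cube vertex offsets and the 6-tetrahedra decomposition (indices into 1..8)
.cubeOff <- matrix(c(0,0,0, 1,0,0, 1,1,0, 0,1,0, 0,0,1, 1,0,1, 1,1,1, 0,1,1),
                   ncol = 3, byrow = TRUE)
.tets <- matrix(c(1,6,2,7, 1,2,3,7, 1,3,4,7, 1,4,8,7, 1,8,5,7, 1,5,6,7),
                ncol = 4, byrow = TRUE)

triArea <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  0.5 * sqrt(sum(cr^2))
}

# surface area (mm^2) of the 0.5 iso-surface of a scalar array with given
# spacing, via marching tetrahedra with linear interpolation of the surface
# vertices along tetrahedron edges; the array is zero-padded so the surface
# is closed. For a binary array the field is first mildly smoothed
# (sigma = 0.5 voxel) by the caller to suppress staircase metrication bias.
meshSurfaceArea <- function(maskArr, spacing) {
  dm <- dim(maskArr)
  pad <- array(0, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- maskArr
  pdm <- dim(pad)
  # cubes with corners on both sides of the iso-level only
  above <- pad > 0.5
  sub <- above[-pdm[1], -pdm[2], -pdm[3]]
  cs <- sub * 1L
  for (d in 1:7)
    cs <- cs + above[(1:(pdm[1]-1)) + .cubeOff[d+1,1],
                     (1:(pdm[2]-1)) + .cubeOff[d+1,2],
                     (1:(pdm[3]-1)) + .cubeOff[d+1,3]]
  mixed <- which(cs > 0 & cs < 8, arr.ind = TRUE)
  if (nrow(mixed) == 0) return(0)
  area <- 0
  for (r in seq_len(nrow(mixed))) {
    base <- mixed[r, ]
    corners <- sweep(.cubeOff, 2, base, "+")           # voxel indices in pad
    vals <- pad[corners]
    pts <- sweep(corners, 2, spacing[1:3], "*")        # mm (centre offsets cancel)
    for (t in 1:6) {
      vi <- .tets[t, ]
      f <- vals[vi]
      inside <- which(f > 0.5)
      ni <- length(inside)
      if (ni == 0 || ni == 4) next
      P <- pts[vi, , drop = FALSE]
      mid <- function(a, b) {
        t <- (0.5 - f[a]) / (f[b] - f[a])
        P[a, ] + t * (P[b, ] - P[a, ])
      }
      if (ni == 1 || ni == 3) {
        a <- if (ni == 1) inside else setdiff(1:4, inside)
        others <- setdiff(1:4, a)
        area <- area + triArea(mid(a, others[1]), mid(a, others[2]),
                               mid(a, others[3]))
      } else {
        a <- inside[1]; b <- inside[2]
        cd <- setdiff(1:4, inside)
        p1 <- mid(a, cd[1]); p2 <- mid(a, cd[2])
        p3 <- mid(b, cd[2]); p4 <- mid(b, cd[1])
        area <- area + triArea(p1, p2, p3) + triArea(p1, p3, p4)
      }
    }
  }
  area
}

#' 3D shape and size features
#'
#' The 8 morphology features from the binary tumour mask: volume (voxel
#' count x voxel volume, mm^3), surface area (marching-tetrahedra iso-surface
#' at level 0.5, mm^2), surface-to-volume ratio, sphericity
#' \eqn{\pi^{1/3}(6V)^{2/3}/A}, compactness1 \eqn{V/(\sqrt{\pi}A^{3/2})},
#' compactness2 \eqn{36\pi V^2/A^3}, spherical disproportion
#' \eqn{A/(4\pi R^2)} with \eqn{R=(3V/4\pi)^{1/3}}, and maximum 3D diameter
#' (largest pairwise world distance between surface voxel centres, mm).
#' All are invariant to translation of the mask.
#'
#' @param mask binary [MRVolume-class].
#' @return Named numeric(8).
#' @export
shapeFeatures <- function(mask) {
  m <- mask@voxels > 0
  if (!any(m)) stop("mask is empty")
  sp <- mask@spacing
  V <- sum(m) * prod(sp)
  # mild smoothing (0.7 voxel sigma) before meshing: the interpolated
  # iso-surface then tracks the true boundary instead of the voxel staircase.
  # Along axes where the mask is only a few voxels thick the sigma is capped
  # so thin lesions are not eroded below the iso-level.
  bb <- apply(which(m, arr.ind = TRUE), 2, range)
  sigma <- pmin(0.7, (bb[2, ] - bb[1, ] + 1) / 6)
  # crop to the bounding box plus a fixed zero margin (>= kernel radius) so
  # the result is exactly invariant to translation within the grid
  mar <- 4L
  ext <- bb[2, ] - bb[1, ] + 1L
  crop <- array(0, ext + 2L * mar)
  crop[mar + seq_len(ext[1]), mar + seq_len(ext[2]), mar + seq_len(ext[3])] <-
    m[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3]]
  A <- meshSurfaceArea(gaussianSmooth3D(crop, sigma), sp)
  # surface voxels: any 6-neighbour outside (or on the array border)
  dm <- dim(m)
  interior <- array(TRUE, dm)
  shiftIn <- function(arr, ax, d) {
    out <- array(FALSE, dm)
    idx <- lapply(dm, seq_len)
    src <- idx; src[[ax]] <- idx[[ax]] + d
    keep <- src[[ax]] >= 1 & src[[ax]] <= dm[ax]
    dst <- idx; dst[[ax]] <- idx[[ax]][keep]; src[[ax]] <- src[[ax]][keep]
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (d in c(-1L, 1L))
    interior <- interior & shiftIn(m, ax, d)
  surf <- which(m & !interior, arr.ind = TRUE)
  if (nrow(surf) == 0) surf <- which(m, arr.ind = TRUE)
  pw <- sweep(surf, 2, sp, "*")
  maxd <- if (nrow(pw) == 1) 0 else max(stats::dist(pw))
  R <- (3 * V / (4 * pi))^(1 / 3)
  c(volume = V,
    surface.area = A,
    surface.to.volume = A / V,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    compactness1 = V / (sqrt(pi) * A^1.5),
    compactness2 = 36 * pi * V^2 / A^3,
    spherical.disproportion = A / (4 * pi * R^2),
    max.diameter3D = maxd)
}
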