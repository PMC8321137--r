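# Harmonization: common voxel grid, rigid mutual-information registration to
# the CET1 reference, bounded intensity normalization.

#' Resample a volume to a target spacing
#'
#' The output grid keeps the input origin; its dimension along each axis is
#' `ceiling(extent / target)` where extent = input dim x input spacing, so the
#' physical extent is preserved to within one output voxel. Images use
#' trilinear interpolation, masks nearest-neighbour.
#'
#' @param vol an [MRVolume-class].
#' @param targetSpacing numeric(3), mm.
#' @param interpolation `"trilinear"` (images) or `"nearest"` (masks).
#' @return A resampled [MRVolume-class].
#' @export
resampleToSpacing <- function(vol, targetSpacing = c(0.75, 0.75, 3.0),
                              interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (any(targetSpacing <= 0)) stop("target spacing must be positive")
  ext <- gridDim(vol) * vol@spacing
  odm <- pmax(as.integer(ceiling(ext / targetSpacing - 1e-9)), 1L)
  w <- voxelCenters(odm, targetSpacing, vol@origin)
  vals <- sampleVolumeWorld(vol, w, interpolation, fill = NULL)
  MRVolume(array(vals, odm), spacing = targetSpacing, origin = vol@origin)
}

#' Rigid transforms
#'
#' A six-parameter rigid-body transform: rotation angles (radians, applied as
#' Rz Ry Rx about a centre point) plus a translation in mm. `rigidTransform()`
#' constructs one; `applyTransformPoints()` maps world points;
#' `resampleThroughTransform()` pulls a moving volume onto a fixed grid, i.e.
#' output voxel at world `x` takes the moving image's value at `T(x)`.
#'
#' @param angles numeric(3) rotations (rad) about x, y, z.
#' @param translation numeric(3) mm.
#' @param center numeric(3) rotation centre (world mm).
#' @return `rigidTransform()`: a `rigid_transform` list.
#' @export
rigidTransform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  structure(list(R = Rz %*% Ry %*% Rx, angles = angles,
                 translation = translation, center = center),
            class = "rigid_transform")
}

#' @rdname rigidTransform
#' @param transform a `rigid_transform`.
#' @param pts n x 3 matrix of world points (mm).
#' @export
applyTransformPoints <- function(transform, pts) {
  ctr <- matrix(transform$center, nrow(pts), 3, byrow = TRUE)
  out <- (pts - ctr) %*% t(transform$R) + ctr
  sweep(out, 2, transform$translation, "+")
}

#' @rdname rigidTransform
#' @param moving moving [MRVolume-class].
#' @param fixed fixed-grid [MRVolume-class] defining the output grid.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill value for points outside the moving field of view.
#' @export
resampleThroughTransform <- function(moving, fixed, transform,
                                     interpolation = "trilinear",
                                     fill = 0) {
  w <- voxelCenters(gridDim(fixed), fixed@spacing, fixed@origin)
  wm <- applyTransformPoints(transform, w)
  vals <- sampleVolumeWorld(moving, wm, interpolation, fill)
  MRVolume(array(vals, gridDim(fixed)), spacing = fixed@spacing,
           origin = fixed@origin)
}

# Histogram-based mutual information between fixed voxel values and the
# moving image sampled through a candidate transform. NA (out-of-field)
# samples are excluded; returns -Inf if the overlap is tiny.
miScore <- function(fixedVals, moving, worldPts, transform, bins,
                    fixedBreaks, movRange) {
  wm <- applyTransformPoints(transform, worldPts)
  mv <- sampleVolumeWorld(moving, wm, "trilinear", fill = NA_real_)
  ok <- !is.na(mv)
  if (sum(ok) < 50) return(-Inf)
  fb <- fixedVals[ok]; mb <- mv[ok]
  fi <- pmin(pmax(findInterval(fb, fixedBreaks, all.inside = TRUE), 1L), bins)
  mbr <- seq(movRange[1], movRange[2], length.out = bins + 1L)
  mi2 <- pmin(pmax(findInterval(mb, mbr, all.inside = TRUE), 1L), bins)
  jt <- tabulate(fi + bins * (mi2 - 1L), nbins = bins * bins)
  p <- jt / sum(jt)
  pm <- matrix(p, bins, bins)
  px <- rowSums(pm); py <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / (px[row(pm)[nz]] * py[col(pm)[nz]])))
}

#' Rigid mutual-information registration
#'
#' Registers `moving` to `fixed` with a six-parameter rigid-body transform
#' maximizing histogram-based mutual information (32 x 32 joint histogram):
#' a multi-start grid over coarse translations followed by Nelder-Mead
#' refinement of all six parameters. The identity transform is always a
#' candidate, so the returned MI is never below the identity's.
#'
#' @param moving,fixed [MRVolume-class] volumes overlapping in world space.
#' @param translationRange half-width (mm) of the translation multi-start
#'   grid.
#' @param translationStep multi-start grid step, mm.
#' @param bins joint-histogram bins per axis.
#' @param maxit Nelder-Mead iteration cap.
#' @return A `rigid_transform` mapping fixed-grid world coordinates into the
#'   moving volume, with fields `mi` (its score) and `miIdentity`.
#' @export
registerRigidMI <- function(moving, fixed, translationRange = 8,
                            translationStep = 4, bins = 32L, maxit = 150) {
  fv <- fixed@voxels
  if (sd(fv) < 1e-12 || sd(moving@voxels) < 1e-12)
    stop("degenerate (constant) image: registration is undefined")
  w <- voxelCenters(gridDim(fixed), fixed@spacing, fixed@origin)
  # MI is estimated on a regular subsample of the fixed grid; 8k voxels give
  # a stable 32 x 32 joint histogram at a fraction of the cost
  if (nrow(w) > 8000L) {
    keep <- round(seq(1L, nrow(w), length.out = 8000L))
    w <- w[keep, , drop = FALSE]
    fvals <- as.numeric(fv)[keep]
  } else fvals <- as.numeric(fv)
  ctr <- fixed@origin + gridDim(fixed) * fixed@spacing / 2
  fbr <- seq(min(fvals), max(fvals), length.out = bins + 1L)
  mrg <- range(moving@voxels)
  score <- function(par) {
    tr <- rigidTransform(par[1:3], par[4:6], ctr)
    miScore(fvals, moving, w, tr, bins, fbr, mrg)
  }
  steps <- seq(-translationRange, translationRange, by = translationStep)
  best <- c(0, 0, 0, 0, 0, 0); bestMI <- score(best)
  miIdentity <- bestMI
  for (tx in steps) for (ty in steps) for (tz in steps) {
    if (tx == 0 && ty == 0 && tz == 0) next
    s <- score(c(0, 0, 0, tx, ty, tz))
    if (s > bestMI) { bestMI <- s; best <- c(0, 0, 0, tx, ty, tz) }
  }
  opt <- stats::optim(best, function(p) -score(p), method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     parscale = c(rep(0.05, 3), rep(1, 3))))
  if (-opt$value > bestMI) { best <- opt$par; bestMI <- -opt$value }
  tr <- rigidTransform(best[1:3], best[4:6], ctr)
  tr$mi <- bestMI
  tr$miIdentity <- miIdentity
  tr
}

#' Bounded intensity normalization
#'
#' Within the region: z-score by the region mean and SD, clip to +/- 3, then
#' map affinely from [-3, 3] to [0, 1]. Outside the region voxels are set
#' to 0. This fixes the standardized, bounded range that equal-width
#' discretization downstream relies on.
#'
#' @param vol an [MRVolume-class].
#' @param regionMask binary [MRVolume-class] on the same grid.
#' @return A normalized [MRVolume-class].
#' @export
normalizeIntensity <- function(vol, regionMask) {
  m <- regionMask@voxels > 0
  if (!any(m)) stop("region mask is empty")
  v <- vol@voxels[m]
  s <- sd(v)
  if (s < 1e-12) stop("zero variance in normalization region")
  z <- pmin(pmax((v - mean(v)) / s, -3), 3)
  out <- array(0, gridDim(vol))
  out[m] <- (z + 3) / 6
  MRVolume(out, spacing = vol@spacing, origin = vol@origin)
}

#' Harmonize one subject
#'
#' Implements the postprocessing protocol: every present modality is
#' resampled to the target spacing (default 0.75 x 0.75 x 3.0 mm), non-CET1
#' modalities are rigidly registered to the resampled CET1 by mutual
#' information and pulled onto its grid, all modalities are normalized to
#' [0, 1] within the tumour mask, and the mask itself is resampled with
#' nearest-neighbour. Missing modalities stay absent.
#'
#' @param study a [SubjectStudy-class] with CET1 and mask.
#' @param targetSpacing numeric(3), mm.
#' @param register logical; rigid MI registration of non-CET1 modalities
#'   (disable only for volumes already on the reference grid).
#' @return A harmonized [SubjectStudy-class]; attribute `absent` lists the
#'   missing modalities and `transforms` the recovered rigid transforms.
#' @export
prepareSubject <- function(study, targetSpacing = c(0.75, 0.75, 3.0),
                           register = TRUE) {
  if (!"CET1" %in% names(study@volumes))
    stop("CET1 reference modality is absent; cannot harmonize")
  fixed <- resampleToSpacing(study@volumes[["CET1"]], targetSpacing,
                             "trilinear")
  mask <- resampleToSpacing(study@mask, targetSpacing, "nearest")
  if (sum(mask@voxels) < 1)
    stop("mask lost all voxels during resampling")
  vols <- list(CET1 = normalizeIntensity(fixed, mask))
  transforms <- list()
  for (mod in setdiff(names(study@volumes), "CET1")) {
    mv <- resampleToSpacing(study@volumes[[mod]], targetSpacing, "trilinear")
    if (register) {
      tr <- registerRigidMI(mv, fixed)
      transforms[[mod]] <- tr
      aligned <- resampleThroughTransform(mv, fixed, tr, "trilinear",
                                          fill = min(mv@voxels))
    } else {
      aligned <- resampleThroughTransform(
        mv, fixed, rigidTransform(), "trilinear", fill = min(mv@voxels))
    }
    vols[[mod]] <- normalizeIntensity(aligned, mask)
  }
  out <- SubjectStudy(study@subjectId, vols, mask, study@subgroup,
                      study@survivalDays, study@event)
  attr(out, "absent") <- setdiff(MODALITIES, names(study@volumes))
  attr(out, "transforms") <- transforms
  out
}

#' Harmonize a whole cohort
#'
#' @param cohort an [MBCohort-class].
#' @param ... passed to [prepareSubject()].
#' @return An [MBCohort-class] of harmonized studies.
#' @export
prepareCohort <- function(cohort, ...) {
  subs <- lapply(cohort@subjects, prepareSubject, ...)
  out <- new("MBCohort", subjects = subs, clinical = cohort@clinical)
  attr(out, "planted") <- attr(cohort, "planted")
  out
}
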