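#' Read and write volumes as NIfTI
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()]. The
#' package stores a volume as an (x, y, z) array with voxel spacing and a
#' world origin such that voxel `(i,j,k)` is centred at
#' `origin + (c(i,j,k) - 0.5) * spacing`; on disk this maps to an axis-aligned
#' qform whose translation is the centre of the first voxel. Non-finite
#' voxels are rejected on load.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readVolume()` returns an [MRVolume-class]; `writeVolume()` returns
#'   `path` invisibly.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume: ", path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (any(!is.finite(arr)))
    stop("non-finite voxel values in ", path)
  sp <- as.numeric(RNifti::pixdim(img))[1:3]
  xf <- RNifti::xform(img)
  MRVolume(arr, spacing = sp, origin = as.numeric(xf[1:3, 4]) - 0.5 * sp)
}

#' @rdname readVolume
#' @param vol an [MRVolume-class].
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacing
  m <- diag(c(vol@spacing, 1))
  m[1:3, 4] <- vol@origin + 0.5 * vol@spacing
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
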