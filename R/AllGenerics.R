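#' Accessors for MRVolume and cohort objects
#'
#' `voxels()` returns the raw 3D array, `spacing()` and `origin()` the grid
#' geometry in mm, `gridDim()` the voxel dimensions, `subjects()` the list of
#' studies, `clinicalData()` the clinical table, and `featureMatrix()` the
#' subjects x features matrix (with `NA` for missing entries).
#'
#' @param x the object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))
#' @rdname accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("modalities", function(x) standardGeneric("modalities"))
#' @rdname accessors
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))

#' @rdname accessors
#' @export
setMethod("voxels", "MRVolume", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("spacing", "MRVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("origin", "MRVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("gridDim", "MRVolume", function(x) dim(x@voxels))
#' @rdname accessors
#' @export
setMethod("subjects", "MBCohort", function(x) x@subjects)
#' @rdname accessors
#' @export
setMethod("clinicalData", "MBCohort", function(x) x@clinical)
#' @rdname accessors
#' @export
setMethod("clinicalData", "RadiomicsFeatureTable",
          function(x) as.data.frame(SummarizedExperiment::colData(x)))
#' @rdname accessors
#' @export
setMethod("featureMatrix", "RadiomicsFeatureTable",
          function(x) t(SummarizedExperiment::assay(x, "features")))
#' @rdname accessors
#' @export
setMethod("modalities", "SubjectStudy", function(x) names(x@volumes))
#' @rdname accessors
#' @export
setMethod("tumorMask", "SubjectStudy", function(x) x@mask)

#' @describeIn accessors modality volumes of a study (named list).
#' @export
setGeneric("studyVolumes", function(x) standardGeneric("studyVolumes"))
#' @rdname accessors
#' @export
setMethod("studyVolumes", "SubjectStudy", function(x) x@volumes)

setMethod("show", "MRVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("MRVolume %dx%dx%d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  v <- object@voxels
  cat(sprintf("  range [%.4g, %.4g], origin (%.3g, %.3g, %.3g) mm\n",
              min(v), max(v), object@origin[1], object@origin[2],
              object@origin[3]))
})

setMethod("show", "SubjectStudy", function(object) {
  cat(sprintf("SubjectStudy %s [%s]: %s; mask %d voxels; %g days (event=%d)\n",
              object@subjectId, object@subgroup,
              paste(names(object@volumes), collapse = ", "),
              sum(object@mask@voxels), object@survivalDays, object@event))
})

setMethod("show", "MBCohort", function(object) {
  tab <- table(factor(object@clinical$subgroup, levels = SUBGROUPS))
  cat(sprintf("MBCohort: %d subjects (%s)\n", length(object@subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})
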