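#' @import methods
#' @importFrom stats rnorm rexp runif quantile sd median pnorm pchisq
#'   kruskal.test setNames rbinom complete.cases
#' @importFrom utils combn head read.csv write.csv
NULL

MODALITIES <- c("CET1", "T1WI", "T2WI", "FLAIR", "ADC")
SUBGROUPS  <- c("WNT", "SHH", "Group3", "Group4")

#' 3D scalar image volume
#'
#' A minimal world-aligned 3D image: a numeric array plus voxel spacing and
#' origin in millimetres. Axes are stored in (x, y, z) order and the world
#' coordinate of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 0.5) * spacing` (cell-centred convention).
#'
#' @slot voxels numeric 3D array of intensities.
#' @slot spacing numeric(3), voxel size in mm per axis, all positive.
#' @slot origin numeric(3), world position (mm) of the corner of voxel
#'   (1,1,1).
#' @export
setClass("MRVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(voxels = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("MRVolume", function(object) {
  if (length(dim(object@voxels)) != 3L)
    return("voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite reals")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite reals")
  TRUE
})

#' One subject's imaging study
#'
#' Holds a subject's modality volumes (a subset of CET1, T1WI, T2WI, FLAIR,
#' ADC; CET1 always present — it is the reference for delineation and
#' registration), the binary tumour mask on the CET1 grid, the molecular
#' subgroup label and the survival record.
#'
#' @slot subjectId character scalar.
#' @slot volumes named list of [MRVolume-class], names from
#'   `c("CET1","T1WI","T2WI","FLAIR","ADC")`.
#' @slot mask binary [MRVolume-class] on the CET1 grid (>= 1 foreground voxel).
#' @slot subgroup one of `"WNT"`, `"SHH"`, `"Group3"`, `"Group4"`.
#' @slot survivalDays non-negative numeric scalar.
#' @slot event integer 0 (censored) or 1 (event).
#' @export
setClass("SubjectStudy",
  representation(subjectId = "character", volumes = "list",
                 mask = "MRVolume", subgroup = "character",
                 survivalDays = "numeric", event = "integer"))

setValidity("SubjectStudy", function(object) {
  if (length(object@subjectId) != 1L) return("subjectId must be scalar")
  nm <- names(object@volumes)
  if (is.null(nm) || !all(nm %in% MODALITIES))
    return("volume names must be among CET1/T1WI/T2WI/FLAIR/ADC")
  if (!"CET1" %in% nm) return("CET1 (reference modality) must be present")
  if (!all(vapply(object@volumes, is, logical(1), class2 = "MRVolume")))
    return("all volumes must be MRVolume")
  if (!all(object@mask@voxels %in% c(0, 1)))
    return("mask must be binary")
  if (sum(object@mask@voxels) < 1) return("mask must have >= 1 foreground voxel")
  if (!object@subgroup %in% SUBGROUPS)
    return(sprintf("unknown subgroup '%s'", object@subgroup))
  if (length(object@survivalDays) != 1L || object@survivalDays < 0)
    return("survivalDays must be a non-negative scalar")
  if (!object@event %in% c(0L, 1L)) return("event must be 0 or 1")
  TRUE
})

#' A cohort of subject studies
#'
#' List of [SubjectStudy-class] objects together with the clinical table
#' (`subject_id`, `subgroup`, `survival_days`, `event`) in matching order.
#'
#' @slot subjects list of [SubjectStudy-class].
#' @slot clinical data.frame, one row per subject.
#' @export
setClass("MBCohort",
  representation(subjects = "list", clinical = "data.frame"))

setValidity("MBCohort", function(object) {
  if (!all(vapply(object@subjects, is, logical(1), class2 = "SubjectStudy")))
    return("subjects must all be SubjectStudy")
  need <- c("subject_id", "subgroup", "survival_days", "event")
  if (!all(need %in% names(object@clinical)))
    return("clinical table must have subject_id, subgroup, survival_days, event")
  if (nrow(object@clinical) != length(object@subjects))
    return("clinical rows must match subjects 1:1")
  ids <- vapply(object@subjects, function(s) s@subjectId, character(1))
  if (!identical(as.character(object@clinical$subject_id), ids))
    return("clinical subject_id order must match subjects")
  TRUE
})

#' Cohort radiomics feature table
#'
#' A [SummarizedExperiment::SummarizedExperiment] with features as rows
#' (253 qualified names, `rowData` columns `modality` and `category`) and
#' subjects as columns (`colData` = the clinical table). Missing values
#' (features of absent modalities) are `NA` in the `features` assay.
#'
#' @export
#' @import SummarizedExperiment
setClass("RadiomicsFeatureTable", contains = "SummarizedExperiment")

#' Construct an MRVolume
#'
#' @param voxels numeric 3D array.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) world origin in mm.
#' @return An [MRVolume-class].
#' @examples
#' v <- MRVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), c(0.75, 0.75, 3))
#' spacing(v)
#' @export
MRVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("MRVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a SubjectStudy
#'
#' @param subjectId character scalar.
#' @param volumes named list of [MRVolume-class] (must include `CET1`).
#' @param mask binary [MRVolume-class] on the CET1 grid.
#' @param subgroup one of WNT, SHH, Group3, Group4.
#' @param survivalDays non-negative survival time in days.
#' @param event 0/1 event indicator.
#' @return A [SubjectStudy-class].
#' @export
SubjectStudy <- function(subjectId, volumes, mask, subgroup,
                         survivalDays = 0, event = 0L) {
  new("SubjectStudy", subjectId = as.character(subjectId), volumes = volumes,
      mask = mask, subgroup = subgroup, survivalDays = as.numeric(survivalDays),
      event = as.integer(event))
}

#' Construct a RadiomicsFeatureTable
#'
#' @param features numeric matrix, subjects x features (qualified names as
#'   column names); `NA` marks features of absent modalities.
#' @param clinical data.frame with `subject_id`, `subgroup`, `survival_days`,
#'   `event`, one row per subject in matching order.
#' @return A [RadiomicsFeatureTable-class] (features x subjects).
#' @export
RadiomicsFeatureTable <- function(features, clinical) {
  stopifnot(is.matrix(features), nrow(features) == nrow(clinical))
  cat0 <- featureCatalog()
  qn <- colnames(features)
  idx <- match(qn, cat0$qualified)
  rd <- S4Vectors::DataFrame(
    modality = ifelse(is.na(idx), NA_character_, cat0$modality[idx]),
    category = ifelse(is.na(idx), NA_character_, cat0$category[idx]),
    row.names = qn)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(features)),
    rowData = rd,
    colData = S4Vectors::DataFrame(clinical,
                                   row.names = clinical$subject_id))
  new("RadiomicsFeatureTable", se)
}
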