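#' Configuration for the synthetic multimodal cohort generator
#'
#' Defines the study conditions emulated by [generateCohort()]: a four-
#' subgroup medulloblastoma-like cohort with subgroup-specific tumour texture
#' (spatial correlation length of a Gaussian random field, in mm), subgroup
#' intensity shifts, modality-wise missingness, and survival times whose
#' hazard depends on a planted texture summary.
#'
#' Non-CET1 modalities are generated on a coarser grid with a known rigid
#' world offset (default 3.0, -1.5, 0 mm) that is *not* recorded in their
#' headers, so that harmonization ([prepareSubject()]) has genuine
#' registration work to do.
#'
#' @param nPerSubgroup integer(4), subjects per subgroup (WNT, SHH, Group3,
#'   Group4); default `c(7, 12, 8, 11)`, a 38-subject cohort.
#' @param gridShape integer(3) CET1 grid (each >= 8).
#' @param spacing numeric(3) CET1 voxel size, mm.
#' @param corrLength named numeric(4), texture correlation length (mm) per
#'   subgroup.
#' @param intensityShift named numeric(4), additive tumour intensity shift
#'   per subgroup.
#' @param noiseSd positive sd of i.i.d. voxel noise.
#' @param missingProb named probability of dropping each modality
#'   (CET1 is never dropped).
#' @param baselineScaleDays exponential survival scale (days) at planted
#'   feature value 0.
#' @param logHazardPerUnit log-hazard increment per unit of the planted
#'   texture summary.
#' @param censorTimeDays administrative censoring time (days); `Inf` disables.
#' @param effectModalities modalities that carry the subgroup-specific
#'   correlation length; the rest use `commonCorrLength`.
#' @param commonCorrLength correlation length (mm) for non-effect modalities.
#' @param movingSpacing numeric(3), grid spacing of non-CET1 modalities.
#' @param movingOffset numeric(3), unrecorded world offset (mm) of non-CET1
#'   modalities.
#' @param seed integer RNG seed.
#' @return A validated `cohort_config` list.
#' @export
cohortConfig <- function(nPerSubgroup = c(7L, 12L, 8L, 11L),
                         gridShape = c(32L, 32L, 16L),
                         spacing = c(0.75, 0.75, 3.0),
                         corrLength = c(WNT = 1.2, SHH = 2.5,
                                        Group3 = 4.5, Group4 = 8.0),
                         intensityShift = c(WNT = 0, SHH = 0.3,
                                            Group3 = 0.6, Group4 = 0.9),
                         noiseSd = 0.25,
                         missingProb = c(CET1 = 0, T1WI = 0.1, T2WI = 0.1,
                                         FLAIR = 0.1, ADC = 0.1),
                         baselineScaleDays = 1200,
                         logHazardPerUnit = 0,
                         censorTimeDays = 2000,
                         effectModalities = MODALITIES,
                         commonCorrLength = 3.0,
                         movingSpacing = c(1.5, 1.5, 3.0),
                         movingOffset = c(3.0, -1.5, 0.0),
                         seed = 1L) {
  cfg <- list(nPerSubgroup = as.integer(nPerSubgroup),
              gridShape = as.integer(gridShape),
              spacing = as.numeric(spacing),
              corrLength = corrLength, intensityShift = intensityShift,
              noiseSd = noiseSd, missingProb = missingProb,
              baselineScaleDays = baselineScaleDays,
              logHazardPerUnit = logHazardPerUnit,
              censorTimeDays = censorTimeDays,
              effectModalities = effectModalities,
              commonCorrLength = commonCorrLength,
              movingSpacing = as.numeric(movingSpacing),
              movingOffset = as.numeric(movingOffset),
              seed = as.integer(seed))
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  if (length(cfg$nPerSubgroup) != 4L || any(cfg$nPerSubgroup < 0))
    stop("nPerSubgroup must be 4 non-negative integers")
  if (length(cfg$gridShape) != 3L || any(cfg$gridShape < 8L))
    stop("gridShape must be >= 8 voxels per axis")
  if (any(cfg$spacing <= 0) || any(cfg$movingSpacing <= 0))
    stop("spacing must be positive")
  if (!all(SUBGROUPS %in% names(cfg$corrLength)) ||
      any(cfg$corrLength <= 0))
    stop("corrLength must name all 4 subgroups with positive values")
  if (!all(SUBGROUPS %in% names(cfg$intensityShift)))
    stop("intensityShift must name all 4 subgroups")
  if (cfg$noiseSd <= 0) stop("noiseSd must be positive")
  if (!all(MODALITIES %in% names(cfg$missingProb)) ||
      any(cfg$missingProb < 0 | cfg$missingProb > 1))
    stop("missingProb must name all 5 modalities with values in [0,1]")
  if (cfg$missingProb[["CET1"]] != 0)
    stop("CET1 is the reference modality and is never dropped")
  if (cfg$baselineScaleDays <= 0 || cfg$censorTimeDays <= 0)
    stop("survival scale and censor time must be positive")
  if (!all(cfg$effectModalities %in% MODALITIES))
    stop("effectModalities must be among the 5 modalities")
  invisible(TRUE)
}

#' Generate a random tumour mask
#'
#' A randomly perturbed ellipsoid, guaranteed to be a single 26-connected
#' component strictly inside the grid with between 50 and 5000 voxels. Uses
#' the current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param config a [cohortConfig()].
#' @return A binary [MRVolume-class] on the CET1 grid.
#' @export
generateTumorMask <- function(config) {
  dm <- config$gridShape; sp <- config$spacing
  if (any(dm < 8L)) stop("grid too small to contain the minimum ellipsoid")
  ext <- dm * sp
  for (try in 1:25) {
    ctr <- ext / 2 + runif(3, -0.05, 0.05) * ext
    # semi-axes in mm, capped so the perturbed surface stays off the border
    cap <- ext / 2 - 1.5 * sp
    semi <- pmin(c(runif(2, 0.18, 0.32) * ext[1:2],
                   runif(1, 0.22, 0.40) * ext[3]), cap / 1.2)
    xyz <- voxelCenters(dm, sp, c(0, 0, 0))
    d <- sqrt(((xyz[, 1] - ctr[1]) / semi[1])^2 +
              ((xyz[, 2] - ctr[2]) / semi[2])^2 +
              ((xyz[, 3] - ctr[3]) / semi[3])^2)
    pert <- gaussianSmooth3D(array(rnorm(prod(dm)), dm), 2.5 / sp)
    pert <- pert / max(sd(pert), 1e-12) * 0.12
    m <- array(d, dm) + pert <= 1
    # keep the component containing the voxel nearest the centre
    seed <- array(FALSE, dm)
    seed[ceiling(dm[1] / 2), ceiling(dm[2] / 2), ceiling(dm[3] / 2)] <- TRUE
    if (!m[which(seed)]) next
    m <- connectedComponent(m, seed)
    # reject if touching any boundary face or out of the size envelope
    touches <- any(m[1, , ]) || any(m[dm[1], , ]) || any(m[, 1, ]) ||
      any(m[, dm[2], ]) || any(m[, , 1]) || any(m[, , dm[3]])
    nv <- sum(m)
    if (!touches && nv >= 50 && nv <= 5000)
      return(MRVolume(array(as.numeric(m), dm), spacing = sp))
  }
  stop("grid too small to contain the minimum ellipsoid")
}

# Smooth Gaussian random field with the given correlation length (mm),
# unit-variance over the mask, on an anisotropic grid.
textureField <- function(dm, spacing, corrLengthMM, maskArr) {
  f <- gaussianSmooth3D(array(rnorm(prod(dm)), dm), corrLengthMM / spacing)
  s <- sd(f[maskArr > 0])
  if (s < 1e-12) s <- sd(f)
  f / max(s, 1e-12)
}

# Planted per-subject texture summary: mean absolute difference between
# x-neighbouring tumour voxels of the CET1 texture field. Short correlation
# lengths give high values; this is the covariate the survival model uses.
plantedTextureSummary <- function(fieldArr, maskArr) {
  dm <- dim(fieldArr)
  a <- fieldArr[-dm[1], , ]; b <- fieldArr[-1, , ]
  ma <- maskArr[-dm[1], , ] > 0 & maskArr[-1, , ] > 0
  if (!any(ma)) return(0)
  mean(abs(a[ma] - b[ma]))
}

#' Simulate survival times under the generator's exponential hazard model
#'
#' Event times are exponential with rate
#' `exp(logHazardPerUnit * x) / baselineScaleDays` — an exact proportional-
#' hazards law — administratively censored at `censorTimeDays`.
#'
#' @param x numeric covariate vector (the planted feature).
#' @param baselineScaleDays baseline exponential scale in days.
#' @param logHazardPerUnit log-hazard per unit of `x`.
#' @param censorTimeDays censoring time in days (`Inf` = none).
#' @return data.frame with `time` (days) and `event` (0/1).
#' @export
simulateSurvival <- function(x, baselineScaleDays = 1200,
                             logHazardPerUnit = 0,
                             censorTimeDays = Inf) {
  rate <- exp(logHazardPerUnit * x) / baselineScaleDays
  t0 <- rexp(length(x), rate = rate)
  data.frame(time = pmin(t0, censorTimeDays),
             event = as.integer(t0 <= censorTimeDays))
}

#' Generate one synthetic subject
#'
#' Tumour voxels of each present modality are a smoothed Gaussian random
#' field with the subgroup's correlation length, plus the subgroup intensity
#' shift and i.i.d. noise; background is a distinct baseline. Non-CET1
#' modalities are sampled onto a coarser grid with an unrecorded rigid world
#' offset and dropped independently with their `missingProb`. Survival is
#' exponential with log-hazard proportional to the planted texture summary.
#' Uses the current RNG state.
#'
#' @param config a [cohortConfig()].
#' @param subgroup one of WNT, SHH, Group3, Group4.
#' @param subjectId subject identifier.
#' @return A [SubjectStudy-class]; attribute `planted` holds the texture
#'   summary that drives the hazard.
#' @export
generateSubject <- function(config, subgroup, subjectId = "S1") {
  if (!subgroup %in% SUBGROUPS)
    stop(sprintf("unknown subgroup label '%s'", subgroup))
  dm <- config$gridShape; sp <- config$spacing
  mask <- generateTumorMask(config)
  maskArr <- mask@voxels
  shift <- config$intensityShift[[subgroup]]
  background <- -2

  planted <- NA_real_
  vols <- list()
  for (mod in MODALITIES) {
    cl <- if (mod %in% config$effectModalities)
      config$corrLength[[subgroup]] else config$commonCorrLength
    field <- textureField(dm, sp, cl, maskArr)
    if (mod == "CET1") planted <- plantedTextureSummary(field, maskArr)
    img <- array(background + rnorm(prod(dm), sd = config$noiseSd), dm)
    inside <- maskArr > 0
    img[inside] <- shift + field[inside] +
      rnorm(sum(inside), sd = config$noiseSd)
    vol <- MRVolume(img, spacing = sp)
    if (mod == "CET1") {
      vols[[mod]] <- vol
    } else if (runif(1) >= config$missingProb[[mod]]) {
      vols[[mod]] <- degradeToMovingGrid(vol, config)
    }
  }
  surv <- simulateSurvival(planted, config$baselineScaleDays,
                           config$logHazardPerUnit, config$censorTimeDays)
  st <- SubjectStudy(subjectId, vols, mask, subgroup,
                     survivalDays = surv$time, event = surv$event)
  attr(st, "planted") <- planted
  st
}

# Resample a CET1-grid volume onto the coarser "scanner" grid of a moving
# modality, applying the configured world offset without recording it in the
# header: stored voxel at world x actually shows content from x + offset.
degradeToMovingGrid <- function(vol, config) {
  ext <- gridDim(vol) * vol@spacing
  msp <- config$movingSpacing
  mdm <- pmax(ceiling(ext / msp), 1)
  w <- voxelCenters(mdm, msp, c(0, 0, 0))
  w <- sweep(w, 2, config$movingOffset, "+")
  vals <- sampleVolumeWorld(vol, w, "trilinear", fill = -2)
  MRVolume(array(vals, mdm), spacing = msp)
}

#' Generate a full synthetic cohort
#'
#' Seeds the RNG from `config$seed` and generates `sum(nPerSubgroup)`
#' subjects plus the clinical table (`subject_id`, `subgroup`,
#' `survival_days`, `event`). Fully reproducible from the seed.
#'
#' @param config a [cohortConfig()].
#' @return An [MBCohort-class]; `attr(, "planted")` holds the per-subject
#'   planted texture summaries.
#' @examples
#' cfg <- cohortConfig(nPerSubgroup = c(1, 1, 1, 1),
#'                     gridShape = c(16, 16, 8), seed = 7)
#' gen <- generateCohort(cfg)
#' clinicalData(gen)
#' @export
generateCohort <- function(config) {
  validateCohortConfig(config)
  set.seed(config$seed)
  subs <- list(); planted <- numeric(0)
  n <- 0L
  for (g in seq_along(SUBGROUPS)) {
    for (i in seq_len(config$nPerSubgroup[g])) {
      n <- n + 1L
      st <- generateSubject(config, SUBGROUPS[g],
                            subjectId = sprintf("S%03d", n))
      planted <- c(planted, attr(st, "planted"))
      subs[[n]] <- st
    }
  }
  clin <- data.frame(
    subject_id = vapply(subs, function(s) s@subjectId, character(1)),
    subgroup = vapply(subs, function(s) s@subgroup, character(1)),
    survival_days = vapply(subs, function(s) s@survivalDays, numeric(1)),
    event = vapply(subs, function(s) s@event, integer(1)),
    stringsAsFactors = FALSE)
  cohort <- new("MBCohort", subjects = subs, clinical = clin)
  attr(cohort, "planted") <- planted
  cohort
}

#' Write a cohort to disk
#'
#' One NIfTI per modality and mask per subject
#' (`<id>_<modality>.nii.gz`, `<id>_mask.nii.gz`) plus `clinical.csv`.
#'
#' @param cohort an [MBCohort-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort@subjects) {
    for (mod in names(s@volumes))
      writeVolume(s@volumes[[mod]],
                  file.path(dir, sprintf("%s_%s.nii.gz", s@subjectId, mod)))
    writeVolume(s@mask, file.path(dir, sprintf("%s_mask.nii.gz", s@subjectId)))
  }
  write.csv(cohort@clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing the NIfTI files and `clinical.csv`.
#' @return An [MBCohort-class].
#' @export
readCohort <- function(dir) {
  clin <- read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
  subs <- lapply(seq_len(nrow(clin)), function(i) {
    id <- clin$subject_id[i]
    vols <- list()
    for (mod in MODALITIES) {
      p <- file.path(dir, sprintf("%s_%s.nii.gz", id, mod))
      if (file.exists(p)) vols[[mod]] <- readVolume(p)
    }
    mask <- readVolume(file.path(dir, sprintf("%s_mask.nii.gz", id)))
    SubjectStudy(id, vols, mask, clin$subgroup[i],
                 survivalDays = clin$survival_days[i],
                 event = as.integer(clin$event[i]))
  })
  new("MBCohort", subjects = subs, clinical = clin)
}

#' Simulate a feature-level cohort
#'
#' Statistical-scale companion to the image-level generator: draws a complete
#' 253-column feature table directly (standard-normal features), optionally
#' planting additive subgroup mean shifts in chosen columns, modality-wise
#' missingness, and survival linked to one feature. Used for calibration
#' studies (null distributions, power, leakage checks) at sample sizes where
#' full 3D image synthesis is not the point.
#'
#' @param nPerSubgroup integer(4) subjects per subgroup.
#' @param effectModality modality whose features carry subgroup signatures
#'   (`NULL` = none).
#' @param effectSize additive shift, in SD units, of a subgroup's own
#'   signature columns.
#' @param nEffectFeatures number of affected columns within the modality,
#'   assigned round-robin to the four subgroups (each subgroup's block is
#'   shifted only in that subgroup's subjects).
#' @param missingProb probability each non-CET1 modality block is missing
#'   per subject.
#' @param survivalFeature qualified column name driving the hazard (`NULL` =
#'   no link).
#' @param logHazardPerSD log-hazard per SD of that feature.
#' @param baselineScaleDays,censorTimeDays survival law parameters.
#' @param seed RNG seed.
#' @return A [RadiomicsFeatureTable-class] (may contain `NA` blocks).
#' @export
simulateFeatureCohort <- function(nPerSubgroup = c(7L, 12L, 8L, 11L),
                                  effectModality = NULL,
                                  effectSize = 1.0,
                                  nEffectFeatures = 10L,
                                  missingProb = 0,
                                  survivalFeature = NULL,
                                  logHazardPerSD = 0,
                                  baselineScaleDays = 1200,
                                  censorTimeDays = Inf,
                                  seed = 1L) {
  set.seed(seed)
  cat0 <- featureCatalog()
  n <- sum(nPerSubgroup)
  grp <- rep(SUBGROUPS, times = nPerSubgroup)
  X <- matrix(rnorm(n * nrow(cat0)), n, nrow(cat0),
              dimnames = list(NULL, cat0$qualified))
  if (!is.null(effectModality)) {
    cols <- which(cat0$modality == effectModality)
    cols <- cols[seq_len(min(nEffectFeatures, length(cols)))]
    blocks <- rep_len(seq_along(SUBGROUPS), length(cols))
    for (g in seq_along(SUBGROUPS)) {
      inG <- grp == SUBGROUPS[g]
      X[inG, cols[blocks == g]] <- X[inG, cols[blocks == g]] + effectSize
    }
  }
  drive <- if (!is.null(survivalFeature)) X[, survivalFeature] else rep(0, n)
  surv <- simulateSurvival(drive, baselineScaleDays, logHazardPerSD,
                           censorTimeDays)
  if (missingProb > 0) {
    for (mod in setdiff(MODALITIES, "CET1")) {
      cols <- which(cat0$modality == mod)
      gone <- runif(n) < missingProb
      X[gone, cols] <- NA_real_
    }
  }
  clin <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                     subgroup = grp, survival_days = surv$time,
                     event = surv$event, stringsAsFactors = FALSE)
  RadiomicsFeatureTable(X, clin)
}
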