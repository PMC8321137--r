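test_that("tumour masks are reproducible, connected, bounded and sized", {
  cfg <- cohortConfig(gridShape = c(24L, 24L, 12L))
  set.seed(42); m1 <- generateTumorMask(cfg)
  set.seed(42); m2 <- generateTumorMask(cfg)
  expect_identical(voxels(m1), voxels(m2))

  for (s in c(1, 7, 19)) {
    set.seed(s)
    m <- voxels(generateTumorMask(cfg)) > 0
    expect_equal(mbRadiomics:::countComponents26(m), 1L)
  }
  set.seed(99)
  for (s in 1:60) {
    m <- voxels(generateTumorMask(cfg)) > 0
    dm <- dim(m)
    expect_false(any(m[1, , ]) || any(m[dm[1], , ]) || any(m[, 1, ]) ||
                   any(m[, dm[2], ]) || any(m[, , 1]) || any(m[, , dm[3]]))
    expect_gte(sum(m), 50)
    expect_lte(sum(m), 5000)
  }
})

test_that("tiny grids are rejected", {
  expect_error(cohortConfig(gridShape = c(4L, 24L, 12L)), "gridShape")
})

test_that("subject generation honours missingness, labels, and modal grids", {
  cfg <- cohortConfig(missingProb = c(CET1 = 0, T1WI = 0, T2WI = 0,
                                      FLAIR = 0, ADC = 0))
  set.seed(1)
  s <- generateSubject(cfg, "Group3")
  expect_setequal(modalities(s), c("CET1", "T1WI", "T2WI", "FLAIR", "ADC"))
  expect_error(generateSubject(cfg, "GroupX"), "unknown subgroup")
  # non-CET1 modalities live on the coarser scanner grid
  expect_equal(spacing(studyVolumes(s)$T2WI), cfg$movingSpacing)
  expect_equal(spacing(studyVolumes(s)$CET1), cfg$spacing)
  # always-dropped modality stays absent
  cfg2 <- cohortConfig(missingProb = c(CET1 = 0, T1WI = 1, T2WI = 0,
                                       FLAIR = 0, ADC = 0))
  set.seed(2)
  expect_false("T1WI" %in% modalities(generateSubject(cfg2, "WNT")))
})

test_that("null survival times follow the baseline exponential law", {
  set.seed(11)
  s <- simulateSurvival(rep(0, 500), baselineScaleDays = 1200,
                        logHazardPerUnit = 0, censorTimeDays = Inf)
  expect_true(all(s$event == 1))
  ks <- suppressWarnings(stats::ks.test(s$time, "pexp", rate = 1 / 1200))
  expect_gt(ks$p.value, 0.01)
})

test_that("shorter texture correlation raises mean GLCM contrast", {
  cfg <- cohortConfig(nPerSubgroup = c(4L, 4L, 0L, 0L),
                      corrLength = c(WNT = 0.8, SHH = 6, Group3 = 3,
                                     Group4 = 3),
                      gridShape = c(24L, 24L, 12L), seed = 5)
  tab <- extractCohortFeatures(prepareCohort(generateCohort(cfg),
                                             register = FALSE))
  X <- featureMatrix(tab); g <- clinicalData(tab)$subgroup
  mShort <- mean(X[g == "WNT", "CET1.glcm.contrast"])
  mLong <- mean(X[g == "SHH", "CET1.glcm.contrast"])
  expect_gt(mShort, mLong)
  expect_lt(mean(X[g == "WNT", "CET1.glcm.idn"]),
            mean(X[g == "SHH", "CET1.glcm.idn"]))
})

test_that("cohort generation is seed-deterministic with the right shape", {
  cfg <- cohortConfig(nPerSubgroup = c(1L, 1L, 1L, 1L),
                      gridShape = c(16L, 16L, 8L), seed = 3)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(clinicalData(c1), clinicalData(c2))
  expect_identical(voxels(studyVolumes(subjects(c1)[[1]])$CET1),
                   voxels(studyVolumes(subjects(c2)[[1]])$CET1))
  expect_equal(length(subjects(c1)), 4L)

  cfg2 <- cohortConfig(nPerSubgroup = c(0L, 0L, 0L, 5L),
                       gridShape = c(16L, 16L, 8L), seed = 3)
  c3 <- generateCohort(cfg2)
  expect_equal(length(subjects(c3)), 5L)
  expect_true(all(clinicalData(c3)$subgroup == "Group4"))
})

test_that("cohort round-trips through NIfTI + CSV on disk", {
  cfg <- cohortConfig(nPerSubgroup = c(1L, 0L, 0L, 1L),
                      gridShape = c(16L, 16L, 8L), seed = 4)
  co <- generateCohort(cfg)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_identical(clinicalData(back)$subject_id,
                   clinicalData(co)$subject_id)
  v0 <- studyVolumes(subjects(co)[[1]])$CET1
  v1 <- studyVolumes(subjects(back)[[1]])$CET1
  expect_equal(voxels(v1), voxels(v0), tolerance = 1e-6)
  expect_equal(spacing(v1), spacing(v0), tolerance = 1e-6)
})
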