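test_that("the catalog has the published structure", {
  cat0 <- featureCatalog()
  expect_equal(nrow(cat0), 253L)
  nm <- catalogNames()
  expect_equal(lengths(nm)[c("first_order", "shape", "glcm", "glrlm")],
               c(first_order = 16L, shape = 8L, glcm = 22L, glrlm = 11L))
  expect_equal(sum(lengths(nm)), 57L)
  expect_false(any(duplicated(cat0$qualified)))
  expect_equal(sum(cat0$modality == "CET1"), 49L)
})

test_that("discretization maps extremes to the end bins", {
  dm <- c(8, 8, 4)
  set.seed(1)
  arr <- array(runif(prod(dm)), dm)
  v <- MRVolume(arr); mk <- MRVolume(array(1, dm))
  dv <- discretizeVolume(v, mk, 8)
  expect_equal(dv$levels[which.min(arr)], 1L)
  expect_equal(dv$levels[which.max(arr)], 8L)
  expect_true(all(dv$levels >= 1 & dv$levels <= 8))
  # constant region: all level 1
  dvc <- discretizeVolume(MRVolume(array(2, dm)), mk, 8)
  expect_true(all(dvc$levels == 1L))
  expect_error(discretizeVolume(v, mk, 1), "ng")
  # uniform values fill bins evenly (3 SE multinomial check)
  set.seed(5)
  big <- array(runif(1e5), c(100, 100, 10))
  dvb <- discretizeVolume(MRVolume(big), MRVolume(array(1, c(100, 100, 10))),
                          32)
  freq <- tabulate(dvb$levels[dvb$levels > 0], 32) / 1e5
  se <- sqrt((1 / 32) * (31 / 32) / 1e5)
  expect_true(all(abs(freq - 1 / 32) < 3 * se + 1e-6))
})

test_that("first-order statistics match closed forms and a direct oracle", {
  v <- MRVolume(array(c(1, 2, 3, 0, 0, 0), c(6, 1, 1)))
  mk <- MRVolume(array(c(1, 1, 1, 0, 0, 0), c(6, 1, 1)))
  fo <- firstOrderFeatures(v, mk)
  expect_equal(fo[["mean"]], 2)
  expect_equal(fo[["median"]], 2)
  expect_equal(fo[["skewness"]], 0)
  expect_equal(fo[["range"]], 2)
  # constant region degeneracies
  foc <- firstOrderFeatures(MRVolume(array(4, c(4, 4, 2))),
                            MRVolume(array(1, c(4, 4, 2))))
  expect_equal(foc[["sd"]], 0)
  expect_equal(foc[["uniformity"]], 1)
  expect_equal(foc[["entropy"]], 0)
  # RMS against direct summation
  set.seed(3)
  arr <- array(rnorm(200), c(10, 10, 2))
  m <- array(as.numeric(runif(200) < 0.7), c(10, 10, 2))
  fo2 <- firstOrderFeatures(MRVolume(arr), MRVolume(m))
  vv <- arr[m > 0]
  expect_equal(fo2[["rms"]], sqrt(sum(vv^2) / length(vv)), tolerance = 1e-12)
  expect_equal(fo2[["energy"]], sum(vv^2), tolerance = 1e-12)
})

test_that("shape features: voxel volume, ball limit, translation invariance", {
  sv <- array(0, c(8, 8, 8)); sv[4, 4, 4] <- 1
  sf <- shapeFeatures(MRVolume(sv, c(0.75, 0.75, 3)))
  expect_equal(sf[["volume"]], 1.6875)

  xyz <- expand.grid(1:25, 1:25, 1:25)
  ball <- array(as.numeric(sqrt((xyz[, 1] - 13)^2 + (xyz[, 2] - 13)^2 +
                                  (xyz[, 3] - 13)^2) <= 10), c(25, 25, 25))
  sfb <- shapeFeatures(MRVolume(ball, c(1, 1, 1)))
  expect_gte(sfb[["sphericity"]], 0.90)
  expect_lte(sfb[["sphericity"]], 1.0)
  expect_gte(sfb[["compactness2"]], 0.73)
  expect_lte(sfb[["compactness2"]], 1.0)
  expect_equal(sfb[["max.diameter3D"]], 20)

  b1 <- array(0, c(20, 20, 8)); b1[7:16, 5:14, 3:4] <- 1
  b2 <- array(0, c(20, 20, 8)); b2[9:18, 7:16, 5:6] <- 1
  expect_equal(shapeFeatures(MRVolume(b1, c(1, 1, 3))),
               shapeFeatures(MRVolume(b2, c(1, 1, 3))), tolerance = 1e-12)
})

test_that("GLCM matches hand enumeration on the 2x2 single-slice example", {
  arr <- array(c(1, 1, 1, 2), c(2, 2, 1))
  dv <- discretizeVolume(MRVolume(arr), MRVolume(array(1, c(2, 2, 1))), 2)
  g <- glcmBuild(dv, offsets = matrix(c(0, 1, 0), 1))
  expect_equal(g$P, matrix(c(0.5, 0.25, 0.25, 0), 2), tolerance = 1e-15)
  f <- glcmFeatures(g)
  expect_equal(f[["contrast"]], 0.5)
  expect_equal(f[["dissimilarity"]], 0.5)
  expect_equal(f[["entropy"]], 1.5)
})

test_that("GLCM degenerate and structural identities hold", {
  dm <- c(6, 6, 3)
  dv <- discretizeVolume(MRVolume(array(3, dm)), MRVolume(array(1, dm)), 16)
  f <- glcmFeatures(glcmBuild(dv))
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["dissimilarity"]], 0)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["idn"]], 1)
  expect_equal(f[["idmn"]], 1)
  expect_equal(f[["cluster.tendency"]], 0)
  expect_equal(f[["cluster.prominence"]], 0)
  # sum-to-one and symmetry on random volumes
  set.seed(4)
  for (rep in 1:5) {
    dvr <- randomDiscretizedVolume(ng = 5)
    P <- glcmBuild(dvr)$P
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-15)
  }
})

test_that("all 22 GLCM features agree with the naive-loop oracle", {
  set.seed(7)
  for (rep in 1:20) {
    dv <- randomDiscretizedVolume(dm = c(6, 6, 3), ng = 8)
    M <- glcmBuild(dv)
    got <- glcmFeatures(M)
    want <- naiveGlcmFeatures(M$P)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
    # and the matrix itself against the naive pair counter
    Pn <- naiveGlcmBuild(dv$levels, dv$ng, mbRadiomics:::OFFSETS13)
    expect_equal(M$P, Pn, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("GLRLM matches hand enumeration and conserves voxels", {
  arr <- array(c(1, 1, 2), c(3, 1, 1))
  dv <- discretizeVolume(MRVolume(arr), MRVolume(array(1, c(3, 1, 1))), 2)
  r <- glrlmBuild(dv, offsets = matrix(c(1, 0, 0), 1))
  expect_equal(r$R[1, 2], 1)
  expect_equal(r$R[2, 1], 1)
  expect_equal(r$nRuns, 2)
  f <- glrlmFeatures(r)
  expect_equal(f[["SRLGLE"]], 0.25)
  expect_equal(f[["RP"]], 2 / 3)

  # constant row of length L -> a single maximal run
  arrL <- array(1, c(7, 1, 1))
  dvL <- discretizeVolume(MRVolume(arrL), MRVolume(array(1, c(7, 1, 1))), 4)
  rL <- glrlmBuild(dvL, offsets = matrix(c(1, 0, 0), 1))
  expect_equal(rL$nRuns, 1)
  expect_equal(rL$R[1, 7], 1)

  # voxel conservation per direction on random volumes
  set.seed(9)
  for (rep in 1:5) {
    dvr <- randomDiscretizedVolume(ng = 4)
    r1 <- glrlmBuild(dvr, offsets = matrix(c(1, 0, 0), 1))
    expect_equal(sum(r1$R * col(r1$R)), sum(dvr$levels > 0))
  }
  # constant tumour: all runs at level 1
  dm <- c(6, 6, 3)
  dvc <- discretizeVolume(MRVolume(array(2, dm)), MRVolume(array(1, dm)), 8)
  fc <- glrlmFeatures(glrlmBuild(dvc))
  expect_equal(fc[["LGLRE"]], 1)
  expect_equal(fc[["HGLRE"]], 1)
})

test_that("all 11 GLRLM features agree with the naive-loop oracle", {
  set.seed(13)
  for (rep in 1:20) {
    dv <- randomDiscretizedVolume(dm = c(6, 6, 3), ng = 4)
    R <- glrlmBuild(dv)
    Rn <- naiveGlrlmBuild(dv$levels, dv$ng, mbRadiomics:::OFFSETS13)
    expect_equal(R$R, Rn, ignore_attr = TRUE)
    got <- glrlmFeatures(R)
    want <- naiveGlrlmFeatures(Rn, 13, sum(dv$levels > 0))
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("pooled texture features are invariant to 90-degree z rotation", {
  set.seed(21)
  dm <- c(10, 10, 4)
  arr <- array(runif(prod(dm)), dm)
  mask <- array(0, dm); mask[3:8, 3:8, 2:3] <- 1
  rot <- function(a) {
    out <- array(0, c(dim(a)[2], dim(a)[1], dim(a)[3]))
    for (k in seq_len(dim(a)[3])) out[, , k] <- t(a[, , k])[, dim(a)[1]:1]
    out
  }
  dv1 <- discretizeVolume(MRVolume(arr), MRVolume(mask), 8)
  dv2 <- discretizeVolume(MRVolume(rot(arr)), MRVolume(rot(mask)), 8)
  expect_equal(glcmFeatures(glcmBuild(dv1)), glcmFeatures(glcmBuild(dv2)),
               tolerance = 1e-12)
  expect_equal(glrlmFeatures(glrlmBuild(dv1)),
               glrlmFeatures(glrlmBuild(dv2)), tolerance = 1e-12)
})

test_that("extraction yields 253 features with NA exactly for absent modalities", {
  s <- makeHarmonizedStudy()
  fv <- extractSubject(s)
  expect_length(fv, 253L)
  expect_equal(sum(is.na(fv)), 0L)

  s2 <- makeHarmonizedStudy(mods = c("CET1", "T1WI", "T2WI"))
  fv2 <- extractSubject(s2)
  expect_equal(sum(is.na(fv2)), 98L)
  missNames <- names(fv2)[is.na(fv2)]
  expect_true(all(grepl("^(FLAIR|ADC)\\.", missNames)))

  s3 <- makeHarmonizedStudy(seed = 1)  # identical to s
  expect_identical(extractSubject(s3), fv)
})
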