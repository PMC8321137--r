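test_that("Cox beta matches a dense grid search of the partial likelihood", {
  # 4 subjects, binary covariate, distinct event times (Efron = Breslow here)
  time <- c(2, 5, 7, 9); event <- c(1, 1, 1, 0); x <- c(1, 0, 1, 0)
  ft <- coxFit(time, event, x)
  logpl <- function(b) {
    risk <- exp(b * x)
    lp <- 0
    for (i in which(event == 1)) {
      rs <- time >= time[i]
      lp <- lp + b * x[i] - log(sum(risk[rs]))
    }
    lp
  }
  grid <- seq(-4, 4, by = 1e-3)
  bHat <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  expect_equal(ft$coefficients$beta, bHat, tolerance = 1e-3)
})

test_that("Cox fit errors on degenerate input and is centering-invariant", {
  expect_error(coxFit(c(1, 2, 3), c(0, 0, 0), c(1, 2, 3)), "no events")
  expect_error(coxFit(c(1, 2, 3), c(1, 1, 0), c(2, 2, 2)), "zero-variance")
  set.seed(1)
  x <- rnorm(60)
  s <- simulateSurvival(x, 1000, log(1.5), 2000)
  b1 <- coxFit(s$time, s$event, x)$coefficients$beta
  b2 <- coxFit(s$time, s$event, x - 17.3)$coefficients$beta
  expect_equal(b1, b2, tolerance = 1e-8)
  # HR invariant under time rescaling
  b3 <- coxFit(s$time * 3.7, s$event, x)$coefficients$beta
  expect_equal(b1, b3, tolerance = 1e-8)
})

test_that("null covariates give small beta and honest p-values", {
  set.seed(2)
  ps <- replicate(60, {
    x <- rnorm(150)
    s <- simulateSurvival(rep(0, 150), 1000, 0, Inf)
    ft <- coxFit(s$time, s$event, x)
    c(ft$coefficients$beta, ft$coefficients$p)
  })
  expect_lt(max(abs(ps[1, ])), 0.5)
  expect_gt(suppressWarnings(stats::ks.test(ps[2, ], "punif"))$p.value, 0.01)
})

test_that("univariate screen flags a planted-hazard feature", {
  hits <- 0
  for (s in 1:10) {
    tab <- simulateFeatureCohort(nPerSubgroup = rep(25L, 4),
                                 survivalFeature = "CET1.glrlm.SRLGLE",
                                 logHazardPerSD = log(2),
                                 censorTimeDays = 3000, seed = 200 + s)
    scr <- screenUnivariate(tab)
    if ("CET1.glrlm.SRLGLE" %in% scr$significant) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("multivariate refinement reduces to the univariate fit for one candidate", {
  tab <- simulateFeatureCohort(nPerSubgroup = rep(10L, 4),
                               survivalFeature = "CET1.fo.mean",
                               logHazardPerSD = log(2), seed = 41)
  uni <- coxFit(clinicalData(tab)$survival_days, clinicalData(tab)$event,
                featureMatrix(tab)[, "CET1.fo.mean", drop = FALSE])
  multi <- multivariateRefine("CET1.fo.mean", tab)
  expect_equal(multi$coefficients$beta, uni$coefficients$beta,
               tolerance = 1e-10)
  empty <- multivariateRefine(character(0), tab)
  expect_null(empty$coefficients)
})

test_that("Q3 dichotomization uses the interpolated quantile, strictly greater", {
  d <- dichotomizeQ3(1:8)
  expect_equal(d$threshold, 6.25)
  expect_equal(which(d$high), c(7L, 8L))
  expect_error(dichotomizeQ3(rep(2, 10)), "identical")
  set.seed(3)
  v <- rnorm(37)
  d2 <- dichotomizeQ3(v)
  # sort-based oracle for the type-7 quantile
  h <- (length(v) - 1) * 0.75 + 1
  lo <- floor(h)
  q <- sort(v)[lo] + (h - lo) * (sort(v)[lo + 1] - sort(v)[lo])
  expect_equal(d2$threshold, q, tolerance = 1e-12)
  expect_true(d2$nHigh %in% c(floor(37 / 4), ceiling(37 / 4)))
})

test_that("Kaplan-Meier medians and the log-rank test match hand computation", {
  km <- kmLogrank(time = c(1, 2, 3, 4, 5, 10, 20, 30, 40, 50),
                  event = rep(1L, 10),
                  group = rep(c("A", "B"), each = 5))
  expect_equal(unname(km$medians["A"]), 3)
  expect_equal(unname(km$medians["B"]), 30)

  # identical groups: chi-square 0, p 1, HR 1
  km0 <- kmLogrank(time = rep(c(2, 4, 6), 2), event = rep(1L, 6),
                   group = rep(c("A", "B"), each = 3))
  expect_equal(km0$chisq, 0, tolerance = 1e-12)
  expect_equal(km0$p, 1, tolerance = 1e-12)
  expect_equal(km0$HR, 1, tolerance = 1e-8)

  # toy 2x2: A events at 1,2; B events at 3,4 -- hand observed/expected
  t0 <- c(1, 2, 3, 4); e0 <- rep(1L, 4); g0 <- c("A", "A", "B", "B")
  kmT <- kmLogrank(t0, e0, g0)
  # at t=1: O_A=1, E_A=2/4; t=2: O_A=1, E_A=1/3; t=3,4: O_A=0, E_A=0
  OA <- 2; EA <- 0.5 + 1 / 3
  VA <- (2 * 2) / 16 + (1 * 2) / 9   # hypergeometric variances
  chi <- (OA - EA)^2 / VA
  expect_equal(kmT$chisq, chi, tolerance = 1e-10)
  expect_error(kmLogrank(t0, e0, rep("A", 4)), "2 groups")
})

test_that("the full survival stage designates a prognosticator end to end", {
  tab <- simulateFeatureCohort(nPerSubgroup = c(7L, 12L, 8L, 11L),
                               survivalFeature = "CET1.glrlm.SRLGLE",
                               logHazardPerSD = log(3),
                               censorTimeDays = 4000, seed = 55)
  st <- survivalStage(tab)
  expect_true("CET1.glrlm.SRLGLE" %in% st$univariate$significant)
  expect_false(is.null(st$prognosticator))
  expect_false(is.null(st$km))
  expect_true(st$km$HR > 0 && st$km$ciLow <= st$km$HR &&
                st$km$HR <= st$km$ciHigh)
})
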