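# Survey calibration fitting and dose reconstruction.

test_that("through-origin fit is exact on proportional data", {
  f2 <- fitProportional(1:10, 2 * (1:10))
  expect_equal(f2$slope, 2)
  expect_equal(f2$sd, 0)
  f1 <- fitProportional(c(3, 7, 11), c(3, 7, 11))
  expect_equal(f1$slope, 1)
  expect_error(fitProportional(c(0, 0), c(1, 2)), "all-zero")
  expect_warning(fitProportional(5, 10), class = "singlePairWarning")
})

test_that("proportional fit recovers the car-body factor from Poisson pairs", {
  set.seed(12)
  n <- 462
  inside <- runif(n, 100, 500)
  outside <- rpois(n, inside * 2.01 * 120) / 120
  insideObs <- rpois(n, inside * 120) / 120
  f <- fitProportional(insideObs, outside)
  expect_lt(abs(f$slope - 2.01), 3 * f$sd)
  expect_lt(f$sd / f$slope, 0.05)
})

test_that("the intercept option reports an ordinary fit", {
  set.seed(13)
  x <- runif(50, 10, 100)
  y <- 5 + 3 * x + rnorm(50, sd = 1e-3)
  f <- fitProportional(x, y, intercept = TRUE)
  expect_equal(f$slope, 3, tolerance = 1e-4)
  expect_equal(f$intercept, 5, tolerance = 1e-2)
})

test_that("calibration estimation recovers the generating truth", {
  cfg <- truthConfig(sfCarbody = c(c1 = 2.01),
                     sfAsphalt = c(north = 0.96, south = 1.37))
  s <- generateSites(cfg, 60, seed = 8)
  p <- simulatePairedCounts(s, cfg, noise = FALSE)
  p$doseNgyH <- s$dDirect
  cal <- estimateCalibration(p, by = "region")
  expect_equal(sfCarbody(cal$south), 2.01, tolerance = 0.01)
  expect_equal(sfAsphalt(cal$south), 1.37, tolerance = 0.01)
  expect_equal(dcf(cal$south), 0.14, tolerance = 0.01)
  # a northern campaign's roadbed factor comes out below one
  expect_equal(sfAsphalt(cal$north), 0.96, tolerance = 0.01)
  expect_lt(sfAsphalt(cal$north), 1)
})

test_that("identity truths give an identity calibration", {
  cfg <- truthConfig(sfCarbody = c(c1 = 1), sfAsphalt = c(north = 1, south = 1), dcf = 1)
  s <- generateSites(cfg, 25, seed = 9)
  p <- simulatePairedCounts(s, cfg, noise = FALSE)
  p$doseNgyH <- s$dDirect
  cal <- estimateCalibration(p)
  expect_equal(unname(cal@factors), c(1, 1, 1), tolerance = 1e-9)
})

test_that("missing column pairs name the calibration they prevent", {
  p <- data.frame(insideCps = 1:3, outsideCps = 2 * (1:3))
  expect_error(estimateCalibration(p), "sfAsphalt")
  p$asphaltCps <- 1:3; p$bareCps <- 1:3
  expect_error(estimateCalibration(p), "dcf")
})

test_that("dose reconstruction applies the multiplicative model", {
  cal <- calibrationSet(2.01, 1.37, 0.14)
  tr <- reconstructDose(data.frame(cps = c(300, 0, 50)), cal)
  expect_equal(tr$doseNgyH, c(300, 0, 50) * 2.01 * 1.37 * 0.14)
  expect_equal(tr$doseNgyH[1], 115.66, tolerance = 1e-3)
  expect_identical(tr$doseNgyH[2], 0)
  ident <- calibrationSet(1, 1, 1)
  expect_equal(reconstructDose(data.frame(cps = 50), ident)$doseNgyH, 50)
  expect_error(reconstructDose(data.frame(cps = -1), cal), "negative")
})

test_that("reconstruction is linear, monotone and permutation-equivariant", {
  cal <- calibrationSet(2.01, 1.37, 0.14)
  set.seed(14)
  cps <- runif(40, 0, 600)
  d <- reconstructDose(data.frame(cps = cps), cal)$doseNgyH
  expect_equal(reconstructDose(data.frame(cps = 2 * cps), cal)$doseNgyH, 2 * d)
  expect_true(all(diff(d[order(cps)]) >= 0))
  perm <- sample(40)
  expect_equal(reconstructDose(data.frame(cps = cps[perm]), cal)$doseNgyH, d[perm])
})

test_that("campaign-keyed calibration lists select by record", {
  cals <- list(a = calibrationSet(2.01, 1, 0.14), b = calibrationSet(1.71, 1, 0.14))
  tr <- data.frame(cps = c(100, 100), campaign = c("a", "b"))
  out <- reconstructDose(tr, cals)
  expect_equal(out$doseNgyH, c(100 * 2.01 * 0.14, 100 * 1.71 * 0.14))
  expect_error(reconstructDose(data.frame(cps = 1, campaign = "c"), cals),
               "no calibration")
})

test_that("the calibrate-then-reconstruct loop recovers the field mean", {
  cfg <- truthConfig()
  s <- generateSites(cfg, 100, seed = 15)
  p <- simulatePairedCounts(s, cfg, seed = 16)
  p$doseNgyH <- s$dDirect  # stand-in for unfolded doses at unit-test scale
  cal <- estimateCalibration(p, by = "region")
  tr <- simulateTrack(makeSurveyRoute(s, 1000), s, cfg, seed = 17)
  rec <- reconstructDose(tr, cal, by = "region")
  se <- sd(rec$doseNgyH) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$doseNgyH) - mean(tr$dTrue)), 3 * se)
})
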