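# Synthetic survey generator: ground truth recoverability and determinism.

test_that("degenerate zero-SD regions reproduce the regional means exactly", {
  reg <- defaultRegionTable()
  reg[, grep("sd$", names(reg))] <- 0
  cfg <- truthConfig(regions = reg)
  s <- generateSites(cfg, 20, seed = 1)
  for (r in c("north", "south")) {
    sr <- s[s$region == r, ]
    row <- reg[reg$region == r, ]
    expect_equal(unique(sr$soilU), row$soilU)
    expect_equal(unique(sr$soilTh), row$soilTh)
    expect_equal(unique(sr$soilK), row$soilK)
    expect_equal(unique(sr$directU), row$directU)
  }
})

test_that("site triplet sample means recover the configured means", {
  reg <- defaultRegionTable()[1, ]
  reg$soilU <- 35; reg$soilUsd <- 22
  reg$soilTh <- 57; reg$soilThsd <- 33
  reg$soilK <- 551; reg$soilKsd <- 342
  cfg <- truthConfig(regions = reg, sfAsphalt = c(north = 0.96))
  s <- generateSites(cfg, 2000, seed = 1)
  for (col in list(c("soilU", 35, 22), c("soilTh", 57, 33), c("soilK", 551, 342))) {
    se <- as.numeric(col[3]) / sqrt(2000)
    expect_lt(abs(mean(s[[col[1]]]) - as.numeric(col[2])), 3 * se)
  }
})

test_that("generators are reproducible under a fixed seed", {
  cfg <- truthConfig()
  expect_identical(generateSites(cfg, 40, seed = 5), generateSites(cfg, 40, seed = 5))
  s <- generateSites(cfg, 5, seed = 5)
  expect_identical(simulateNaiSpectrum(s[1, ], 30, cfg, seed = 9),
                   simulateNaiSpectrum(s[1, ], 30, cfg, seed = 9))
  expect_identical(simulatePairedCounts(s, cfg, seed = 9),
                   simulatePairedCounts(s, cfg, seed = 9))
  r <- makeSurveyRoute(s, 20)
  expect_identical(simulateTrack(r, s, cfg, seed = 9), simulateTrack(r, s, cfg, seed = 9))
})

test_that("site generation rejects bad inputs", {
  cfg <- truthConfig()
  expect_error(generateSites(cfg, 0), "positive count")
  expect_error(generateSites(cfg, 10, regions = "mekong"), "unknown region")
})

test_that("NaI forward model: zero activity and cosmic give an empty spectrum", {
  cfg <- truthConfig(cosmicRate = 0)
  site <- list(directU = 0, directTh = 0, directK = 0)
  sp <- simulateNaiSpectrum(site, 600, cfg, noise = FALSE)
  expect_true(all(spectrumCounts(sp) == 0))
})

test_that("NaI forward model: a pure K-40 site puts its photopeak at 1.464 MeV", {
  cfg <- truthConfig(cosmicRate = 0, continuumFraction = 0)
  site <- list(directU = 0, directTh = 0, directK = 500)
  sp <- simulateNaiSpectrum(site, 600, cfg, noise = FALSE)
  counts <- spectrumCounts(sp)
  peakCh <- which.max(counts)
  expectCh <- 1464 / cfg@gain + 0.5
  expect_lt(abs(peakCh - expectCh), 1)
  # all detected counts belong to the peak and its tails
  expect_equal(sum(counts), 500 * 0.040 * 600, tolerance = 1e-6)
})

test_that("NaI expected counts scale linearly with live time", {
  cfg <- truthConfig()
  site <- list(directU = 35, directTh = 57, directK = 551)
  s30 <- spectrumCounts(simulateNaiSpectrum(site, 30, cfg, noise = FALSE))
  s600 <- spectrumCounts(simulateNaiSpectrum(site, 600, cfg, noise = FALSE))
  expect_equal(s600, 20 * s30, tolerance = 1e-12)
  expect_error(simulateNaiSpectrum(site, 0, cfg), "positive")
  shallow <- truthConfig(gain = 2, channels = 1024L)
  expect_error(simulateNaiSpectrum(site, 30, shallow, noise = FALSE), "3.2 MeV")
})

test_that("paired counts obey the shielding-factor expectations", {
  cfg <- truthConfig(sfCarbody = c(c1 = 2.0))
  s <- generateSites(cfg, 30, seed = 2)
  p <- simulatePairedCounts(s, cfg, noise = FALSE)
  expect_equal(p$outsideCps / p$insideCps, rep(2, nrow(p)))
  # DCF worked example: D = 70 nGy/h at DCF 0.14 gives 500 cps outside
  s70 <- s[1, ]; s70$dDirect <- 70
  p70 <- simulatePairedCounts(s70, cfg, noise = FALSE)
  expect_equal(p70$outsideCps, 500)
  # a northern roadbed (SF 0.96) lowers bare counts below asphalt counts
  north <- p[p$region == "north", ]
  expect_true(all(north$bareCps < north$asphaltCps))
  south <- p[p$region == "south", ]
  expect_equal(south$bareCps / south$asphaltCps, rep(1.37, nrow(south)))
  expect_error(simulatePairedCounts(s[0, ], cfg), "empty")
})

test_that("noise-free tracks invert exactly through the dose model", {
  reg <- defaultRegionTable()[1, ]
  reg[, grep("sd$", names(reg))] <- 0
  cfg <- truthConfig(regions = reg, sfCarbody = c(c1 = 2.01),
                     sfAsphalt = c(north = 0.96))
  s <- generateSites(cfg, 10, seed = 3)
  route <- makeSurveyRoute(s, 50)
  tr <- simulateTrack(route, s, cfg, noise = FALSE)
  # constant field: constant cps
  expect_equal(length(unique(round(tr$cps, 9))), 1L)
  calib <- calibrationSet(2.01, 0.96, 0.14)
  rec <- reconstructDose(tr, calib)
  expect_equal(rec$doseNgyH, tr$dTrue, tolerance = 1e-12)
  expect_error(simulateTrack(route[1, , drop = FALSE], s, cfg), "2 points")
})

test_that("a 1000-interval track over a flat 75 nGy/h field averages to 75", {
  reg <- defaultRegionTable()[1, ]
  reg[, grep("sd$", names(reg))] <- 0
  # direct truth 75 nGy/h: scale the zero-SD composition to hit 75 exactly
  d0 <- 0.43 * reg$directU + 0.666 * reg$directTh + 0.042 * reg$directK
  reg[, c("directU", "directTh", "directK")] <-
    reg[, c("directU", "directTh", "directK")] * 75 / d0
  cfg <- truthConfig(regions = reg, sfAsphalt = c(north = 0.96))
  s <- generateSites(cfg, 10, seed = 4)
  tr <- simulateTrack(makeSurveyRoute(s, 1000), s, cfg, seed = 4)
  rec <- reconstructDose(tr, calibrationSet(2.01, 0.96, 0.14))
  se <- sd(rec$doseNgyH) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$doseNgyH) - 75), 3 * se)
})

test_that("HPGe expected areas follow the activity-efficiency product", {
  # engineered single-line library: area = A * p * eff * t * m
  lineOne <- data.frame(nuclide = "X", series = "U", energy = 661.7,
                        probability = 0.5, stringsAsFactors = FALSE)
  curve <- efficiencyCurve(c(600, 700), c(0.01, 0.01))
  a <- hpgeExpectedAreas(activityTriplet(100, 0, 0), curve, 30000, 0.1, lines = lineOne)
  expect_equal(a$area, 100 * 0.5 * 0.01 * 30000 * 0.1, tolerance = 1e-9)
  # zero activity, zero areas
  z <- hpgeExpectedAreas(activityTriplet(0, 0, 0), defaultEfficiencyCurve(), 30000, 0.1)
  expect_true(all(z$area == 0))
  # linearity in mass
  full <- hpgeExpectedAreas(activityTriplet(35, 57, 551), defaultEfficiencyCurve(), 30000, 0.2)
  half <- hpgeExpectedAreas(activityTriplet(35, 57, 551), defaultEfficiencyCurve(), 30000, 0.1)
  expect_equal(full$area, 2 * half$area)
  expect_error(hpgeExpectedAreas(activityTriplet(1, 1, 1), curve, 0, 0.1), "positive")
})

test_that("built-up perturbation hits its configured below-unity fraction", {
  cfg <- truthConfig(builtUp = list(enabled = TRUE, sdlog = 0.25,
                                    fractionBelow = 0.65, range = c(0.5, 2.1)))
  s <- generateSites(cfg, 4000, seed = 6)
  expect_true(all(s$builtUp >= 0.5 & s$builtUp <= 2.1))
  frac <- mean(s$builtUp < 1)
  expect_lt(abs(frac - 0.65), 3 * sqrt(0.65 * 0.35 / 4000))
  # multiplier touches the direct truth only
  base <- 0.43 * s$directU + 0.666 * s$directTh + 0.042 * s$directK
  expect_equal(s$dDirect, base * s$builtUp)
  expect_equal(s$dSoil, 0.43 * s$soilU + 0.666 * s$soilTh + 0.042 * s$soilK)
})
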