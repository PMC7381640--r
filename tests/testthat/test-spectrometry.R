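# NaI spectrometry: smoothing, calibration, cosmic subtraction, response
# matrix, unfolding and activity/dose evaluation.

test_that("moving-average smoothing spreads, conserves and fixes peaks", {
  expect_equal(smoothSpectrum(c(0, 9, 0), halfWidth = 1), c(3, 3, 3))
  const <- rep(4, 64)
  expect_equal(smoothSpectrum(const, halfWidth = 3)[4:61], const[4:61])
  # interior mass conserved
  x <- numeric(200); x[80:120] <- rpois(41, 50)
  expect_equal(sum(smoothSpectrum(x, halfWidth = 4)), sum(x), tolerance = 1e-3)
  expect_error(smoothSpectrum(c(1, 2, 3), halfWidth = 2), "half the channel count")
  # peak location after smoothing vs a dense quadratic-fit oracle
  set.seed(21)
  truth <- 101.3
  spec <- rpois(200, 40 * dnorm(1:200, truth, 6) * 6 * sqrt(2 * pi) + 1)
  sm <- smoothSpectrum(spec, halfWidth = 2)
  expect_lt(abs(which.max(sm) - densePeakFit(spec)), 1 + 1e-9)
})

test_that("two-point energy calibration is exact on clean synthetic peaks", {
  # Gaussian peaks centred where a gain-3.2 offset-0 instrument puts
  # 1.464 and 2.615 MeV
  n <- 1024; gain <- 3.2
  ch <- 1:n
  chK <- 1464 / gain + 0.5; chTl <- 2615 / gain + 0.5
  counts <- 4000 * dnorm(ch, chK, 8) + 1500 * dnorm(ch, chTl, 10)
  sp <- pulseHeightSpectrum(counts, 600)
  cal <- calibrateEnergy(sp, nominalGain = gain)
  expect_equal(cal$gain, gain, tolerance = 1e-4)
  expect_equal(cal$offset, 0, tolerance = 0.2)
})

test_that("energy calibration recovers generator gains, nominal and drifted", {
  cfg <- truthConfig()
  site <- list(directU = 50, directTh = 43, directK = 486)
  sp <- simulateNaiSpectrum(site, 600, cfg, noise = FALSE)
  cal <- calibrateEnergy(sp)
  expect_equal(cal$gain, cfg@gain, tolerance = 0.005)
  # gain drifted by x1.05; search from the nominal 3.2 keV/channel
  drift <- truthConfig(gain = 3.2 * 1.05)
  spd <- simulateNaiSpectrum(site, 600, drift, noise = FALSE)
  spd <- pulseHeightSpectrum(spectrumCounts(spd), 600)  # strip the stored truth
  cald <- calibrateEnergy(spd, nominalGain = 3.2)
  expect_equal(cald$gain / 3.2, 1.05, tolerance = 0.005)
})

test_that("a missing photopeak raises a calibration error naming it", {
  cfg <- truthConfig(cosmicRate = 0)
  noTh <- list(directU = 0, directTh = 0, directK = 400)
  sp <- simulateNaiSpectrum(noTh, 600, cfg, noise = FALSE)
  err <- tryCatch(calibrateEnergy(sp), error = function(e) e)
  expect_s3_class(err, "calibrationError")
  expect_match(conditionMessage(err), "Tl-208")
})

test_that("cosmic subtraction recovers a flat floor and leaves clean spectra", {
  # pure flat floor -> terrestrial spectrum ~ 0, rate recovered exactly
  flat <- pulseHeightSpectrum(rep(120, 1024), 600, c(0, 3.2))
  out <- subtractCosmic(flat)
  expect_true(all(spectrumCounts(out$spectrum) == 0))
  expect_equal(out$cosmicRate, 0.2)
  # zero counts above 3 MeV -> unchanged, rate 0
  low <- numeric(1024); low[100:200] <- 50
  sp <- pulseHeightSpectrum(low, 600, c(0, 3.2))
  out2 <- subtractCosmic(sp)
  expect_equal(spectrumCounts(out2$spectrum), low)
  expect_equal(out2$cosmicRate, 0)
  # generator floor recovered within Poisson counting error
  cfg <- truthConfig(cosmicRate = 0.2)
  site <- list(directU = 35, directTh = 57, directK = 551)
  spn <- simulateNaiSpectrum(site, 600, cfg, seed = 31)
  out3 <- subtractCosmic(spn)
  nWin <- sum(channelEnergies(spn) >= 3000 & channelEnergies(spn) <= 3200)
  se <- sqrt(0.2 / (600 * nWin))
  expect_lt(abs(out3$cosmicRate - 0.2), 4 * se)
  expect_error(subtractCosmic(pulseHeightSpectrum(rep(1, 512), 60, c(0, 2))),
               "cosmic window")
})

test_that("response matrix degenerates to identity and only downscatters", {
  b <- defaultEnergyBinning()
  sharp <- buildResponseMatrix(b, resolution = 0.01, continuumFraction = 0)
  R <- responseMatrix(sharp)
  expect_equal(unname(diag(R)), rep(1, nBins(b)), tolerance = 1e-6)
  expect_lt(max(R - diag(diag(R))), 1e-6)
  # with a continuum, scattered counts land only below the incident bin:
  # rows are detected bins, so downscatter fills the upper triangle
  # (row < column) and nothing appears above the incident energy
  soft <- buildResponseMatrix(b, resolution = 0.01, continuumFraction = 0.3)
  Rs <- responseMatrix(soft)
  expect_true(all(Rs[lower.tri(Rs)] < 1e-6))
  expect_gt(sum(Rs[upper.tri(Rs)]), 0.1)
})

test_that("response columns integrate to the model efficiency (quadrature oracle)", {
  b <- defaultEnergyBinning()
  resp <- buildResponseMatrix(b, resolution = 7.5, continuumFraction = 0.55)
  R <- responseMatrix(resp)
  edges <- binEdges(b)
  flags <- binFlags(b)
  lines <- naiLineLibrary()
  for (nm in names(flags)) {
    j <- flags[[nm]]
    E <- lines$energy[findInterval(lines$energy, edges) == j]
    sig <- (7.5 / 100) * sqrt(0.662 * E) / (2 * sqrt(2 * log(2)))
    # fine numerical integration of the forward model over 0-3.2 MeV
    eGrid <- seq(1e-5, 3.2, length.out = 200000)
    de <- eGrid[2] - eGrid[1]
    ce <- 2 * E^2 / (0.511 + 2 * E)
    dens <- 0.45 * dnorm(eGrid, E, sig) + 0.55 * (eGrid < ce) / ce
    expect_equal(sum(R[, j]), sum(dens) * de, tolerance = 1e-3)
  }
})

test_that("unfolding matches identity, zero and noise-free forward spectra", {
  b <- defaultEnergyBinning()
  resp <- buildResponseMatrix(b)
  # zero spectrum -> zero flux
  z <- unfoldSpectrum(numeric(22), resp)
  expect_equal(z$flux, numeric(22))
  expect_equal(z$residual, 0)
  # identity response returns the counts
  ident <- new("ResponseMatrix", matrix = diag(22), binning = b,
               doseCoef = doseCoefficientsPerBin(resp),
               activityCoef = activityCoefficients(resp))
  cts <- runif(22, 0, 5)
  expect_equal(unfoldSpectrum(cts, ident)$flux, cts, tolerance = 1e-9)
  # pure 500 Bq/kg K-40 forward spectrum unfolds to the generator line flux
  cfg <- truthConfig(cosmicRate = 0)
  sp <- simulateNaiSpectrum(list(directU = 0, directTh = 0, directK = 500), 600,
                            cfg, noise = FALSE)
  respG <- buildResponseMatrix(b, resolution = cfg@resolution,
                               continuumFraction = cfg@continuumFraction)
  binned <- rebinSpectrum(sp, responseBinning(respG))
  uf <- unfoldSpectrum(binned, respG)
  expect_equal(uf$flux[binFlags(b)[["k"]]], 500 * 0.040, tolerance = 0.01)
})

test_that("unfolding agrees with brute-force active-set enumeration", {
  set.seed(17)
  for (rep in 1:5) {
    A <- matrix(runif(36), 6, 6) + diag(6)
    x0 <- pmax(rnorm(6), 0)
    b <- drop(A %*% x0) + rnorm(6, sd = 0.3)
    binning <- new("EnergyBinning",
                   edges = c(0, 1.0, 1.6, 1.69, 1.84, 2.31, 3.2),
                   flags = c(k = 2L, bi1 = 4L, bi2 = 5L, tl = 6L))
    resp <- new("ResponseMatrix", matrix = A, binning = binning,
                doseCoef = numeric(6),
                activityCoef = data.frame(series = c("K", "U", "U", "Th"),
                                          bin = c(2L, 4L, 5L, 6L),
                                          coefficient = rep(1, 4)))
    mine <- unfoldSpectrum(pmax(b, 0), resp)
    oracle <- bruteForceNnls(A, pmax(b, 0))
    expect_equal(sum((A %*% mine$flux - pmax(b, 0))^2), oracle$rss, tolerance = 1e-6)
    expect_equal(mine$flux, oracle$x, tolerance = 1e-5)
  }
})

test_that("an ill-conditioned response triggers a conditioning warning", {
  b <- defaultEnergyBinning()
  resp <- buildResponseMatrix(b)
  Rbad <- responseMatrix(resp)
  Rbad[, 2] <- Rbad[, 1] * (1 + 1e-13)
  bad <- new("ResponseMatrix", matrix = Rbad, binning = b,
             doseCoef = doseCoefficientsPerBin(resp),
             activityCoef = activityCoefficients(resp))
  expect_warning(unfoldSpectrum(rep(1, 22), bad), class = "conditioningWarning")
})

test_that("activities and dose from flux: zeros, linearity and recovery", {
  resp <- buildResponseMatrix()
  z <- activitiesFromFlux(numeric(22), resp)
  expect_equal(unname(activities(z)), c(0, 0, 0))
  expect_identical(doseFromFlux(numeric(22), resp), 0)
  flux <- numeric(22)
  flags <- binFlags(responseBinning(resp))
  flux[flags] <- c(19.4, 1.9, 0.63, 2.85)
  a1 <- activities(activitiesFromFlux(flux, resp))
  a2 <- activities(activitiesFromFlux(2 * flux, resp))
  expect_equal(a2, 2 * a1)
  expect_equal(doseFromFlux(2 * flux, resp), 2 * doseFromFlux(flux, resp))
  expect_equal(doseFromFlux(flux, resp, bins = "peak"), doseFromFlux(flux, resp))
  # noise-free simulated site at the reference direct composition
  cfg <- truthConfig()
  site <- list(directU = 50, directTh = 43, directK = 486)
  sp <- simulateNaiSpectrum(site, 600, cfg, noise = FALSE)
  respG <- buildResponseMatrix(resolution = cfg@resolution,
                               continuumFraction = cfg@continuumFraction)
  pr <- processNaiSpectrum(sp, respG)
  a <- activities(pr$activities)
  expect_equal(unname(a), c(50, 43, 486), tolerance = 0.02)
  # dose consistent with the soil model on the same triplet
  expect_equal(pr$dose, doseFromSoil(activityTriplet(50, 43, 486)), tolerance = 0.03)
})

test_that("the full chain round-trips within 1% across three decades", {
  cfg <- truthConfig()
  respG <- buildResponseMatrix(resolution = cfg@resolution,
                               continuumFraction = cfg@continuumFraction)
  for (scale in c(0.1, 1, 10)) {
    site <- list(directU = 35 * scale, directTh = 57 * scale, directK = 551 * scale)
    sp <- simulateNaiSpectrum(site, 600, cfg, noise = FALSE)
    pr <- processNaiSpectrum(sp, respG)
    a <- activities(pr$activities)
    expect_equal(unname(a) / unlist(site, use.names = FALSE), c(1, 1, 1),
                 tolerance = 0.01)
    expect_lt(pr$residual / sum(rebinSpectrum(sp, responseBinning(respG))), 1e-4)
  }
})

test_that("default binning places the evaluation windows exactly", {
  b <- defaultEnergyBinning()
  expect_equal(nBins(b), 22L)
  e <- binEdges(b)
  f <- binFlags(b)
  expect_equal(e[f[["k"]] + 0:1], c(1.39, 1.54))
  expect_equal(e[f[["bi1"]] + 0:1], c(1.69, 1.84))
  expect_equal(e[f[["bi2"]] + 0:1], c(2.10, 2.31))
  expect_equal(e[f[["tl"]] + 0:1], c(2.51, 2.72))
  expect_equal(range(e), c(0, 3.2))
  expect_true(3.0 %in% e)  # the cosmic window is resolved
})
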