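# NaI(Tl) spectrometry: smoothing, two-point energy calibration, cosmic-ray
# subtraction, response-matrix construction and non-negative least-squares
# unfolding into activity concentrations and absorbed dose rate in air.

#' Smooth a pulse-height spectrum
#'
#' Zero-padded moving-average (boxcar) filter of half-width `halfWidth`
#' channels. Interior counts are conserved exactly; only counts within
#' `halfWidth` channels of the spectrum ends lose a little mass to the
#' (virtual) zero padding.
#'
#' @param spectrum a [PulseHeightSpectrum-class] or bare numeric vector.
#' @param halfWidth half-width in channels (>= 1; window is `2*halfWidth+1`).
#' @return Same type as the input, with smoothed counts.
#' @export
smoothSpectrum <- function(spectrum, halfWidth = 2L) {
  counts <- if (is(spectrum, "PulseHeightSpectrum")) spectrumCounts(spectrum) else spectrum
  n <- length(counts)
  halfWidth <- as.integer(halfWidth)
  if (halfWidth < 1L) stop("halfWidth must be >= 1")
  if (halfWidth > n %/% 2L) stop("halfWidth exceeds half the channel count")
  padded <- c(numeric(halfWidth), counts, numeric(halfWidth))
  cs <- c(0, cumsum(padded))
  w <- 2L * halfWidth + 1L
  sm <- (cs[(1:n) + w] - cs[1:n]) / w
  if (is(spectrum, "PulseHeightSpectrum"))
    pulseHeightSpectrum(sm, liveTime(spectrum), energyCalibration(spectrum))
  else sm
}

# Peak centroid (fractional channel) by quadratic fit through the smoothed
# maximum and its neighbours; window = channels around the maximum.
peakCentroid <- function(counts, window = 2L) {
  m <- which.max(counts)
  lo <- max(1L, m - window); hi <- min(length(counts), m + window)
  x <- lo:hi; y <- counts[x]
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  b <- fit$coefficients
  if (!is.finite(b[3]) || b[3] >= 0) return(m)  # flat/degenerate: keep the max
  ctr <- unname(-b[2] / (2 * b[3]))
  # a near-flat noisy fit can throw the vertex far outside the data: fall
  # back to the raw maximum rather than extrapolate
  if (ctr < lo - 1 || ctr > hi + 1) return(m)
  ctr
}

#' Two-point energy calibration from the K-40 and Tl-208 photopeaks
#'
#' Locates the 1.464 MeV (K-40) and 2.615 MeV (Tl-208) photopeaks by
#' smoothing and quadratic centroid fitting within search windows of +-8%
#' around the nominal energies, then solves the linear calibration through
#' the two centroids.
#'
#' @param spectrum a [PulseHeightSpectrum-class].
#' @param nominalGain initial keV/channel guess used to place the search
#'   windows; defaults to the spectrum's stored calibration gain, else to
#'   3.2 MeV full scale.
#' @param nominalOffset initial offset guess (keV).
#' @param window fractional half-width of the search windows (default 0.08).
#' @param halfWidth smoothing half-width (channels).
#' @return list with `offset` (keV), `gain` (keV/channel) and the two peak
#'   centroids `channels` (K-40, Tl-208).
#' @section Errors: a peak whose smoothed maximum sits at the edge of its
#'   search window (or an empty window) raises a condition of class
#'   `calibrationError` naming the missing peak.
#' @export
calibrateEnergy <- function(spectrum, nominalGain = NULL, nominalOffset = 0,
                            window = 0.08, halfWidth = 2L) {
  stopifnot(is(spectrum, "PulseHeightSpectrum"))
  counts <- spectrumCounts(spectrum)
  n <- length(counts)
  if (is.null(nominalGain))
    nominalGain <- if (isCalibrated(spectrum)) energyCalibration(spectrum)[2] else 3200 / n
  sm <- smoothSpectrum(counts, halfWidth)
  findPeak <- function(energyKeV, label) {
    centre <- (energyKeV - nominalOffset) / nominalGain
    lo <- max(1L, floor(centre * (1 - window)))
    hi <- min(n, ceiling(centre * (1 + window)))
    if (hi - lo < 4L)
      stop(errorCondition(sprintf("calibration failed: no %s search window in spectrum", label),
                          class = c("calibrationError", "error", "condition")))
    seg <- sm[lo:hi]
    m <- which.max(seg)
    if (m <= 1L || m >= length(seg) || max(seg) <= 0)
      stop(errorCondition(sprintf("calibration failed: %s peak not found in its window", label),
                          class = c("calibrationError", "error", "condition")))
    lo - 1 + peakCentroid(seg)
  }
  chK <- findPeak(1464, "K-40 (1.464 MeV)")
  chTl <- findPeak(2615, "Tl-208 (2.615 MeV)")
  gain <- (2615 - 1464) / (chTl - chK)
  # channel centre i sits at offset + gain*(i - 0.5)
  offset <- 1464 - gain * (chK - 0.5)
  list(offset = offset, gain = gain, channels = c(k = chK, tl = chTl))
}

#' Subtract the cosmic-ray component
#'
#' Estimates the cosmic count rate as the mean per-channel rate in the
#' 3.0-3.2 MeV window (terrestrial gamma rays do not reach it) and
#' subtracts that flat floor from every channel, clamping at zero.
#'
#' @param spectrum a calibrated [PulseHeightSpectrum-class] whose range
#'   includes channels above 3.0 MeV.
#' @return list with `spectrum` (terrestrial component) and `cosmicRate`
#'   (cps per channel).
#' @export
subtractCosmic <- function(spectrum) {
  stopifnot(is(spectrum, "PulseHeightSpectrum"))
  if (!isCalibrated(spectrum)) stop("spectrum must be energy-calibrated")
  e <- channelEnergies(spectrum)
  win <- which(e >= 3000 & e <= 3200)
  if (length(win) == 0L) stop("no channels in the 3.0-3.2 MeV cosmic window")
  counts <- spectrumCounts(spectrum)
  floorCounts <- mean(counts[win])
  out <- pmax(counts - floorCounts, 0)
  list(spectrum = pulseHeightSpectrum(out, liveTime(spectrum), energyCalibration(spectrum)),
       cosmicRate = floorCounts / liveTime(spectrum))
}

#' Default 22-bin unfolding binning
#'
#' Unequal-interval incident-energy bins over 0-3.2 MeV. The four
#' evaluation windows sit exactly at 1.39-1.54 (K-40), 1.69-1.84 and
#' 2.10-2.31 (Bi-214) and 2.51-2.72 MeV (Tl-208); the remaining ranges are
#' split log-uniformly (0.05-1.39 MeV in 11 bins below a 0-0.05 MeV
#' threshold bin) with single bins in the short gaps and a 3.0 MeV edge so
#' the cosmic window is resolved.
#'
#' @return An [EnergyBinning-class] with 22 bins.
#' @export
defaultEnergyBinning <- function() {
  low <- 0.05 * (1.39 / 0.05)^((0:11) / 11)
  edges <- c(0, low, 1.54, 1.69, 1.84, 1.97, 2.10, 2.31, 2.51, 2.72, 3.0, 3.2)
  new("EnergyBinning", edges = edges,
      flags = c(k = 13L, bi1 = 15L, bi2 = 18L, tl = 20L))
}

#' Rebin a channel spectrum onto an unfolding binning
#'
#' Distributes each channel's count rate over the energy bins by fractional
#' overlap of the channel's energy span with each bin (counts assumed
#' uniform within a channel).
#'
#' @param spectrum a calibrated [PulseHeightSpectrum-class].
#' @param binning an [EnergyBinning-class].
#' @return numeric vector of count rates (cps) per bin.
#' @export
rebinSpectrum <- function(spectrum, binning) {
  stopifnot(is(spectrum, "PulseHeightSpectrum"), is(binning, "EnergyBinning"))
  if (!isCalibrated(spectrum)) stop("spectrum must be energy-calibrated")
  cal <- energyCalibration(spectrum)
  counts <- spectrumCounts(spectrum) / liveTime(spectrum)
  n <- length(counts)
  chLo <- (cal[1] + cal[2] * (0:(n - 1))) / 1000  # MeV
  chHi <- chLo + cal[2] / 1000
  edges <- binEdges(binning)
  K <- length(edges) - 1L
  out <- numeric(K)
  for (j in seq_len(K)) {
    ov <- pmax(pmin(chHi, edges[j + 1]) - pmax(chLo, edges[j]), 0)
    out[j] <- sum(counts * ov / (chHi - chLo))
  }
  out
}

#' Build the detector response matrix
#'
#' Column `j` is the forward model's expected pulse-height histogram
#' (on the same binning) for unit source strength in incident bin `j`:
#' a Gaussian photopeak carrying `1 - continuumFraction` of the counts plus
#' a flat continuum below the bin energy's Compton edge carrying the rest.
#' Flagged bins are evaluated at their nuclide line energy, other bins at
#' their geometric midpoint. The per-bin flux-to-dose and flux-to-activity
#' coefficients bundled with the matrix are derived from the same line
#' library, so unfolded dose rates are exactly consistent with the soil
#' dose-rate model applied to recovered activities.
#'
#' @param binning an [EnergyBinning-class].
#' @param resolution FWHM percent at 0.662 MeV.
#' @param continuumFraction per-line continuum fraction in `[0, 1)`.
#' @param lines NaI line library (see [naiLineLibrary()]).
#' @param doseCoef dose coefficients used to anchor the per-bin dose
#'   conversion (default [doseCoefficients()]).
#' @return A [ResponseMatrix-class].
#' @export
buildResponseMatrix <- function(binning = defaultEnergyBinning(), resolution = 7.5,
                                continuumFraction = 0.55, lines = naiLineLibrary(),
                                doseCoef = doseCoefficients()) {
  stopifnot(is(binning, "EnergyBinning"))
  if (continuumFraction < 0 || continuumFraction >= 1)
    stop("continuumFraction must lie in [0, 1)")
  edges <- binEdges(binning)
  K <- length(edges) - 1L
  if (max(edges) < max(lines$energy))
    stop("binning does not cover the detector range of the line library")
  flags <- binFlags(binning)
  # representative incident energy per column
  rep_e <- exp((log(pmax(edges[-(K + 1)], 1e-3)) + log(edges[-1])) / 2)
  rep_e[1] <- (edges[1] + edges[2]) / 2
  lineBin <- findInterval(lines$energy, edges, rightmost.closed = TRUE)
  rep_e[lineBin] <- lines$energy
  R <- matrix(0, K, K)
  f <- continuumFraction
  for (j in seq_len(K)) {
    E <- rep_e[j]
    sig <- peakSigma(E, resolution)
    peakMass <- diff(pnorm(edges, E, sig))
    ce <- comptonEdge(E)
    contMass <- pmax(pmin(edges[-1], ce) - pmin(edges[-(K + 1)], ce), 0) / ce
    R[, j] <- (1 - f) * peakMass + f * contMass
  }
  # activity coefficients: detected cps per Bq/kg at each evaluation bin
  seriesKey <- c(k = "K", bi1 = "U", bi2 = "U", tl = "Th")
  ac <- data.frame(series = unname(seriesKey[names(flags)]),
                   bin = unname(flags),
                   coefficient = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ac)))
    ac$coefficient[i] <- lines$yield[lineBin == ac$bin[i]][1]
  # per-bin dose coefficients: line l of series s carries fraction
  # yield_l / sum(yield_s) of the series' dose e_s per unit activity, so a
  # unit of unfolded source strength in that bin is worth e_s / sum(yield_s).
  dc <- numeric(K)
  e_s <- c(U = unname(doseCoef$soil["u"]), Th = unname(doseCoef$soil["th"]),
           K = unname(doseCoef$soil["k"]))
  ytot <- tapply(lines$yield, lines$series, sum)
  for (i in seq_len(nrow(lines)))
    dc[lineBin[i]] <- e_s[[lines$series[i]]] / ytot[[lines$series[i]]]
  new("ResponseMatrix", matrix = R, binning = binning, doseCoef = dc,
      activityCoef = ac)
}

#' Unfold a binned pulse-height spectrum
#'
#' Solves the non-negative least-squares problem
#' `min ||R phi - c||^2, phi >= 0` for the incident source strength per
#' energy bin, and reports the residual norm. An ill-conditioned response
#' (condition number above `conditionLimit`) raises a warning of class
#' `conditioningWarning`.
#'
#' @param counts binned count rates (cps), length equal to the response's
#'   bin count.
#' @param response a [ResponseMatrix-class].
#' @param conditionLimit condition-number threshold (default 1e8).
#' @return list with `flux` (non-negative, per bin) and `residual`
#'   (Euclidean norm of the fit residual).
#' @export
unfoldSpectrum <- function(counts, response, conditionLimit = 1e8) {
  stopifnot(is(response, "ResponseMatrix"))
  R <- responseMatrix(response)
  if (length(counts) != nrow(R))
    stop("binned counts length does not match the response matrix")
  if (any(counts < 0)) counts <- pmax(counts, 0)
  kap <- kappa(R, exact = FALSE)
  if (!is.finite(kap) || kap > conditionLimit)
    warning(warningCondition(sprintf("response matrix is ill-conditioned (kappa ~ %.3g)", kap),
                             class = c("conditioningWarning", "warning", "condition")))
  if (all(counts == 0)) return(list(flux = numeric(nrow(R)), residual = 0))
  fit <- pracma::lsqnonneg(R, as.numeric(counts))
  list(flux = fit$x, residual = sqrt(max(fit$resid.norm, 0)))
}

#' Activity concentrations from unfolded flux
#'
#' K-40 from the 1.464 MeV bin and Th-232 series from the 2.615 MeV bin by
#' direct division with their flux-per-unit-activity coefficients; the
#' U-238 series from the 1.765 and 2.205 MeV bins combined by
#' inverse-variance weighting (variances from Poisson counting statistics
#' in each evaluation window when `liveTime` is given, equal weights
#' otherwise).
#'
#' @param flux non-negative unfolded source strengths per bin.
#' @param response the [ResponseMatrix-class] used for the unfolding.
#' @param liveTime optional live time (s) for Poisson variance weighting.
#' @return An [ActivityTriplet-class] with propagated uncertainties.
#' @export
activitiesFromFlux <- function(flux, response, liveTime = NULL) {
  stopifnot(is(response, "ResponseMatrix"))
  if (any(flux < -1e-9)) stop("flux must be non-negative")
  ac <- activityCoefficients(response)
  if (any(ac$coefficient == 0, na.rm = TRUE) || any(is.na(ac$coefficient)))
    stop("zero flux-to-activity coefficient")
  est <- flux[ac$bin] / ac$coefficient
  # Poisson variance of the bin rate: var(cps) = cps / t; propagate through
  # the division. Without a live time all evaluation bins weigh equally.
  if (!is.null(liveTime)) {
    v <- pmax(flux[ac$bin], max(flux[ac$bin]) * 1e-6) / liveTime / ac$coefficient^2
  } else v <- rep(1, nrow(ac))
  pick <- function(series) {
    i <- which(ac$series == series)
    if (length(i) == 1L) return(c(est[i], if (!is.null(liveTime)) sqrt(v[i]) else 0))
    w <- 1 / v[i]
    c(sum(w * est[i]) / sum(w), if (!is.null(liveTime)) 1 / sqrt(sum(w)) else 0)
  }
  u <- pick("U"); th <- pick("Th"); k <- pick("K")
  activityTriplet(u[1], th[1], k[1], sd = c(u[2], th[2], k[2]))
}

#' Absorbed dose rate in air from unfolded flux
#'
#' Dot product of the unfolded source strengths with the per-bin
#' flux-to-dose coefficients. `bins = "peak"` restricts the sum to the four
#' evaluation windows; `bins = "all"` uses every bin (identical under the
#' default coefficients, which are zero away from the evaluation lines).
#'
#' @inheritParams activitiesFromFlux
#' @param bins `"all"` or `"peak"`.
#' @return absorbed dose rate in air (nGy h^-1).
#' @export
doseFromFlux <- function(flux, response, bins = c("all", "peak")) {
  bins <- match.arg(bins)
  stopifnot(is(response, "ResponseMatrix"))
  dc <- doseCoefficientsPerBin(response)
  if (length(flux) != length(dc)) stop("flux length does not match coefficient vector")
  if (any(flux < -1e-9)) stop("flux must be non-negative")
  if (bins == "peak") {
    keep <- binFlags(responseBinning(response))
    sum(flux[keep] * dc[keep])
  } else sum(flux * dc)
}

#' Full spectrum-to-activities workflow for one NaI spectrum
#'
#' Calibrate energy from the K-40/Tl-208 peaks, subtract the cosmic floor,
#' rebin, unfold and evaluate activities and dose rate.
#'
#' @param spectrum a [PulseHeightSpectrum-class].
#' @param response a [ResponseMatrix-class].
#' @param recalibrate re-derive the energy calibration from the spectrum
#'   (default TRUE; FALSE trusts the stored calibration).
#' @return list with `activities` ([ActivityTriplet-class]), `dose`
#'   (nGy h^-1), `cosmicRate` (cps/channel), `calibration`, `flux`,
#'   `residual`.
#' @export
processNaiSpectrum <- function(spectrum, response, recalibrate = TRUE) {
  if (recalibrate) {
    cal <- calibrateEnergy(spectrum)
    spectrum <- pulseHeightSpectrum(spectrumCounts(spectrum), liveTime(spectrum),
                                    c(cal$offset, cal$gain))
  }
  cosmic <- subtractCosmic(spectrum)
  binned <- rebinSpectrum(cosmic$spectrum, responseBinning(response))
  uf <- unfoldSpectrum(binned, response)
  list(activities = activitiesFromFlux(uf$flux, response, liveTime = liveTime(spectrum)),
       dose = doseFromFlux(uf$flux, response),
       cosmicRate = cosmic$cosmicRate,
       calibration = energyCalibration(spectrum),
       flux = uf$flux, residual = uf$residual)
}
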