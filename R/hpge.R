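# HPGe soil assay by the absolute-efficiency method: net peak areas over a
# linear baseline, log-log efficiency interpolation, activity conversion and
# the U-238 series weighted average.

#' Net peak area over a linear baseline
#'
#' Gross counts in the region of interest minus a linear baseline
#' interpolated between the mean levels of `flank` channels on each side,
#' with Poisson uncertainty propagation (gross counts plus the propagated
#' baseline estimate). Negative net areas are clamped to zero and flagged.
#'
#' @param spectrum a [PulseHeightSpectrum-class].
#' @param roi integer channel range `c(first, last)` of the peak window.
#' @param flank number of baseline channels on each flank (default 3).
#' @return list with `net` (counts, >= 0), `sd`, `clamped` (logical).
#' @export
netPeakArea <- function(spectrum, roi, flank = 3L) {
  stopifnot(is(spectrum, "PulseHeightSpectrum"))
  counts <- spectrumCounts(spectrum)
  n <- length(counts)
  roi <- as.integer(round(roi))
  if (length(roi) != 2L || roi[1] > roi[2]) stop("roi must be c(first, last)")
  if (roi[1] - flank < 1L || roi[2] + flank > n)
    stop("ROI (with its baseline flanks) extends beyond the spectrum edge")
  if (sum(counts) == 0) return(list(net = 0, sd = 0, clamped = FALSE))
  loIdx <- (roi[1] - flank):(roi[1] - 1L)
  hiIdx <- (roi[2] + 1L):(roi[2] + flank)
  w <- roi[2] - roi[1] + 1L
  bLo <- mean(counts[loIdx]); bHi <- mean(counts[hiIdx])
  gross <- sum(counts[roi[1]:roi[2]])
  base <- w * (bLo + bHi) / 2
  net <- gross - base
  # var(base) from Poisson flank counts: (w/2)^2 * (var(bLo) + var(bHi))
  vBase <- (w / 2)^2 * (sum(counts[loIdx]) / flank^2 + sum(counts[hiIdx]) / flank^2)
  sd <- sqrt(gross + vBase)
  clamped <- net < 0
  list(net = max(net, 0), sd = sd, clamped = clamped)
}

#' Interpolate a full-energy-peak efficiency
#'
#' Log-log linear interpolation between the bracketing calibration points.
#' Queries outside the calibrated span raise an `extrapolationError` beyond
#' a small tolerance (5% in energy).
#'
#' @param curve an [EfficiencyCurve-class].
#' @param energy query energy (keV).
#' @return efficiency (dimensionless).
#' @examples
#' efficiencyAt(efficiencyCurve(c(100, 400), c(0.04, 0.01)), 200)  # 0.02
#' @export
efficiencyAt <- function(curve, energy) {
  stopifnot(is(curve, "EfficiencyCurve"))
  e <- curve@energy; eff <- curve@efficiency
  if (energy < e[1] * 0.95 || energy > e[length(e)] * 1.05)
    stop(errorCondition(sprintf("efficiency curve undefined at %.1f keV (span %.1f-%.1f)",
                                energy, e[1], e[length(e)]),
                        class = c("extrapolationError", "error", "condition")))
  exp(approx(log(e), log(eff), xout = log(energy), rule = 2)$y)
}

#' Activity concentration from one peak measurement
#'
#' The absolute method:
#' `A = net / (efficiency x emission probability x liveTime x mass)`
#' (Bq kg^-1), with the relative uncertainties of the net area and of the
#' efficiency combined in quadrature.
#'
#' @param net net peak area (counts) with standard uncertainty `netSd`.
#' @param efficiency full-energy-peak efficiency at the line energy.
#' @param probability gamma emission probability per decay.
#' @param liveTime live time (s).
#' @param mass sample mass (kg).
#' @param effRelSd relative standard uncertainty of the efficiency.
#' @return list with `activity` (Bq kg^-1) and `sd`.
#' @examples
#' activityFromPeak(10000, 0, 0.01, 0.5, 30000, 0.1)  # 666.7 Bq/kg
#' @export
activityFromPeak <- function(net, netSd, efficiency, probability, liveTime, mass,
                             effRelSd = 0) {
  if (efficiency <= 0 || probability <= 0 || liveTime <= 0 || mass <= 0)
    stop("efficiency, emission probability, live time and mass must all be > 0")
  if (net < 0) stop("net area must be non-negative")
  a <- net / (efficiency * probability * liveTime * mass)
  relNet <- if (net > 0) netSd / net else 0
  list(activity = a, sd = a * combinedRelativeUncertainty(c(relNet, effRelSd)))
}

#' Inverse-variance weighted average for the U-238 series
#'
#' Combines the Pb-214 and Bi-214 activity estimates with weights
#' `1/u^2`; the combined uncertainty is `(sum w)^(-1/2)`.
#'
#' @param aPb,aBi numeric `c(value, sd)` for the two progeny estimates;
#'   both uncertainties must be strictly positive.
#' @return numeric `c(value, sd)`.
#' @examples
#' u238WeightedAverage(c(30, 3), c(60, 6))  # value 36
#' @export
u238WeightedAverage <- function(aPb, aBi) {
  if (aPb[2] <= 0 || aBi[2] <= 0)
    stop(errorCondition("zero uncertainty gives a degenerate weight",
                        class = c("degenerateWeightError", "error", "condition")))
  w <- c(1 / aPb[2]^2, 1 / aBi[2]^2)
  v <- c(aPb[1], aBi[1])
  c(sum(w * v) / sum(w), 1 / sqrt(sum(w)))
}

#' Assay a soil HPGe spectrum
#'
#' Runs the absolute method on a calibrated spectrum: for each library line
#' the ROI is the peak centroid +- `roiSigma` peak widths, the net area is
#' taken over a linear baseline, converted to activity, and the U-238
#' series is the inverse-variance weighted average of the Pb-214 and Bi-214
#' results (equal weights with `weighting = "equal"`).
#'
#' @param spectrum a calibrated [PulseHeightSpectrum-class].
#' @param curve an [EfficiencyCurve-class].
#' @param mass sample mass (kg).
#' @param lines line library (default [hpgeLineLibrary()]).
#' @param fwhm resolution function of energy in keV (must match the
#'   acquisition; default as in [simulateHpgeSpectrum()]).
#' @param roiSigma ROI half-width in peak sigmas (default 3).
#' @param weighting `"inverse-variance"` or `"equal"` for the U-238 average.
#' @return An [ActivityTriplet-class] with uncertainties.
#' @export
assaySoilSpectrum <- function(spectrum, curve, mass, lines = hpgeLineLibrary(),
                              fwhm = function(e) 1.2 + 5e-4 * e, roiSigma = 3,
                              weighting = c("inverse-variance", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(is(spectrum, "PulseHeightSpectrum"))
  if (!isCalibrated(spectrum)) stop("HPGe spectrum must be energy-calibrated")
  cal <- energyCalibration(spectrum)
  t <- liveTime(spectrum)
  res <- vector("list", nrow(lines))
  for (i in seq_len(nrow(lines))) {
    E <- lines$energy[i]
    sig <- fwhm(E) / (2 * sqrt(2 * log(2)))
    centre <- (E - cal[1]) / cal[2] + 0.5
    half <- roiSigma * sig / cal[2]
    np <- netPeakArea(spectrum, c(floor(centre - half), ceiling(centre + half)))
    res[[i]] <- activityFromPeak(np$net, np$sd, efficiencyAt(curve, E),
                                 lines$probability[i], t, mass,
                                 effRelSd = curve@relSd)
  }
  val <- vapply(res, `[[`, numeric(1), "activity")
  sdv <- vapply(res, `[[`, numeric(1), "sd")
  pickU <- which(lines$series == "U")
  if (length(pickU) == 2L) {
    if (weighting == "equal") {
      aU <- c(mean(val[pickU]), sqrt(sum(sdv[pickU]^2)) / 2)
    } else aU <- u238WeightedAverage(c(val[pickU[1]], sdv[pickU[1]]),
                                     c(val[pickU[2]], sdv[pickU[2]]))
  } else aU <- c(val[pickU[1]], sdv[pickU[1]])
  iTh <- which(lines$series == "Th")[1]
  iK <- which(lines$series == "K")[1]
  activityTriplet(aU[1], val[iTh], val[iK], sd = c(aU[2], sdv[iTh], sdv[iK]))
}
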