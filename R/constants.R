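# Nuclide line libraries and physical constants shared by the forward
# spectral model, the response matrix and the HPGe assay.

#' NaI(Tl) evaluation line library
#'
#' The gamma lines used by the simplified NaI(Tl) forward model and by the
#' unfolding coefficients: K-40 at 1.464 MeV, the two Bi-214 evaluation
#' lines of the U-238 series at 1.765 and 2.205 MeV, and Tl-208 of the
#' Th-232 series at 2.615 MeV. `yield` is the total detected count rate per
#' unit activity concentration (cps per Bq kg^-1) for the line, photopeak
#' plus its Compton continuum; the values are nominal model constants for a
#' 3-in x 3-in detector 1 m above an infinite half-space and are
#' configurable.
#'
#' @return data.frame with columns `series` ("U", "Th", "K"), `energy`
#'   (MeV) and `yield` (cps per Bq kg^-1).
#' @export
naiLineLibrary <- function() {
  data.frame(
    series = c("K", "U", "U", "Th"),
    energy = c(1.464, 1.765, 2.205, 2.615),
    yield  = c(0.040, 0.055, 0.018, 0.050),
    stringsAsFactors = FALSE
  )
}

#' HPGe soil-assay line library
#'
#' Peaks used in the absolute-efficiency soil assay: Pb-214 (352 keV) and
#' Bi-214 (609 keV) for the U-238 series, Ac-228 (911 keV) for the Th-232
#' series and K-40 (1461 keV). `probability` is the gamma emission
#' probability per decay.
#'
#' @return data.frame with columns `nuclide`, `series`, `energy` (keV) and
#'   `probability`.
#' @export
hpgeLineLibrary <- function() {
  data.frame(
    nuclide = c("Pb-214", "Bi-214", "Ac-228", "K-40"),
    series  = c("U", "U", "Th", "K"),
    energy  = c(351.9, 609.3, 911.2, 1460.8),
    probability = c(0.356, 0.455, 0.258, 0.107),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic HPGe efficiency curve
#'
#' A synthetic full-energy-peak efficiency curve for a p-type HPGe detector
#' (17.5% relative efficiency class) with a soil sample in a U-8 container on
#' the endcap. Calibration energies follow the nine-nuclide certified source
#' (Cd-109, Co-57, Ce-139, Cr-51, Sr-85, Cs-137, Mn-54, Y-88, Co-60); the
#' efficiencies are plausible nominal values, not a measured curve.
#'
#' @param relSd relative standard uncertainty of the curve.
#' @return An [EfficiencyCurve-class].
#' @export
defaultEfficiencyCurve <- function(relSd = 0.01) {
  efficiencyCurve(
    energy     = c(88, 122.1, 165.9, 320.1, 514, 661.7, 834.8, 898, 1173.2, 1332.5, 1836.1),
    efficiency = c(0.130, 0.150, 0.140, 0.085, 0.058, 0.045, 0.037, 0.035, 0.028, 0.025, 0.019),
    relSd = relSd
  )
}

# Compton edge (MeV) for incident energy E (MeV); m_e c^2 = 0.511 MeV.
comptonEdge <- function(energy) 2 * energy^2 / (0.511 + 2 * energy)

# Gaussian sigma (MeV) at energy E (MeV) for a resolution coefficient given
# as FWHM percent at 0.662 MeV; FWHM scales as sqrt(E).
peakSigma <- function(energy, resolution) {
  (resolution / 100) * sqrt(0.662 * energy) / (2 * sqrt(2 * log(2)))
}
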