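#' @useDynLib radsurvey, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats approx dnorm pnorm qnorm rnorm rpois runif sd uniroot
#'   rlnorm setNames
#' @importFrom utils read.csv write.csv head tail packageVersion
NULL

# ---------------------------------------------------------------------------
# ActivityTriplet -----------------------------------------------------------

#' Activity concentrations of the three natural series
#'
#' Holds the activity concentrations (Bq kg^-1) of the U-238 series, the
#' Th-232 series and K-40, with standard uncertainties. This is the argument
#' of the soil dose-rate model and of both hazard indices.
#'
#' @slot activity named numeric of length 3 (`u`, `th`, `k`), Bq kg^-1.
#' @slot uncertainty named numeric of length 3, standard uncertainties
#'   (Bq kg^-1); zero when unknown.
#' @export
setClass("ActivityTriplet",
  representation(activity = "numeric", uncertainty = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@activity) != 3L || !identical(names(object@activity), c("u", "th", "k")))
      msg <- c(msg, "activity must be a numeric of length 3 named u, th, k")
    if (length(object@uncertainty) != 3L)
      msg <- c(msg, "uncertainty must have length 3")
    if (any(!is.finite(object@activity)) || any(object@activity < 0))
      msg <- c(msg, "activities must be finite and non-negative")
    if (any(object@uncertainty < 0))
      msg <- c(msg, "uncertainties must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an ActivityTriplet
#'
#' @param u,th,k activity concentrations (Bq kg^-1) of the U-238 series,
#'   Th-232 series and K-40.
#' @param sd standard uncertainties, recycled to length 3 (order u, th, k).
#' @return An [ActivityTriplet-class] object.
#' @examples
#' activityTriplet(35, 57, 551)
#' @export
activityTriplet <- function(u, th, k, sd = c(0, 0, 0)) {
  sd <- rep_len(as.numeric(sd), 3L)
  new("ActivityTriplet",
      activity = c(u = as.numeric(u), th = as.numeric(th), k = as.numeric(k)),
      uncertainty = setNames(sd, c("u", "th", "k")))
}

#' @describeIn activityTriplet accessor for the activity vector (named, Bq kg^-1).
#' @param x an `ActivityTriplet`.
#' @export
activities <- function(x) {
  stopifnot(is(x, "ActivityTriplet"))
  x@activity
}

#' @describeIn activityTriplet accessor for the standard uncertainties.
#' @export
activityUncertainties <- function(x) {
  stopifnot(is(x, "ActivityTriplet"))
  x@uncertainty
}

setMethod("show", "ActivityTriplet", function(object) {
  a <- object@activity; u <- object@uncertainty
  cat(sprintf("ActivityTriplet (Bq kg^-1): U %.1f +- %.1f | Th %.1f +- %.1f | K %.1f +- %.1f\n",
              a["u"], u["u"], a["th"], u["th"], a["k"], u["k"]))
})

# ---------------------------------------------------------------------------
# PulseHeightSpectrum -------------------------------------------------------

#' Pulse-height spectrum
#'
#' A channel-indexed gamma-ray pulse-height distribution with its live time
#' and (optionally) a linear energy calibration. Channel `i` spans
#' `offset + gain*(i-1)` to `offset + gain*i` keV under the calibration.
#'
#' @slot counts numeric vector of non-negative channel counts (may be
#'   non-integer for noise-free expected spectra).
#' @slot liveTime live time in seconds (> 0).
#' @slot calibration numeric of length 2, `c(offset, gain)` in keV and
#'   keV/channel; `NA` when uncalibrated.
#' @export
setClass("PulseHeightSpectrum",
  representation(counts = "numeric", liveTime = "numeric", calibration = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@counts) < 2L) msg <- c(msg, "spectrum needs at least 2 channels")
    if (any(object@counts < 0, na.rm = TRUE)) msg <- c(msg, "channel counts must be non-negative")
    if (length(object@liveTime) != 1L || !is.finite(object@liveTime) || object@liveTime <= 0)
      msg <- c(msg, "live time must be a single positive number")
    if (length(object@calibration) != 2L)
      msg <- c(msg, "calibration must be c(offset, gain)")
    else if (!any(is.na(object@calibration)) && object@calibration[2] <= 0)
      msg <- c(msg, "gain must be strictly positive (energy increasing in channel)")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a PulseHeightSpectrum
#'
#' @param counts non-negative channel counts.
#' @param liveTime live time (s).
#' @param calibration `c(offset, gain)` in keV, keV/channel, or `c(NA, NA)`.
#' @return A [PulseHeightSpectrum-class] object.
#' @export
pulseHeightSpectrum <- function(counts, liveTime, calibration = c(NA_real_, NA_real_)) {
  new("PulseHeightSpectrum", counts = as.numeric(counts),
      liveTime = as.numeric(liveTime),
      calibration = as.numeric(calibration))
}

#' Spectrum accessors
#'
#' @param x a [PulseHeightSpectrum-class].
#' @return `spectrumCounts`: channel counts; `liveTime`: seconds;
#'   `energyCalibration`: `c(offset, gain)` keV; `channelEnergies`:
#'   channel-centre energies in keV (errors if uncalibrated).
#' @export
spectrumCounts <- function(x) { stopifnot(is(x, "PulseHeightSpectrum")); x@counts }

#' @rdname spectrumCounts
#' @export
liveTime <- function(x) { stopifnot(is(x, "PulseHeightSpectrum")); x@liveTime }

#' @rdname spectrumCounts
#' @export
energyCalibration <- function(x) { stopifnot(is(x, "PulseHeightSpectrum")); x@calibration }

#' @rdname spectrumCounts
#' @export
isCalibrated <- function(x) { stopifnot(is(x, "PulseHeightSpectrum")); !any(is.na(x@calibration)) }

#' @rdname spectrumCounts
#' @export
channelEnergies <- function(x) {
  if (!isCalibrated(x)) stop("spectrum has no energy calibration")
  cal <- x@calibration
  cal[1] + cal[2] * (seq_along(x@counts) - 0.5)
}

setMethod("show", "PulseHeightSpectrum", function(object) {
  cat(sprintf("PulseHeightSpectrum: %d channels, live time %.0f s, total %.0f counts\n",
              length(object@counts), object@liveTime, sum(object@counts)))
  if (isCalibrated(object))
    cat(sprintf("  calibration: offset %.2f keV, gain %.4f keV/channel\n",
                object@calibration[1], object@calibration[2]))
  else cat("  calibration: none\n")
})

# ---------------------------------------------------------------------------
# EnergyBinning --------------------------------------------------------------

#' Unfolding energy binning
#'
#' The incident-energy bins used for response-matrix unfolding, spanning
#' 0-3.2 MeV, with the four evaluation windows flagged: K-40 (1.39-1.54 MeV
#' around 1.464), Bi-214 (1.69-1.84 around 1.765 and 2.10-2.31 around 2.205)
#' and Tl-208 (2.51-2.72 around 2.615).
#'
#' @slot edges strictly increasing bin edges in MeV, length K+1.
#' @slot flags named integer bin indices: `k`, `bi1`, `bi2`, `tl`.
#' @export
setClass("EnergyBinning",
  representation(edges = "numeric", flags = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(diff(object@edges) <= 0)) msg <- c(msg, "edges must be strictly increasing")
    need <- c("k", "bi1", "bi2", "tl")
    if (!all(need %in% names(object@flags)))
      msg <- c(msg, "flags must name bins k, bi1, bi2, tl")
    else {
      lines <- c(k = 1.464, bi1 = 1.765, bi2 = 2.205, tl = 2.615)
      for (nm in need) {
        i <- object@flags[[nm]]
        if (i < 1L || i > length(object@edges) - 1L ||
            lines[[nm]] < object@edges[i] || lines[[nm]] > object@edges[i + 1L])
          msg <- c(msg, sprintf("flagged bin '%s' must contain %.3f MeV", nm, lines[[nm]]))
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn defaultEnergyBinning number of bins.
#' @param x an `EnergyBinning`.
#' @export
nBins <- function(x) { stopifnot(is(x, "EnergyBinning")); length(x@edges) - 1L }

#' @describeIn defaultEnergyBinning bin edges (MeV).
#' @export
binEdges <- function(x) { stopifnot(is(x, "EnergyBinning")); x@edges }

#' @describeIn defaultEnergyBinning named flagged bin indices.
#' @export
binFlags <- function(x) { stopifnot(is(x, "EnergyBinning")); x@flags }

setMethod("show", "EnergyBinning", function(object) {
  cat(sprintf("EnergyBinning: %d bins over %.2f-%.2f MeV; flags: %s\n",
              length(object@edges) - 1L, min(object@edges), max(object@edges),
              paste(sprintf("%s=%d", names(object@flags), object@flags), collapse = ", ")))
})

# ---------------------------------------------------------------------------
# ResponseMatrix -------------------------------------------------------------

#' Detector response matrix with evaluation coefficients
#'
#' Square non-negative matrix mapping source strength per incident-energy bin
#' to detected count rate per pulse-height bin, bundled with its binning and
#' the coefficients that turn unfolded source strengths into activity
#' concentrations and absorbed dose rate in air.
#'
#' @slot matrix K x K non-negative matrix (pulse-height bin x incident bin).
#' @slot binning the [EnergyBinning-class] shared by rows and columns.
#' @slot doseCoef numeric length K; nGy h^-1 per unit unfolded source
#'   strength (cps) in each bin.
#' @slot activityCoef data.frame with columns `series`, `bin`, `coefficient`
#'   (cps per Bq kg^-1 at the flagged evaluation bins).
#' @export
setClass("ResponseMatrix",
  representation(matrix = "matrix", binning = "EnergyBinning",
                 doseCoef = "numeric", activityCoef = "data.frame"),
  validity = function(object) {
    msg <- character()
    K <- nBins(object@binning)
    if (!all(dim(object@matrix) == c(K, K)))
      msg <- c(msg, sprintf("matrix must be %d x %d", K, K))
    if (any(object@matrix < 0)) msg <- c(msg, "matrix entries must be non-negative")
    if (length(object@doseCoef) != K) msg <- c(msg, "doseCoef length must equal bin count")
    if (!all(c("series", "bin", "coefficient") %in% names(object@activityCoef)))
      msg <- c(msg, "activityCoef needs columns series, bin, coefficient")
    if (length(msg)) msg else TRUE
  }
)

#' ResponseMatrix accessors
#' @param x a [ResponseMatrix-class].
#' @export
responseMatrix <- function(x) { stopifnot(is(x, "ResponseMatrix")); x@matrix }

#' @rdname responseMatrix
#' @export
responseBinning <- function(x) { stopifnot(is(x, "ResponseMatrix")); x@binning }

#' @rdname responseMatrix
#' @export
doseCoefficientsPerBin <- function(x) { stopifnot(is(x, "ResponseMatrix")); x@doseCoef }

#' @rdname responseMatrix
#' @export
activityCoefficients <- function(x) { stopifnot(is(x, "ResponseMatrix")); x@activityCoef }

setMethod("show", "ResponseMatrix", function(object) {
  cat(sprintf("ResponseMatrix: %d x %d, column efficiency %.3f-%.3f\n",
              nrow(object@matrix), ncol(object@matrix),
              min(colSums(object@matrix)), max(colSums(object@matrix))))
})

# ---------------------------------------------------------------------------
# CalibrationSet -------------------------------------------------------------

#' Car-borne survey calibration factors
#'
#' The three multipliers of the dose-reconstruction model
#' `D_air = C_in * SF_carbody * SF_asphalt * DCF`: the car-body shielding
#' factor, the asphalt/roadbed shielding factor (may be below 1 where the
#' roadbed acts as a source), and the dose conversion factor in nGy h^-1 per
#' cps, each with standard uncertainty and fit sample size.
#'
#' @slot factors named numeric: `sfCarbody`, `sfAsphalt`, `dcf`.
#' @slot uncertainty named numeric of the same length (NA allowed).
#' @slot n named integer fit sample sizes.
#' @export
setClass("CalibrationSet",
  representation(factors = "numeric", uncertainty = "numeric", n = "integer"),
  validity = function(object) {
    nm <- c("sfCarbody", "sfAsphalt", "dcf")
    msg <- character()
    if (!identical(names(object@factors), nm))
      msg <- c(msg, "factors must be named sfCarbody, sfAsphalt, dcf")
    if (any(!is.finite(object@factors)) || any(object@factors <= 0))
      msg <- c(msg, "all calibration factors must be finite and > 0")
    if (length(object@uncertainty) != 3L || length(object@n) != 3L)
      msg <- c(msg, "uncertainty and n must have length 3")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a CalibrationSet
#'
#' @param sfCarbody,sfAsphalt,dcf the three factors (all > 0).
#' @param sd standard uncertainties (recycled to 3; NA allowed).
#' @param n fit sample sizes (recycled to 3).
#' @export
calibrationSet <- function(sfCarbody, sfAsphalt, dcf, sd = c(NA, NA, NA), n = c(0L, 0L, 0L)) {
  nm <- c("sfCarbody", "sfAsphalt", "dcf")
  new("CalibrationSet",
      factors = setNames(as.numeric(c(sfCarbody, sfAsphalt, dcf)), nm),
      uncertainty = setNames(rep_len(as.numeric(sd), 3L), nm),
      n = setNames(rep_len(as.integer(n), 3L), nm))
}

#' CalibrationSet accessors
#' @param x a [CalibrationSet-class].
#' @export
sfCarbody <- function(x) { stopifnot(is(x, "CalibrationSet")); unname(x@factors["sfCarbody"]) }

#' @rdname sfCarbody
#' @export
sfAsphalt <- function(x) { stopifnot(is(x, "CalibrationSet")); unname(x@factors["sfAsphalt"]) }

#' @rdname sfCarbody
#' @export
dcf <- function(x) { stopifnot(is(x, "CalibrationSet")); unname(x@factors["dcf"]) }

#' @rdname sfCarbody
#' @export
calibrationUncertainty <- function(x) { stopifnot(is(x, "CalibrationSet")); x@uncertainty }

setMethod("show", "CalibrationSet", function(object) {
  f <- object@factors; u <- object@uncertainty; n <- object@n
  cat(sprintf("CalibrationSet: SF_carbody %.3f +- %.3f (n=%d) | SF_asphalt %.3f +- %.3f (n=%d) | DCF %.4f +- %.4f nGy/h/cps (n=%d)\n",
              f[1], u[1], n[1], f[2], u[2], n[2], f[3], u[3], n[3]))
})

# ---------------------------------------------------------------------------
# EfficiencyCurve -------------------------------------------------------------

#' HPGe full-energy-peak efficiency curve
#'
#' Calibration points from a certified multi-nuclide volume source, queried
#' by log-log linear interpolation.
#'
#' @slot energy strictly increasing energies (keV), at least 2 points.
#' @slot efficiency full-energy-peak efficiencies in (0, 1).
#' @slot relSd single relative standard uncertainty applied to interpolated
#'   efficiencies (dimensionless).
#' @export
setClass("EfficiencyCurve",
  representation(energy = "numeric", efficiency = "numeric", relSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@energy) < 2L) msg <- c(msg, "need at least 2 calibration points")
    if (any(diff(object@energy) <= 0)) msg <- c(msg, "energies must be strictly increasing")
    if (length(object@efficiency) != length(object@energy))
      msg <- c(msg, "efficiency and energy lengths differ")
    if (any(object@efficiency <= 0) || any(object@efficiency >= 1))
      msg <- c(msg, "efficiencies must lie in (0, 1)")
    if (length(object@relSd) != 1L || object@relSd < 0)
      msg <- c(msg, "relSd must be a single non-negative number")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an EfficiencyCurve
#'
#' @param energy energies in keV, strictly increasing.
#' @param efficiency full-energy-peak efficiencies in (0, 1).
#' @param relSd relative standard uncertainty of the curve (default 0.01).
#' @export
efficiencyCurve <- function(energy, efficiency, relSd = 0.01) {
  new("EfficiencyCurve", energy = as.numeric(energy),
      efficiency = as.numeric(efficiency), relSd = as.numeric(relSd))
}

setMethod("show", "EfficiencyCurve", function(object) {
  cat(sprintf("EfficiencyCurve: %d points, %.0f-%.0f keV, eff %.4f-%.4f (rel sd %.1f%%)\n",
              length(object@energy), min(object@energy), max(object@energy),
              min(object@efficiency), max(object@efficiency), 100 * object@relSd))
})

# ---------------------------------------------------------------------------
# DoseGrid --------------------------------------------------------------------

#' Gridded dose-rate surface
#'
#' Regular lon/lat grid of interpolated absorbed dose rate in air, with a
#' mask hiding cells farther than a configured number of cells from any
#' datum.
#'
#' @slot lon,lat grid-node coordinate vectors (regular spacing).
#' @slot values matrix (length(lat) x length(lon)) with masked cells NA.
#' @slot surface unmasked solution matrix of the same shape.
#' @slot spacing grid spacing (degrees).
#' @export
setClass("DoseGrid",
  representation(lon = "numeric", lat = "numeric", values = "matrix",
                 surface = "matrix", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@values) == c(length(object@lat), length(object@lon))))
      msg <- c(msg, "values must be length(lat) x length(lon)")
    if (!all(dim(object@surface) == dim(object@values)))
      msg <- c(msg, "surface and values shapes differ")
    if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "DoseGrid", function(object) {
  cat(sprintf("DoseGrid: %d x %d cells at %.3f deg, %d unmasked\n",
              length(object@lat), length(object@lon), object@spacing,
              sum(!is.na(object@values))))
})

#' DoseGrid accessors
#' @param x a [DoseGrid-class].
#' @export
gridValues <- function(x) { stopifnot(is(x, "DoseGrid")); x@values }

#' @rdname gridValues
#' @export
gridSurface <- function(x) { stopifnot(is(x, "DoseGrid")); x@surface }

#' @rdname gridValues
#' @export
gridCoordinates <- function(x) { stopifnot(is(x, "DoseGrid")); list(lon = x@lon, lat = x@lat) }
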