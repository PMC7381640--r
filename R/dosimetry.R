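# Closed-form dose and hazard calculus: annual effective doses, soil dose
# rate, radium equivalent activity, external hazard index, the
# direct-vs-soil ratio of difference, and uncertainty combination.

#' Dose coefficients
#'
#' Constants of the annual-effective-dose and soil dose-rate models: the
#' absorbed-dose-to-effective-dose conversion coefficient for adults
#' (0.7 Sv Gy^-1), the indoor (0.8) and outdoor (0.2) occupancy factors,
#' hours per year (8760), and the linear soil coefficients turning activity
#' concentrations (Bq kg^-1) of U-238 series, Th-232 series and K-40 into
#' absorbed dose rate in air 1 m above ground (nGy h^-1):
#' `D_soil = 0.43 A_U + 0.666 A_Th + 0.042 A_K`.
#'
#' @param effective dose conversion coefficient (Sv Gy^-1).
#' @param indoorOccupancy,outdoorOccupancy occupancy fractions; must sum to 1.
#' @param hoursPerYear hours in a year.
#' @param soil named numeric `c(u=, th=, k=)` soil dose coefficients.
#' @return list of validated coefficients.
#' @export
doseCoefficients <- function(effective = 0.7, indoorOccupancy = 0.8,
                             outdoorOccupancy = 0.2, hoursPerYear = 8760,
                             soil = c(u = 0.43, th = 0.666, k = 0.042)) {
  stopifnot(effective > 0, hoursPerYear > 0, all(soil > 0),
            indoorOccupancy > 0, outdoorOccupancy > 0)
  if (abs(indoorOccupancy + outdoorOccupancy - 1) > 1e-12)
    stop("occupancy factors must sum to 1")
  if (!all(c("u", "th", "k") %in% names(soil)))
    stop("soil coefficients must be named u, th, k")
  list(effective = effective, indoorOccupancy = indoorOccupancy,
       outdoorOccupancy = outdoorOccupancy, hoursPerYear = hoursPerYear,
       soil = soil[c("u", "th", "k")])
}

#' Hazard index coefficients
#'
#' Constants of the radium equivalent activity
#' `Ra_eq = A_U + 1.43 A_Th + 0.077 A_K` and the external hazard index
#' `H_ex = A_U/370 + A_Th/259 + A_K/4810`, with the H_ex acceptability
#' limit fixed at unity.
#'
#' @param raeq Ra_eq weights (u, th, k).
#' @param hex H_ex denominators (u, th, k), Bq kg^-1.
#' @param limit H_ex acceptability limit (1).
#' @export
hazardCoefficients <- function(raeq = c(u = 1, th = 1.43, k = 0.077),
                               hex = c(u = 370, th = 259, k = 4810),
                               limit = 1) {
  stopifnot(all(raeq > 0), all(hex > 0), limit == 1)
  list(raeq = raeq[c("u", "th", "k")], hex = hex[c("u", "th", "k")], limit = limit)
}

checkDose <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("absorbed dose rate must be non-negative")
  d
}

asTripletMatrix <- function(a) {
  if (is(a, "ActivityTriplet")) a <- matrix(activities(a), nrow = 1,
                                            dimnames = list(NULL, c("u", "th", "k")))
  else if (is.data.frame(a)) a <- as.matrix(a[, c("u", "th", "k")])
  else if (is.numeric(a) && length(a) == 3L) a <- matrix(a, nrow = 1,
                                            dimnames = list(NULL, c("u", "th", "k")))
  if (any(a < 0)) stop("activity concentrations must be non-negative")
  a
}

#' Annual outdoor effective dose
#'
#' `OAED = D_air x 0.7 x 8760 x 0.2 x 1e-6` (mSv year^-1). Vectorised over
#' `dAir`; values are unrounded — rounding happens only at presentation.
#'
#' @param dAir absorbed dose rate in air (nGy h^-1), non-negative.
#' @param coef [doseCoefficients()].
#' @return OAED in mSv year^-1.
#' @examples
#' oaed(75)   # 0.092 -> printed 0.09
#' @export
oaed <- function(dAir, coef = doseCoefficients()) {
  checkDose(dAir) * coef$effective * coef$hoursPerYear * coef$outdoorOccupancy * 1e-6
}

#' Annual indoor effective dose
#'
#' `IAED = D_air x 0.7 x 8760 x 0.8 x 1e-6` (mSv year^-1).
#'
#' @inheritParams oaed
#' @return IAED in mSv year^-1.
#' @examples
#' iaed(71)   # 0.348 -> printed 0.35
#' @export
iaed <- function(dAir, coef = doseCoefficients()) {
  checkDose(dAir) * coef$effective * coef$hoursPerYear * coef$indoorOccupancy * 1e-6
}

#' Absorbed dose rate in air from soil activity concentrations
#'
#' `D_soil = 0.43 A_U + 0.666 A_Th + 0.042 A_K` (nGy h^-1), the terrestrial
#' dose rate 1 m above ground implied by soil composition alone.
#'
#' @param a an [ActivityTriplet-class], a numeric `c(u, th, k)`, or a
#'   data.frame/matrix with columns `u`, `th`, `k` (Bq kg^-1).
#' @param coef [doseCoefficients()].
#' @return nGy h^-1 (vector over rows).
#' @examples
#' doseFromSoil(activityTriplet(35, 57, 551))  # 76.15
#' @export
doseFromSoil <- function(a, coef = doseCoefficients()) {
  drop(asTripletMatrix(a) %*% coef$soil)
}

#' Radium equivalent activity
#'
#' `Ra_eq = A_U + 1.43 A_Th + 0.077 A_K` (Bq kg^-1): the single-index
#' gamma-equivalent radium activity of a mixed U/Th/K material.
#'
#' @inheritParams doseFromSoil
#' @param h [hazardCoefficients()].
#' @examples
#' radiumEquivalent(activityTriplet(35, 57, 551))  # 158.9 -> printed 159
#' @export
radiumEquivalent <- function(a, h = hazardCoefficients()) {
  drop(asTripletMatrix(a) %*% h$raeq)
}

#' External hazard index
#'
#' `H_ex = A_U/370 + A_Th/259 + A_K/4810`; values at or below 1 indicate a
#' negligible external gamma hazard.
#'
#' @inheritParams radiumEquivalent
#' @return list with `value` (numeric) and `exceeds` (logical, `value > 1`).
#' @examples
#' externalHazardIndex(activityTriplet(370, 0, 0))  # value 1, exceeds FALSE
#' @export
externalHazardIndex <- function(a, h = hazardCoefficients()) {
  v <- drop(asTripletMatrix(a) %*% (1 / h$hex))
  list(value = v, exceeds = v > h$limit)
}

#' Ratio of difference between direct and soil-derived dose rates
#'
#' The quotient of the directly measured absorbed dose rate in air over the
#' dose rate computed from soil activity concentrations at the same site.
#' Values below 1 indicate that the built-up environment shields terrestrial
#' gamma rays; values above 1 indicate that construction materials act as
#' additional sources.
#'
#' @param dDirect direct-measurement dose rates (nGy h^-1).
#' @param dSoil soil-derived dose rates (nGy h^-1), strictly positive.
#' @return numeric ratios (vectorised).
#' @examples
#' ratioOfDifference(71, 77)  # 0.92 -> printed 0.9
#' @export
ratioOfDifference <- function(dDirect, dSoil) {
  if (any(!is.finite(dSoil)) || any(dSoil <= 0))
    stop("soil-derived dose rate must be strictly positive")
  checkDose(dDirect) / dSoil
}

#' Classify built-up effect from the ratio of difference
#'
#' @param ratio ratios from [ratioOfDifference()].
#' @param neutralBand half-width of the band around 1 treated as neutral.
#' @return factor with levels `shielding`, `neutral`, `source`.
#' @export
classifyBuiltUp <- function(ratio, neutralBand = 0) {
  stopifnot(neutralBand >= 0)
  cut(ratio, c(-Inf, 1 - neutralBand, 1 + neutralBand, Inf),
      labels = c("shielding", "neutral", "source"), right = TRUE)
}

#' Combined relative standard uncertainty
#'
#' Root-sum-of-squares combination of independent relative uncertainty
#' components; an empty list combines to 0.
#'
#' @param components non-negative relative uncertainties.
#' @examples
#' combinedRelativeUncertainty(c(0.03, 0.04))  # 0.05
#' @export
combinedRelativeUncertainty <- function(components) {
  if (length(components) == 0L) return(0)
  if (any(components < 0)) stop("relative uncertainties must be non-negative")
  sqrt(sum(components^2))
}

#' Full radiological hazard assessment
#'
#' Computes, for each site, the soil-derived dose rate, annual indoor and
#' outdoor effective doses for the chosen dose rate, radium equivalent
#' activity, external hazard index, the direct/soil ratio of difference
#' (when a direct dose rate is supplied), and reference-level flags.
#'
#' @param a activities as in [doseFromSoil()] (one row per site).
#' @param dDirect optional direct-measurement dose rates (nGy h^-1),
#'   recycled to the number of sites.
#' @param coef [doseCoefficients()].
#' @param h [hazardCoefficients()].
#' @param referenceBand annual-effective-dose reference band (mSv year^-1);
#'   `belowReference` flags totals under its lower edge.
#' @return data.frame with columns `dSoil`, `dDirect`, `oaedSoil`,
#'   `iaedSoil`, `totalSoil`, `oaedDirect`, `iaedDirect`, `totalDirect`,
#'   `raeq`, `hex`, `hexExceeds`, `ratio`, `belowReference`.
#' @export
assessHazard <- function(a, dDirect = NULL, coef = doseCoefficients(),
                         h = hazardCoefficients(), referenceBand = c(1, 20)) {
  m <- asTripletMatrix(a)
  dS <- drop(m %*% coef$soil)
  hx <- externalHazardIndex(m, h)
  out <- data.frame(
    dSoil = dS,
    dDirect = if (is.null(dDirect)) NA_real_ else rep_len(dDirect, length(dS)),
    oaedSoil = oaed(dS, coef), iaedSoil = iaed(dS, coef)
  )
  out$totalSoil <- out$oaedSoil + out$iaedSoil
  if (is.null(dDirect)) {
    out$oaedDirect <- out$iaedDirect <- out$totalDirect <- NA_real_
    out$ratio <- NA_real_
  } else {
    out$oaedDirect <- oaed(out$dDirect, coef)
    out$iaedDirect <- iaed(out$dDirect, coef)
    out$totalDirect <- out$oaedDirect + out$iaedDirect
    out$ratio <- ratioOfDifference(out$dDirect, dS)
  }
  out$raeq <- radiumEquivalent(m, h)
  out$hex <- hx$value
  out$hexExceeds <- hx$exceeds
  out$belowReference <- pmax(out$totalSoil, out$totalDirect, na.rm = TRUE) < referenceBand[1]
  out
}

#' Presentation rounding mirroring survey-report conventions
#'
#' Dose rates to whole nGy h^-1, annual effective doses to 2 decimals
#' (mSv year^-1), ratios and H_ex to 1 decimal, Ra_eq to whole Bq kg^-1.
#' Internal computation is never rounded; use only for display.
#'
#' @param x numeric value(s).
#' @param what one of `"doseRate"`, `"aed"`, `"ratio"`, `"hex"`, `"raeq"`.
#' @export
presentationRound <- function(x, what = c("doseRate", "aed", "ratio", "hex", "raeq")) {
  what <- match.arg(what)
  switch(what,
         doseRate = round(x), aed = round(x, 2), ratio = round(x, 1),
         hex = round(x, 1), raeq = round(x))
}
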