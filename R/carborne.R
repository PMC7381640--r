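# Car-borne survey calibration and dose reconstruction:
# D_air = C_in x SF_carbody x SF_asphalt x DCF.

#' Through-origin proportional fit
#'
#' Least-squares slope of `y = beta * x` (no intercept: the
#' dose-reconstruction model is purely multiplicative), with the standard
#' uncertainty of the slope from the residual variance. An ordinary fit
#' with intercept is available for diagnostics via `intercept = TRUE`; its
#' intercept is reported but never used in dose reconstruction.
#'
#' @param x,y paired observations (>= 2 pairs; `x` not all zero).
#' @param intercept fit an ordinary regression with intercept instead.
#' @return list with `slope`, `sd` (standard uncertainty; `NA` with a
#'   `singlePairWarning` when only one pair leaves no residual dof),
#'   `intercept` (0 for the through-origin fit) and `n`.
#' @examples
#' fitProportional(1:5, 2 * (1:5))  # slope 2, sd 0
#' @export
fitProportional <- function(x, y, intercept = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 1L || length(y) != n) stop("x and y must be non-empty and of equal length")
  if (all(x == 0)) stop("all-zero x: proportional slope undefined")
  if (intercept) {
    if (n < 3L) stop("intercept fit needs at least 3 pairs")
    fit <- stats::lm(y ~ x)
    s <- summary(fit)$coefficients
    return(list(slope = unname(s["x", 1]), sd = unname(s["x", 2]),
                intercept = unname(s["(Intercept)", 1]), n = n))
  }
  slope <- sum(x * y) / sum(x^2)
  if (n == 1L) {
    warning(warningCondition("single pair: slope uncertainty undefined",
                             class = c("singlePairWarning", "warning", "condition")))
    return(list(slope = slope, sd = NA_real_, intercept = 0, n = 1L))
  }
  r <- y - slope * x
  sd <- sqrt(sum(r^2) / (n - 1) / sum(x^2))
  list(slope = slope, sd = sd, intercept = 0, n = n)
}

#' Estimate the survey calibration from paired measurements
#'
#' Through-origin fits on a paired table: `SF_carbody` as the slope of
#' outside-car vs inside-car count rates, `SF_asphalt` as the slope of
#' bare-surface vs asphalt count rates, and `DCF` as the slope of unfolded
#' absorbed dose rate vs outside-car count rate. The table needs columns
#' `insideCps`/`outsideCps`, `asphaltCps`/`bareCps` and
#' `outsideCps`/`doseNgyH`; a missing pair raises an error naming the
#' calibration it prevents.
#'
#' @param paired data.frame of paired site measurements.
#' @param intercept use ordinary fits with intercept (diagnostic option).
#' @param by optional grouping column (e.g. `"region"` where the asphalt
#'   factor is region-specific, or `"campaign"` where each car has its own
#'   body factor); returns one calibration per group.
#' @return A [CalibrationSet-class], or a named list of them when `by` is
#'   given.
#' @export
estimateCalibration <- function(paired, intercept = FALSE, by = NULL) {
  if (!is.null(by)) {
    if (!by %in% names(paired)) stop("no grouping column named '", by, "'")
    groups <- split(paired, paired[[by]])
    return(lapply(groups, estimateCalibration, intercept = intercept))
  }
  needPair <- function(cols, what) {
    if (!all(cols %in% names(paired)))
      stop(sprintf("missing column pair (%s): cannot estimate %s",
                   paste(cols, collapse = ", "), what))
  }
  needPair(c("insideCps", "outsideCps"), "sfCarbody")
  needPair(c("asphaltCps", "bareCps"), "sfAsphalt")
  needPair(c("outsideCps", "doseNgyH"), "dcf")
  fCar <- fitProportional(paired$insideCps, paired$outsideCps, intercept)
  fAsp <- fitProportional(paired$asphaltCps, paired$bareCps, intercept)
  fDcf <- fitProportional(paired$outsideCps, paired$doseNgyH, intercept)
  calibrationSet(fCar$slope, fAsp$slope, fDcf$slope,
                 sd = c(fCar$sd, fAsp$sd, fDcf$sd),
                 n = c(fCar$n, fAsp$n, fDcf$n))
}

#' Reconstruct absorbed dose rate in air along a survey track
#'
#' Applies `D_air = C_in x SF_carbody x SF_asphalt x DCF` to every record.
#' With a named list of calibrations, each record's `campaign` column
#' selects its calibration set.
#'
#' @param track data.frame with at least a `cps` column (count rate inside
#'   the car); the `by` column is required when `calib` is a named list.
#' @param calib a [CalibrationSet-class], or a named list of them keyed by
#'   the values of the `by` column (campaign or region).
#' @param by record column selecting among multiple calibration sets
#'   (default `"campaign"`; use `"region"` for region-specific asphalt
#'   factors).
#' @return the track with a `doseNgyH` column appended.
#' @examples
#' reconstructDose(data.frame(cps = 300), calibrationSet(2.01, 1.37, 0.14))
#' @export
reconstructDose <- function(track, calib, by = "campaign") {
  if (!"cps" %in% names(track)) stop("track needs a 'cps' column")
  if (any(track$cps < 0)) stop("negative count rate in track")
  factorOf <- function(cs) prod(cs@factors)
  if (is(calib, "CalibrationSet")) {
    track$doseNgyH <- track$cps * factorOf(calib)
  } else {
    if (!by %in% names(track))
      stop("track needs a '", by, "' column to select among calibration sets")
    miss <- setdiff(unique(track[[by]]), names(calib))
    if (length(miss)) stop("no calibration for ", by, ": ", paste(miss, collapse = ", "))
    mult <- vapply(calib, factorOf, numeric(1))
    track$doseNgyH <- track$cps * mult[track[[by]]]
  }
  track
}
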