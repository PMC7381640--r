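# Synthetic survey-campaign generator: ground-truth activity fields, NaI and
# HPGe spectra, car-borne tracks and paired shielding measurements, all with
# known parameters so every downstream stage has a recoverable truth.

#' Ground-truth configuration for a synthetic survey campaign
#'
#' Holds the generating truth: per-region activity distributions for the
#' soil column and for the direct-measurement (built-up) field, the true
#' car-body and asphalt shielding factors, the true dose conversion factor,
#' the cosmic floor, and the NaI(Tl) detector model (resolution, gain,
#' channel count, continuum fraction).
#'
#' @slot regions data.frame; one row per region with columns `region`,
#'   `campaign`, `weight`, truncated-normal means/SDs `soilU`, `soilUsd`,
#'   `soilTh`, `soilThsd`, `soilK`, `soilKsd`, `directU`, `directUsd`,
#'   `directTh`, `directThsd`, `directK`, `directKsd` (Bq kg^-1) and a
#'   bounding box `lat0`, `lat1`, `lon0`, `lon1`.
#' @slot sfCarbody named numeric, true car-body shielding factor per campaign.
#' @slot sfAsphalt named numeric, true asphalt shielding factor per region.
#' @slot dcf true dose conversion factor (nGy h^-1 per cps).
#' @slot cosmicRate flat cosmic count rate (cps per channel).
#' @slot resolution NaI FWHM at 0.662 MeV, percent.
#' @slot gain keV per channel.
#' @slot channels channel count (>= 512).
#' @slot continuumFraction fraction of each line's detected counts in its
#'   flat Compton continuum (rest in the photopeak).
#' @slot builtUp list: `enabled`, `sdlog`, `fractionBelow`, `range` for the
#'   optional per-site multiplicative built-up perturbation of the direct
#'   truth.
#' @slot seed default random seed.
#' @export
setClass("TruthConfig",
  representation(regions = "data.frame", sfCarbody = "numeric",
                 sfAsphalt = "numeric", dcf = "numeric", cosmicRate = "numeric",
                 resolution = "numeric", gain = "numeric", channels = "integer",
                 continuumFraction = "numeric", builtUp = "list", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("region", "campaign", "weight",
              "soilU", "soilUsd", "soilTh", "soilThsd", "soilK", "soilKsd",
              "directU", "directUsd", "directTh", "directThsd", "directK", "directKsd",
              "lat0", "lat1", "lon0", "lon1")
    if (!all(need %in% names(object@regions)))
      msg <- c(msg, paste("regions is missing columns:",
                          paste(setdiff(need, names(object@regions)), collapse = ", ")))
    else {
      means <- as.matrix(object@regions[, c("soilU", "soilTh", "soilK",
                                            "directU", "directTh", "directK")])
      sds <- as.matrix(object@regions[, c("soilUsd", "soilThsd", "soilKsd",
                                          "directUsd", "directThsd", "directKsd")])
      if (any(means <= 0)) msg <- c(msg, "all activity means must be strictly positive")
      if (any(sds < 0)) msg <- c(msg, "activity SDs must be non-negative")
      if (any(object@regions$weight <= 0)) msg <- c(msg, "region weights must be positive")
    }
    if (any(object@sfCarbody <= 0) || any(object@sfAsphalt <= 0) || object@dcf <= 0)
      msg <- c(msg, "shielding factors and DCF must be strictly positive")
    if (object@gain <= 0) msg <- c(msg, "gain must be strictly positive")
    if (object@channels < 512L) msg <- c(msg, "channel count must be >= 512")
    if (object@cosmicRate < 0) msg <- c(msg, "cosmic rate must be non-negative")
    if (object@continuumFraction < 0 || object@continuumFraction >= 1)
      msg <- c(msg, "continuum fraction must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a TruthConfig
#'
#' Defaults reproduce the all-country campaign structure: two regions
#' (north, weight 178; south, weight 284) whose soil and direct activity
#' means/SDs are the regional summary values of the study area
#' (north soil 39/63/551, south soil 32/54/551 Bq kg^-1, etc.), true
#' shielding factors 2.01 (car body), 0.96 north / 1.37 south (asphalt) and
#' DCF 0.14 nGy h^-1 per cps.
#'
#' @param regions region table (see [TruthConfig-class]); default two-region
#'   layout described above.
#' @param sfCarbody named numeric per campaign (default `c(c1 = 2.01)`).
#' @param sfAsphalt named numeric per region (default north 0.96, south 1.37).
#' @param dcf dose conversion factor (default 0.14 nGy h^-1/cps).
#' @param cosmicRate cosmic floor, cps per channel (default 0.008).
#' @param resolution FWHM percent at 0.662 MeV (default 7.5).
#' @param gain keV/channel (default 3.2).
#' @param channels channel count (default 1024).
#' @param continuumFraction per-line continuum fraction (default 0.55).
#' @param builtUp list(`enabled`, `sdlog`, `fractionBelow`, `range`);
#'   default disabled.
#' @param seed default seed (default 20150801).
#' @return A validated [TruthConfig-class].
#' @export
truthConfig <- function(regions = defaultRegionTable(), sfCarbody = c(c1 = 2.01),
                        sfAsphalt = c(north = 0.96, south = 1.37), dcf = 0.14,
                        cosmicRate = 0.008, resolution = 7.5, gain = 3.2,
                        channels = 1024L, continuumFraction = 0.55,
                        builtUp = list(enabled = FALSE, sdlog = 0.25,
                                       fractionBelow = NA_real_, range = c(0.5, 2.1)),
                        seed = 20150801) {
  if (is.null(names(sfCarbody))) names(sfCarbody) <- unique(regions$campaign)[seq_along(sfCarbody)]
  if (is.null(names(sfAsphalt))) names(sfAsphalt) <- regions$region[seq_along(sfAsphalt)]
  new("TruthConfig", regions = regions, sfCarbody = sfCarbody,
      sfAsphalt = sfAsphalt, dcf = dcf, cosmicRate = cosmicRate,
      resolution = resolution, gain = gain, channels = as.integer(channels),
      continuumFraction = continuumFraction, builtUp = builtUp, seed = seed)
}

#' @describeIn truthConfig the default two-region table (regional means and
#'   SDs of the study's soil and direct-measurement compositions).
#' @export
defaultRegionTable <- function() {
  data.frame(
    region = c("north", "south"), campaign = c("c1", "c1"),
    weight = c(178, 284),
    soilU = c(39, 32), soilUsd = c(25, 19),
    soilTh = c(63, 54), soilThsd = c(33, 33),
    soilK = c(551, 551), soilKsd = c(259, 389),
    directU = c(60, 44), directUsd = c(43, 20),
    directTh = c(44, 43), directThsd = c(20, 21),
    directK = c(415, 531), directKsd = c(208, 230),
    lat0 = c(16.5, 8.5), lat1 = c(23.0, 16.5),
    lon0 = c(102.5, 104.5), lon1 = c(107.5, 109.5),
    stringsAsFactors = FALSE
  )
}

# Location parameter of a zero-truncated normal whose truncated mean equals
# `target` at scale `sd`; solved so configured means are population means.
truncNormLocation <- function(target, sd) {
  if (sd == 0) return(target)
  # phi(a)/Phi(a) on the log scale to survive deep truncation
  mills <- function(a) exp(dnorm(a, log = TRUE) - pnorm(a, log.p = TRUE))
  f <- function(mu) mu + sd * mills(mu / sd) - target
  uniroot(f, lower = target - 30 * sd, upper = target, extendInt = "upX",
          tol = 1e-12)$root
}

# Inverse-CDF draw from the zero-truncated normal with location mu, scale sd,
# driven by standard-normal deviates z (comonotone across linked draws).
truncNormDraw <- function(z, target, sd) {
  if (sd == 0) return(rep(target, length(z)))
  mu <- truncNormLocation(target, sd)
  pLow <- pnorm(-mu / sd)
  q <- pLow + pnorm(z) * (1 - pLow)
  mu + sd * qnorm(q)
}

#' Generate synthetic fixed-point sites
#'
#' Draws `nSites` sites across the configured regions (allocation
#' proportional to region weights, largest-remainder rounding). Soil and
#' direct activity triplets are drawn per nuclide from zero-truncated
#' normals with the configured means/SDs; the soil and direct draws share
#' the same standard-normal deviate per nuclide, so a site that is U-rich in
#' soil is U-rich in the direct field too. True dose rates are the soil
#' dose-rate model applied to each triplet; the optional built-up multiplier
#' perturbs the direct truth only.
#'
#' @param config a [TruthConfig-class].
#' @param nSites number of sites (>= 1).
#' @param regions optional character vector restricting generation to these
#'   region ids; unknown ids are an error.
#' @param seed seed (default `config@seed`); fixed seed gives identical output.
#' @return data.frame with one row per site: `site`, `region`, `campaign`,
#'   `lat`, `lon`, soil and direct triplets (`soilU`, `soilTh`, `soilK`,
#'   `directU`, `directTh`, `directK`), `builtUp`, and true dose rates
#'   `dSoil`, `dDirect` (nGy h^-1).
#' @export
generateSites <- function(config, nSites, regions = NULL, seed = config@seed) {
  stopifnot(is(config, "TruthConfig"))
  validObject(config)
  if (length(nSites) != 1L || !is.finite(nSites) || nSites < 1)
    stop("nSites must be a positive count")
  nSites <- as.integer(nSites)
  reg <- config@regions
  if (!is.null(regions)) {
    unknown <- setdiff(regions, reg$region)
    if (length(unknown)) stop("unknown region id: ", paste(unknown, collapse = ", "))
    reg <- reg[reg$region %in% regions, , drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  # largest-remainder allocation of sites to regions
  raw <- nSites * reg$weight / sum(reg$weight)
  n_r <- floor(raw)
  left <- nSites - sum(n_r)
  if (left > 0) {
    ord <- order(raw - n_r, decreasing = TRUE)
    n_r[ord[seq_len(left)]] <- n_r[ord[seq_len(left)]] + 1
  }
  pieces <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    n <- n_r[i]
    if (n == 0) next
    r <- reg[i, ]
    z <- matrix(rnorm(3 * n), ncol = 3)
    soil <- cbind(truncNormDraw(z[, 1], r$soilU, r$soilUsd),
                  truncNormDraw(z[, 2], r$soilTh, r$soilThsd),
                  truncNormDraw(z[, 3], r$soilK, r$soilKsd))
    direct <- cbind(truncNormDraw(z[, 1], r$directU, r$directUsd),
                    truncNormDraw(z[, 2], r$directTh, r$directThsd),
                    truncNormDraw(z[, 3], r$directK, r$directKsd))
    pieces[[i]] <- data.frame(
      region = r$region, campaign = r$campaign,
      lat = runif(n, r$lat0, r$lat1), lon = runif(n, r$lon0, r$lon1),
      soilU = soil[, 1], soilTh = soil[, 2], soilK = soil[, 3],
      directU = direct[, 1], directTh = direct[, 2], directK = direct[, 3],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- cbind(site = sprintf("S%04d", seq_len(nrow(out))), out)
  bu <- config@builtUp
  if (isTRUE(bu$enabled)) {
    sdlog <- if (is.null(bu$sdlog)) 0.25 else bu$sdlog
    meanlog <- if (is.finite(bu$fractionBelow %||% NA_real_))
      -qnorm(bu$fractionBelow) * sdlog else 0
    f <- rlnorm(nrow(out), meanlog, sdlog)
    rng <- bu$range %||% c(0.5, 2.1)
    out$builtUp <- pmin(pmax(f, rng[1]), rng[2])
  } else out$builtUp <- 1
  coefs <- doseCoefficients()$soil
  out$dSoil <- drop(as.matrix(out[, c("soilU", "soilTh", "soilK")]) %*% coefs)
  out$dDirect <- drop(as.matrix(out[, c("directU", "directTh", "directK")]) %*% coefs) * out$builtUp
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expected NaI channel count rates (cps per channel) for a direct-field
# activity triplet under the simplified forward model: Gaussian photopeaks
# with FWHM ~ sqrt(E), per-line flat continuum below the Compton edge, flat
# cosmic floor.
naiExpectedRates <- function(u, th, k, config, lines = naiLineLibrary()) {
  gain <- config@gain
  nch <- config@channels
  if (gain * nch < 3200)
    stop("channel range cannot contain 3.2 MeV (gain x channels too small)")
  act <- c(U = u, Th = th, K = k)
  edges <- (0:nch) * gain / 1000  # MeV
  rate <- rep(config@cosmicRate, nch)
  f <- config@continuumFraction
  for (i in seq_len(nrow(lines))) {
    A <- act[[lines$series[i]]]
    if (A <= 0) next
    tot <- A * lines$yield[i]
    E <- lines$energy[i]
    sig <- peakSigma(E, config@resolution)
    peakMass <- diff(pnorm(edges, E, sig))
    ce <- comptonEdge(E)
    contMass <- pmax(pmin(edges[-1], ce) - pmin(edges[-length(edges)], ce), 0) / ce
    rate <- rate + tot * ((1 - f) * peakMass + f * contMass)
  }
  rate
}

#' Simulate a NaI(Tl) pulse-height spectrum for a site
#'
#' Forward-models the fixed-point spectrum measured 1 m above ground: one
#' Gaussian photopeak per library line (area `activity x yield x liveTime`,
#' FWHM scaling with sqrt(E)), a per-line flat Compton continuum below the
#' line's Compton edge, and a flat cosmic floor across all channels. With
#' `noise = TRUE` channel counts are Poisson-sampled; with `noise = FALSE`
#' the noise-free expected spectrum is returned.
#'
#' @param site one row of [generateSites()] output (the direct-field triplet
#'   is what the detector sees), or a list with `directU`, `directTh`,
#'   `directK`.
#' @param liveTime live time in seconds (> 0).
#' @param config a [TruthConfig-class].
#' @param noise Poisson noise flag.
#' @param seed optional seed for the Poisson draw.
#' @return A [PulseHeightSpectrum-class] carrying the instrument's nominal
#'   energy calibration `c(0, gain)`.
#' @export
simulateNaiSpectrum <- function(site, liveTime, config, noise = TRUE, seed = NULL) {
  stopifnot(is(config, "TruthConfig"))
  if (length(liveTime) != 1L || !is.finite(liveTime) || liveTime <= 0)
    stop("liveTime must be a single positive number of seconds")
  expected <- naiExpectedRates(site$directU, site$directTh, site$directK, config) * liveTime
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    counts <- rpois(length(expected), expected)
  } else counts <- expected
  pulseHeightSpectrum(counts, liveTime, calibration = c(0, config@gain))
}

#' Simulate paired shielding measurements
#'
#' For each site, the four count rates used to fit the survey calibration:
#' outside the car (the count rate whose product with DCF is the true direct
#' dose rate), inside the car (outside divided by the car-body shielding
#' factor), and the asphalt/bare pair for the asphalt factor (bare = asphalt
#' x SF_asphalt, so bare counts fall below asphalt counts where the roadbed
#' acts as a source, SF < 1). Counts over `liveTime` are Poisson unless
#' `noise = FALSE`.
#'
#' @param sites output of [generateSites()] (non-empty).
#' @param config a [TruthConfig-class].
#' @param liveTime total counting time per surface (s; default 120, four
#'   30-s intervals over 2 min).
#' @param noise Poisson noise flag.
#' @param seed optional seed.
#' @return data.frame: `site`, `campaign`, `region`, `insideCps`,
#'   `outsideCps`, `asphaltCps`, `bareCps`.
#' @export
simulatePairedCounts <- function(sites, config, liveTime = 120, noise = TRUE, seed = NULL) {
  stopifnot(is(config, "TruthConfig"))
  if (is.null(sites) || nrow(sites) == 0L) stop("site list is empty")
  if (liveTime <= 0) stop("liveTime must be positive")
  sfCar <- lookupFactor(config@sfCarbody, sites$campaign, "sfCarbody")
  sfAsp <- lookupFactor(config@sfAsphalt, sites$region, "sfAsphalt")
  outside <- sites$dDirect / config@dcf
  inside <- outside / sfCar
  asphalt <- outside
  bare <- asphalt * sfAsp
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    draw <- function(e) rpois(length(e), e * liveTime) / liveTime
    inside <- draw(inside); outside <- draw(outside)
    asphalt <- draw(asphalt); bare <- draw(bare)
  }
  data.frame(site = sites$site, campaign = sites$campaign, region = sites$region,
             insideCps = inside, outsideCps = outside,
             asphaltCps = asphalt, bareCps = bare, stringsAsFactors = FALSE)
}

lookupFactor <- function(tab, key, what) {
  if (length(tab) == 1L && is.null(names(tab))) return(rep(tab, length(key)))
  if (length(tab) == 1L && all(!key %in% names(tab))) return(rep(unname(tab), length(key)))
  miss <- setdiff(unique(key), names(tab))
  if (length(miss))
    stop(sprintf("no %s truth configured for: %s", what, paste(miss, collapse = ", ")))
  unname(tab[key])
}

#' Build a survey route through the generated sites
#'
#' Piecewise-linear interpolation along the site sequence, giving `n`
#' equally spaced route points (one per 30-s interval).
#'
#' @param sites [generateSites()] output.
#' @param n number of route points.
#' @return data.frame with `lat`, `lon`.
#' @export
makeSurveyRoute <- function(sites, n) {
  stopifnot(nrow(sites) >= 2L, n >= 2L)
  t0 <- seq_len(nrow(sites))
  tq <- seq(1, nrow(sites), length.out = n)
  data.frame(lat = approx(t0, sites$lat, tq)$y, lon = approx(t0, sites$lon, tq)$y)
}

#' Simulate a car-borne survey track
#'
#' One count-rate record per 30-s interval along the route. The local true
#' dose rate is the direct-field truth of the nearest site; the expected
#' inside-car count rate is `D_air / (DCF x SF_carbody x SF_asphalt)`, so
#' that the dose-reconstruction model applied to the noise-free track
#' returns the field exactly. Counts over each interval are Poisson
#' (`cps x interval`, then divided by the interval) unless `noise = FALSE`.
#'
#' @param route data.frame with `lat`, `lon` (>= 2 points).
#' @param sites [generateSites()] output defining the dose field.
#' @param config a [TruthConfig-class].
#' @param interval counting interval (s, default 30).
#' @param noise Poisson noise flag.
#' @param seed optional seed.
#' @param start first record timestamp (POSIXct or ISO string, UTC).
#' @return data.frame: `timestamp` (ISO 8601), `lat`, `lon`, `cps`,
#'   `campaign`, `region`, `dTrue`.
#' @export
simulateTrack <- function(route, sites, config, interval = 30, noise = TRUE,
                          seed = NULL, start = "2015-08-01T00:00:00Z") {
  stopifnot(is(config, "TruthConfig"))
  if (is.null(route) || nrow(route) < 2L) stop("route must contain at least 2 points")
  nearest <- nearestSiteIndex(route$lat, route$lon, sites$lat, sites$lon)
  campaign <- sites$campaign[nearest]
  region <- sites$region[nearest]
  dTrue <- sites$dDirect[nearest]
  sfCar <- lookupFactor(config@sfCarbody, campaign, "sfCarbody")
  sfAsp <- lookupFactor(config@sfAsphalt, region, "sfAsphalt")
  cpsExp <- dTrue / (config@dcf * sfCar * sfAsp)
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    cps <- rpois(length(cpsExp), cpsExp * interval) / interval
  } else cps <- cpsExp
  t0 <- as.POSIXct(sub("Z$", "", sub("T", " ", start)), tz = "UTC")
  stamps <- format(t0 + interval * (seq_along(cps) - 1), "%Y-%m-%dT%H:%M:%SZ")
  data.frame(timestamp = stamps, lat = route$lat, lon = route$lon, cps = cps,
             campaign = campaign, region = region, dTrue = dTrue,
             stringsAsFactors = FALSE)
}

nearestSiteIndex <- function(lat, lon, siteLat, siteLon) {
  vapply(seq_along(lat), function(i) {
    which.min((siteLat - lat[i])^2 + (siteLon - lon[i])^2)
  }, integer(1))
}

#' Expected HPGe net peak areas
#'
#' `area = activity x emission probability x efficiency(E) x liveTime x
#' mass` for each library line.
#'
#' @param activity an [ActivityTriplet-class] (soil concentrations).
#' @param curve an [EfficiencyCurve-class].
#' @param liveTime live time (s).
#' @param mass sample mass (kg).
#' @param lines line library (default [hpgeLineLibrary()]).
#' @return data.frame with `nuclide`, `series`, `energy`, `area`.
#' @export
hpgeExpectedAreas <- function(activity, curve, liveTime, mass,
                              lines = hpgeLineLibrary()) {
  stopifnot(is(activity, "ActivityTriplet"), is(curve, "EfficiencyCurve"))
  if (liveTime <= 0 || mass <= 0) stop("liveTime and mass must be positive")
  a <- activities(activity)
  act <- c(U = unname(a["u"]), Th = unname(a["th"]), K = unname(a["k"]))
  eff <- vapply(lines$energy, function(e) efficiencyAt(curve, e), numeric(1))
  data.frame(nuclide = lines$nuclide, series = lines$series, energy = lines$energy,
             area = act[lines$series] * lines$probability * eff * liveTime * mass,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate an HPGe soil spectrum
#'
#' Gaussian photopeaks at the library lines with expected net areas from
#' [hpgeExpectedAreas()], each sitting on a flat Compton continuum below its
#' Compton edge (continuum counts = `continuumRatio` x peak counts), Poisson
#' sampled unless `noise = FALSE`.
#'
#' @inheritParams hpgeExpectedAreas
#' @param channels channel count (default 4096).
#' @param gain keV per channel (default 0.5).
#' @param fwhm function of energy (keV) returning FWHM in keV; default
#'   `1.2 + 5e-4 * E`, a typical coaxial-HPGe resolution trend.
#' @param continuumRatio continuum-to-peak count ratio per line (default 0.4).
#' @param noise Poisson noise flag.
#' @param seed optional seed.
#' @return A [PulseHeightSpectrum-class] with calibration `c(0, gain)`.
#' @export
simulateHpgeSpectrum <- function(activity, curve, liveTime, mass,
                                 lines = hpgeLineLibrary(), channels = 4096L,
                                 gain = 0.5, fwhm = function(e) 1.2 + 5e-4 * e,
                                 continuumRatio = 0.4, noise = TRUE, seed = NULL) {
  areas <- hpgeExpectedAreas(activity, curve, liveTime, mass, lines)
  edges <- (0:channels) * gain  # keV
  expected <- numeric(channels)
  for (i in seq_len(nrow(areas))) {
    E <- areas$energy[i]
    A <- areas$area[i]
    if (A <= 0) next
    sig <- fwhm(E) / (2 * sqrt(2 * log(2)))
    expected <- expected + A * diff(pnorm(edges, E, sig))
    ce <- 1000 * comptonEdge(E / 1000)
    contMass <- pmax(pmin(edges[-1], ce) - pmin(edges[-length(edges)], ce), 0) / ce
    expected <- expected + A * continuumRatio * contMass
  }
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    counts <- rpois(channels, expected)
  } else counts <- expected
  pulseHeightSpectrum(counts, liveTime, calibration = c(0, gain))
}
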