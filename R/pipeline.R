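# End-to-end survey pipeline: simulate -> unfold -> calibrate -> carborne ->
# soil assay -> assess -> report, as a configured, logged, reproducible run.

#' Default pipeline run configuration
#'
#' All tunables of a pipeline run in one inspectable list. The defaults
#' reproduce the study design at desk scale: 462 fixed-point sites, 10-min
#' fixed-point NaI spectra, 2-min paired shielding measurements, 30,000-s
#' HPGe soil assays and a 1,000-record car-borne track.
#'
#' @param outDir output directory for tables and the manifest.
#' @param seed run seed; identical config + seed reproduces every output
#'   byte for byte.
#' @param nSites number of fixed-point sites.
#' @param nTrackRecords number of 30-s track records.
#' @param truth a [TruthConfig-class] (default [truthConfig()]).
#' @param naiLiveTime fixed-point NaI live time (s).
#' @param pairedLiveTime paired-measurement counting time (s).
#' @param hpgeLiveTime,hpgeMass HPGe live time (s) and sample mass (kg).
#' @param simulate generate synthetic inputs (`TRUE`) or read them from
#'   `inputs` (`FALSE`).
#' @param inputs list of input paths when `simulate = FALSE`: `track`,
#'   `paired`, `naiDir` (directory of per-site SPE files), `hpgeDir`.
#' @param grid list: `enabled`, `spacing` (deg), `maskRadius` (cells).
#' @param verbose print stage banners.
#' @return config list.
#' @export
defaultRunConfig <- function(outDir = tempfile("radsurvey_run"), seed = 20150801,
                             nSites = 462L, nTrackRecords = 1000L,
                             truth = truthConfig(), naiLiveTime = 600,
                             pairedLiveTime = 120, hpgeLiveTime = 30000,
                             hpgeMass = 0.12, simulate = TRUE, inputs = list(),
                             grid = list(enabled = TRUE, spacing = 0.5, maskRadius = 3),
                             verbose = FALSE) {
  list(outDir = outDir, seed = seed, nSites = as.integer(nSites),
       nTrackRecords = as.integer(nTrackRecords), truth = truth,
       naiLiveTime = naiLiveTime, pairedLiveTime = pairedLiveTime,
       hpgeLiveTime = hpgeLiveTime, hpgeMass = hpgeMass,
       simulate = isTRUE(simulate), inputs = inputs, grid = grid,
       verbose = isTRUE(verbose))
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields override [defaultRunConfig()]; the generating truth can be
#' customised through a `truth:` mapping whose keys are [truthConfig()]
#' arguments (region table excluded).
#'
#' @param path YAML file.
#' @return config list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  truthArgs <- y$truth %||% list()
  y$truth <- NULL
  cfg <- do.call(defaultRunConfig, y[intersect(names(y), names(formals(defaultRunConfig)))])
  cfg$truth <- do.call(truthConfig, truthArgs)
  cfg
}

pipelineStage <- function(name, config, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop(errorCondition(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                        class = c("pipelineStageError", "error", "condition")))
  })
  if (config$verbose)
    message(sprintf("[%s] done in %.1f s", name, proc.time()[["elapsed"]] - t0))
  res
}

writeTable <- function(x, outDir, name) {
  path <- file.path(outDir, name)
  write.csv(x, path, row.names = FALSE)
  path
}

tripletToRow <- function(a) {
  v <- activities(a); u <- activityUncertainties(a)
  data.frame(u = v[["u"]], th = v[["th"]], k = v[["k"]],
             uSd = u[["u"]], thSd = u[["th"]], kSd = u[["k"]])
}

#' Run the full survey pipeline
#'
#' Executes the stages in dependency order — simulate (or load), NaI
#' unfolding of the fixed-point spectra, calibration fitting, car-borne
#' dose reconstruction, HPGe soil assay, hazard assessment, and regional
#' reporting — writing every stage's table under `config$outDir` together
#' with a `manifest.json` recording the config hash, seed, package version
#' and output checksums. Identical config and seed reproduce identical
#' outputs.
#'
#' @param config a config list from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @return (invisibly) list with the in-memory tables (`sites`, `paired`,
#'   `calibration`, `track`, `direct`, `soil`, `assessment`, summaries) and
#'   `manifest`.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  truth <- config$truth
  set.seed(config$seed)
  outputs <- character()

  # --- simulate or load --------------------------------------------------
  if (config$simulate) {
    sim <- pipelineStage("simulate", config, {
      sites <- generateSites(truth, config$nSites, seed = NULL)
      paired <- simulatePairedCounts(sites, truth, liveTime = config$pairedLiveTime)
      naiSpectra <- lapply(seq_len(nrow(sites)), function(i)
        simulateNaiSpectrum(sites[i, ], config$naiLiveTime, truth))
      curve <- defaultEfficiencyCurve()
      hpgeSpectra <- lapply(seq_len(nrow(sites)), function(i)
        simulateHpgeSpectrum(activityTriplet(sites$soilU[i], sites$soilTh[i], sites$soilK[i]),
                             curve, config$hpgeLiveTime, config$hpgeMass))
      route <- makeSurveyRoute(sites, config$nTrackRecords)
      track <- simulateTrack(route, sites, truth)
      list(sites = sites, paired = paired, naiSpectra = naiSpectra,
           hpgeSpectra = hpgeSpectra, track = track, curve = curve)
    })
    outputs["sites.csv"] <- writeTable(sim$sites, config$outDir, "sites.csv")
  } else {
    sim <- pipelineStage("load", config, {
      inp <- config$inputs
      track <- if (!is.null(inp$track)) readTrackCsv(inp$track) else NULL
      paired <- if (!is.null(inp$paired)) read.csv(inp$paired, stringsAsFactors = FALSE) else NULL
      list(sites = NULL, paired = paired, naiSpectra = NULL, hpgeSpectra = NULL,
           track = track, curve = defaultEfficiencyCurve())
    })
  }

  # --- unfold fixed-point NaI spectra ------------------------------------
  direct <- pipelineStage("unfold", config, {
    spectra <- sim$naiSpectra
    ids <- sim$sites$site
    if (is.null(spectra)) {
      dirIn <- config$inputs$naiDir
      if (is.null(dirIn) || !dir.exists(dirIn))
        stop("spectra directory not found: ", dirIn %||% "<unset>")
      files <- list.files(dirIn, pattern = "\\.spe$", full.names = TRUE)
      if (length(files) == 0L) stop("no SPE files in ", dirIn)
      spectra <- lapply(files, readSpe)
      ids <- sub("\\.spe$", "", basename(files))
    }
    resp <- buildResponseMatrix(resolution = truth@resolution,
                                continuumFraction = truth@continuumFraction)
    rows <- lapply(seq_along(spectra), function(i) {
      pr <- processNaiSpectrum(spectra[[i]], resp)
      cbind(site = ids[i], tripletToRow(pr$activities),
            doseNgyH = pr$dose, cosmicRate = pr$cosmicRate,
            residual = pr$residual)
    })
    do.call(rbind, rows)
  })
  outputs["activities_direct.csv"] <- writeTable(direct, config$outDir, "activities_direct.csv")

  # --- calibration --------------------------------------------------------
  paired <- sim$paired
  calibration <- pipelineStage("calibrate", config, {
    paired$doseNgyH <- direct$doseNgyH[match(paired$site, direct$site)]
    # asphalt shielding is region-specific (roadbed construction differs),
    # so each region gets its own calibration fit
    if ("region" %in% names(paired)) estimateCalibration(paired, by = "region")
    else estimateCalibration(paired)
  })
  outputs["paired.csv"] <- writeTable(paired, config$outDir, "paired.csv")
  calList <- if (is(calibration, "CalibrationSet")) list(all = calibration) else calibration
  calTab <- do.call(rbind, lapply(names(calList), function(g) {
    cs <- calList[[g]]
    data.frame(group = g, factor = names(cs@factors), value = unname(cs@factors),
               sd = unname(cs@uncertainty), n = unname(cs@n))
  }))
  outputs["calibration.csv"] <- writeTable(calTab, config$outDir, "calibration.csv")

  # --- car-borne reconstruction -------------------------------------------
  track <- pipelineStage("carborne", config,
                         reconstructDose(sim$track, calibration,
                                         by = if (is(calibration, "CalibrationSet")) "campaign"
                                              else "region"))
  outputs["track_dose.csv"] <- writeTable(track, config$outDir, "track_dose.csv")

  # --- HPGe soil assay -----------------------------------------------------
  soil <- pipelineStage("soil", config, {
    spectra <- sim$hpgeSpectra
    ids <- sim$sites$site
    if (is.null(spectra)) {
      dirIn <- config$inputs$hpgeDir
      if (is.null(dirIn) || !dir.exists(dirIn))
        stop("spectra directory not found: ", dirIn %||% "<unset>")
      files <- list.files(dirIn, pattern = "\\.spe$", full.names = TRUE)
      spectra <- lapply(files, readSpe)
      ids <- sub("\\.spe$", "", basename(files))
    }
    rows <- lapply(seq_along(spectra), function(i) {
      a <- assaySoilSpectrum(spectra[[i]], sim$curve, config$hpgeMass)
      cbind(site = ids[i], tripletToRow(a), dSoil = doseFromSoil(a))
    })
    do.call(rbind, rows)
  })
  outputs["activities_soil.csv"] <- writeTable(soil, config$outDir, "activities_soil.csv")

  # --- hazard assessment ---------------------------------------------------
  assessment <- pipelineStage("assess", config, {
    dNames <- c(u = "uDirect", th = "thDirect", k = "kDirect")
    dTrip <- direct[, c("site", "u", "th", "k", "doseNgyH")]
    names(dTrip)[2:4] <- dNames
    m <- merge(soil[, c("site", "u", "th", "k")], dTrip, by = "site", sort = TRUE)
    a <- assessHazard(m[, c("u", "th", "k")], dDirect = m$doseNgyH)
    names(a)[names(a) == "raeq"] <- "raeqSoil"
    names(a)[names(a) == "hex"] <- "hexSoil"
    a$raeqDirect <- radiumEquivalent(as.matrix(setNames(m[, dNames], c("u", "th", "k"))))
    a$hexDirect <- externalHazardIndex(as.matrix(setNames(m[, dNames], c("u", "th", "k"))))$value
    cbind(site = m$site,
          region = if (!is.null(sim$sites)) sim$sites$region[match(m$site, sim$sites$site)]
                   else NA_character_, a)
  })
  outputs["assessment.csv"] <- writeTable(assessment, config$outDir, "assessment.csv")

  # --- report ---------------------------------------------------------------
  report <- pipelineStage("report", config, {
    withAll <- function(df) rbind(df, transform(df, region = "all"))
    av <- withAll(assessment)
    sumOf <- function(value) summarizeByRegion(av, value, "region")
    qty <- c("dDirect", "dSoil", "raeqSoil", "hexSoil", "raeqDirect", "hexDirect",
             "iaedSoil", "oaedSoil", "totalSoil",
             "iaedDirect", "oaedDirect", "totalDirect", "ratio")
    long <- do.call(rbind, lapply(qty, function(q) cbind(quantity = q, sumOf(q))))
    n <- nrow(assessment)
    hexCdf <- rbind(
      data.frame(method = "direct", value = sort(assessment$hexDirect),
                 fraction = seq_len(n) / n),
      data.frame(method = "soil", value = sort(assessment$hexSoil),
                 fraction = seq_len(n) / n))
    list(summary = long, hexCdf = hexCdf,
         hexFractionBelow = mean(assessment$hexDirect < assessment$hexSoil))
  })
  outputs["summary.csv"] <- writeTable(report$summary, config$outDir, "summary.csv")
  outputs["hex_cdf.csv"] <- writeTable(report$hexCdf, config$outDir, "hex_cdf.csv")

  # --- optional dose-rate grid ---------------------------------------------
  if (isTRUE(config$grid$enabled) && !is.null(track)) {
    gridPath <- pipelineStage("grid", config, {
      g <- gridMinimumCurvature(data.frame(lon = track$lon, lat = track$lat,
                                           value = track$doseNgyH),
                                spacing = config$grid$spacing %||% 0.5,
                                maskRadius = config$grid$maskRadius %||% 3)
      writeAsciiGrid(g, file.path(config$outDir, "dose_grid.asc"))
    })
    outputs["dose_grid.asc"] <- gridPath
  }

  # --- manifest --------------------------------------------------------------
  manifest <- pipelineStage("manifest", config, {
    cfgJson <- jsonlite::toJSON(configFingerprint(config), auto_unbox = TRUE, digits = NA)
    tmp <- tempfile(); writeLines(cfgJson, tmp)
    m <- list(package = "radsurvey",
              version = as.character(packageVersion("radsurvey")),
              seed = config$seed,
              configHash = unname(tools::md5sum(tmp)),
              outputs = lapply(outputs, function(p) list(
                file = basename(p), md5 = unname(tools::md5sum(p)))))
    unlink(tmp)
    path <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
  })

  invisible(list(sites = sim$sites, paired = paired, calibration = calibration,
                 track = track, direct = direct, soil = soil,
                 assessment = assessment, summary = report$summary,
                 hexCdf = report$hexCdf, hexFractionBelow = report$hexFractionBelow,
                 manifest = manifest,
                 outputs = outputs))
}

# a JSON-serialisable view of the config (truth object flattened); volatile
# fields (output location, verbosity) are excluded so the hash identifies
# the scientific configuration only
configFingerprint <- function(config) {
  cfg <- config
  cfg$outDir <- NULL
  t <- cfg$truth
  cfg$truth <- list(regions = t@regions, sfCarbody = as.list(t@sfCarbody),
                    sfAsphalt = as.list(t@sfAsphalt), dcf = t@dcf,
                    cosmicRate = t@cosmicRate, resolution = t@resolution,
                    gain = t@gain, channels = t@channels,
                    continuumFraction = t@continuumFraction,
                    builtUp = t@builtUp, seed = t@seed)
  cfg$verbose <- NULL
  cfg
}

#' Validate survey input files
#'
#' Schema, unit-range, timestamp-monotonicity and coordinate checks on the
#' pipeline's input files; report-only (never throws for content problems).
#'
#' @param paths named list of paths to check: any of `track`, `paired`
#'   (CSV), `spe` (character vector of SPE files), `boundaries` (GeoJSON).
#' @return data.frame with columns `file`, `row`, `level`
#'   (`"error"`/`"warning"`) and `message`; zero rows when everything is
#'   well-formed.
#' @export
validateInputs <- function(paths) {
  report <- data.frame(file = character(), row = integer(), level = character(),
                       message = character(), stringsAsFactors = FALSE)
  add <- function(file, row, level, message) {
    report[nrow(report) + 1L, ] <<- list(file, as.integer(row), level, message)
  }
  if (!is.null(paths$track)) {
    f <- paths$track
    tr <- tryCatch(readTrackCsv(f), error = function(e) {
      add(f, NA, "error", conditionMessage(e)); NULL })
    if (!is.null(tr)) {
      need <- c("timestamp", "lat", "lon", "cps")
      miss <- setdiff(need, names(tr))
      if (length(miss)) add(f, NA, "error", paste("missing columns:", paste(miss, collapse = ", ")))
      else {
        bad <- which(tr$lat < -90 | tr$lat > 90)
        for (i in bad) add(f, i, "error", sprintf("latitude %.3f outside [-90, 90]", tr$lat[i]))
        bad <- which(tr$lon < -180 | tr$lon > 180)
        for (i in bad) add(f, i, "error", sprintf("longitude %.3f outside [-180, 180]", tr$lon[i]))
        bad <- which(tr$cps < 0)
        for (i in bad) add(f, i, "error", "negative count rate")
        ts <- suppressWarnings(as.POSIXct(sub("Z$", "", sub("T", " ", tr$timestamp)), tz = "UTC"))
        if (any(is.na(ts))) add(f, which(is.na(ts))[1], "error", "unparseable timestamp")
        else if (any(diff(as.numeric(ts)) < 0))
          add(f, which(diff(as.numeric(ts)) < 0)[1] + 1L, "error", "timestamps not monotone")
      }
    }
  }
  if (!is.null(paths$paired)) {
    f <- paths$paired
    pr <- tryCatch(read.csv(f, stringsAsFactors = FALSE), error = function(e) {
      add(f, NA, "error", conditionMessage(e)); NULL })
    if (!is.null(pr)) {
      need <- c("insideCps", "outsideCps")
      miss <- setdiff(need, names(pr))
      if (length(miss)) add(f, NA, "error", paste("missing columns:", paste(miss, collapse = ", ")))
      else {
        for (cn in intersect(c("insideCps", "outsideCps", "asphaltCps", "bareCps"), names(pr)))
          for (i in which(pr[[cn]] < 0)) add(f, i, "error", paste("negative", cn))
      }
    }
  }
  for (f in paths$spe %||% character()) {
    tryCatch(readSpe(f), error = function(e) add(f, NA, "error", conditionMessage(e)))
  }
  if (!is.null(paths$boundaries)) {
    f <- paths$boundaries
    tryCatch(readRegionBoundaries(f), error = function(e) add(f, NA, "error", conditionMessage(e)))
  }
  report
}
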