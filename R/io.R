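# File formats: SPE-style spectra, track/paired/activity CSV tables,
# GeoJSON region boundaries and ESRI ASCII grids.

#' Write a spectrum as an SPE-style text file
#'
#' Plain-text blocks: `$MEAS_TIM:` (live and real seconds), `$DATA:`
#' (first/last channel followed by one count per line) and, when the
#' spectrum is calibrated, `$ENER_FIT:` (offset and gain in keV).
#'
#' @param spectrum a [PulseHeightSpectrum-class].
#' @param path output file path.
#' @export
writeSpe <- function(spectrum, path) {
  stopifnot(is(spectrum, "PulseHeightSpectrum"))
  counts <- spectrumCounts(spectrum)
  lt <- liveTime(spectrum)
  lines <- c("$MEAS_TIM:",
             sprintf("%s %s", format(lt), format(lt)),
             "$DATA:",
             sprintf("0 %d", length(counts) - 1L),
             format(counts, trim = TRUE, scientific = FALSE))
  if (isCalibrated(spectrum)) {
    cal <- energyCalibration(spectrum)
    lines <- c(lines, "$ENER_FIT:", sprintf("%.6f %.6f", cal[1], cal[2]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an SPE-style spectrum file
#'
#' @param path path to a file written in the layout of [writeSpe()].
#' @return A [PulseHeightSpectrum-class].
#' @export
readSpe <- function(path) {
  txt <- readLines(path, warn = FALSE)
  tags <- grep("^\\$", txt)
  block <- function(tag) {
    i <- grep(paste0("^\\$", tag, ":"), txt)
    if (length(i) == 0L) return(NULL)
    nxt <- tags[tags > i[1]]
    end <- if (length(nxt)) min(nxt) - 1L else length(txt)
    txt[(i[1] + 1L):end]
  }
  mt <- block("MEAS_TIM")
  if (is.null(mt)) stop("SPE file has no $MEAS_TIM block: ", path)
  lt <- as.numeric(strsplit(trimws(mt[1]), "\\s+")[[1]][1])
  dat <- block("DATA")
  if (is.null(dat) || length(dat) < 2L) stop("SPE file has no $DATA block: ", path)
  rng <- as.numeric(strsplit(trimws(dat[1]), "\\s+")[[1]])
  counts <- as.numeric(trimws(dat[-1]))
  counts <- counts[!is.na(counts)]
  if (length(counts) != rng[2] - rng[1] + 1)
    stop(sprintf("SPE $DATA length %d does not match declared range %d-%d: %s",
                 length(counts), rng[1], rng[2], path))
  bad <- which(counts < 0)
  if (length(bad))
    stop(sprintf("negative count in channel %d of %s", bad[1] - 1L + rng[1], path))
  ef <- block("ENER_FIT")
  cal <- if (!is.null(ef)) as.numeric(strsplit(trimws(ef[1]), "\\s+")[[1]])[1:2]
         else c(NA_real_, NA_real_)
  pulseHeightSpectrum(counts, lt, cal)
}

#' Read and write survey track tables
#'
#' Tracks are CSV with columns `timestamp` (ISO 8601), `lat`, `lon`, `cps`
#' and `campaign` (plus any extra columns, kept verbatim).
#'
#' @param track track data.frame.
#' @param path CSV path.
#' @export
writeTrackCsv <- function(track, path) {
  write.csv(track, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrackCsv
#' @export
readTrackCsv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read region boundaries from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon or MultiPolygon features in WGS84
#' lon-lat order; the region name is taken from the feature property
#' `name` (or `region`, or the feature `id`). Only outer rings are used.
#'
#' @param path GeoJSON file path.
#' @return named list of polygons (data.frames with `lon`, `lat`).
#' @export
readRegionBoundaries <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (f in feats) {
    nm <- f$properties$name %||% f$properties$region %||% f$id %||%
      paste0("region", length(out) + 1L)
    g <- f$geometry %||% f
    ringToDf <- function(ring) {
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      data.frame(lon = m[, 1], lat = m[, 2])
    }
    if (identical(g$type, "Polygon")) {
      out[[nm]] <- ringToDf(g$coordinates[[1]])
    } else if (identical(g$type, "MultiPolygon")) {
      # largest outer ring represents the region
      rings <- lapply(g$coordinates, function(poly) ringToDf(poly[[1]]))
      out[[nm]] <- rings[[which.max(vapply(rings, nrow, integer(1)))]]
    } else stop("unsupported GeoJSON geometry type: ", g$type)
  }
  if (length(out) == 0L) stop("no polygon features in ", path)
  out
}

#' Write a DoseGrid as an ESRI ASCII grid
#'
#' @param grid a [DoseGrid-class].
#' @param path output path (`.asc`).
#' @param nodata NODATA sentinel (default -9999).
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  stopifnot(is(grid, "DoseGrid"))
  v <- gridValues(grid)
  v[is.na(v)] <- nodata
  co <- gridCoordinates(grid)
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.6f", min(co$lon) - grid@spacing / 2),
           sprintf("yllcorner %.6f", min(co$lat) - grid@spacing / 2),
           sprintf("cellsize %.6f", grid@spacing),
           sprintf("NODATA_value %s", format(nodata)))
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
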