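# Regional aggregation: point-in-polygon region assignment, per-region
# summaries, and cumulative distributions of the hazard index.

# Even-odd rule point-in-polygon; polygon is a matrix with columns lon, lat.
pointInPolygon <- function(lon, lat, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (((yi > lat) != (yj > lat)) &&
        (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)) inside <- !inside
    j <- i
  }
  inside
}

# Minimum distance from a point to a polygon boundary (degrees,
# equirectangular treatment of small extents).
polygonDistance <- function(lon, lat, poly) {
  n <- nrow(poly)
  d2 <- Inf
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else max(0, min(1, ((lon - ax) * vx + (lat - ay) * vy) / L2))
    px <- ax + t * vx; py <- ay + t * vy
    d2 <- min(d2, (lon - px)^2 + (lat - py)^2)
    j <- i
  }
  sqrt(d2)
}

#' Assign survey points to region polygons
#'
#' Point-in-polygon assignment (even-odd rule). Points inside no polygon
#' are attached to the nearest polygon boundary when that distance is
#' within `tolerance` degrees, otherwise flagged unassigned (`NA` region).
#'
#' @param points data.frame with `lat` and `lon` (WGS84 decimal degrees).
#' @param boundaries named list of polygons, each a matrix/data.frame with
#'   columns `lon`, `lat` (closed or open rings), e.g. from
#'   [readRegionBoundaries()].
#' @param tolerance nearest-boundary attachment tolerance in degrees.
#' @return the points with columns `region` (NA when unassigned) and
#'   `unassigned` (logical) appended.
#' @export
assignRegion <- function(points, boundaries, tolerance = 0.25) {
  if (length(boundaries) == 0L) stop("empty boundary set")
  if (is.null(names(boundaries)) || any(!nzchar(names(boundaries))))
    stop("boundaries must be a named list of polygons")
  polys <- lapply(boundaries, function(p) {
    p <- as.matrix(as.data.frame(p)[, c("lon", "lat")])
    storage.mode(p) <- "double"
    p
  })
  n <- nrow(points)
  region <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    hit <- names(polys)[vapply(polys, function(p)
      pointInPolygon(points$lon[i], points$lat[i], p), logical(1))]
    if (length(hit)) { region[i] <- hit[1]; next }
    d <- vapply(polys, function(p) polygonDistance(points$lon[i], points$lat[i], p),
                numeric(1))
    if (min(d) <= tolerance) region[i] <- names(polys)[which.min(d)]
  }
  points$region <- region
  points$unassigned <- is.na(region)
  points
}

#' Per-group summaries of survey records
#'
#' n, mean, sample SD, min and max per group; groups of one record carry an
#' `NA` SD sentinel. Ranges are computed on the unrounded values.
#'
#' @param records data.frame of records.
#' @param value name of the value column to summarise.
#' @param by name of the grouping column.
#' @return data.frame with one row per group: `group`, `n`, `mean`, `sd`,
#'   `min`, `max`, ordered by first appearance.
#' @export
summarizeByRegion <- function(records, value, by) {
  if (is.null(records) || nrow(records) == 0L) stop("no records to summarise")
  if (!value %in% names(records)) stop("no column named '", value, "'")
  if (!by %in% names(records)) stop("no grouping column named '", by, "'")
  g <- factor(records[[by]], levels = unique(records[[by]]))
  if (all(is.na(g))) stop("empty group set")
  v <- records[[value]]
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    x <- v[which(g == lev)]
    data.frame(group = lev, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) sd(x) else NA_real_,
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Empirical cumulative distribution, with paired below-unity fraction
#'
#' Right-continuous empirical CDF with step fractions `k/n` at the sorted
#' values. Given a paired two-column input `(direct, soil)`, additionally
#' reports the fraction of pairs with direct strictly below soil — the
#' quantity read off paired hazard-index distributions.
#'
#' @param values numeric vector, or a two-column matrix/data.frame of
#'   `(direct, soil)` pairs.
#' @return list with `values` (sorted), `fraction` (k/n), and — for paired
#'   input — `fractionBelow` plus the two marginal CDFs `direct`, `soil`.
#' @export
cumulativeDistribution <- function(values) {
  one <- function(x) {
    x <- sort(x)
    list(values = x, fraction = seq_along(x) / length(x))
  }
  if (is.matrix(values) || is.data.frame(values)) {
    if (ncol(values) != 2L) stop("paired input must have two columns (direct, soil)")
    values <- as.data.frame(values)
    d <- as.numeric(values[[1]])
    s <- as.numeric(values[[2]])
    if (length(d) == 0L) stop("empty input")
    c(one(c(d, s))[1:2],
      list(fractionBelow = mean(d < s), direct = one(d), soil = one(s)))
  } else {
    if (length(values) == 0L) stop("empty input")
    one(values)
  }
}
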