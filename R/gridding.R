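# Minimum-curvature gridding of scattered dose-rate data, the interpolation
# used to turn track records into a smooth dose-rate surface.

#' Grid scattered data with a minimum-curvature surface
#'
#' Interpolates scattered `(lon, lat, value)` data onto a regular grid as
#' the smoothest (discrete biharmonic) surface passing through the data:
#' grid cells holding data are constrained to the (cell-averaged) datum
#' value and the free cells are relaxed iteratively (conjugate gradients on
#' the normal equations of the constrained biharmonic system) until the
#' largest cell update falls below `tol`. `tension` blends in a harmonic (membrane)
#' term, `(1 - tension) * biharmonic - tension * laplacian = 0`; the default
#' 0 is pure minimum curvature, which reproduces linear fields exactly.
#' Cells farther than `maskRadius` cells from any datum are masked `NA` in
#' the returned values (the full surface is kept alongside).
#'
#' @param points data.frame with `lon`, `lat` and a value column (third
#'   column, or named `value`).
#' @param spacing grid spacing in degrees (default 0.1).
#' @param tension tension parameter in `[0, 1)`.
#' @param maskRadius mask distance in cells (default 3).
#' @param tol convergence tolerance on the largest cell update, relative to
#'   the data range (default 1e-10).
#' @param maxIter iteration cap; non-convergence raises a warning of class
#'   `gridConvergenceWarning` carrying the residual.
#' @param omega retained for interface stability; unused by the conjugate
#'   gradient relaxation.
#' @param allowDegenerate permit fewer than 3 data points (the surface then
#'   degenerates to a constant/linear fit through what is available).
#' @return A [DoseGrid-class].
#' @export
gridMinimumCurvature <- function(points, spacing = 0.1, tension = 0,
                                 maskRadius = 3, tol = 1e-10, maxIter = 100000L,
                                 omega = 1.5, allowDegenerate = FALSE) {
  stopifnot(spacing > 0, tension >= 0, tension < 1)
  pts <- as.data.frame(points)
  vcol <- if ("value" %in% names(pts)) "value" else names(pts)[3]
  lon <- pts$lon; lat <- pts$lat; val <- pts[[vcol]]
  keep <- is.finite(lon) & is.finite(lat) & is.finite(val)
  lon <- lon[keep]; lat <- lat[keep]; val <- val[keep]
  if (length(val) < 3L) {
    if (!allowDegenerate)
      stop("need at least 3 data points for a non-degenerate surface")
  } else if (!allowDegenerate) {
    # collinearity check: rank of centred coordinates
    if (qr(cbind(lon - mean(lon), lat - mean(lat)))$rank < 2L)
      stop("data points are collinear; surface is degenerate")
  }
  lonAxis <- seq(floor(min(lon) / spacing) * spacing,
                 ceiling(max(lon) / spacing) * spacing, by = spacing)
  latAxis <- seq(floor(min(lat) / spacing) * spacing,
                 ceiling(max(lat) / spacing) * spacing, by = spacing)
  if (length(lonAxis) < 2L) lonAxis <- c(lonAxis, lonAxis + spacing)
  if (length(latAxis) < 2L) latAxis <- c(latAxis, latAxis + spacing)
  nr <- length(latAxis); nc <- length(lonAxis)
  ii <- pmin(pmax(round((lat - latAxis[1]) / spacing) + 1L, 1L), nr)
  jj <- pmin(pmax(round((lon - lonAxis[1]) / spacing) + 1L, 1L), nc)
  cell <- (jj - 1L) * nr + ii
  fixedVal <- tapply(val, cell, mean)
  u <- matrix(mean(val), nr, nc)
  fixed <- matrix(FALSE, nr, nc)
  idx <- as.integer(names(fixedVal))
  u[idx] <- fixedVal
  fixed[idx] <- TRUE
  if (sum(fixed) == 1L) {
    surface <- matrix(u[idx], nr, nc)  # constant surface at the datum
    res <- list(surface = surface, iterations = 0L, maxUpdate = 0,
                residual = 0, converged = TRUE)
  } else {
    scale <- max(diff(range(val)), abs(mean(val)), 1)
    res <- .relaxMinCurv(u, fixed, tension, tol * scale, as.integer(maxIter), omega)
    if (!res$converged)
      warning(warningCondition(
        sprintf("minimum-curvature relaxation did not converge in %d iterations (max residual %.3g)",
                res$iterations, res$residual),
        class = c("gridConvergenceWarning", "warning", "condition")))
  }
  # mask: chebyshev cell distance to the nearest datum cell
  dist <- matrix(Inf, nr, nc)
  for (k in seq_along(idx)) {
    i0 <- (idx[k] - 1L) %% nr + 1L
    j0 <- (idx[k] - 1L) %/% nr + 1L
    di <- abs(row(dist) - i0); dj <- abs(col(dist) - j0)
    dist <- pmin(dist, pmax(di, dj))
  }
  values <- res$surface
  values[dist > maskRadius] <- NA_real_
  new("DoseGrid", lon = lonAxis, lat = latAxis, values = values,
      surface = res$surface, spacing = spacing)
}
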