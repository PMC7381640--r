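# Independent oracles used across the suite.

# Dense direct solve of the discretised constrained biharmonic problem:
# 5-point natural-BC Laplacian composed twice, planar corner closure, data
# rows replaced by identities. Built as an explicit matrix and solved with
# base::solve — independent of the package's iterative relaxation.
denseMinCurvSolve <- function(nr, nc, fixedIdx, fixedVal, tension = 0) {
  N <- nr * nc
  id <- function(i, j) (j - 1) * nr + i
  L <- matrix(0, N, N)
  for (i in 1:nr) for (j in 1:nc) {
    r <- id(i, j)
    if (i > 1 && i < nr) {
      L[r, id(i - 1, j)] <- L[r, id(i - 1, j)] + 1
      L[r, id(i + 1, j)] <- L[r, id(i + 1, j)] + 1
      L[r, r] <- L[r, r] - 2
    }
    if (j > 1 && j < nc) {
      L[r, id(i, j - 1)] <- L[r, id(i, j - 1)] + 1
      L[r, id(i, j + 1)] <- L[r, id(i, j + 1)] + 1
      L[r, r] <- L[r, r] - 2
    }
  }
  B <- (1 - tension) * (L %*% L) - tension * L
  corners <- rbind(c(1, 1, 2, 2), c(1, nc, 2, nc - 1),
                   c(nr, 1, nr - 1, 2), c(nr, nc, nr - 1, nc - 1))
  for (k in 1:4) {
    r <- id(corners[k, 1], corners[k, 2])
    B[r, ] <- 0
    B[r, id(corners[k, 1], corners[k, 2])] <- 1
    B[r, id(corners[k, 3], corners[k, 2])] <- -1
    B[r, id(corners[k, 1], corners[k, 4])] <- -1
    B[r, id(corners[k, 3], corners[k, 4])] <- 1
  }
  b <- rep(0, N)
  for (k in seq_along(fixedIdx)) {
    r <- fixedIdx[k]
    B[r, ] <- 0
    B[r, r] <- 1
    b[r] <- fixedVal[k]
  }
  matrix(solve(B, b), nr, nc)
}

# Brute-force non-negative least squares by active-set enumeration: try
# every subset of variables, solve the unconstrained least squares on the
# subset, keep feasible candidates, return the best. Exponential — tiny
# problems only.
bruteForceNnls <- function(A, b) {
  n <- ncol(A)
  best <- NULL
  bestRss <- Inf
  for (mask in 0:(2^n - 1)) {
    on <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    x <- numeric(n)
    if (length(on)) {
      sol <- tryCatch(qr.solve(A[, on, drop = FALSE], b), error = function(e) NULL)
      if (is.null(sol) || any(sol < 0)) next
      x[on] <- sol
    }
    rss <- sum((A %*% x - b)^2)
    if (rss < bestRss - 1e-12) {
      bestRss <- rss
      best <- x
    }
  }
  list(x = best, rss = bestRss)
}

# Winding-number point-in-polygon oracle (independent of the package's
# even-odd ray casting).
windingNumberInside <- function(lon, lat, poly) {
  n <- nrow(poly)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    if (y1 <= lat) {
      if (y2 > lat && ((x2 - x1) * (lat - y1) - (lon - x1) * (y2 - y1)) > 0) wn <- wn + 1
    } else {
      if (y2 <= lat && ((x2 - x1) * (lat - y1) - (lon - x1) * (y2 - y1)) < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# One-pass streaming summary oracle (Welford) for mean/sd/min/max.
streamingSummary <- function(x) {
  n <- 0; mean <- 0; m2 <- 0; mn <- Inf; mx <- -Inf
  for (v in x) {
    n <- n + 1
    d <- v - mean
    mean <- mean + d / n
    m2 <- m2 + d * (v - mean)
    mn <- min(mn, v); mx <- max(mx, v)
  }
  list(n = n, mean = mean, sd = if (n > 1) sqrt(m2 / (n - 1)) else NA_real_,
       min = mn, max = mx)
}

# Quadratic-fit peak locator on a dense grid (oracle for smoothing-based
# peak finding): parabola through all points within +-w of the max.
densePeakFit <- function(counts, w = 5L) {
  m <- which.max(counts)
  x <- max(1, m - w):min(length(counts), m + w)
  fit <- lm(counts[x] ~ x + I(x^2))
  b <- coef(fit)
  -b[2] / (2 * b[3])
}

# Shared small fixtures -------------------------------------------------------

smallTruthConfig <- function(...) {
  truthConfig(...)
}
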