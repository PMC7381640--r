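# Regional aggregation, cumulative distributions and gridding.

regionFixture <- function() {
  readRegionBoundaries(system.file("extdata", "survey_regions_synthetic.geojson",
                                   package = "radsurvey"))
}

test_that("points land in their polygons; far points stay unassigned", {
  b <- regionFixture()
  centroid <- data.frame(lat = 20, lon = 105)  # inside the northern box
  out <- assignRegion(centroid, b)
  expect_equal(out$region, "north")
  far <- assignRegion(data.frame(lat = 45, lon = 10), b)
  expect_true(far$unassigned)
  near <- assignRegion(data.frame(lat = 23.1, lon = 105), b, tolerance = 0.25)
  expect_equal(near$region, "north")
  expect_error(assignRegion(centroid, list()), "empty boundary")
})

test_that("region assignment matches a winding-number oracle on random points", {
  b <- regionFixture()
  set.seed(33)
  pts <- data.frame(lat = runif(1000, 7, 24), lon = runif(1000, 101, 111))
  out <- assignRegion(pts, b, tolerance = 0)
  for (i in seq_len(nrow(pts))) {
    oracle <- NA_character_
    for (nm in names(b)) {
      if (windingNumberInside(pts$lon[i], pts$lat[i], as.matrix(b[[nm]])))
        oracle <- nm
    }
    expect_identical(out$region[i], oracle)
  }
})

test_that("summaries match a streaming one-pass oracle and use the n=1 sentinel", {
  rec <- data.frame(g = c("a", "a", "a", "b"), v = c(10, 20, 30, 71))
  s <- summarizeByRegion(rec, "v", "g")
  expect_equal(s$mean, c(20, 71))
  expect_equal(s$sd, c(10, NA))
  expect_equal(s$min, c(10, 71))
  expect_equal(s$max, c(30, 71))
  # permutation invariance + streaming oracle on larger data
  set.seed(34)
  rec2 <- data.frame(g = sample(c("x", "y"), 200, TRUE), v = rnorm(200, 75, 30))
  s2 <- summarizeByRegion(rec2, "v", "g")
  perm <- rec2[sample(nrow(rec2)), ]
  s2p <- summarizeByRegion(perm, "v", "g")
  s2p <- s2p[match(s2$group, s2p$group), ]
  expect_equal(s2$mean, s2p$mean)
  for (grp in s2$group) {
    o <- streamingSummary(rec2$v[rec2$g == grp])
    row <- s2[s2$group == grp, ]
    expect_equal(row$n, o$n)
    expect_equal(row$mean, o$mean)
    expect_equal(row$sd, o$sd)
    expect_equal(c(row$min, row$max), c(o$min, o$max))
  }
  # a single group equals the ungrouped totals
  one <- summarizeByRegion(transform(rec2, g = "all"), "v", "g")
  expect_equal(one$mean, mean(rec2$v))
  expect_error(summarizeByRegion(rec2[0, ], "v", "g"), "no records")
})

test_that("empirical CDF steps at k/n and reports the paired fraction", {
  cd <- cumulativeDistribution(c(3, 1, 2))
  expect_equal(cd$values, c(1, 2, 3))
  expect_equal(cd$fraction, c(1, 2, 3) / 3)
  paired <- data.frame(direct = c(1, 5, 2, 2), soil = c(2, 4, 3, 2))
  pc <- cumulativeDistribution(paired)
  expect_equal(pc$fractionBelow, 0.5)  # strict: ties do not count
  expect_equal(cumulativeDistribution(data.frame(d = 1:4, s = 1:4))$fractionBelow, 0)
  expect_error(cumulativeDistribution(numeric(0)), "empty")
})

test_that("a below-unity fraction planted at 65% is recovered from pairs", {
  cfg <- truthConfig(builtUp = list(enabled = TRUE, sdlog = 0.25,
                                    fractionBelow = 0.65, range = c(0.5, 2.1)))
  s <- generateSites(cfg, 462, seed = 35)
  # same-composition pairs: the built-up multiplier is the only difference
  base <- 0.43 * s$directU + 0.666 * s$directTh + 0.042 * s$directK
  pc <- cumulativeDistribution(data.frame(direct = s$dDirect, soil = base))
  tol <- 3 * sqrt(0.65 * 0.35 / 462)
  expect_lt(abs(pc$fractionBelow - 0.65), tol)
})

test_that("gridding matches the dense biharmonic solve within 1e-6", {
  set.seed(36)
  pts <- data.frame(lon = runif(5, 0.05, 0.65), lat = runif(5, 0.05, 0.65),
                    value = runif(5, 40, 160))
  g <- gridMinimumCurvature(pts, spacing = 0.1, tol = 1e-13, maskRadius = 99)
  co <- gridCoordinates(g)
  nr <- length(co$lat); nc <- length(co$lon)
  ii <- round((pts$lat - min(co$lat)) / 0.1) + 1
  jj <- round((pts$lon - min(co$lon)) / 0.1) + 1
  fv <- tapply(pts$value, (jj - 1) * nr + ii, mean)
  oracle <- denseMinCurvSolve(nr, nc, as.integer(names(fv)), as.numeric(fv))
  expect_lt(max(abs(gridSurface(g) - oracle)), 1e-6)
  # data cells reproduce their data
  expect_equal(gridSurface(g)[as.integer(names(fv))], as.numeric(fv))
  # tension blends towards the membrane solution, still matching the oracle
  gt <- gridMinimumCurvature(pts, spacing = 0.1, tension = 0.4, tol = 1e-13,
                             maskRadius = 99)
  ot <- denseMinCurvSolve(nr, nc, as.integer(names(fv)), as.numeric(fv), tension = 0.4)
  expect_lt(max(abs(gridSurface(gt) - ot)), 1e-6)
})

test_that("minimum curvature reproduces planes exactly", {
  plane <- function(lon, lat) 3 + 10 * lon - 4 * lat
  pts <- data.frame(lon = c(0, 0.6, 0.1, 0.5, 0.3), lat = c(0, 0.1, 0.6, 0.5, 0.2))
  pts$value <- plane(pts$lon, pts$lat)
  g <- gridMinimumCurvature(pts, spacing = 0.1, tol = 1e-13, maskRadius = 99)
  co <- gridCoordinates(g)
  truth <- outer(co$lat, co$lon, function(la, lo) plane(lo, la))
  expect_lt(max(abs(gridSurface(g) - truth)), 1e-7)
})

test_that("gridding is translation-equivariant and masks remote cells", {
  set.seed(37)
  pts <- data.frame(lon = runif(6, 0, 1), lat = runif(6, 0, 1),
                    value = runif(6, 50, 100))
  g0 <- gridMinimumCurvature(pts, spacing = 0.2, tol = 1e-12, maskRadius = 1)
  g1 <- gridMinimumCurvature(transform(pts, value = value + 55),
                             spacing = 0.2, tol = 1e-12, maskRadius = 1)
  expect_equal(gridSurface(g1), gridSurface(g0) + 55, tolerance = 1e-6)
  expect_identical(is.na(gridValues(g1)), is.na(gridValues(g0)))
  # a wide grid with radius-1 mask must hide something beyond the data
  wide <- gridMinimumCurvature(rbind(pts, data.frame(lon = 3, lat = 3, value = 75)),
                               spacing = 0.2, tol = 1e-10, maskRadius = 1)
  expect_true(any(is.na(gridValues(wide))))
  expect_false(any(is.na(gridSurface(wide))))
})

test_that("degenerate inputs: single datum gives a constant surface", {
  g <- gridMinimumCurvature(data.frame(lon = 5, lat = 5, value = 42),
                            allowDegenerate = TRUE)
  expect_equal(unique(as.numeric(gridSurface(g))), 42)
  expect_error(gridMinimumCurvature(data.frame(lon = 1:2, lat = c(1, 1),
                                               value = c(1, 2))),
               "at least 3")
  expect_error(gridMinimumCurvature(data.frame(lon = 1:3, lat = 1:3, value = 1:3)),
               "collinear")
})
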