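# Exact 5th-order edge: z(s) with known coefficients, straight x/y.
polyEdgePoints <- function(n = 60, coefZ = c(0.1, -0.4, 2, -1.5, 0.8, 0.3),
                           noiseSD = 0, seed = 1) {
  set.seed(seed)
  s <- seq(0.1, 0.9, length.out = n)
  V <- outer(s, 0:5, `^`)
  data.frame(s = s, x_mm = 40 * s, y_mm = rep(1, n),
             z_mm = as.vector(V %*% coefZ) + rnorm(n, sd = noiseSD))
}

test_that("exact 5th-order polynomials are recovered to machine precision", {
  coefZ <- c(0.1, -0.4, 2, -1.5, 0.8, 0.3)
  fit <- fitEdgePolynomial(polyEdgePoints(coefZ = coefZ))
  expect_equal(as.vector(fit$coefficients[, "z_mm"]), coefZ,
               tolerance = 1e-9)
  expect_lt(fit$residualRMS["z_mm"], 1e-10)
})

test_that("residual RMS tracks the injected noise floor", {
  sigma <- 0.05
  fit <- fitEdgePolynomial(polyEdgePoints(n = 200, noiseSD = sigma, seed = 2))
  expect_gte(fit$residualRMS[["z_mm"]], 0.8 * sigma)
  expect_lte(fit$residualRMS[["z_mm"]], 1.2 * sigma)
})

test_that("underdetermined edge fits are rejected", {
  pts <- polyEdgePoints(n = 5)
  expect_error(fitEdgePolynomial(pts), "at least 6")
})

test_that("surface reconstruction is 80 x 50 with linear chordwise interpolation", {
  lead <- fitEdgePolynomial(polyEdgePoints(coefZ = c(0, 0, 2, 0, 0, 0)))
  trail <- fitEdgePolynomial(polyEdgePoints(coefZ = c(0.5, 1, 0, 0, 0, 0)))
  surf <- reconstructSurface(lead, trail)
  expect_equal(dim(surf$points), c(80, 50, 3))
  # midchord z = mean of the edge z at each station
  zmid <- (surf$points[, 1, 3] + surf$points[, 50, 3]) / 2
  iMid <- 25  # w = 24/49; use exact interpolation formula instead
  w <- seq(0, 1, length.out = 50)
  zq <- surf$points[, 1, 3] * (1 - w[25]) + surf$points[, 50, 3] * w[25]
  expect_equal(surf$points[, 25, 3], zq, tolerance = 1e-12)
  expect_equal((surf$points[, 1, 3] + surf$points[, 50, 3]) / 2, zmid,
               tolerance = 1e-12)
  # flat edges give a flat surface
  flat <- fitEdgePolynomial(polyEdgePoints(coefZ = rep(0, 6)))
  expect_equal(max(abs(reconstructSurface(flat, flat)$points[, , 3])), 0,
               tolerance = 1e-12)
})

# Hand-built surfaces for the metric tests (odd chord count puts a grid
# point exactly at midchord).
flatSurface <- function(nSpan = 40, nChord = 51, span = 40, chord = 10) {
  s <- seq(0.1, 0.9, length.out = nSpan)
  y <- seq(0, chord, length.out = nChord)
  pts <- array(0, c(nSpan, nChord, 3))
  pts[, , 1] <- matrix(s * span, nSpan, nChord)
  pts[, , 2] <- matrix(y, nSpan, nChord, byrow = TRUE)
  list(points = pts, s = s)
}

test_that("rest-equal surfaces give zero bend and zero twist", {
  rest <- flatSurface()
  met <- deformationMetrics(list(rest, rest), rest)
  expect_equal(met$bendAmplitude, c(0, 0))
  expect_equal(max(abs(met$twist)), 0)
})

test_that("a rigid 10-degree chord rotation reads as 10 degrees of twist", {
  rest <- flatSurface()
  rot <- rest
  chord <- 10; mid <- chord / 2
  y <- rest$points[1, , 2]
  ang <- 10 * pi / 180
  rot$points[, , 2] <- matrix(mid + (y - mid) * cos(ang),
                              dim(rest$points)[1], dim(rest$points)[2],
                              byrow = TRUE)
  rot$points[, , 3] <- matrix((y - mid) * sin(ang),
                              dim(rest$points)[1], dim(rest$points)[2],
                              byrow = TRUE)
  met <- deformationMetrics(list(rot), rest)
  expect_equal(as.vector(met$twist), rep(10, ncol(met$twist)),
               tolerance = 1e-6)
  expect_equal(met$bendAmplitude, 0, tolerance = 1e-9)  # midchord pivot
})

test_that("a planar 40-degree arc yields stroke angles in [-40, 40] degrees", {
  rest <- flatSurface()
  n <- 400
  phi <- 40 * pi / 180 * sin(seq(0, 4 * pi, length.out = n))
  R <- 38
  tips <- cbind(R * cos(phi), R * sin(phi), 0)
  met <- deformationMetrics(rep(list(rest), n), rest, wingtipTrack = tips)
  expect_lt(abs(max(met$strokeAngle) - 40), 0.1)
  expect_lt(abs(min(met$strokeAngle) + 40), 0.1)
  expect_error(deformationMetrics(list(rest), rest,
                                  wingtipTrack = matrix(1, 1, 3)),
               "stationary")
})

test_that("edge traces -> polynomial fit -> surface recovers the generating bend", {
  g <- wingGrid(5, 21, span = 40, chord = 10)
  A <- 1.5
  f <- analyticField(g, function(x, y) A * (x / max(g@x))^2, nFrames = 1)
  tr <- synthEdgeTraces(f)
  lead <- fitEdgePolynomial(tr[tr$edge == "L", c("s", "x_mm", "y_mm", "z_mm")])
  trail <- fitEdgePolynomial(tr[tr$edge == "T", c("s", "x_mm", "y_mm", "z_mm")])
  surf <- reconstructSurface(lead, trail)
  expect_equal(surf$points[, 1, 3], A * surf$s^2,
               tolerance = max(1e-9, 2 * lead$residualRMS[["z_mm"]]))
})
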