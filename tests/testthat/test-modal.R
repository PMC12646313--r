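test_that("a rank-1 field is fully captured by one component", {
  g <- tinyGrid()
  m <- modalModel(modes = "bend", frequencies = 170, rms = 1,
                  harmonicWeights = 0, noiseSD = 0, seed = 2)
  f <- synthDisplacementField(g, m, duration = 0.3, fs = 2000)
  dec <- fitModes(f, 1)
  expect_equal(varianceFractions(dec)[1], 1, tolerance = 1e-9)
})

test_that("noiseless orthogonal modes are recovered shape-for-shape", {
  g <- tinyGrid(rows = 8, cols = 16)
  m <- modalModel(rms = c(5, 3, 1), noiseSD = 0, seed = 3)
  f <- synthDisplacementField(g, m, duration = 2, fs = 2000)
  dec <- fitModes(f, 3)
  tr <- groundTruth(f)
  # compare on the basis bins: normalize truth shapes to unit L2
  for (j in 1:3) {
    v <- tr$shapes[, j] / sqrt(sum(tr$shapes[, j]^2))
    cs <- abs(sum(v * modeShapes(dec)[, j]))
    expect_gte(cs, 0.999)
  }
})

test_that("fit invariants hold: orthonormal shapes, ordered fractions, uncorrelated scores", {
  f <- quickFlutterField(seed = 4, duration = 1)
  dec <- fitModes(f, 3)
  G <- crossprod(modeShapes(dec))
  expect_lt(max(abs(G - diag(3))), 1e-8)
  vf <- varianceFractions(dec)
  expect_true(all(diff(vf) <= 1e-12))
  expect_lte(sum(vf), 1 + 1e-9)
  cv <- cov(modeScores(dec))
  expect_lt(max(abs(cv[upper.tri(cv)])) / min(diag(cv)), 1e-6)
})

test_that("projection is idempotent on the training field and linear in shapes", {
  f <- quickFlutterField(seed = 5, duration = 0.5)
  dec <- fitModes(f, 3)
  sc <- projectScores(f, dec)
  expect_equal(sc, modeScores(dec), tolerance = 1e-9, ignore_attr = TRUE)
  g <- gridGeometry(f)
  # field equal to the stored mean -> all scores zero
  Xm <- matrix(NA_real_, 4, g@rows * g@cols)
  Xm[, dec@binIndex] <- matrix(dec@center, 4, length(dec@binIndex), byrow = TRUE)
  fm <- deformationField(Xm, g, fs = frameRate(f))
  expect_equal(max(abs(projectScores(fm, dec))), 0, tolerance = 1e-9)
  # mean + 2 * shape1 -> scores (2, 0, 0)
  X1 <- Xm
  X1[, dec@binIndex] <- X1[, dec@binIndex] +
    matrix(2 * modeShapes(dec)[, 1], 4, length(dec@binIndex), byrow = TRUE)
  f1 <- deformationField(X1, g, fs = frameRate(f))
  sc1 <- projectScores(f1, dec)
  expect_equal(sc1[1, ], c(2, 0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  # grid mismatch errors
  g2 <- wingGrid(g@rows, g@cols, span = 2 * max(g@x))
  f2 <- deformationField(fieldData(f), g2, fs = frameRate(f))
  expect_error(projectScores(f2, dec), "grid")
})

test_that("reconstruction is complete for a full-rank basis and Parseval holds", {
  g <- tinyGrid(rows = 4, cols = 6)
  f <- quickFlutterField(seed = 6, duration = 0.2, fs = 2000, grid = g)
  B <- sum(g@mask)
  full <- fitModes(f, B)
  rec <- reconstructField(modeScores(full), full)
  expect_equal(fieldData(rec)[, full@binIndex],
               fieldData(f)[, full@binIndex], tolerance = 1e-9)
  # zero scores -> mean field
  rec0 <- reconstructField(matrix(0, 1, B), full)
  expect_equal(fieldData(rec0)[1, full@binIndex], full@center,
               tolerance = 1e-12, ignore_attr = TRUE)
  # residual variance of a k-mode truncation = discarded variance
  k <- 3
  recK <- reconstructField(modeScores(full)[, 1:k, drop = FALSE], full,
                           modes = 1:k)
  resid <- fieldData(f)[, full@binIndex] - fieldData(recK)[, full@binIndex]
  residVar <- sum(apply(resid, 2, var))
  expected <- sum(varianceFractions(full)[-(1:k)]) * full@totalVariance
  expect_equal(residVar, expected, tolerance = 1e-6 * max(expected, 1e-12))
  expect_error(reconstructField(modeScores(full), full, modes = B + 1),
               "subset")
})

test_that("bins invalid in any frame are dropped from the basis", {
  g <- tinyGrid()
  f <- quickFlutterField(seed = 7, duration = 0.1, fs = 2000, grid = g)
  X <- fieldData(f)
  badBin <- which(g@mask)[5]
  X[3, badBin] <- NA
  f2 <- deformationField(X, g, fs = frameRate(f))
  dec <- fitModes(f2, 3)
  expect_false(badBin %in% binIndices(dec))
})

test_that("added white noise raises the top-k variance deficit by its share", {
  g <- tinyGrid(rows = 6, cols = 10)
  m <- modalModel(modes = c("bend", "twist"), frequencies = c(170, 170),
                  rms = c(2, 1.2), harmonicWeights = c(0, 0), noiseSD = 0,
                  seed = 8)
  f <- synthDisplacementField(g, m, duration = 6, fs = 2000)  # 12,000 frames
  vBin <- 0.01  # per-bin noise variance, mm^2
  set.seed(99)
  X <- fieldData(f)
  mask <- as.vector(g@mask)
  X[, mask] <- X[, mask] + matrix(rnorm(nrow(X) * sum(mask), sd = sqrt(vBin)),
                                  nrow(X))
  dec <- fitModes(deformationField(X, g, fs = frameRate(f)), 2)
  deficit <- 1 - sum(varianceFractions(dec))
  B <- sum(mask)
  expected <- (B - 2) * vBin / dec@totalVariance
  expect_lt(abs(deficit - expected) / expected, 0.2)
})
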