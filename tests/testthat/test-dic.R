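# Interior bin centers for a reference texture.
dicCenters <- function(W, Hh, margin = 15, nx = 5, ny = 4) {
  as.matrix(expand.grid(x = round(seq(margin, W - margin, length.out = nx)),
                        y = round(seq(margin, Hh - margin, length.out = ny))))
}

shiftImage <- function(img, dx, dy) {
  # sample img at (x - dx, y - dy) via the package's bilinear warp so
  # subpixel shifts are well-defined
  Hh <- nrow(img); W <- ncol(img)
  pts <- cbind(rep(seq_len(W), each = Hh) - dx, rep(seq_len(Hh), W) - dy)
  matrix(aeronerve:::bilinearSample(img, pts[, 1], pts[, 2]), Hh, W)
}

test_that("identical frames give zero displacement with unit correlation", {
  img <- speckleTexture(90, 70, seed = 2)
  res <- dicDisplacementField(img, img, dicCenters(90, 70), subsetSize = 11,
                              searchRadius = 6)
  expect_true(all(res$valid))
  expect_equal(res$cc, rep(1, nrow(res)), tolerance = 1e-12)
  expect_equal(max(abs(c(res$u, res$v))), 0, tolerance = 1e-9)
})

test_that("an imposed integer shift is recovered within 0.05 px", {
  img <- speckleTexture(90, 70, seed = 3)
  cur <- shiftImage(img, 4, 0)
  res <- dicDisplacementField(img, cur, dicCenters(90, 70), subsetSize = 11,
                              searchRadius = 7)
  expect_true(all(res$valid))
  expect_lt(max(abs(res$u - 4)), 0.05)
  expect_lt(max(abs(res$v)), 0.05)
})

test_that("a 0.5 px subpixel shift is recovered within 0.1 px and flat regions are flagged", {
  img <- speckleTexture(90, 70, seed = 4)
  img[25:45, 35:60] <- 128  # textureless patch
  cur <- shiftImage(img, 0.5, 0)
  centers <- rbind(dicCenters(90, 70), c(47, 35))  # last center inside patch
  res <- dicDisplacementField(img, cur, centers, subsetSize = 11,
                              searchRadius = 5)
  inPatch <- nrow(centers)
  expect_false(res$valid[inPatch])
  ok <- res$valid[-inPatch]
  expect_true(all(ok))
  expect_lt(max(abs(res$u[-inPatch][ok] - 0.5)), 0.1)
})

test_that("shifting both frames identically changes no estimate", {
  img <- speckleTexture(100, 80, seed = 5)
  cur <- shiftImage(img, 2, 1)
  ctr <- dicCenters(100, 80)
  r1 <- dicDisplacementField(img, cur, ctr, 11, 6)
  r2 <- dicDisplacementField(shiftImage(img, 3, 0), shiftImage(cur, 3, 0),
                             ctr, 11, 6)
  expect_equal(r1$u[r1$valid & r2$valid], r2$u[r1$valid & r2$valid],
               tolerance = 0.05)
  expect_equal(r1$v[r1$valid & r2$valid], r2$v[r1$valid & r2$valid],
               tolerance = 0.05)
})

test_that("degenerate DIC parameters are rejected", {
  img <- speckleTexture(40, 30, seed = 1)
  ctr <- dicCenters(40, 30, margin = 10, nx = 2, ny = 2)
  expect_error(dicDisplacementField(img, img, ctr, 11, searchRadius = 0),
               "search radius")
  expect_error(dicDisplacementField(img, img, ctr, 10, 5), "odd")
  expect_error(dicDisplacementField(img, img, ctr, 51, 5), "larger than frame")
  expect_equal(dicSubsetSize(10000), 11)  # sqrt(0.01 * 1e4) = 10 -> odd 11
})

test_that("plane-fit strain matches analytic gradients and kills rigid motion", {
  g <- wingGrid(6, 12, span = 11, chord = 5)
  bc <- binCenters(g)
  # rigid translation
  U <- matrix(rep(0.7, nrow(bc)), 1)
  st <- fieldData(strainFromDisplacement(U, g))[1, ]
  expect_equal(max(abs(st), na.rm = TRUE), 0, tolerance = 1e-12)
  # linear: u = 0.01 x
  U <- matrix(0.01 * bc$x_mm, 1)
  st <- fieldData(strainFromDisplacement(U, g))[1, ]
  expect_equal(st[!is.na(st)], rep(0.01, sum(!is.na(st))), tolerance = 1e-10,
               ignore_attr = TRUE)
  # quadratic: u = a x^2 -> strain 2 a x at interior bins
  a <- 0.002
  U <- matrix(a * bc$x_mm^2, 1)
  st <- fieldData(strainFromDisplacement(U, g))[1, ]
  interior <- bc$col > 1 & bc$col < g@cols & bc$row > 1 & bc$row < g@rows
  expect_equal(st[interior] / (2 * a * bc$x_mm[interior]),
               rep(1, sum(interior)), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("an all-invalid frame yields all-invalid strain", {
  g <- wingGrid(5, 8)
  U <- matrix(NA_real_, 2, 40)
  st <- fieldData(strainFromDisplacement(U, g))
  expect_true(all(is.na(st)))
})
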