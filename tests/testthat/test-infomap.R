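test_that("self-coherence is unity at every frequency", {
  set.seed(1)
  x <- rnorm(3000)
  wc <- welchCoherence(x, x, fs = 1000)
  expect_equal(wc$coherence, rep(1, length(wc$freq)), tolerance = 1e-9)
})

test_that("independent white noises sit near the 1/n_segments bias floor", {
  set.seed(2)
  n <- 2600  # ~50 Welch segments of 100 ms at 50% overlap
  wc <- welchCoherence(rnorm(n), rnorm(n), fs = 1000)
  floorC <- mean(wc$coherence)
  expect_gt(floorC, 0.5 / wc$nSegments)
  expect_lt(floorC, 2 / wc$nSegments)
})

test_that("a flat-SNR linear channel gives C = SNR / (1 + SNR)", {
  set.seed(3)
  n <- 60000
  x <- rnorm(n)
  # pure-delay filter with gain 2, white noise at SNR = 3 across the band
  y <- 2 * c(numeric(3), x[1:(n - 3)]) + rnorm(n, sd = 2 / sqrt(3))
  wc <- welchCoherence(x, y, fs = 1000)
  inBand <- wc$freq >= 20 & wc$freq <= 480
  expect_equal(mean(wc$coherence[inBand]), 0.75, tolerance = 0.05)
})

test_that("halving the segment length lowers the independent-noise floor", {
  set.seed(4)
  n <- 6000
  x <- rnorm(n); y <- rnorm(n)
  f100 <- mean(welchCoherence(x, y, fs = 1000, segmentMs = 100)$coherence)
  f50 <- mean(welchCoherence(x, y, fs = 1000, segmentMs = 50)$coherence)
  expect_lt(f50, f100)
})

test_that("information rate matches closed forms and is monotone", {
  freq <- seq(0, 500, by = 10)
  expect_equal(informationRate(rep(0, length(freq)), freq), 0)
  expect_equal(informationRate(rep(0.5, length(freq)), freq), 500,
               tolerance = 1e-6 * 500)
  # C = 0.75 over 0-100 Hz, 0 elsewhere -> 200 bits/s
  f2 <- seq(0, 500, by = 1)
  C2 <- ifelse(f2 <= 100, 0.75, 0)
  expect_equal(informationRate(C2, f2), 200, tolerance = 1e-3 * 200)
  expect_error(informationRate(c(0.2, 1.5), c(0, 10)), "outside")
  # monotonicity under pointwise domination, random spectra
  set.seed(5)
  for (i in 1:20) {
    Ca <- runif(51, 0, 0.95)
    Cb <- pmin(Ca + runif(51, 0, 0.04), 0.999)
    expect_gte(informationRate(Cb, freq), informationRate(Ca, freq))
  }
})

test_that("coherence map rejects unreachable bands and short recordings", {
  g <- tinyGrid(rows = 4, cols = 6)
  f <- quickFlutterField(seed = 6, duration = 1, fs = 800, grid = g)
  sp <- rep(0, nFrames(f)); sp[seq(10, length(sp), by = 7)] <- 1
  expect_error(coherenceMap(sp, f, band = c(0, 500)), "Nyquist")
  fShort <- quickFlutterField(seed = 6, duration = 0.12, fs = 1000, grid = g)
  expect_error(coherenceMap(rep(0:1, 60), fShort), "2 segments")
})

test_that("per-bin invalid samples drop segments, not whole frames", {
  g <- tinyGrid(rows = 4, cols = 6)
  f <- quickFlutterField(seed = 7, duration = 3, fs = 1000, grid = g)
  X <- fieldData(f)
  b1 <- which(g@mask)[1]; b2 <- which(g@mask)[2]
  X[100:220, b1] <- NA          # a stretch of unresolved samples in one bin
  X[, b2] <- NA                 # a bin that never resolves
  f2 <- deformationField(X, g, fs = 1000)
  sp <- synthSpikeTrain(groundTruth(f)$scores, "bend",
                        spikeModel(seed = 8), fs = 1000)
  cm <- coherenceMap(sp, f2)
  expect_false(b2 %in% binIndices(cm))   # excluded entirely
  expect_true(b1 %in% binIndices(cm))    # kept with fewer segments
  expect_true(all(cm@coherence >= 0 & cm@coherence <= 1))
})

test_that("high-information regions select the top percentile with tie handling", {
  g <- wingGrid(10, 10)
  bins <- which(as.vector(g@mask))
  vals <- seq_len(100)  # distinct
  im <- highInformationRegions(vals, spikes = 50, percentile = 5,
                               grid = g, binIndex = bins, duration = 10)
  expect_equal(sum(highInfoMask(im)), 5)
  expect_setequal(which(highInfoMask(im)), 96:100)
  # normalized rate = rate / (spikes / duration)
  expect_equal(infoRatePerSpike(im), vals / 5)
  # uniform map: all bins tie and are all included
  expect_message(
    imu <- highInformationRegions(rep(1, 100), spikes = 50, percentile = 5,
                                  grid = g, binIndex = bins, duration = 10),
    "ties")
  expect_true(all(highInfoMask(imu)))
  expect_error(highInformationRegions(vals, spikes = 0, percentile = 5,
                                      grid = g, binIndex = bins,
                                      duration = 10), "zero spikes")
  expect_error(highInformationRegions(vals, spikes = 50, percentile = 20,
                                      grid = g, binIndex = bins,
                                      duration = 10), "percentile")
})

test_that("sensor matching ranks by local information with stable ties", {
  g <- wingGrid(10, 10, span = 9, chord = 9)
  bins <- which(as.vector(g@mask))
  vals <- seq_len(100)
  im <- highInformationRegions(vals, spikes = 50, percentile = 5,
                               grid = g, binIndex = bins, duration = 10)
  bc <- binCenters(g)
  argmaxBin <- bins[which.max(infoRatePerSpike(im))]
  sensors <- data.frame(
    sensor_id = c("s_argmax", "a_twin", "b_twin", "s_far"),
    x_mm = c(bc$x_mm[argmaxBin], bc$x_mm[98], bc$x_mm[98], bc$x_mm[3]),
    y_mm = c(bc$y_mm[argmaxBin], bc$y_mm[98], bc$y_mm[98], bc$y_mm[3]),
    side = "dorsal", vein = "v1")
  cand <- matchCandidateSensors(im, sensors)
  expect_equal(cand$sensor_id[cand$rank == 1 & !is.na(cand$rank)], "s_argmax")
  twins <- cand[cand$sensor_id %in% c("a_twin", "b_twin"), ]
  expect_equal(twins$bits_per_spike[1], twins$bits_per_spike[2])
  expect_equal(twins$sensor_id, c("a_twin", "b_twin"))  # id order on ties
  far <- cand[cand$sensor_id == "s_far", ]
  expect_false(far$in_region)
  expect_gt(far$dist_mm, 0)
  # sensors outside the grid are excluded with a warning
  out <- rbind(sensors, data.frame(sensor_id = "oob", x_mm = 99, y_mm = 0,
                                   side = "dorsal", vein = "v1"))
  expect_warning(cand2 <- matchCandidateSensors(im, out), "outside")
  expect_false("oob" %in% cand2$sensor_id)
  # no sensors inside the region -> no ranked candidates
  lone <- data.frame(sensor_id = "s_far", x_mm = bc$x_mm[3],
                     y_mm = bc$y_mm[3], side = "dorsal", vein = "v1")
  cand3 <- matchCandidateSensors(im, lone)
  expect_true(all(is.na(cand3$rank)))
})

test_that("one seeded localization run recovers the driving bin", {
  sc <- synthLocalizationScenario(seed = 42, duration = 30)
  cm <- coherenceMap(sc$spikes, sc$strain)
  im <- highInformationRegions(cm, sc$spikes, percentile = 5)
  expect_lte(localizationError(im, sc$trueBin), 2)
  cand <- matchCandidateSensors(im, sc$sensors)
  expect_equal(cand$sensor_id[which(cand$rank == 1)], "planted")
  # displacement and strain share one code path, distinguished by kind
  expect_equal(fieldKind(cm), "strain")
  cmD <- coherenceMap(sc$spikes, sc$field)
  expect_equal(fieldKind(cmD), "displacement")
})
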