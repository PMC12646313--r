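test_that("spike binning follows floor arithmetic and collapses duplicates", {
  v <- binSpikeTrain(numeric(), 1, 1000)
  expect_equal(sum(v), 0)
  expect_length(v, 1000)
  v <- binSpikeTrain(0.0105, 1, 1000)
  expect_equal(which(v == 1), 11L)  # frame floor(10.5) in 1-based indexing
  expect_message(v2 <- binSpikeTrain(c(0.0101, 0.0109), 1, 1000), "collapsed")
  expect_equal(which(v2 == 1), 11L)
  expect_equal(attr(v2, "collapsed"), 1L)
  expect_error(binSpikeTrain(1.0, 1, 1000), "duration")
  expect_error(binSpikeTrain(0.5, 1, 0), "fs")
})

test_that("cycle phases are exact on an analytic sinusoid", {
  fs <- 10000
  tt <- seq(0, 0.5, by = 1 / fs)
  score <- sin(2 * pi * 100 * tt)  # peaks at 2.5 ms + k * 10 ms
  # spike exactly at a peak
  cp <- cyclePhases(score, 0.0225, fs)
  expect_lt(abs(cp$theta), 2e-3)
  # spike 2.5 ms after a peak: one quarter cycle
  cp <- cyclePhases(score, 0.025, fs)
  expect_equal(cp$theta, 0.25, tolerance = 1e-3)
  expect_error(cyclePhases(tt, 0.1, fs), "peaks")
  # phases always wrapped to [0, 1)
  cpAll <- cyclePhases(score, seq(0.05, 0.45, by = 0.003), fs)
  expect_true(all(cpAll$theta >= 0 & cpAll$theta < 1))
})

test_that("vector strength reproduces hand-computed values", {
  expect_equal(vectorStrength(rep(0.3, 17)), 1)
  expect_equal(vectorStrength(c(0, 0.25, 0.5, 0.75)), 0, tolerance = 1e-12)
  expect_equal(vectorStrength(c(0, 0.25)), sqrt(2) / 2, tolerance = 1e-12)
  expect_error(vectorStrength(numeric()), "empty")
})

test_that("phase-locking classes use strict thresholds at 0.5 and 0.6", {
  expect_equal(classifyPhaseLocking(0.65), "strong")
  expect_equal(classifyPhaseLocking(0.55), "weak")
  expect_equal(classifyPhaseLocking(0.60), "weak")
  expect_equal(classifyPhaseLocking(0.50), "none")
  expect_error(classifyPhaseLocking(1.2), "\\[0, 1\\]")
})

test_that("empirical vector strength converges to the Bessel ratio", {
  # per-cycle von Mises spiking, N = 2000, three concentrations, 3 SE bands
  for (kappa in c(0.5, 2, 8)) {
    set.seed(round(10 * kappa))
    theta <- (rvonmises(2000, mu = 2 * pi * 0.3, kappa = kappa) / (2 * pi)) %% 1
    vs <- vectorStrength(theta)
    rho <- besselI(kappa, 1) / besselI(kappa, 0)
    expect_lt(abs(vs - rho), 3 * vonMisesVsSE(kappa, 2000) + 1e-6)
  }
})

test_that("STA recovers constructed locking and handles edge cases", {
  fs <- 1000
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  score <- sin(2 * pi * 125 * tt)          # exact sample peaks every 8 frames
  spikes <- numeric(length(tt))
  pk <- which(score > 1 - 1e-12)
  spikes[pk] <- 1
  sta <- spikeTriggeredAverage(score, spikes, fs, halfWindowMs = 25)
  i0 <- which(sta$lag_ms == 0)
  expect_equal(sta$sta[i0, 1], 1, tolerance = 0.01)
  # periodic at 125 Hz: +/- 8 ms lags return to the peak
  expect_equal(sta$sta[i0 + 8, 1], 1, tolerance = 0.01)
  expect_equal(sta$sta[i0 - 8, 1], 1, tolerance = 0.01)
  # unconditional average of a zero-mean series stays near zero
  set.seed(11)
  noise <- rnorm(4000)
  all1 <- rep(1, 4000)
  sta0 <- spikeTriggeredAverage(noise, all1, fs, halfWindowMs = 10)
  expect_lt(max(abs(sta0$sta)), 3 / sqrt(sta0$nSpikes))
  # a single spike returns its window exactly
  one <- numeric(200); one[100] <- 1
  sta1 <- spikeTriggeredAverage(noise[1:200], one, fs, halfWindowMs = 10)
  expect_equal(sta1$sta[, 1], noise[90:110], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sta1$nSpikes, 1)
  # truncated windows are excluded and counted
  edge <- numeric(200); edge[3] <- 1; edge[100] <- 1
  staE <- spikeTriggeredAverage(noise[1:200], edge, fs, halfWindowMs = 10)
  expect_equal(staE$nExcluded, 1)
  expect_error(spikeTriggeredAverage(noise[1:20], c(1, numeric(19)), fs, 25),
               "full window")
})

test_that("phase-amplitude profile is flat when the generator slope is zero", {
  set.seed(21)
  n <- 2000
  amps <- runif(n, 1, 4)
  theta <- (rvonmises(n, mu = 2 * pi * 0.3, kappa = 6) / (2 * pi)) %% 1
  prof <- phaseAmplitudeProfile(theta, amps)
  expect_equal(prof$lo[1], 1)
  expect_equal(prof$hi[nrow(prof)], 4)
  d <- outer(prof$meanPhase, prof$meanPhase,
             function(a, b) abs(aeronerve:::circularDiffCycles(a, b)))
  expect_lt(max(d), 0.05)
  expect_error(phaseAmplitudeProfile(theta, amps, edges = c(2, 1)),
               "increasing")
})

test_that("the pipeline-level exclusion rule keeps STA to phase-locked units", {
  # a unit with uniform phases is classed 'none' and must not be reported
  cfg <- list(duration = 2, synth = list(rows = 5L, cols = 8L),
              encode = list(kappa = 0))
  rep <- runPipeline(cfg, outputDir = withr::local_tempdir())
  expect_true(all(rep$vectorStrength$class == "none"))
  expect_null(rep[["sta"]])
})
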