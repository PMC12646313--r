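#' @include synth-field.R synth-spikes.R synth-edges.R infomap.R
NULL

#' Synthetic sensor-localization scenario
#'
#' End-to-end ground-truth scenario for the spatial-selectivity analysis: a
#' flutter-like displacement field (bend + twist at the working natural
#' frequency with slow amplitude modulation and measurement noise), its
#' spanwise strain field, and a unit whose spikes phase-lock to the strain
#' oscillation at one known "true" bin — the maximum-strain-RMS bin, where a
#' strain sensor would sit.  A sensor map with one sensor planted at the
#' true bin (plus background sensors) is included so candidate matching can
#' be scored.
#'
#' @param seed integer seed controlling field, spiking and sensor placement.
#' @param duration recording length, s (default 60).
#' @param fs frame rate, frames/s (default 1,000).
#' @param grid a [WingGrid-class] (default 12 x 20 bins).
#' @param kappa von Mises concentration of the unit (default 4).
#' @param noiseSD relative measurement-noise SD (fraction of field RMS).
#' @return list with `field`, `strain`, `spikes`, `trueBin` (column-major
#'   index), `sensors` (planted sensor id `"planted"`), `grid`.
#' @export
synthLocalizationScenario <- function(seed = 1L, duration = 60, fs = 1000,
                                      grid = wingGrid(12, 20), kappa = 4,
                                      noiseSD = 0.05) {
  model <- modalModel(modes = c("bend", "twist"), frequencies = c(170, 170),
                      rms = c(1.8, 1.1), harmonicWeights = c(0, 0),
                      amDepth = 0.6, amRateHz = 3,
                      noiseSD = noiseSD, noiseRelative = TRUE,
                      seed = seed)
  field <- synthDisplacementField(grid, model, duration, fs)
  strain <- synthStrainField(field)
  ## true bin: maximum strain RMS (clean signal), i.e. where the structural
  ## strain concentrates
  rms <- sqrt(colMeans(strain@data^2, na.rm = TRUE))
  trueBin <- which.max(ifelse(as.vector(grid@mask), rms, -Inf))
  spikes <- synthSpikeTrain(strain@data[, trueBin], model =
                              spikeModel(mu0 = 0.25, kappa = kappa, p = 0.9,
                                         beta = 0, refractory = 0.001,
                                         seed = seed + 10L),
                            fs = fs, unitId = "unit1")
  bc <- binCenters(grid)
  sensors <- synthSensorMap(grid, n = 30, proximalFraction = 0.7,
                            seed = seed + 20L)
  sensors <- rbind(
    data.frame(sensor_id = "planted", x_mm = bc$x_mm[trueBin],
               y_mm = bc$y_mm[trueBin], side = "dorsal", vein = "v0"),
    sensors)
  list(field = field, strain = strain, spikes = spikes, trueBin = trueBin,
       sensors = sensors, grid = grid)
}

#' Localization error of an information map
#'
#' Distance, in bin widths, between the argmax of the normalized information
#' rate and a reference bin.
#'
#' @param infoMap an [InformationMap-class].
#' @param trueBin column-major bin index of the ground-truth driving bin.
#' @return distance in bin units (`sqrt(drow^2 + dcol^2)` scaled by the grid
#'   spacings).
#' @export
localizationError <- function(infoMap, trueBin) {
  g <- infoMap@grid
  best <- infoMap@binIndex[which.max(infoMap@ratePerSpike)]
  a <- binRowCol(g, best); b <- binRowCol(g, trueBin)
  sqrt(as.numeric(a[, "row"] - b[, "row"])^2 +
       as.numeric(a[, "col"] - b[, "col"])^2)
}
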