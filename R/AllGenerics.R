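#' @include AllClasses.R
NULL

#' Accessors for aeronerve containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `frameRate()` (frames/s), `nFrames()`, `fieldData()` (frames x bins
#' matrix), `fieldKind()`, `gridGeometry()` (the [WingGrid-class]),
#' `groundTruth()` (generator sidecar list), `spikeTimes()` / `spikeFrames()`,
#' `modeShapes()` / `modeScores()` / `varianceFractions()`, and
#' `infoRate()` / `infoRatePerSpike()` / `highInfoMask()`.
#'
#' @param x an aeronerve object.
#' @return the slot contents documented above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("fieldData", function(x) standardGeneric("fieldData"))
#' @rdname accessors
#' @export
setGeneric("fieldKind", function(x) standardGeneric("fieldKind"))
#' @rdname accessors
#' @export
setGeneric("gridGeometry", function(x) standardGeneric("gridGeometry"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("spikeFrames", function(x) standardGeneric("spikeFrames"))
#' @rdname accessors
#' @export
setGeneric("modeShapes", function(x) standardGeneric("modeShapes"))
#' @rdname accessors
#' @export
setGeneric("modeScores", function(x) standardGeneric("modeScores"))
#' @rdname accessors
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))
#' @rdname accessors
#' @export
setGeneric("binIndices", function(x) standardGeneric("binIndices"))
#' @rdname accessors
#' @export
setGeneric("infoRate", function(x) standardGeneric("infoRate"))
#' @rdname accessors
#' @export
setGeneric("infoRatePerSpike", function(x) standardGeneric("infoRatePerSpike"))
#' @rdname accessors
#' @export
setGeneric("highInfoMask", function(x) standardGeneric("highInfoMask"))

setMethod("frameRate", "DeformationField", function(x) x@fs)
setMethod("frameRate", "SpikeTrain", function(x) x@fs)
setMethod("frameRate", "ModalDecomposition", function(x) x@fs)
setMethod("nFrames", "DeformationField", function(x) nrow(x@data))
setMethod("nFrames", "ModalDecomposition", function(x) nrow(x@scores))
setMethod("fieldData", "DeformationField", function(x) x@data)
setMethod("fieldKind", "DeformationField", function(x) x@kind)
setMethod("fieldKind", "CoherenceMap", function(x) x@fieldKind)
setMethod("gridGeometry", "DeformationField", function(x) x@grid)
setMethod("gridGeometry", "ModalDecomposition", function(x) x@grid)
setMethod("gridGeometry", "CoherenceMap", function(x) x@grid)
setMethod("gridGeometry", "InformationMap", function(x) x@grid)
setMethod("groundTruth", "DeformationField", function(x) x@truth)
setMethod("groundTruth", "SpikeTrain", function(x) x@truth)
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)
setMethod("spikeFrames", "SpikeTrain", function(x) x@frames)
setMethod("modeShapes", "ModalDecomposition", function(x) x@shapes)
setMethod("modeScores", "ModalDecomposition", function(x) x@scores)
setMethod("varianceFractions", "ModalDecomposition", function(x) x@varianceFractions)
setMethod("binIndices", "ModalDecomposition", function(x) x@binIndex)
setMethod("binIndices", "CoherenceMap", function(x) x@binIndex)
setMethod("binIndices", "InformationMap", function(x) x@binIndex)
setMethod("infoRate", "InformationMap", function(x) x@rate)
setMethod("infoRatePerSpike", "InformationMap", function(x) x@ratePerSpike)
setMethod("highInfoMask", "InformationMap", function(x) x@highMask)

setMethod("show", "WingGrid", function(object) {
  cat(sprintf("WingGrid: %d x %d bins (chord x span), %d in planform\n",
              object@rows, object@cols, sum(object@mask)))
  cat(sprintf("  span %.1f-%.1f mm, chord %.1f-%.1f mm\n",
              min(object@x), max(object@x), min(object@y), max(object@y)))
})

setMethod("show", "DeformationField", function(object) {
  cat(sprintf("DeformationField (%s): %d frames @ %g fps on %d x %d grid\n",
              object@kind, nrow(object@data), object@fs,
              object@grid@rows, object@grid@cols))
  v <- object@data[, object@grid@mask, drop = FALSE]
  cat(sprintf("  RMS %.4g, range [%.4g, %.4g]%s\n",
              sqrt(mean(v^2, na.rm = TRUE)), min(v, na.rm = TRUE),
              max(v, na.rm = TRUE),
              if (length(object@truth)) ", ground truth attached" else ""))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes over %.3g s (%.2f Hz), fs = %g\n",
              object@unitId, length(object@times), object@duration,
              length(object@times) / object@duration, object@fs))
})

setMethod("show", "ModalDecomposition", function(object) {
  vf <- object@varianceFractions
  cat(sprintf("ModalDecomposition: %d modes over %d bins, %d frames\n",
              ncol(object@shapes), length(object@binIndex), nrow(object@scores)))
  cat("  variance fractions:", paste(sprintf("%.4f", vf), collapse = " "),
      sprintf("(sum %.4f)\n", sum(vf)))
})

setMethod("show", "CoherenceMap", function(object) {
  cat(sprintf("CoherenceMap (%s): %d bins, %d frequencies (%g-%g Hz), %d segments\n",
              object@fieldKind, length(object@binIndex), length(object@freq),
              min(object@freq), max(object@freq), object@nSegments))
  cat(sprintf("  peak coherence max %.3f at %g Hz\n",
              max(object@peakCoherence, na.rm = TRUE),
              object@peakFrequency[which.max(object@peakCoherence)]))
})

setMethod("show", "InformationMap", function(object) {
  cat(sprintf("InformationMap: %d bins, top %.3g%% region = %d bins%s\n",
              length(object@binIndex), object@percentile, sum(object@highMask),
              if (object@tied) " (ties at cutoff)" else ""))
  cat(sprintf("  max %.3g bits/s, %.3g bits/spike\n",
              max(object@rate, na.rm = TRUE),
              max(object@ratePerSpike, na.rm = TRUE)))
})
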