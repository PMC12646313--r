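#' @include utils.R
NULL

#' WingGrid: spatial binning of the wing planform
#'
#' Regular grid of spatial bins covering the wing surface.  `x` holds the
#' spanwise coordinate of each column (mm, 0 at the wingbase, increasing
#' distally) and `y` the chordwise coordinate of each row (mm, 0 at the
#' leading edge, increasing toward the trailing edge).  `mask` marks bins
#' inside the wing planform.  Bins are indexed column-major, i.e. bin
#' `(row, col)` is element `row + (col - 1) * rows`.
#'
#' @slot rows integer, number of chordwise rows (>= 2).
#' @slot cols integer, number of spanwise columns (>= 2).
#' @slot x numeric of length `cols`, strictly increasing (mm).
#' @slot y numeric of length `rows`, strictly increasing (mm).
#' @slot mask logical `rows x cols` matrix, at least one `TRUE` bin.
#' @export
setClass("WingGrid",
  representation(rows = "integer", cols = "integer",
                 x = "numeric", y = "numeric", mask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@rows < 2L || object@cols < 2L)
      msg <- c(msg, "rows and cols must both be >= 2")
    if (length(object@x) != object@cols)
      msg <- c(msg, "length(x) must equal cols")
    if (length(object@y) != object@rows)
      msg <- c(msg, "length(y) must equal rows")
    if (any(diff(object@x) <= 0)) msg <- c(msg, "x must be strictly increasing")
    if (any(diff(object@y) <= 0)) msg <- c(msg, "y must be strictly increasing")
    if (!is.logical(object@mask) ||
        !identical(dim(object@mask), c(object@rows, object@cols)))
      msg <- c(msg, "mask must be a logical rows x cols matrix")
    else if (!any(object@mask)) msg <- c(msg, "mask must contain >= 1 TRUE bin")
    if (length(msg)) msg else TRUE
  })

#' DeformationField: time-resolved field on a wing grid
#'
#' Frames x bins matrix of dorsoventral displacement (mm, positive = dorsal)
#' or spanwise normal strain (unitless, tensile positive).  Bins outside the
#' grid mask, and bins that a measurement stage could not resolve, are `NA`;
#' downstream stages treat `NA` as invalid.  The `truth` list carries
#' generator ground truth (mode shapes, score series, driving bins) when the
#' field is synthetic, so recovery can be scored.
#'
#' @slot grid a [WingGrid-class].
#' @slot data numeric `frames x (rows*cols)` matrix (column-major bin order).
#' @slot fs sampling rate, frames/s.
#' @slot kind `"displacement"` (mm) or `"strain"` (unitless).
#' @slot truth list of generator ground truth (may be empty).
#' @export
setClass("DeformationField",
  representation(grid = "WingGrid", data = "matrix", fs = "numeric",
                 kind = "character", truth = "list"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@data) != object@grid@rows * object@grid@cols)
      msg <- c(msg, "data must have rows*cols columns")
    if (nrow(object@data) < 1L) msg <- c(msg, "field needs >= 1 frame")
    if (length(object@fs) != 1L || object@fs <= 0)
      msg <- c(msg, "fs must be a positive scalar")
    if (!object@kind %in% c("displacement", "strain"))
      msg <- c(msg, "kind must be 'displacement' or 'strain'")
    if (length(msg)) msg else TRUE
  })

#' ModalModel: structural-mode generative model for synthetic fields
#'
#' Defines the spatial modes (bend, twist, camber), their oscillation
#' frequencies, score RMS amplitudes, second-harmonic weights, slow amplitude
#' modulation, and per-bin measurement noise used by
#' [synthDisplacementField()].
#'
#' @slot modes character, subset of `c("bend", "twist", "camber")`, in order.
#' @slot frequencies numeric, Hz per mode (must stay below Nyquist).
#' @slot rms numeric, score RMS amplitude per mode (mm, >= 0).
#' @slot harmonicWeights numeric, relative weight of the 2nd harmonic per mode.
#' @slot amDepth amplitude-modulation depth in `[0, 1)`.
#' @slot amRateHz upper frequency of the slow modulation envelope (Hz).
#' @slot noiseSD measurement-noise SD (mm, >= 0).
#' @slot noiseRelative if `TRUE`, `noiseSD` is a fraction of the clean-field
#'   RMS rather than an absolute SD in mm.
#' @slot seed integer RNG seed.
#' @export
setClass("ModalModel",
  representation(modes = "character", frequencies = "numeric", rms = "numeric",
                 harmonicWeights = "numeric", amDepth = "numeric",
                 amRateHz = "numeric", noiseSD = "numeric",
                 noiseRelative = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character()
    m <- length(object@modes)
    if (!all(object@modes %in% c("bend", "twist", "camber")))
      msg <- c(msg, "modes must be in {bend, twist, camber}")
    if (anyDuplicated(object@modes)) msg <- c(msg, "duplicate mode names")
    if (length(object@frequencies) != m || length(object@rms) != m ||
        length(object@harmonicWeights) != m)
      msg <- c(msg, "frequencies, rms, harmonicWeights must match modes")
    if (any(object@frequencies <= 0)) msg <- c(msg, "frequencies must be > 0")
    if (any(object@rms < 0)) msg <- c(msg, "rms amplitudes must be >= 0")
    if (object@amDepth < 0 || object@amDepth >= 1)
      msg <- c(msg, "amDepth must lie in [0, 1)")
    if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' SpikeModel: per-cycle phase-locked spiking model
#'
#' One spike per oscillation cycle with probability `p`, at a phase drawn
#' from a von Mises law whose mean shifts linearly with the cycle peak
#' amplitude: `mu = mu0 + beta * amplitude` (cycles).  This per-cycle
#' Bernoulli x von Mises construction has the closed-form expected vector
#' strength `I1(kappa)/I0(kappa)`, which anchors the statistical tests.
#'
#' @slot mu0 preferred phase, cycles in `[0, 1)`.
#' @slot kappa von Mises concentration, >= 0 and finite.
#' @slot p per-cycle spike probability in `[0, 1]`.
#' @slot beta amplitude-phase slope, cycles per mm.
#' @slot refractory absolute refractory period, s (>= 0).
#' @slot seed integer RNG seed.
#' @export
setClass("SpikeModel",
  representation(mu0 = "numeric", kappa = "numeric", p = "numeric",
                 beta = "numeric", refractory = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@mu0 < 0 || object@mu0 >= 1) msg <- c(msg, "mu0 must be in [0, 1)")
    if (object@kappa < 0 || !is.finite(object@kappa))
      msg <- c(msg, "kappa must be finite and >= 0")
    if (object@p < 0 || object@p > 1) msg <- c(msg, "p must be in [0, 1]")
    if (object@refractory < 0) msg <- c(msg, "refractory must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' SpikeTrain: sorted-unit spike times with frame-aligned binary vector
#'
#' Spike times in seconds plus the binary frame vector at the video frame
#' rate (1 = spike in frame, 0 = none) used by the coherence analysis.
#' Multiple spikes falling in one frame collapse to a single 1 (the count of
#' collapsed events is kept in `truth$collapsed` when binned here).
#'
#' @slot unitId character unit label.
#' @slot times numeric spike times, s, sorted, within `[0, duration)`.
#' @slot duration recording duration, s.
#' @slot fs frame rate used for the binary vector, frames/s.
#' @slot frames numeric 0/1 vector of length `round(duration * fs)`.
#' @slot truth list of generator ground truth (drawn phases, cycle
#'   amplitudes) for synthetic trains; empty otherwise.
#' @export
setClass("SpikeTrain",
  representation(unitId = "character", times = "numeric", duration = "numeric",
                 fs = "numeric", frames = "numeric", truth = "list"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@times)) msg <- c(msg, "times must be sorted")
    if (length(object@times) &&
        (min(object@times) < 0 || max(object@times) >= object@duration))
      msg <- c(msg, "times must lie within [0, duration)")
    if (length(object@frames) != round(object@duration * object@fs))
      msg <- c(msg, "frames length must equal round(duration * fs)")
    if (!all(object@frames %in% c(0, 1)))
      msg <- c(msg, "frames entries must be 0 or 1")
    if (length(msg)) msg else TRUE
  })

#' ModalDecomposition: PCA basis of a deformation field
#'
#' Mean field, orthonormal spatial mode shapes over the usable (masked and
#' everywhere-valid) bins, mm-scaled score series, and variance fractions.
#'
#' @slot grid the [WingGrid-class] the basis lives on.
#' @slot binIndex integer indices (into `rows*cols`) of the bins in the basis.
#' @slot center numeric per-bin temporal mean (mm), length `length(binIndex)`.
#' @slot shapes numeric `bins x nModes` matrix, columns orthonormal.
#' @slot scores numeric `frames x nModes` matrix (mm).
#' @slot varianceFractions numeric per mode, non-increasing, sum <= 1.
#' @slot totalVariance total field variance (sum over bins of temporal
#'   variance, mm^2).
#' @slot fs frames/s of the fitted field.
#' @export
setClass("ModalDecomposition",
  representation(grid = "WingGrid", binIndex = "integer", center = "numeric",
                 shapes = "matrix", scores = "matrix",
                 varianceFractions = "numeric", totalVariance = "numeric",
                 fs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@shapes) != length(object@binIndex) ||
        length(object@center) != length(object@binIndex))
      msg <- c(msg, "shapes/center size must match binIndex")
    if (ncol(object@shapes) != ncol(object@scores))
      msg <- c(msg, "shapes and scores must agree on number of modes")
    G <- crossprod(object@shapes)
    if (max(abs(G - diag(ncol(G)))) > 1e-8)
      msg <- c(msg, "mode shapes must be orthonormal (tol 1e-8)")
    vf <- object@varianceFractions
    if (length(vf) != ncol(object@shapes))
      msg <- c(msg, "one variance fraction per mode required")
    if (any(diff(vf) > 1e-12)) msg <- c(msg, "variance fractions must be non-increasing")
    if (sum(vf) > 1 + 1e-9) msg <- c(msg, "variance fractions must sum to <= 1")
    if (nrow(object@scores) >= 2 && ncol(object@scores) >= 2) {
      cv <- stats::cov(object@scores)
      v <- diag(cv)
      off <- abs(cv[upper.tri(cv)])
      lim <- 1e-6 * sqrt(outer(v, v))[upper.tri(cv)] + 1e-9 * max(v, 1)
      if (any(off > lim)) msg <- c(msg, "retained scores must be uncorrelated")
    }
    if (length(msg)) msg else TRUE
  })

#' CoherenceMap: per-bin spike-field magnitude-squared coherence
#'
#' Welch-averaged magnitude-squared coherence `Cxy(f) = |Pxy|^2 / (Pxx Pyy)`
#' between a unit's binary spike vector and the displacement or strain of
#' every usable wing bin, restricted to the analysis band, plus per-bin peak
#' coherence and peak frequency.
#'
#' @slot grid the [WingGrid-class].
#' @slot binIndex integer bin indices covered (bins with enough valid data).
#' @slot freq numeric frequency grid, Hz.
#' @slot coherence numeric `bins x freqs` matrix in `[0, 1]`.
#' @slot peakCoherence numeric per bin.
#' @slot peakFrequency numeric per bin, Hz.
#' @slot nSegments integer, Welch segments averaged (full-data bins).
#' @slot fieldKind `"displacement"` or `"strain"`.
#' @export
setClass("CoherenceMap",
  representation(grid = "WingGrid", binIndex = "integer", freq = "numeric",
                 coherence = "matrix", peakCoherence = "numeric",
                 peakFrequency = "numeric", nSegments = "integer",
                 fieldKind = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@coherence) != length(object@binIndex))
      msg <- c(msg, "one coherence spectrum per bin required")
    if (ncol(object@coherence) != length(object@freq))
      msg <- c(msg, "coherence columns must match frequency grid")
    cc <- object@coherence[!is.na(object@coherence)]
    if (length(cc) && (min(cc) < -1e-9 || max(cc) > 1 + 1e-9))
      msg <- c(msg, "coherence must lie in [0, 1]")
    if (object@nSegments < 2L) msg <- c(msg, "need >= 2 Welch segments")
    if (length(msg)) msg else TRUE
  })

#' InformationMap: lower-bound information rates across the wing
#'
#' Per-bin lower-bound information rate `I = -integral log2(1 - Cxy) df`
#' (bits/s), its spike-rate-normalized version (bits/spike), and the
#' high-information region mask (top percentile of the normalized rate).
#'
#' @slot grid the [WingGrid-class].
#' @slot binIndex integer bin indices covered.
#' @slot rate numeric bits/s per bin.
#' @slot ratePerSpike numeric bits/spike per bin.
#' @slot highMask logical per bin, `TRUE` inside the high-information region.
#' @slot percentile percentile used (percent, e.g. 5 = top 5%).
#' @slot spikeRate mean firing rate used for normalization (spikes/s).
#' @slot tied `TRUE` if ties at the cutoff enlarged the mask.
#' @export
setClass("InformationMap",
  representation(grid = "WingGrid", binIndex = "integer", rate = "numeric",
                 ratePerSpike = "numeric", highMask = "logical",
                 percentile = "numeric", spikeRate = "numeric",
                 tied = "logical"),
  validity = function(object) {
    msg <- character()
    nb <- length(object@binIndex)
    if (length(object@rate) != nb || length(object@ratePerSpike) != nb ||
        length(object@highMask) != nb)
      msg <- c(msg, "rate, ratePerSpike and highMask must match binIndex")
    if (any(object@rate < -1e-9, na.rm = TRUE))
      msg <- c(msg, "information rates must be >= 0")
    if (object@spikeRate <= 0) msg <- c(msg, "spikeRate must be > 0")
    if (length(msg)) msg else TRUE
  })
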