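#' @include AllClasses.R wing-grid.R
NULL

## Welch segment plan: start indices for segments of segLen samples with the
## given overlap fraction.
welchSegments <- function(n, segLen, overlap) {
  step <- max(1L, round(segLen * (1 - overlap)))
  starts <- seq.int(1L, n - segLen + 1L, by = step)
  if (length(starts) < 2L) stop("recording shorter than 2 segments")
  starts
}

#' Welch magnitude-squared coherence between two signals
#'
#' Hann-tapered, overlapping-segment averaged power spectral densities and
#' cross-spectrum: `Cxy(f) = |Pxy|^2 / (Pxx * Pyy)`.  Both signals are
#' mean-subtracted first.  Segments containing `NA` samples in `y` are
#' dropped (per-signal validity handling); at least 2 segments must remain.
#'
#' @param x,y numeric signals at the same sampling rate (`y` may contain
#'   `NA`).
#' @param fs sampling rate, Hz.
#' @param segmentMs segment length, ms (default 100).
#' @param overlap overlap fraction (default 0.5).
#' @return list with `freq` (Hz, one-sided), `coherence`, `nSegments`.
#' @export
welchCoherence <- function(x, y, fs, segmentMs = 100, overlap = 0.5) {
  stopifnot(length(x) == length(y))
  segLen <- round(segmentMs / 1000 * fs)
  starts <- welchSegments(length(x), segLen, overlap)
  w <- hannWindow(segLen)
  segIdx <- outer(seq_len(segLen) - 1L, starts, `+`)
  X <- stats::mvfft(matrix(x[segIdx] - mean(x), segLen) * w)
  Ym <- matrix(y[segIdx], segLen)
  ok <- colSums(is.na(Ym)) == 0L
  if (sum(ok) < 2L) stop("fewer than 2 valid segments")
  Y <- stats::mvfft((Ym[, ok, drop = FALSE] - mean(y, na.rm = TRUE)) * w)
  X <- X[, ok, drop = FALSE]
  nf <- floor(segLen / 2) + 1L
  X <- X[seq_len(nf), , drop = FALSE]; Y <- Y[seq_len(nf), , drop = FALSE]
  Pxx <- rowSums(Mod(X)^2); Pyy <- rowSums(Mod(Y)^2)
  Pxy <- rowSums(X * Conj(Y))
  den <- Pxx * Pyy
  C <- ifelse(den > 1e-300, Mod(Pxy)^2 / den, 0)
  list(freq = (seq_len(nf) - 1L) * fs / segLen, coherence = pmin(C, 1),
       nSegments = sum(ok))
}

#' Spike-field coherence map across wing bins
#'
#' Welch magnitude-squared coherence between a unit's binary spike vector
#' (mean-subtracted internally) and the displacement or strain series of
#' every usable wing bin, restricted to the analysis band, with per-bin peak
#' coherence and peak frequency.  Per bin, segments containing invalid
#' (`NA`) field samples are dropped rather than whole frames; bins with
#' fewer than 2 valid segments are excluded from the map.
#'
#' @param spikes a [SpikeTrain-class] (or a 0/1 frame vector).
#' @param field a [DeformationField-class] at the same frame rate.
#' @param segmentMs Welch segment length, ms (default 100: 10 Hz resolution
#'   at 1,000 fps).
#' @param overlap overlap fraction (default 0.5, Hann taper).
#' @param band analysis band, Hz (default 0-500; `band[2]` must not exceed
#'   Nyquist).
#' @return a [CoherenceMap-class].
#' @export
coherenceMap <- function(spikes, field, segmentMs = 100, overlap = 0.5,
                         band = c(0, 500)) {
  stopifnot(methods::is(field, "DeformationField"))
  x <- if (methods::is(spikes, "SpikeTrain")) {
    if (abs(frameRate(spikes) - field@fs) > 1e-9)
      stop("spike vector and field must share one frame rate")
    spikeFrames(spikes)
  } else as.numeric(spikes)
  if (length(x) != nFrames(field))
    stop("spike vector and field must cover the same frames")
  fs <- field@fs
  if (band[2] > fs / 2 + 1e-9)
    stop("band upper edge exceeds Nyquist: ", band[2], " Hz unreachable at fs = ", fs)
  segLen <- round(segmentMs / 1000 * fs)
  starts <- welchSegments(length(x), segLen, overlap)
  w <- hannWindow(segLen)
  segIdx <- outer(seq_len(segLen) - 1L, starts, `+`)
  Xf <- stats::mvfft(matrix(x[segIdx] - mean(x), segLen) * w)
  nf <- floor(segLen / 2) + 1L
  freqAll <- (seq_len(nf) - 1L) * fs / segLen
  inBand <- freqAll >= band[1] - 1e-9 & freqAll <= band[2] + 1e-9
  Xf <- Xf[seq_len(nf), , drop = FALSE]
  PxxFull <- rowSums(Mod(Xf)^2)

  maskBins <- which(as.vector(field@grid@mask))
  keep <- logical(length(maskBins))
  Cmat <- matrix(NA_real_, length(maskBins), sum(inBand))
  for (i in seq_along(maskBins)) {
    yv <- field@data[, maskBins[i]]
    Ym <- matrix(yv[segIdx], segLen)
    okSeg <- colSums(is.na(Ym)) == 0L
    if (sum(okSeg) < 2L) next
    Yf <- stats::mvfft((Ym[, okSeg, drop = FALSE] - mean(yv, na.rm = TRUE)) * w)
    Yf <- Yf[seq_len(nf), , drop = FALSE]
    if (all(okSeg)) {
      Pxx <- PxxFull
      Xs <- Xf
    } else {
      Xs <- Xf[, okSeg, drop = FALSE]
      Pxx <- rowSums(Mod(Xs)^2)
    }
    Pyy <- rowSums(Mod(Yf)^2)
    Pxy <- rowSums(Xs * Conj(Yf))
    den <- Pxx * Pyy
    C <- ifelse(den > 1e-300, Mod(Pxy)^2 / den, 0)
    Cmat[i, ] <- pmin(C[inBand], 1)
    keep[i] <- TRUE
  }
  binIdx <- maskBins[keep]
  Cmat <- Cmat[keep, , drop = FALSE]
  pkIdx <- apply(Cmat, 1, which.max)
  freq <- freqAll[inBand]
  methods::new("CoherenceMap", grid = field@grid, binIndex = as.integer(binIdx),
               freq = freq, coherence = Cmat,
               peakCoherence = Cmat[cbind(seq_len(nrow(Cmat)), pkIdx)],
               peakFrequency = freq[pkIdx],
               nSegments = length(starts), fieldKind = field@kind)
}

#' Lower-bound information rate from a coherence spectrum
#'
#' `I = -integral over the band of log2(1 - Cxy(f)) df` by the trapezoidal
#' rule, the conservative lower-bound information estimate valid under
#' linearity and stationarity.  Coherence is clipped to `1 - 1e-9` before
#' the logarithm.
#'
#' @param coherence coherence values on `freq` (vector), or a
#'   [CoherenceMap-class] (then per-bin rates are returned).
#' @param freq frequency grid, Hz (ignored for a map).
#' @param band integration band, Hz.
#' @return bits/s (scalar, or one value per map bin).
#' @examples
#' informationRate(rep(0.5, 51), seq(0, 500, 10))  # 500 bits/s
#' @export
informationRate <- function(coherence, freq = NULL, band = c(0, 500)) {
  if (methods::is(coherence, "CoherenceMap")) {
    freq <- coherence@freq
    C <- coherence@coherence
  } else {
    if (is.null(freq)) stop("freq required for a plain spectrum")
    C <- matrix(coherence, nrow = 1)
  }
  if (any(C < -1e-6 | C > 1 + 1e-6, na.rm = TRUE))
    stop("coherence outside [0, 1]")
  sel <- freq >= band[1] - 1e-9 & freq <= band[2] + 1e-9
  if (sum(sel) < 2L) stop("band must contain >= 2 frequency points")
  Cb <- pmin(pmax(C[, sel, drop = FALSE], 0), 1 - 1e-9)
  I <- trapzIntegrate(freq[sel], -log2(1 - Cb))
  if (nrow(Cb) == 1L && !methods::is(coherence, "CoherenceMap")) I[1] else I
}

#' High-information wing regions
#'
#' Normalizes per-bin information rates by the unit's mean firing rate
#' (bits/spike) and masks the bins at or above the `(100 - p)`th percentile
#' of the normalized rate — the top `p` percent.  Ties at the cutoff are all
#' included (and flagged).
#'
#' @param rates bits/s per bin (aligned with `binIndex`), or a
#'   [CoherenceMap-class] (rates computed via [informationRate()]).
#' @param spikes a [SpikeTrain-class], or the spike count (then `duration`
#'   is required).
#' @param percentile top percentile `p` in percent, within `[0.5, 10]`
#'   (default 5).
#' @param grid,binIndex grid and bin indices (taken from the map when
#'   `rates` is a [CoherenceMap-class]).
#' @param duration recording duration, s (when `spikes` is a count).
#' @param band integration band when `rates` is a map.
#' @return an [InformationMap-class].
#' @export
highInformationRegions <- function(rates, spikes, percentile = 5,
                                   grid = NULL, binIndex = NULL,
                                   duration = NULL, band = c(0, 500)) {
  if (percentile < 0.5 || percentile > 10)
    stop("percentile must lie in [0.5, 10]")
  if (methods::is(rates, "CoherenceMap")) {
    grid <- rates@grid; binIndex <- rates@binIndex
    rates <- informationRate(rates, band = band)
  }
  if (is.null(grid) || is.null(binIndex))
    stop("grid and binIndex required with plain rate input")
  if (methods::is(spikes, "SpikeTrain")) {
    nSpk <- length(spikeTimes(spikes)); dur <- spikes@duration
  } else { nSpk <- spikes; dur <- duration }
  if (is.null(dur)) stop("duration required with a spike count")
  if (nSpk <= 0) stop("zero spikes: normalized rate undefined")
  spikeRate <- nSpk / dur
  perSpike <- rates / spikeRate
  ok <- !is.na(perSpike)
  k <- max(1L, round(percentile / 100 * sum(ok)))
  cutoff <- sort(perSpike[ok], decreasing = TRUE)[k]
  mask <- ok & perSpike >= cutoff
  tied <- sum(mask) > k
  if (tied) message("ties at the percentile cutoff: mask enlarged to ",
                    sum(mask), " bins")
  methods::new("InformationMap", grid = grid, binIndex = as.integer(binIndex),
               rate = as.numeric(rates), ratePerSpike = as.numeric(perSpike),
               highMask = mask, percentile = percentile,
               spikeRate = spikeRate, tied = tied)
}

#' Match sensors to high-information regions
#'
#' Assigns each sensor to its nearest bin center; sensors whose bin lies in
#' the high-information mask are candidates, ranked by the local normalized
#' information rate (ties broken by sensor id).  Non-candidates get their
#' distance to the region; sensors outside the grid bounds are dropped with
#' a warning.
#'
#' @param infoMap an [InformationMap-class].
#' @param sensors sensor map data.frame with columns `sensor_id`, `x_mm`,
#'   `y_mm` (and optionally `side`, `vein`).
#' @return data.frame with `sensor_id`, `bin`, `bits_per_spike`,
#'   `in_region`, `rank` (NA outside the region), `dist_mm` (0 inside).
#' @export
matchCandidateSensors <- function(infoMap, sensors) {
  stopifnot(methods::is(infoMap, "InformationMap"))
  g <- infoMap@grid
  bins <- nearestBin(g, sensors$x_mm, sensors$y_mm)
  if (any(is.na(bins))) {
    warning(sum(is.na(bins)), " sensor(s) outside grid bounds excluded")
    sensors <- sensors[!is.na(bins), , drop = FALSE]
    bins <- bins[!is.na(bins)]
  }
  pos <- match(bins, infoMap@binIndex)
  perSpike <- infoMap@ratePerSpike[pos]
  inRegion <- !is.na(pos) & infoMap@highMask[pos]
  bc <- binCenters(g)
  maskBins <- infoMap@binIndex[infoMap@highMask]
  dist <- vapply(seq_along(bins), function(i) {
    if (isTRUE(inRegion[i])) return(0)
    if (!length(maskBins)) return(NA_real_)
    min(sqrt((bc$x_mm[maskBins] - sensors$x_mm[i])^2 +
             (bc$y_mm[maskBins] - sensors$y_mm[i])^2))
  }, numeric(1))
  out <- data.frame(sensor_id = sensors$sensor_id, bin = bins,
                    bits_per_spike = perSpike, in_region = inRegion,
                    rank = NA_integer_, dist_mm = dist,
                    stringsAsFactors = FALSE)
  if (any(inRegion)) {
    cand <- which(inRegion)
    ord <- cand[order(-out$bits_per_spike[cand], out$sensor_id[cand])]
    out$rank[ord] <- seq_along(ord)
  }
  out[order(!out$in_region, out$rank, out$dist_mm), ]
}
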