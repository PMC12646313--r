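#' @include AllClasses.R utils.R
NULL

#' Bin spike times into a frame-aligned binary vector
#'
#' Frame index of a spike at time `t` is `floor(t * fs) + 1`; multiple
#' spikes in one frame collapse to a single 1 (the number of collapsed
#' events is attached as attribute `collapsed` and messaged).
#'
#' @param times spike times, s, each `< duration`.
#' @param duration recording duration, s.
#' @param fs frame rate, frames/s (> 0).
#' @return numeric 0/1 vector of length `round(duration * fs)`.
#' @export
binSpikeTrain <- function(times, duration, fs) {
  if (fs <= 0) stop("fs must be > 0")
  nF <- round(duration * fs)
  if (length(times) && max(times) >= duration)
    stop("spike time at or beyond duration")
  if (length(times) && min(times) < 0) stop("negative spike time")
  v <- numeric(nF)
  idx <- floor(times * fs) + 1L
  idx <- idx[idx >= 1L & idx <= nF]
  collapsed <- length(idx) - length(unique(idx))
  v[unique(idx)] <- 1
  if (collapsed > 0)
    message(collapsed, " spike(s) collapsed into occupied frames")
  attr(v, "collapsed") <- collapsed
  v
}

#' Spike phases relative to score oscillation cycles
#'
#' Detects positive peaks of the mode score (local maxima with minimum
#' prominence 10% of the score SD and minimum separation half the dominant
#' period, sub-sample refined) and assigns each spike the normalized time
#' between its two enclosing peaks: `theta = (t - t_prev) / (t_next -
#' t_prev)`, in cycles `[0, 1)`.  Spikes before the first or after the last
#' peak are dropped.  The cycle amplitude attached to each spike is the
#' enclosing cycle's starting peak score.
#'
#' @param score numeric score series of the driving mode.
#' @param spikeTimes spike times, s.
#' @param fs frame rate of the score series, frames/s.
#' @return list with `theta` (cycles), `amplitude` (mm per spike), `used`
#'   (logical per input spike), `peakTimes` (s).
#' @export
cyclePhases <- function(score, spikeTimes, fs) {
  pk <- findOscillationPeaks(score)
  pk <- pk[pk$value > 0, , drop = FALSE]
  if (nrow(pk) < 2L) stop("fewer than 2 positive peaks: no cycles detected")
  tp <- (pk$position - 1) / fs
  cyc <- findInterval(spikeTimes, tp)
  used <- cyc >= 1L & cyc < length(tp) & spikeTimes >= tp[1]
  cycU <- cyc[used]
  theta <- (spikeTimes[used] - tp[cycU]) / (tp[cycU + 1L] - tp[cycU])
  theta <- pmin(pmax(theta, 0), 1 - 1e-12)
  list(theta = theta, amplitude = pk$value[cycU], used = used, peakTimes = tp)
}

#' Vector strength of a phase set
#'
#' `VS = (1/N) * sqrt((sum cos 2*pi*theta)^2 + (sum sin 2*pi*theta)^2)` with
#' `N` the number of spikes: 1 for perfect phase locking, 0 for uniform
#' phases.
#'
#' @param theta spike phases in cycles (any real values; used modulo 1).
#' @return vector strength in `[0, 1]`.
#' @examples
#' vectorStrength(c(0, 0.25))  # sqrt(2)/2
#' @export
vectorStrength <- function(theta) {
  if (!length(theta)) stop("empty phase set")
  ang <- 2 * pi * theta
  sqrt(sum(cos(ang))^2 + sum(sin(ang))^2) / length(theta)
}

#' Classify phase locking from vector strength
#'
#' Strong for `VS > 0.6`, weak for `0.5 < VS <= 0.6`, otherwise none
#' (boundaries strict).
#'
#' @param vs vector strength in `[0, 1]`.
#' @return one of `"strong"`, `"weak"`, `"none"`.
#' @export
classifyPhaseLocking <- function(vs) {
  if (vs < 0 || vs > 1) stop("vector strength must lie in [0, 1]")
  if (vs > 0.6) "strong" else if (vs > 0.5) "weak" else "none"
}

#' Spike-triggered average of modal scores
#'
#' Mean of score windows centered on spike frames, over a symmetric lag
#' window; spikes whose window would leave the recording are excluded and
#' counted.
#'
#' @param scores frames x nModes score matrix (or numeric vector).
#' @param spikeFrames 0/1 spike frame vector of matching length.
#' @param fs frame rate, frames/s.
#' @param halfWindowMs half-window, ms (default 25, several cycles at the
#'   ~170 Hz working natural frequency).
#' @return list with `lag_ms`, `sta` (lags x modes matrix, mm), `nSpikes`
#'   used, `nExcluded` truncated-window spikes, `halfWindowMs`.
#' @export
spikeTriggeredAverage <- function(scores, spikeFrames, fs, halfWindowMs = 25) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(spikeFrames))
    stop("scores and spikeFrames must cover the same frames")
  L <- round(halfWindowMs * fs / 1000)
  at <- which(spikeFrames > 0)
  ok <- at > L & at <= nrow(scores) - L
  nExcluded <- sum(!ok)
  at <- at[ok]
  if (!length(at)) stop("no spike with a full window inside the recording")
  lags <- -L:L
  sta <- matrix(0, length(lags), ncol(scores))
  for (i in at) sta <- sta + scores[i + lags, , drop = FALSE]
  sta <- sta / length(at)
  colnames(sta) <- colnames(scores)
  list(lag_ms = lags * 1000 / fs, sta = sta, nSpikes = length(at),
       nExcluded = nExcluded, halfWindowMs = halfWindowMs)
}

#' Phase-locking profile across displacement amplitude
#'
#' Bins spikes by the enclosing cycle's peak amplitude and reports circular
#' mean phase and vector strength per amplitude bin (default: four bins
#' spanning 1-4 mm).  Bins without spikes are absent from the output.
#'
#' @param theta spike phases, cycles.
#' @param amplitude per-spike cycle peak amplitude, mm.
#' @param edges increasing amplitude bin edges, mm.
#' @return data.frame with `lo`, `hi`, `center` (mm), `n`, `meanPhase`
#'   (cycles), `vs`.
#' @export
phaseAmplitudeProfile <- function(theta, amplitude,
                                  edges = seq(1, 4, length.out = 5)) {
  if (any(diff(edges) <= 0)) stop("amplitude bin edges must be increasing")
  bin <- findInterval(amplitude, edges, rightmost.closed = TRUE)
  out <- lapply(seq_len(length(edges) - 1L), function(k) {
    i <- bin == k
    if (!any(i)) return(NULL)
    data.frame(lo = edges[k], hi = edges[k + 1],
               center = (edges[k] + edges[k + 1]) / 2, n = sum(i),
               meanPhase = circularMeanCycles(theta[i]),
               vs = vectorStrength(theta[i]))
  })
  do.call(rbind, out)
}

#' Phase-locking summary for a unit against one mode
#'
#' Convenience wrapper: spike phases from [cyclePhases()], vector strength,
#' and the phase-locking class.  STA should only be interpreted for units
#' classed `"strong"` or `"weak"`.
#'
#' @param score driving-mode score series.
#' @param spikes a [SpikeTrain-class].
#' @param mode label for the mode (bookkeeping only).
#' @return data.frame row with `unit`, `mode`, `n`, `vs`, `class`,
#'   `meanPhase` plus attribute `phases` (the [cyclePhases()] result).
#' @export
phaseLocking <- function(score, spikes, mode = "mode1") {
  cp <- cyclePhases(score, spikeTimes(spikes), frameRate(spikes))
  vs <- vectorStrength(cp$theta)
  out <- data.frame(unit = spikes@unitId, mode = mode, n = length(cp$theta),
                    vs = vs, class = classifyPhaseLocking(vs),
                    meanPhase = circularMeanCycles(cp$theta))
  attr(out, "phases") <- cp
  out
}
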