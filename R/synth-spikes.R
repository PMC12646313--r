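#' @include AllClasses.R synth-field.R
NULL

#' Construct a phase-locked spiking model
#'
#' @param mu0 preferred phase, cycles in `[0, 1)`.
#' @param kappa von Mises concentration (>= 0); expected vector strength of
#'   the resulting train is `besselI(kappa, 1) / besselI(kappa, 0)`.
#' @param p per-cycle spike probability.
#' @param beta amplitude-phase slope, cycles per mm of cycle peak amplitude
#'   (phase timing shifts with displacement amplitude).
#' @param refractory absolute refractory period, s.
#' @param seed integer RNG seed.
#' @return a [SpikeModel-class].
#' @export
spikeModel <- function(mu0 = 0.25, kappa = 4, p = 0.9, beta = 0,
                       refractory = 0.001, seed = 1L) {
  methods::new("SpikeModel", mu0 = mu0, kappa = kappa, p = p, beta = beta,
               refractory = refractory, seed = as.integer(seed))
}

#' Construct a spike train from explicit times
#'
#' @param times spike times, s (sorted or sortable), within `[0, duration)`.
#' @param duration recording duration, s.
#' @param fs frame rate for the binary vector, frames/s.
#' @param unitId unit label.
#' @param truth optional generator ground-truth list.
#' @return a [SpikeTrain-class].
#' @export
spikeTrain <- function(times, duration, fs, unitId = "unit1", truth = list()) {
  times <- sort(as.numeric(times))
  frames <- binSpikeTrain(times, duration, fs)
  methods::new("SpikeTrain", unitId = unitId, times = times,
               duration = duration, fs = fs, frames = as.numeric(frames),
               truth = truth)
}

#' Generate a phase-locked synthetic spike train
#'
#' Detects oscillation cycles (successive peaks) in the driving mode's score
#' series; in each cycle, with probability `p`, one spike is emitted at a
#' phase drawn from a von Mises law with mean `mu0 + beta * A` (cycles,
#' where `A` is the cycle's starting peak amplitude) and concentration
#' `kappa`.  Spikes violating the refractory period are dropped.
#' Deterministic given the model seed.
#'
#' The ground-truth sidecar records the drawn phases (`theta`), the per-spike
#' cycle peak amplitudes and the per-cycle mean phase, so the encoding stage
#' can be scored without re-estimating cycles.
#'
#' @param scores score series: matrix with named columns (one per mode) or a
#'   numeric vector.
#' @param drivingMode name of the driving mode (ignored for a vector input).
#' @param model a [SpikeModel-class].
#' @param fs frame rate of the score series, frames/s.
#' @param unitId unit label.
#' @return a [SpikeTrain-class].
#' @export
synthSpikeTrain <- function(scores, drivingMode = NULL, model = spikeModel(),
                            fs, unitId = "unit1") {
  if (is.matrix(scores)) {
    if (is.null(drivingMode) || !drivingMode %in% colnames(scores))
      stop("drivingMode must name a column of scores")
    s <- scores[, drivingMode]
  } else s <- as.numeric(scores)
  duration <- length(s) / fs
  pk <- findOscillationPeaks(s)
  if (nrow(pk) < 2L) stop("no detectable oscillation cycles in driving score")
  tp <- (pk$position - 1) / fs                  # peak times, s
  amp <- pk$value
  nCyc <- length(tp) - 1L

  drawn <- withSeed(model@seed, {
    fire <- stats::runif(nCyc) < model@p
    idx <- which(fire)
    mu <- 2 * pi * (model@mu0 + model@beta * amp[idx])
    th <- if (length(idx)) (rvonmises(length(idx), mu, model@kappa) / (2 * pi)) %% 1
          else numeric()
    list(idx = idx, theta = th)
  })
  tSpk <- tp[drawn$idx] + drawn$theta * (tp[drawn$idx + 1L] - tp[drawn$idx])
  ord <- order(tSpk)
  tSpk <- tSpk[ord]
  theta <- drawn$theta[ord]
  cycAmp <- amp[drawn$idx][ord]
  cycIdx <- drawn$idx[ord]
  ## refractory: greedy forward pass
  if (length(tSpk) > 1L && model@refractory > 0) {
    keep <- logical(length(tSpk)); last <- -Inf
    for (i in seq_along(tSpk)) {
      if (tSpk[i] - last >= model@refractory) { keep[i] <- TRUE; last <- tSpk[i] }
    }
    tSpk <- tSpk[keep]; theta <- theta[keep]
    cycAmp <- cycAmp[keep]; cycIdx <- cycIdx[keep]
  }
  inWin <- tSpk >= 0 & tSpk < duration
  spikeTrain(tSpk[inWin], duration, fs, unitId = unitId,
             truth = list(theta = theta[inWin], cycleAmplitude = cycAmp[inWin],
                          cycleIndex = cycIdx[inWin], peakTimes = tp,
                          peakAmplitudes = amp, model = model))
}
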