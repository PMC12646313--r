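#' @include AllClasses.R wing-grid.R
NULL

#' Construct a modal generative model
#'
#' Parameterizes the synthetic flutter/flapping generator: which structural
#' modes are present, their frequencies and score RMS amplitudes, harmonic
#' content, slow amplitude modulation, and measurement noise.  Defaults give
#' a flutter-like field: bend and twist at the 170 Hz working natural
#' frequency plus a weaker camber mode at the first harmonic, with cycle
#' amplitudes spanning roughly 1-4 mm.
#'
#' @param modes character vector from `c("bend", "twist", "camber")`.
#' @param frequencies Hz per mode.
#' @param rms score RMS amplitude per mode, mm.
#' @param harmonicWeights relative amplitude of each mode's 2nd harmonic.
#' @param amDepth amplitude-modulation depth in `[0, 1)`.
#' @param amRateHz upper frequency of the modulation envelope (<= 5 Hz keeps
#'   cycle amplitudes slowly varying).
#' @param noiseSD measurement-noise SD; interpreted as a fraction of the
#'   clean-field RMS when `noiseRelative = TRUE`, else mm.
#' @param noiseRelative see `noiseSD`.
#' @param seed integer RNG seed.
#' @return a [ModalModel-class].
#' @export
modalModel <- function(modes = c("bend", "twist", "camber"),
                       frequencies = c(170, 170, 340),
                       rms = c(1.8, 1.1, 0.4),
                       harmonicWeights = rep(0, length(modes)),
                       amDepth = 0.6, amRateHz = 3,
                       noiseSD = 0.05, noiseRelative = TRUE,
                       seed = 1L) {
  methods::new("ModalModel", modes = modes, frequencies = as.numeric(frequencies),
               rms = as.numeric(rms),
               harmonicWeights = as.numeric(harmonicWeights),
               amDepth = amDepth, amRateHz = amRateHz, noiseSD = noiseSD,
               noiseRelative = noiseRelative, seed = as.integer(seed))
}

#' Spatial mode shapes on a wing grid
#'
#' Analytic bend / twist / camber shapes evaluated on the masked bins and
#' orthonormalized (Gram-Schmidt in the given order), then scaled to unit
#' RMS over bins so that score series are in mm.  Bend is a monotone
#' spanwise deflection (~ s^2, cantilever-like), twist a chordwise gradient
#' growing with span, camber a chordwise curvature concentrated along the
#' trailing edge.
#'
#' @param grid a [WingGrid-class].
#' @param modes character subset of `c("bend", "twist", "camber")`.
#' @return matrix `nMaskedBins x nModes`; rownames are bin indices.
#' @export
structuralModeShapes <- function(grid, modes = c("bend", "twist", "camber")) {
  bc <- binCenters(grid, maskedOnly = TRUE)
  s <- bc$x_mm / max(grid@x)                   # span fraction
  cfrac <- (bc$y_mm - min(grid@y)) / (max(grid@y) - min(grid@y))
  raw <- sapply(modes, function(m) switch(m,
    bend   = s^2,
    twist  = s * (cfrac - 0.5),
    camber = s * cfrac^2,
    stop("unknown mode: ", m)))
  raw <- as.matrix(raw)
  ## Gram-Schmidt, then unit-RMS scaling (keeps orthogonality)
  B <- nrow(raw)
  for (j in seq_len(ncol(raw))) {
    v <- raw[, j]
    if (j > 1) for (k in seq_len(j - 1))
      v <- v - sum(v * raw[, k]) / sum(raw[, k]^2) * raw[, k]
    nrm <- sqrt(mean(v^2))
    if (nrm < 1e-12) stop("degenerate mode shape on this grid: ", modes[j])
    raw[, j] <- v / nrm
  }
  rownames(raw) <- bc$bin
  colnames(raw) <- modes
  raw
}

## Smooth random envelope in [1 - depth, 1 + depth]: a sum of slow
## random-phase sinusoids normalized to unit maximum amplitude.
slowEnvelope <- function(t, depth, rateHz, nComponents = 3L) {
  if (depth <= 0) return(rep(1, length(t)))
  f <- stats::runif(nComponents, 0.15 * rateHz, rateHz)
  ph <- stats::runif(nComponents, 0, 2 * pi)
  w <- stats::runif(nComponents, 0.5, 1)
  e <- colSums(w * t(sapply(seq_len(nComponents),
                            function(k) sin(2 * pi * f[k] * t + ph[k]))))
  1 + depth * e / max(abs(e))
}

#' Generate a synthetic displacement field
#'
#' Superposes the model's spatial modes with amplitude-modulated sinusoidal
#' score series (fundamental plus optional 2nd harmonic) and adds i.i.d.
#' Gaussian measurement noise per bin.  Modes sharing a frequency are driven
#' in quadrature so their scores stay uncorrelated and the decomposition
#' stage can recover them.  Positive displacement is dorsal.  Bins outside
#' the planform mask are `NA`.
#'
#' The ground-truth sidecar (`groundTruth()`) carries the mode shapes, the
#' realized score series and the modulation envelopes so downstream recovery
#' can be scored.
#'
#' @param grid a [WingGrid-class].
#' @param model a [ModalModel-class].
#' @param duration recording length, s (`duration * fs >= 2` frames).
#' @param fs frame rate, frames/s; all mode frequencies (and active 2nd
#'   harmonics) must stay below `fs / 2`.
#' @return a [DeformationField-class] of kind `"displacement"`.
#' @examples
#' g <- wingGrid(6, 12)
#' f <- synthDisplacementField(g, modalModel(seed = 3), duration = 0.25, fs = 2000)
#' f
#' @export
synthDisplacementField <- function(grid, model, duration, fs) {
  stopifnot(methods::is(grid, "WingGrid"), methods::is(model, "ModalModel"))
  nT <- round(duration * fs)
  if (nT < 2) stop("duration * fs must give at least 2 frames")
  fmax <- ifelse(model@harmonicWeights > 0, 2, 1) * model@frequencies
  if (any(fmax >= fs / 2))
    stop("mode frequency (or active 2nd harmonic) at or above Nyquist")
  shp <- structuralModeShapes(grid, model@modes)           # errors on grid mismatch
  binIdx <- as.integer(rownames(shp))
  tt <- (seq_len(nT) - 1) / fs
  m <- length(model@modes)

  scores <- withSeed(model@seed, {
    S <- matrix(0, nT, m, dimnames = list(NULL, model@modes))
    for (j in seq_len(m)) {
      if (model@rms[j] <= 0) next
      phi <- (j - 1) * pi / 2                    # quadrature between modes
      w <- model@harmonicWeights[j]
      base <- sin(2 * pi * model@frequencies[j] * tt + phi)
      if (w > 0) base <- base + w * sin(4 * pi * model@frequencies[j] * tt + 2 * phi)
      env <- slowEnvelope(tt, model@amDepth, model@amRateHz)
      v <- env * base
      S[, j] <- model@rms[j] * v / sqrt(mean(v^2))
    }
    S
  })

  X <- scores %*% t(shp)                         # nT x nMasked
  cleanRMS <- sqrt(mean(X^2))
  sd0 <- if (model@noiseRelative) model@noiseSD * cleanRMS else model@noiseSD
  if (sd0 > 0) {
    withSeed(model@seed + 1L, {
      ## chunked so no full-size temporary is allocated
      chunk <- max(1L, floor(2e6 / nT))
      j <- 1L
      while (j <= ncol(X)) {
        jj <- j:min(ncol(X), j + chunk - 1L)
        X[, jj] <- X[, jj] + stats::rnorm(nT * length(jj), sd = sd0)
        j <- j + chunk
      }
    })
  }

  data <- matrix(NA_real_, nT, grid@rows * grid@cols)
  data[, binIdx] <- X
  methods::new("DeformationField", grid = grid, data = data, fs = fs,
               kind = "displacement",
               truth = list(shapes = shp, scores = scores, binIndex = binIdx,
                            model = model, noiseSD = sd0))
}

#' Generate a white-noise-driven displacement field
#'
#' Emulates broadband mechanical vibration (uniform white noise over
#' 0 Hz - Nyquist): each mode's score series is Gaussian white noise of the
#' stated RMS, so per-bin spectra are flat instead of line-dominated.  Used
#' as the contrast scenario to the flutter generator.
#'
#' @inheritParams synthDisplacementField
#' @return a [DeformationField-class] of kind `"displacement"`.
#' @export
synthWhiteNoiseField <- function(grid, model, duration, fs) {
  stopifnot(methods::is(grid, "WingGrid"), methods::is(model, "ModalModel"))
  nT <- round(duration * fs)
  if (nT < 2) stop("duration * fs must give at least 2 frames")
  shp <- structuralModeShapes(grid, model@modes)
  binIdx <- as.integer(rownames(shp))
  m <- length(model@modes)
  scores <- withSeed(model@seed, {
    S <- matrix(stats::rnorm(nT * m), nT, m, dimnames = list(NULL, model@modes))
    sweep(S, 2, model@rms / apply(S, 2, function(v) sqrt(mean(v^2))), `*`)
  })
  X <- scores %*% t(shp)
  cleanRMS <- sqrt(mean(X^2))
  sd0 <- if (model@noiseRelative) model@noiseSD * cleanRMS else model@noiseSD
  if (sd0 > 0)
    X <- X + withSeed(model@seed + 1L,
                      matrix(stats::rnorm(length(X), sd = sd0), nrow(X)))
  data <- matrix(NA_real_, nT, grid@rows * grid@cols)
  data[, binIdx] <- X
  methods::new("DeformationField", grid = grid, data = data, fs = fs,
               kind = "displacement",
               truth = list(shapes = shp, scores = scores, binIndex = binIdx,
                            model = model, noiseSD = sd0))
}

#' Spanwise normal strain of a displacement field
#'
#' Finite-difference gradient of the dorsoventral displacement along the
#' spanwise coordinate: central differences at interior columns, one-sided
#' at the first and last column.  Uniform (rigid-translation) fields give
#' zero strain.  `NA` bins propagate to their finite-difference neighbours.
#'
#' @param field a [DeformationField-class] of kind `"displacement"`.
#' @return a [DeformationField-class] of kind `"strain"` on the same grid;
#'   the ground-truth sidecar of the input is carried through.
#' @export
synthStrainField <- function(field) {
  stopifnot(methods::is(field, "DeformationField"))
  g <- field@grid
  if (g@cols < 2L) stop("strain needs at least two spanwise columns")
  X <- field@data
  S <- matrix(NA_real_, nrow(X), ncol(X))
  rows <- g@rows
  colBins <- function(j) ((j - 1L) * rows + 1L):(j * rows)
  for (j in seq_len(g@cols)) {
    if (j == 1L) {
      S[, colBins(j)] <- (X[, colBins(2L)] - X[, colBins(1L)]) / (g@x[2] - g@x[1])
    } else if (j == g@cols) {
      S[, colBins(j)] <- (X[, colBins(j)] - X[, colBins(j - 1L)]) /
        (g@x[j] - g@x[j - 1])
    } else {
      S[, colBins(j)] <- (X[, colBins(j + 1L)] - X[, colBins(j - 1L)]) /
        (g@x[j + 1] - g@x[j - 1])
    }
  }
  methods::new("DeformationField", grid = g, data = S, fs = field@fs,
               kind = "strain", truth = field@truth)
}
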