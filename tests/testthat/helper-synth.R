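# Shared fixtures: everything is generated in code at test time.

tinyGrid <- function(rows = 6, cols = 12, span = 40, chord = 10)
  wingGrid(rows, cols, span = span, chord = chord)

# Field whose displacement is an analytic function u(x_mm, y_mm) replicated
# over nFrames (constant in time unless scale(t) given).
analyticField <- function(grid, u, nFrames = 3, fs = 1000,
                          scale = rep(1, nFrames), kind = "displacement") {
  bc <- binCenters(grid)
  prof <- u(bc$x_mm, bc$y_mm)
  deformationField(outer(scale, prof), grid, fs, kind = kind)
}

# Quick flutter surrogate used by several files.
quickFlutterField <- function(seed = 1, duration = 2, fs = 2000,
                              grid = tinyGrid(), noiseSD = 0.05) {
  synthDisplacementField(
    grid,
    modalModel(rms = c(2.5, 1.5, 0.5), noiseSD = noiseSD, seed = seed),
    duration = duration, fs = fs)
}

# Delta-method SE of the mean resultant length of N i.i.d. von Mises draws.
vonMisesVsSE <- function(kappa, n) {
  rho <- besselI(kappa, 1) / besselI(kappa, 0)
  a2 <- besselI(kappa, 2) / besselI(kappa, 0)
  sqrt(max(0, (1 + a2) / 2 - rho^2) / n)
}
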