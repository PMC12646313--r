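#' @include AllClasses.R wing-grid.R
NULL

#' Sample leading/trailing edge traces from a displacement field
#'
#' Emulates the free-flight edge reconstruction input: per frame, 3D points
#' along the leading and trailing edge rows of the grid at span fractions
#' within the window (default 0.10-0.90), with `z` equal to the local
#' dorsoventral displacement.  Points are taken at grid column positions so
#' `z` is exact (no interpolation error).
#'
#' @param field a [DeformationField-class] (kind `"displacement"`).
#' @param grid the field's [WingGrid-class] (defaults to `gridGeometry(field)`).
#' @param spanWindow span-fraction range sampled.
#' @param frames which field frames to trace (default all).
#' @return data.frame with columns `frame`, `edge` (`"L"`/`"T"`), `s` (span
#'   fraction), `x_mm`, `y_mm`, `z_mm`.
#' @export
synthEdgeTraces <- function(field, grid = gridGeometry(field),
                            spanWindow = c(0.10, 0.90),
                            frames = seq_len(nFrames(field))) {
  stopifnot(methods::is(field, "DeformationField"))
  s <- grid@x / max(grid@x)
  cols <- which(s >= spanWindow[1] - 1e-9 & s <= spanWindow[2] + 1e-9)
  if (length(cols) < 6L)
    stop("fewer than 6 grid columns inside the span window")
  leadRow <- 1L; trailRow <- grid@rows
  if (!all(grid@mask[leadRow, cols]) || !all(grid@mask[trailRow, cols]))
    stop("mask lacks leading/trailing edge rows across the span window")
  recs <- lapply(frames, function(f) {
    zi <- matrix(field@data[f, ], grid@rows, grid@cols)
    rbind(
      data.frame(frame = f, edge = "L", s = s[cols], x_mm = grid@x[cols],
                 y_mm = grid@y[leadRow], z_mm = zi[leadRow, cols]),
      data.frame(frame = f, edge = "T", s = s[cols], x_mm = grid@x[cols],
                 y_mm = grid@y[trailRow], z_mm = zi[trailRow, cols]))
  })
  do.call(rbind, recs)
}

#' Sample a synthetic sensor map
#'
#' Places `n` campaniform-sensilla-like sensors along straight spanwise vein
#' rays, with a stated fraction in the proximal third of the span, and
#' assigns dorsal/ventral labels.  All sensors land inside the grid mask.
#'
#' @param grid a [WingGrid-class].
#' @param n number of sensors (>= 0).
#' @param proximalFraction fraction of sensors with `x < span/3`, in `[0, 1]`.
#' @param seed RNG seed.
#' @param nVeins number of simulated vein lines (evenly spaced in chord).
#' @return data.frame (a sensor map) with columns `sensor_id`, `x_mm`,
#'   `y_mm`, `side` (`"dorsal"`/`"ventral"`), `vein`.
#' @export
synthSensorMap <- function(grid, n, proximalFraction = 0.7, seed = 1L,
                           nVeins = 4L) {
  stopifnot(methods::is(grid, "WingGrid"), n >= 0)
  if (proximalFraction < 0 || proximalFraction > 1)
    stop("proximalFraction must lie in [0, 1]")
  empty <- data.frame(sensor_id = character(), x_mm = numeric(),
                      y_mm = numeric(), side = character(), vein = character())
  if (n == 0) return(empty)
  span <- max(grid@x)
  veinY <- seq(min(grid@y), max(grid@y), length.out = nVeins + 2L)[-c(1, nVeins + 2L)]
  nProx <- round(proximalFraction * n)
  withSeed(seed, {
    xProx <- stats::runif(nProx, min(grid@x), span / 3 - 1e-9)
    xDist <- stats::runif(n - nProx, span / 3, max(grid@x))
    xs <- c(xProx, xDist)
    vein <- sample(seq_len(nVeins), n, replace = TRUE)
    ys <- veinY[vein]
    side <- sample(c("dorsal", "ventral"), n, replace = TRUE)
    ## keep sensors on masked bins: nudge any off-mask draw to the nearest
    ## masked bin center on its vein
    bins <- nearestBin(grid, xs, ys)
    for (i in seq_len(n)) {
      if (is.na(bins[i]) || !grid@mask[bins[i]]) {
        cand <- binCenters(grid, maskedOnly = TRUE)
        cand <- cand[abs(cand$y_mm - ys[i]) ==
                       min(abs(cand$y_mm - ys[i])), , drop = FALSE]
        ## stay on the correct side of span/3
        prox <- i <= nProx
        sub <- cand[if (prox) cand$x_mm < span / 3 else cand$x_mm >= span / 3, ,
                    drop = FALSE]
        if (!nrow(sub)) sub <- cand
        j <- which.min(abs(sub$x_mm - xs[i]))
        xs[i] <- sub$x_mm[j]; ys[i] <- sub$y_mm[j]
      }
    }
    data.frame(sensor_id = sprintf("cs%03d", seq_len(n)), x_mm = xs, y_mm = ys,
               side = side, vein = paste0("v", vein))
  })
}
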