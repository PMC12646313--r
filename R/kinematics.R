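#' @include utils.R
NULL

#' Fit per-axis edge polynomials
#'
#' Least-squares polynomial fit (default 5th order) of each spatial axis of
#' an edge point set against span fraction, restricted to the span window.
#'
#' @param points data.frame with columns `s` (span fraction) and `x_mm`,
#'   `y_mm`, `z_mm` (or matrix with those four columns in order).
#' @param order polynomial order (default 5).
#' @param spanWindow span-fraction window used for fitting.
#' @return list with `coefficients` (`(order+1) x 3` matrix, ascending
#'   powers; columns x/y/z), `residualRMS` (per axis), `order`, `spanWindow`,
#'   `n` points used.
#' @export
fitEdgePolynomial <- function(points, order = 5L, spanWindow = c(0.10, 0.90)) {
  if (is.matrix(points)) points <- as.data.frame(points)
  if (!all(c("s", "x_mm", "y_mm", "z_mm") %in% names(points)))
    names(points)[1:4] <- c("s", "x_mm", "y_mm", "z_mm")
  keep <- points$s >= spanWindow[1] - 1e-9 & points$s <= spanWindow[2] + 1e-9
  pts <- points[keep, , drop = FALSE]
  if (nrow(pts) < order + 1L)
    stop("need at least ", order + 1L, " points inside the span window")
  V <- outer(pts$s, 0:order, `^`)
  qrV <- qr(V)
  axes <- c("x_mm", "y_mm", "z_mm")
  coef <- sapply(axes, function(a) qr.coef(qrV, pts[[a]]))
  res <- sapply(axes, function(a) {
    r <- pts[[a]] - V %*% coef[, a]
    sqrt(mean(r^2))
  })
  rownames(coef) <- paste0("s^", 0:order)
  list(coefficients = coef, residualRMS = res, order = order,
       spanWindow = spanWindow, n = nrow(pts))
}

evalPoly <- function(coef, s) outer(s, seq_along(coef) - 1, `^`) %*% coef

#' Reconstruct a wing surface from edge polynomials
#'
#' Evaluates both edge polynomial sets at `nSpan` stations across the span
#' window and fills `nChord` chordwise points per station by linear
#' interpolation between the leading and trailing edge (default 80 x 50
#' points).
#'
#' @param leading,trailing results of [fitEdgePolynomial()].
#' @param nSpan,nChord surface grid size (default 80 x 50).
#' @return list with `points` (`nSpan x nChord x 3` array of x/y/z, mm) and
#'   `s` (span stations).
#' @export
reconstructSurface <- function(leading, trailing, nSpan = 80L, nChord = 50L) {
  win <- leading$spanWindow
  s <- seq(win[1], win[2], length.out = nSpan)
  L <- sapply(1:3, function(a) evalPoly(leading$coefficients[, a], s))
  T_ <- sapply(1:3, function(a) evalPoly(trailing$coefficients[, a], s))
  w <- seq(0, 1, length.out = nChord)
  pts <- array(NA_real_, c(nSpan, nChord, 3),
               dimnames = list(NULL, NULL, c("x", "y", "z")))
  for (a in 1:3)
    pts[, , a] <- outer(L[, a], 1 - w) + outer(T_[, a], w)
  list(points = pts, s = s)
}

## Total-least-squares plane through 3D points: returns unit normal and
## centroid.
fitPlaneTLS <- function(P) {
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  list(normal = sv$v[, 3], centroid = ctr)
}

#' Deformation metrics from a surface sequence
#'
#' Computes per frame, against a rest surface:
#' * bend amplitude (mm): dorsoventral (`z`) deviation from rest of the
#'   midchord point at the reference span station (default 70% span);
#' * twist (deg, per span station): signed rotation of the chord line about
#'   the spanwise axis relative to its rest orientation, measured in the
#'   chord-normal (`y`-`z`) plane about the midchord pivot;
#' * stroke angle (deg): signed angle, within the mean stroke plane (total
#'   least-squares plane through the wingtip track), between each frame's
#'   wingbase-to-wingtip vector and the mean tip direction.
#'
#' @param surfaces list of surfaces from [reconstructSurface()] (one per
#'   frame).
#' @param restSurface the resting surface (same grid shape).
#' @param wingtipTrack optional frames x 3 matrix of wingtip positions in the
#'   wingbase frame; stroke angle is skipped when absent and an error is
#'   raised when the track is degenerate (stationary).
#' @param bendStation span fraction of the bend reference station.
#' @return list with `bendAmplitude` (per frame, mm), `twist` (frames x
#'   stations matrix, deg), `strokeAngle` (per frame, deg, or `NULL`), `s`
#'   (span stations).
#' @export
deformationMetrics <- function(surfaces, restSurface, wingtipTrack = NULL,
                               bendStation = 0.70) {
  stopifnot(length(surfaces) >= 1L)
  dimS <- dim(restSurface$points)
  for (sf in surfaces)
    if (!identical(dim(sf$points), dimS))
      stop("all surfaces must share the rest surface's grid shape")
  s <- restSurface$s
  nSpan <- dimS[1]; nChord <- dimS[2]
  iStation <- which.min(abs(s - bendStation))
  iMid <- max(1L, round(nChord / 2))

  chordAngles <- function(pts) {
    ## chord vector leading -> trailing per station, angle in (y, z) plane
    dy <- pts[, nChord, 2] - pts[, 1, 2]
    dz <- pts[, nChord, 3] - pts[, 1, 3]
    atan2(dz, dy)
  }
  restAng <- chordAngles(restSurface$points)
  nF <- length(surfaces)
  bend <- numeric(nF)
  twist <- matrix(NA_real_, nF, nSpan)
  for (f in seq_len(nF)) {
    pts <- surfaces[[f]]$points
    bend[f] <- pts[iStation, iMid, 3] - restSurface$points[iStation, iMid, 3]
    d <- (chordAngles(pts) - restAng + pi) %% (2 * pi) - pi
    twist[f, ] <- d * 180 / pi
  }

  strokeAngle <- NULL
  if (!is.null(wingtipTrack)) {
    W <- as.matrix(wingtipTrack)
    if (nrow(W) != nF) stop("wingtip track must have one row per frame")
    sds <- apply(W, 2, stats::sd)
    if (nrow(W) < 2L || all(is.na(sds)) || max(sds, na.rm = TRUE) < 1e-9)
      stop("degenerate (stationary) wingtip track: stroke angle undefined")
    pl <- fitPlaneTLS(W)
    ## in-plane orthonormal basis aligned with the mean tip direction
    mu <- colMeans(W)
    e1 <- mu - sum(mu * pl$normal) * pl$normal
    if (sqrt(sum(e1^2)) < 1e-9) e1 <- W[1, ] - sum(W[1, ] * pl$normal) * pl$normal
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(pl$normal[2] * e1[3] - pl$normal[3] * e1[2],
            pl$normal[3] * e1[1] - pl$normal[1] * e1[3],
            pl$normal[1] * e1[2] - pl$normal[2] * e1[1])
    strokeAngle <- atan2(W %*% e2, W %*% e1)[, 1] * 180 / pi
  }
  list(bendAmplitude = bend, twist = twist, strokeAngle = strokeAngle, s = s)
}
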