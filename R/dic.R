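#' @include AllClasses.R wing-grid.R
NULL

## Zero-normalized cross-correlation between a template and equally sized
## window (both vectors, means removed internally).
znccVec <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den < 1e-12) return(NA_real_)
  sum(a * b) / den
}

## Sub-sample peak offset from three samples (cm, c0, cp) around the
## maximum: Gaussian three-point estimator when all values are positive
## (exact for a Gaussian-shaped correlation peak), parabolic otherwise.
peakOffset1D <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0 && c0 >= cm && c0 >= cp) {
    den <- log(cm) - 2 * log(c0) + log(cp)
    if (den < -1e-12) return(max(-0.5, min(0.5, (log(cm) - log(cp)) / (2 * den))))
  }
  den <- cm - 2 * c0 + cp
  if (den < -1e-12) max(-0.5, min(0.5, (cm - cp) / (2 * den))) else 0
}

#' Automatic DIC subset size
#'
#' Subset side chosen so the subset area is about 1% of the wing area in
#' pixels (rounded to the nearest odd integer >= 3).
#'
#' @param maskAreaPx wing planform area, px^2.
#' @return odd integer subset side, px.
#' @export
dicSubsetSize <- function(maskAreaPx) oddRound(sqrt(0.01 * maskAreaPx))

#' Subset digital image correlation between two frames
#'
#' For each bin center, an odd-sided subset around the bin in the reference
#' frame is matched in the current frame by integer-pixel zero-normalized
#' cross-correlation search within `searchRadius`, followed by subpixel
#' refinement from a quadratic fit to the 3 x 3 correlation neighbourhood.
#' Bins whose peak correlation falls below `minCorrelation` (textureless or
#' lost subsets) are flagged invalid, as are bins whose peak lies on the
#' search border or whose subset leaves the frame.
#'
#' @param reference,current numeric grayscale image matrices (rows = y).
#' @param centers n x 2 matrix / data.frame of bin centers in pixel
#'   coordinates `(x, y)`.
#' @param subsetSize odd subset side, px (e.g. [dicSubsetSize()]).
#' @param searchRadius integer search radius, px (> 0).
#' @param minCorrelation validity threshold on the correlation peak.
#' @return data.frame with per-bin `u` (x-displacement, px), `v`
#'   (y-displacement, px), `cc` (peak correlation), `valid`.
#' @export
dicDisplacementField <- function(reference, current, centers, subsetSize,
                                 searchRadius = 10L, minCorrelation = 0.6) {
  if (searchRadius <= 0) stop("search radius must be > 0")
  if (subsetSize %% 2 == 0) stop("subset side must be odd")
  if (subsetSize > min(dim(reference)) || subsetSize > min(dim(current)))
    stop("subset larger than frame")
  centers <- as.matrix(centers)[, 1:2, drop = FALSE]
  hw <- (subsetSize - 1L) %/% 2L
  r <- as.integer(searchRadius)
  nr <- nrow(reference); nc <- ncol(reference)
  n <- nrow(centers)
  u <- v <- cc <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  offs <- (-r):r
  for (i in seq_len(n)) {
    cx <- round(centers[i, 1]); cy <- round(centers[i, 2])
    if (cx - hw < 1 || cx + hw > nc || cy - hw < 1 || cy + hw > nr) next
    tmpl <- reference[(cy - hw):(cy + hw), (cx - hw):(cx + hw)]
    if (stats::sd(tmpl) < 1e-9) next          # textureless reference subset
    C <- matrix(NA_real_, 2 * r + 1, 2 * r + 1)
    for (a in seq_along(offs)) {
      dy <- offs[a]
      ylo <- cy + dy - hw; yhi <- cy + dy + hw
      if (ylo < 1 || yhi > nrow(current)) next
      for (b in seq_along(offs)) {
        dx <- offs[b]
        xlo <- cx + dx - hw; xhi <- cx + dx + hw
        if (xlo < 1 || xhi > ncol(current)) next
        C[a, b] <- znccVec(tmpl, current[ylo:yhi, xlo:xhi])
      }
    }
    if (all(is.na(C))) next
    pk <- which(C == max(C, na.rm = TRUE), arr.ind = TRUE)[1, ]
    cc[i] <- C[pk[1], pk[2]]
    if (pk[1] == 1 || pk[1] == nrow(C) || pk[2] == 1 || pk[2] == ncol(C)) {
      u[i] <- offs[pk[2]]; v[i] <- offs[pk[1]]
      next                                     # peak on search border
    }
    nb <- C[(pk[1] - 1):(pk[1] + 1), (pk[2] - 1):(pk[2] + 1)]
    if (any(is.na(nb))) { u[i] <- offs[pk[2]]; v[i] <- offs[pk[1]]; next }
    if (cc[i] >= 1 - 1e-12) {
      dxy <- c(0, 0)                          # exact match: no refinement
    } else {
      ## three-point Gaussian (log-parabolic) peak estimator per axis,
      ## falling back to a plain parabola for non-positive neighbours
      dxy <- c(peakOffset1D(nb[2, 1], nb[2, 2], nb[2, 3]),
               peakOffset1D(nb[1, 2], nb[2, 2], nb[3, 2]))
    }
    u[i] <- offs[pk[2]] + dxy[1]
    v[i] <- offs[pk[1]] + dxy[2]
    valid[i] <- cc[i] >= minCorrelation
  }
  data.frame(u = u, v = v, cc = cc, valid = valid)
}

#' Strain field from per-bin displacement
#'
#' Small-strain spanwise normal strain from a local least-squares plane fit:
#' for each frame and each bin, the spanwise displacement component over the
#' bin's valid `(2k+1) x (2k+1)` grid neighbourhood is regressed on the bin
#' coordinates, and the strain is the spanwise slope `d u_x / d x`.  Bins
#' with fewer than 6 valid neighbours (or no spanwise spread) are invalid.
#'
#' @param displacement frames x bins matrix of the spanwise displacement
#'   component (mm or px, consistent with `grid` units), `NA` = invalid.
#' @param grid a [WingGrid-class].
#' @param halfWidth neighbourhood half-width in bins (default 1, i.e. 3 x 3).
#' @param fs frame rate of the series (frames/s) for the returned field.
#' @return a [DeformationField-class] of kind `"strain"`.
#' @export
strainFromDisplacement <- function(displacement, grid, halfWidth = 1L,
                                   fs = 1) {
  displacement <- as.matrix(displacement)
  if (ncol(displacement) != grid@rows * grid@cols)
    stop("displacement must have rows*cols columns")
  nT <- nrow(displacement)
  bc <- binCenters(grid)
  S <- matrix(NA_real_, nT, ncol(displacement))
  ## precompute neighbourhood bin indices per bin
  nbrs <- vector("list", ncol(displacement))
  for (b in which(as.vector(grid@mask))) {
    rc <- binRowCol(grid, b)
    rr <- max(1, rc[1] - halfWidth):min(grid@rows, rc[1] + halfWidth)
    cc <- max(1, rc[2] - halfWidth):min(grid@cols, rc[2] + halfWidth)
    nbrs[[b]] <- as.integer(outer(rr, (cc - 1L) * grid@rows, `+`))
  }
  for (f in seq_len(nT)) {
    ui <- displacement[f, ]
    for (b in which(as.vector(grid@mask))) {
      nb <- nbrs[[b]]
      ok <- nb[!is.na(ui[nb]) & grid@mask[nb]]
      if (length(ok) < 6L) next
      xs <- bc$x_mm[ok]; ys <- bc$y_mm[ok]
      if (diff(range(xs)) < 1e-12) next
      X <- cbind(1, xs - mean(xs), ys - mean(ys))
      beta <- tryCatch(qr.solve(X, ui[ok]), error = function(e) NULL)
      if (!is.null(beta)) S[f, b] <- beta[2]
    }
  }
  methods::new("DeformationField", grid = grid, data = S, fs = fs,
               kind = "strain", truth = list())
}
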