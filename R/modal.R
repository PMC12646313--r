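#' @include AllClasses.R
NULL

#' Fit structural modes by PCA of a displacement field
#'
#' Removes the per-bin temporal mean and decomposes the frames x bins matrix
#' into orthonormal spatial mode shapes, mm-scaled score series and variance
#' fractions (eigendecomposition of the smaller of the two covariance
#' matrices, so both tall and wide fields are handled).  Bins outside the
#' planform mask, or invalid (`NA`) in any frame, are dropped from the basis
#' — the decomposition stays a fixed linear map.  Each shape is scaled so
#' its largest-magnitude bin is positive (dorsal), fixing the PC sign.
#'
#' @param field a [DeformationField-class].
#' @param nModes number of modes to retain (<= `min(frames, usable bins)`).
#' @return a [ModalDecomposition-class].
#' @examples
#' g <- wingGrid(6, 12)
#' f <- synthDisplacementField(g, modalModel(seed = 5), duration = 0.5, fs = 2000)
#' dec <- fitModes(f, 3)
#' varianceFractions(dec)
#' @export
fitModes <- function(field, nModes) {
  stopifnot(methods::is(field, "DeformationField"))
  X <- field@data
  nT <- nrow(X)
  if (nT < 2L) stop("need at least 2 frames")
  usable <- as.vector(field@grid@mask) & colSums(is.na(X)) == 0L
  binIdx <- which(usable)
  B <- length(binIdx)
  if (B < nModes) stop("fewer usable bins than requested modes")
  if (nModes > min(nT, B)) stop("nModes exceeds min(frames, bins)")
  Xc <- X[, binIdx, drop = FALSE]
  ctr <- colMeans(Xc)
  Xc <- sweep(Xc, 2, ctr)
  totVar <- sum(Xc^2) / (nT - 1)

  if (B <= nT) {
    C <- crossprod(Xc) / (nT - 1)
    eg <- eigen(C, symmetric = TRUE)
    lam <- pmax(eg$values[seq_len(nModes)], 0)
    shapes <- eg$vectors[, seq_len(nModes), drop = FALSE]
    scores <- Xc %*% shapes
  } else {
    G <- tcrossprod(Xc) / (nT - 1)
    eg <- eigen(G, symmetric = TRUE)
    lam <- pmax(eg$values[seq_len(nModes)], 0)
    U <- eg$vectors[, seq_len(nModes), drop = FALSE]
    shapes <- crossprod(Xc, U)
    nrm <- sqrt(pmax(colSums(shapes^2), 1e-300))
    shapes <- sweep(shapes, 2, nrm, `/`)
    scores <- Xc %*% shapes
  }
  ## deterministic sign: largest-|value| bin of each shape is positive
  for (j in seq_len(nModes)) {
    k <- which.max(abs(shapes[, j]))
    if (shapes[k, j] < 0) { shapes[, j] <- -shapes[, j]; scores[, j] <- -scores[, j] }
  }
  methods::new("ModalDecomposition", grid = field@grid,
               binIndex = as.integer(binIdx), center = ctr, shapes = shapes,
               scores = scores,
               varianceFractions = lam / totVar, totalVariance = totVar,
               fs = field@fs)
}

#' Project a field onto a fitted modal basis
#'
#' Mean-subtracts the field (using the decomposition's stored mean) and
#' projects onto the orthonormal shapes; projecting the training field
#' returns the stored scores.
#'
#' @param field a [DeformationField-class] on the same grid.
#' @param decomposition a [ModalDecomposition-class].
#' @return frames x nModes score matrix (mm).
#' @export
projectScores <- function(field, decomposition) {
  stopifnot(methods::is(field, "DeformationField"),
            methods::is(decomposition, "ModalDecomposition"))
  g <- field@grid; d <- decomposition@grid
  if (g@rows != d@rows || g@cols != d@cols ||
      max(abs(g@x - d@x)) > 1e-9 || max(abs(g@y - d@y)) > 1e-9)
    stop("field grid does not match the decomposition grid")
  Xc <- sweep(field@data[, decomposition@binIndex, drop = FALSE], 2,
              decomposition@center)
  Xc %*% decomposition@shapes
}

#' Reconstruct a field from modal scores
#'
#' `mean + sum over the selected modes of score * shape`; with all modes of
#' a full-rank decomposition this reproduces the original field.
#'
#' @param scores frames x nModes score matrix (columns matching the
#'   decomposition's modes).
#' @param decomposition a [ModalDecomposition-class].
#' @param modes integer subset of modes to use (default all fitted).
#' @return a [DeformationField-class] of kind `"displacement"`; bins outside
#'   the decomposition basis are `NA`.
#' @export
reconstructField <- function(scores, decomposition,
                             modes = seq_len(ncol(decomposition@shapes))) {
  stopifnot(methods::is(decomposition, "ModalDecomposition"))
  if (any(modes < 1L) || any(modes > ncol(decomposition@shapes)))
    stop("modes subset outside the fitted modes")
  scores <- as.matrix(scores)
  X <- scores[, modes, drop = FALSE] %*%
    t(decomposition@shapes[, modes, drop = FALSE])
  X <- sweep(X, 2, decomposition@center, `+`)
  g <- decomposition@grid
  data <- matrix(NA_real_, nrow(X), g@rows * g@cols)
  data[, decomposition@binIndex] <- X
  methods::new("DeformationField", grid = g, data = data,
               fs = decomposition@fs, kind = "displacement", truth = list())
}
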