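#' @include utils.R
NULL

## Collinearity test for a 4-point quad (any 3 of the 4 points).
anyThreeCollinear <- function(p, tol = 1e-8) {
  combs <- utils::combn(4, 3)
  scale2 <- max(apply(p, 2, function(v) diff(range(v))))^2
  for (k in seq_len(ncol(combs))) {
    a <- p[combs[1, k], ]; b <- p[combs[2, k], ]; c <- p[combs[3, k], ]
    area2 <- abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    if (area2 <= tol * scale2) return(TRUE)
  }
  FALSE
}

#' Estimate a projective homography from four point correspondences
#'
#' Direct linear solution of the 8 homography parameters mapping each `src`
#' point exactly onto its `dst` point, normalized so the bottom-right entry
#' is 1.
#'
#' @param src 4 x 2 matrix of source (image) points.
#' @param dst 4 x 2 matrix of destination (plane) points.
#' @return 3 x 3 homography matrix `H` with `H[3, 3] == 1`, mapping
#'   `src -> dst` in homogeneous coordinates.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' estimateHomography(sq, sq)  # identity
#' @export
estimateHomography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(identical(dim(src), c(4L, 2L)), identical(dim(dst), c(4L, 2L)))
  if (anyDuplicated(src) || anyDuplicated(dst))
    stop("duplicate points in quad")
  if (anyThreeCollinear(src) || anyThreeCollinear(dst))
    stop("three collinear points in quad; homography is degenerate")
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  H <- rbind(h[1:3], h[4:6], c(h[7], h[8], 1))
  if (abs(det(H)) < 1e-12) stop("estimated homography is singular")
  H
}

#' Apply a homography to 2D points
#'
#' @param H 3 x 3 homography matrix.
#' @param pts n x 2 matrix of points.
#' @return n x 2 matrix of mapped points.
#' @export
applyHomography <- function(H, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  P <- cbind(pts, 1) %*% t(H)
  P[, 1:2, drop = FALSE] / P[, 3]
}

## Bilinear sampling of an image matrix (rows = y, cols = x) at fractional
## coordinates; out-of-bounds samples return `fill`.
bilinearSample <- function(img, x, y, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & x0 <= nc - 1 & y0 >= 1 & y0 <= nr - 1
  out <- rep(fill, length(x))
  if (any(ok)) {
    i00 <- y0[ok] + (x0[ok] - 1) * nr
    v00 <- img[i00];        v10 <- img[i00 + nr]
    v01 <- img[i00 + 1];    v11 <- img[i00 + nr + 1]
    out[ok] <- v00 * (1 - fx[ok]) * (1 - fy[ok]) + v10 * fx[ok] * (1 - fy[ok]) +
               v01 * (1 - fx[ok]) * fy[ok]       + v11 * fx[ok] * fy[ok]
  }
  out
}

#' Rectify frames with a homography
#'
#' Inverse-warps each frame into the wing plane: output pixel `(x, y)` (in
#' plane coordinates) samples the input frame at `H^-1 (x, y)` with bilinear
#' interpolation.  `H` is the image -> plane homography, as returned by
#' [estimateHomography()] with image points as `src`.
#'
#' @param frames list of numeric image matrices (rows = y, cols = x),
#'   grayscale in any consistent intensity scale.
#' @param H 3 x 3 homography mapping image coordinates to plane coordinates.
#' @param outSize integer `c(width, height)` of the rectified output.
#' @return list of rectified frames (`height x width` matrices).
#' @export
rectifyFrames <- function(frames, H, outSize) {
  if (!length(frames)) stop("empty frame stack")
  if (abs(det(H)) < 1e-12) stop("homography is not invertible")
  Hinv <- solve(H)
  W <- outSize[1]; Hgt <- outSize[2]
  gridPts <- cbind(rep(seq_len(W), each = Hgt), rep(seq_len(Hgt), W))
  srcPts <- applyHomography(Hinv, gridPts)
  lapply(frames, function(fr)
    matrix(bilinearSample(fr, srcPts[, 1], srcPts[, 2]), nrow = Hgt, ncol = W))
}
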