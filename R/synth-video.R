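#' @include AllClasses.R homography.R
NULL

#' Random speckle texture
#'
#' Smoothed uniform noise, rescaled to 8-bit range; the correlation length of
#' about 1.5 px gives the intensity gradients subset correlation needs.
#'
#' @param width,height texture size, px.
#' @param seed RNG seed.
#' @param sigma Gaussian smoothing SD, px.
#' @return `height x width` numeric matrix with values in 0..255.
#' @export
speckleTexture <- function(width, height, seed = 1L, sigma = 1.2) {
  withSeed(seed, {
    img <- matrix(stats::runif(width * height), height, width)
    hw <- max(2L, ceiling(3 * sigma))
    k <- stats::dnorm(-hw:hw, sd = sigma); k <- k / sum(k)
    img <- apply(img, 2, function(col) stats::filter(col, k, circular = TRUE))
    img <- t(apply(img, 1, function(row) stats::filter(row, k, circular = TRUE)))
    img <- img - min(img)
    img <- img / max(img)
    30 + 195 * img
  })
}

## Map wing-plane mm coordinates to plane-image pixel coordinates.
gridToPixelMap <- function(grid, imageSize, margin) {
  W <- imageSize[1]; H <- imageSize[2]
  sx <- (W - 2 * margin) / diff(range(grid@x))
  sy <- (H - 2 * margin) / diff(range(grid@y))
  list(
    px = function(x_mm) margin + (x_mm - min(grid@x)) * sx,
    py = function(y_mm) margin + (y_mm - min(grid@y)) * sy,
    sx = sx, sy = sy)
}

#' Render a synthetic speckle video from a displacement field
#'
#' Frame 1 is the reference texture (the resting wing).  Each later frame
#' warps the texture by the per-bin displacement of the corresponding field
#' frame — converted to image pixels via `pxPerMm` and the unit image-plane
#' `direction` the out-of-plane motion projects onto — and then, if a
#' homography is supplied, by the plane-to-camera projective map.  Output is
#' 8-bit grayscale.
#'
#' @param field a [DeformationField-class] (kind `"displacement"`).
#' @param imageSize integer `c(width, height)` of the plane image, px.
#' @param pxPerMm out-of-plane-to-image gain, px per mm of displacement
#'   (> 0).
#' @param direction length-2 image-plane direction the displacement maps to
#'   (normalized internally); default straight down the image y axis.
#' @param homography optional 3 x 3 plane-to-camera homography; frames are
#'   projected through it after the displacement warp.
#' @param textureSeed seed for the speckle texture.
#' @param margin texture border outside the grid, px.
#' @param frames which field frames to render (default all).
#' @return list with `frames` (list of integer `height x width` matrices,
#'   0-255), `texture`, and the grid-to-pixel mapping functions (`px`, `py`).
#' @export
synthSpeckleVideo <- function(field, imageSize = c(160, 120), pxPerMm = 4,
                              direction = c(0, 1), homography = NULL,
                              textureSeed = 1L, margin = 12,
                              frames = seq_len(nFrames(field))) {
  stopifnot(methods::is(field, "DeformationField"))
  if (pxPerMm <= 0) stop("pxPerMm gain must be > 0")
  if (!is.null(homography) && abs(det(homography)) < 1e-12)
    stop("homography is not invertible")
  dirn <- direction / sqrt(sum(direction^2))
  g <- field@grid
  W <- imageSize[1]; H <- imageSize[2]
  mp <- gridToPixelMap(g, imageSize, margin)
  tex <- speckleTexture(W, H, seed = textureSeed)

  ## pixel grid -> fractional bin coordinates (clamped to grid edges so the
  ## texture outside the planform follows the nearest edge bin)
  pxAll <- rep(seq_len(W), each = H)
  pyAll <- rep(seq_len(H), W)
  colF <- stats::approx(mp$px(g@x), seq_len(g@cols), xout = pxAll,
                        rule = 2)$y
  rowF <- stats::approx(mp$py(g@y), seq_len(g@rows), xout = pyAll,
                        rule = 2)$y

  quant <- function(img) {
    img <- round(pmin(pmax(img, 0), 255))
    matrix(as.integer(img), nrow(img), ncol(img))
  }
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fIdx <- frames[k]
    U <- matrix(field@data[fIdx, ], g@rows, g@cols)
    U[is.na(U)] <- 0
    uPix <- bilinearSample(U, colF, rowF) * pxPerMm    # px along `direction`
    warped <- matrix(
      bilinearSample(tex, pxAll - uPix * dirn[1], pyAll - uPix * dirn[2]),
      nrow = H, ncol = W)
    if (!is.null(homography)) {
      ## render camera view: camera pixel q samples plane at H^-1 q
      warped <- rectifyFrames(list(warped), homography,
                              outSize = imageSize)[[1]]
    }
    out[[k]] <- quant(warped)
  }
  list(frames = out, texture = quant(tex), px = mp$px, py = mp$py,
       pxPerMm = pxPerMm, direction = dirn)
}
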