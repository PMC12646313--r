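#' @include AllClasses.R
NULL

#' Construct a wing grid
#'
#' Builds the regular spatial binning of the wing planform on which
#' displacement and strain fields are defined.  Coordinates follow the
#' wingbase convention: `x` spanwise in mm (0 at the wingbase, positive
#' distal), `y` chordwise in mm (0 at the leading edge, positive toward the
#' trailing edge).
#'
#' @param rows number of chordwise rows (>= 2).
#' @param cols number of spanwise columns (>= 2).
#' @param span wing length, mm (default 40, a typical darter forewing).
#' @param chord maximum chord, mm (default 10).
#' @param planform `"full"` (every bin inside) or `"tapered"` (chord narrows
#'   elliptically toward the tip, emulating a wing outline).
#' @return a [WingGrid-class].
#' @examples
#' g <- wingGrid(10, 20)
#' g
#' @export
wingGrid <- function(rows, cols, span = 40, chord = 10,
                     planform = c("full", "tapered")) {
  planform <- match.arg(planform)
  rows <- as.integer(rows); cols <- as.integer(cols)
  x <- seq(0, span, length.out = cols)
  y <- seq(0, chord, length.out = rows)
  mask <- matrix(TRUE, rows, cols)
  if (planform == "tapered") {
    ## chord shrinks toward the tip; keep leading-edge rows, trim trailing
    s <- x / span
    localChord <- chord * sqrt(pmax(0, 1 - 0.85 * s^2))
    for (j in seq_len(cols)) mask[, j] <- y <= localChord[j] + 1e-9
    mask[1, ] <- TRUE  # leading edge always present
  }
  methods::new("WingGrid", rows = rows, cols = cols, x = x, y = y, mask = mask)
}

#' Bin center coordinates of a wing grid
#'
#' @param grid a [WingGrid-class].
#' @param maskedOnly return only bins inside the planform mask.
#' @return data.frame with columns `bin` (column-major index), `row`, `col`,
#'   `x_mm`, `y_mm`, `masked`.
#' @export
binCenters <- function(grid, maskedOnly = FALSE) {
  stopifnot(methods::is(grid, "WingGrid"))
  df <- data.frame(
    bin = seq_len(grid@rows * grid@cols),
    row = rep(seq_len(grid@rows), grid@cols),
    col = rep(seq_len(grid@cols), each = grid@rows),
    x_mm = rep(grid@x, each = grid@rows),
    y_mm = rep(grid@y, grid@cols),
    masked = as.vector(grid@mask))
  if (maskedOnly) df[df$masked, , drop = FALSE] else df
}

## Column-major bin index helpers.
binIndexOf <- function(grid, row, col) row + (col - 1L) * grid@rows
binRowCol <- function(grid, bin) {
  r <- ((bin - 1L) %% grid@rows) + 1L
  c <- ((bin - 1L) %/% grid@rows) + 1L
  cbind(row = r, col = c)
}

## Nearest bin (column-major index) to wing-plane coordinates; NA outside
## grid bounds (beyond half a bin spacing).
nearestBin <- function(grid, x_mm, y_mm) {
  dx <- mean(diff(grid@x)); dy <- mean(diff(grid@y))
  ok <- x_mm >= min(grid@x) - dx / 2 & x_mm <= max(grid@x) + dx / 2 &
        y_mm >= min(grid@y) - dy / 2 & y_mm <= max(grid@y) + dy / 2
  ci <- vapply(x_mm, function(v) which.min(abs(grid@x - v)), integer(1))
  ri <- vapply(y_mm, function(v) which.min(abs(grid@y - v)), integer(1))
  out <- binIndexOf(grid, ri, ci)
  out[!ok] <- NA_integer_
  out
}

#' Construct a deformation field from a data matrix
#'
#' Wraps a frames x bins matrix (column-major bin order; `NA` = invalid or
#' outside the planform) as a deformation field, e.g. for user-measured
#' data entering the pipeline.
#'
#' @param data numeric `frames x (rows*cols)` matrix.
#' @param grid a [WingGrid-class].
#' @param fs frame rate, frames/s.
#' @param kind `"displacement"` (mm, positive = dorsal) or `"strain"`.
#' @param truth optional ground-truth sidecar list.
#' @return a [DeformationField-class].
#' @export
deformationField <- function(data, grid, fs, kind = "displacement",
                             truth = list()) {
  methods::new("DeformationField", grid = grid, data = as.matrix(data),
               fs = fs, kind = kind, truth = truth)
}
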