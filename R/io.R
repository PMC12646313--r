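#' @include AllClasses.R wing-grid.R
NULL

#' Read/write the plain-text field container
#'
#' A deformation field is stored as a directory: `meta.json` (rows, cols,
#' fs, kind), `grid_x.csv`, `grid_y.csv`, `mask.csv`, and `field.csv`
#' (frames x bins, column-major bin order, `NA` = invalid/outside-mask).
#' Round-trips exactly at full double precision.
#'
#' @param field a [DeformationField-class].
#' @param path container directory (created if needed).
#' @return `writeFieldContainer`: `path`, invisibly.  `readFieldContainer`:
#'   a [DeformationField-class] (ground-truth sidecar not persisted).
#' @export
writeFieldContainer <- function(field, path) {
  stopifnot(methods::is(field, "DeformationField"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  g <- field@grid
  jsonlite::write_json(list(rows = g@rows, cols = g@cols, fs = field@fs,
                            kind = field@kind),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  data.table::fwrite(data.table::data.table(x_mm = g@x),
                     file.path(path, "grid_x.csv"))
  data.table::fwrite(data.table::data.table(y_mm = g@y),
                     file.path(path, "grid_y.csv"))
  data.table::fwrite(data.table::as.data.table(g@mask * 1L),
                     file.path(path, "mask.csv"), col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(field@data),
                     file.path(path, "field.csv"), col.names = FALSE)
  invisible(path)
}

#' @rdname writeFieldContainer
#' @export
readFieldContainer <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  x <- data.table::fread(file.path(path, "grid_x.csv"))$x_mm
  y <- data.table::fread(file.path(path, "grid_y.csv"))$y_mm
  mask <- as.matrix(data.table::fread(file.path(path, "mask.csv"),
                                      header = FALSE)) > 0
  dimnames(mask) <- NULL
  grid <- methods::new("WingGrid", rows = as.integer(meta$rows),
                       cols = as.integer(meta$cols), x = x, y = y, mask = mask)
  dat <- as.matrix(data.table::fread(file.path(path, "field.csv"),
                                     header = FALSE))
  dimnames(dat) <- NULL
  methods::new("DeformationField", grid = grid, data = dat, fs = meta$fs,
               kind = meta$kind, truth = list())
}

#' Read/write spike trains as CSV
#'
#' Columns `unit_id`, `t_s`.  Duration and frame rate are recording-level
#' metadata supplied by the caller on read.
#'
#' @param spikes a [SpikeTrain-class] or list of them.
#' @param path CSV file path.
#' @param duration,fs recording duration (s) and frame rate (frames/s).
#' @return `writeSpikes`: `path` invisibly; `readSpikes`: list of
#'   [SpikeTrain-class], one per unit.
#' @export
writeSpikes <- function(spikes, path) {
  if (methods::is(spikes, "SpikeTrain")) spikes <- list(spikes)
  df <- do.call(rbind, lapply(spikes, function(s)
    data.frame(unit_id = s@unitId, t_s = s@times)))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeSpikes
#' @export
readSpikes <- function(path, duration, fs) {
  df <- data.table::fread(path)
  byUnit <- split(df$t_s, df$unit_id)
  Map(function(tt, id) spikeTrain(tt, duration, fs, unitId = id),
      byUnit, names(byUnit))
}

#' Read/write a sensor map as CSV
#'
#' Columns `sensor_id`, `x_mm`, `y_mm`, `side`, `vein`.
#'
#' @param sensors sensor map data.frame.
#' @param path CSV file path.
#' @return `writeSensorMap`: `path` invisibly; `readSensorMap`: data.frame.
#' @export
writeSensorMap <- function(sensors, path) {
  data.table::fwrite(sensors, path)
  invisible(path)
}

#' @rdname writeSensorMap
#' @export
readSensorMap <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Read/write edge traces as CSV
#'
#' Columns `frame`, `edge` (`L`/`T`), `s`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param traces edge-trace data.frame ([synthEdgeTraces()] format).
#' @param path CSV file path.
#' @return `writeEdgeTraces`: `path` invisibly; `readEdgeTraces`: data.frame.
#' @export
writeEdgeTraces <- function(traces, path) {
  data.table::fwrite(traces, path)
  invisible(path)
}

#' @rdname writeEdgeTraces
#' @export
readEdgeTraces <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Read/write 8-bit grayscale video as numbered PNG frames
#'
#' @param frames list of integer matrices (0-255).
#' @param dir output directory (`frame_000001.png`, ...).
#' @return `writeVideoPNG`: `dir` invisibly; `readVideoPNG`: list of
#'   integer matrices.
#' @export
writeVideoPNG <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames))
    png::writePNG(frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  invisible(dir)
}

#' @rdname writeVideoPNG
#' @export
readVideoPNG <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  })
}
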