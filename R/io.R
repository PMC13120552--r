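# File I/O: lossless CSV grids, 32-bit float TIFF with a JSON scale sidecar,
# and sinogram/report serialization.

#' Write / read a numeric grid as CSV
#'
#' Plain CSV of the matrix values (no header), lossless at double precision.
#'
#' @param x numeric matrix, [ActivityImage-class] or [Sinogram-class].
#' @param path file path.
#' @return `readGridCSV` returns a numeric matrix; writers return `path`
#'   invisibly.
#' @export
writeGridCSV <- function(x, path) {
  m <- if (is.matrix(x)) x else values(x)
  data.table::fwrite(as.data.frame(m), path, col.names = FALSE)
  invisible(path)
}

#' @rdname writeGridCSV
#' @export
readGridCSV <- function(path) {
  unname(as.matrix(data.table::fread(path, header = FALSE)))
}

#' Write / read a grid as 32-bit float TIFF
#'
#' TIFF float samples are stored in [0, 1]; values are therefore divided by a
#' scale factor (the data maximum) recorded in a JSON sidecar
#' (`<path>.json`), making the round trip lossless to float32 precision.
#'
#' @param x numeric matrix or [ActivityImage-class].
#' @param path TIFF file path.
#' @return `readGridTIFF` returns a numeric matrix; the writer returns
#'   `path` invisibly.
#' @export
writeGridTIFF <- function(x, path) {
  m <- if (is.matrix(x)) x else values(x)
  scale <- max(m, 1e-300)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = scale, nrow = nrow(m), ncol = ncol(m)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGridTIFF
#' @export
readGridTIFF <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tiff::readTIFF(path) * meta$scale
}

#' Write / read a sinogram (values + variance + angles)
#'
#' CSV pair (`<path>` for counts, `<path>.var.csv` for variance) with a JSON
#' sidecar holding angles and bin pitch.
#'
#' @param sino a [Sinogram-class].
#' @param path CSV file path.
#' @return `readSinogram` returns a [Sinogram-class]; the writer returns
#'   `path` invisibly.
#' @export
writeSinogram <- function(sino, path) {
  data.table::fwrite(as.data.frame(sino@values), path, col.names = FALSE)
  data.table::fwrite(as.data.frame(sino@variance), paste0(path, ".var.csv"),
                     col.names = FALSE)
  jsonlite::write_json(list(anglesDeg = sino@anglesDeg, binMm = sino@binMm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  v <- unname(as.matrix(data.table::fread(path, header = FALSE)))
  vr <- unname(as.matrix(data.table::fread(paste0(path, ".var.csv"),
                                           header = FALSE)))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sinogram(v, anglesDeg = meta$anglesDeg, binMm = meta$binMm, variance = vr)
}
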