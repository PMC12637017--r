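#' Write / read MRC (mode 2, float32) images and volumes
#'
#' Minimal MRC2014 implementation sufficient for exchanging simulated images
#' and rasterised material volumes with standard EM viewers.  Data are
#' written little-endian as 32-bit floats with the pixel size recorded in the
#' cell dimensions; an extended-header text label carries provenance.
#'
#' @param data 2D matrix or 3D array.
#' @param path Output path.
#' @param pixel_size_nm Pixel (and slice) size in nm.
#' @param label Short provenance string (<= 80 chars).
#' @return `read_mrc()` returns a list with `data`, `pixel_size_nm`.
#' @export
write_mrc <- function(data, path, pixel_size_nm = 1, label = "thickEM") {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L)
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  px_A <- pixel_size_nm * 10
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2 = float32
  wi(c(0L, 0L, 0L))          # nstart
  wi(d)                      # mx my mz
  wf(d * px_A)               # cell lengths, Angstrom
  wf(c(90, 90, 90))          # cell angles
  wi(c(1L, 2L, 3L))          # axis mapping
  wf(c(min(data), max(data), mean(data)))
  wi(0L)                     # ispg
  wi(0L)                     # nsymbt
  writeBin(raw(100L), con)   # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(data)))
  wi(1L)                     # nlabl
  lab <- substr(sprintf("%-80s", label), 1L, 80L)
  writeChar(lab, con, nchars = 80L, eos = NULL)
  writeBin(raw(80L * 9L), con)
  writeBin(as.numeric(data), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  d <- ri(3L)
  mode <- ri(1L)
  if (mode != 2L) stop("only mode-2 (float32) MRC supported", call. = FALSE)
  ri(3L); mx <- ri(3L)
  cell <- rf(3L)
  seek(con, 1024L)
  data <- array(rf(prod(d)), dim = d)
  list(data = data, pixel_size_nm = cell[1] / d[1] / 10)
}

#' Write a numeric curve as CSV
#'
#' @param df Data frame (e.g. a [ctf()] table).
#' @param path Output path.
#' @export
write_curve <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
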