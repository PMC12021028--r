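#' 3D scalar volume with physical scale
#'
#' A `volume3d` wraps a numeric 3D array together with its voxel size in
#' Angstrom and the physical origin of voxel (1,1,1). Arrays are stored in
#' R's native column-major order, `dim = c(nx, ny, nz)` with x fastest,
#' which is also the on-disk layout of MRC files.
#'
#' @param data numeric 3D array, `dim = c(nx, ny, nz)`; finite values only.
#' @param voxel_size isotropic voxel size in Angstrom (> 0).
#' @param origin length-3 numeric, Angstrom offset of voxel (1,1,1).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume3d: 'data' must be a 3D array")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume3d: non-finite values in 'data'")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("volume3d: 'voxel_size' must be a single positive number")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("volume3d: 'origin' must be 3 finite numbers")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d: %d x %d x %d voxels, %.4g A/voxel, origin (%g, %g, %g) A\n",
              d[1], d[2], d[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

as_volume3d <- function(x, voxel_size = 1, origin = c(0, 0, 0)) {
  if (inherits(x, "volume3d")) x else volume3d(x, voxel_size, origin)
}

## MRC2014 header word layout (1024 bytes, 56 int/float words + labels).
## Only the fields this package uses are interpreted.

#' Read an MRC2014 volume
#'
#' Supports data modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16).
#' The voxel size is `cella / mx` and is rounded to 7 significant digits
#' (the precision a float32 header can carry) so that printed pixel sizes
#' such as 3.06 survive a round trip.
#'
#' @param path path to an MRC file.
#' @return A [volume3d].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop("read_volume: malformed header: file shorter than 1024 bytes")
  cookie <- rawToChar(hdr_raw[209:212])
  little <- TRUE
  if (!identical(substr(cookie, 1, 3), "MAP")) {
    stop("read_volume: malformed header: missing MAP cookie (field 'map')")
  }
  ## machine stamp, bytes 213-214: 0x44 0x44 little endian, 0x11 0x11 big
  if (as.integer(hdr_raw[213]) == 0x11) little <- FALSE
  endi <- if (little) "little" else "big"
  int_at <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                   "integer", size = 4, endian = endi)
  flt_at <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                   "numeric", size = 4, endian = endi)
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  cella <- c(flt_at(11), flt_at(12), flt_at(13))
  nsymbt <- int_at(24)
  orig <- c(flt_at(50), flt_at(51), flt_at(52))
  if (nx <= 0 || ny <= 0 || nz <= 0)
    stop("read_volume: malformed header: non-positive dimension (fields nx/ny/nz)")
  if (nz == 1L || ny == 1L || nx == 1L)
    stop("read_volume: data is not 3D (field nz/ny/nx equals 1)")
  n <- as.numeric(nx) * ny * nz
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  dat <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE, endian = endi)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = endi)),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = endi),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = endi)),
    stop("read_volume: unreadable data mode (field 'mode' = ", mode, ")"))
  if (length(dat) < n) stop("read_volume: truncated data section")
  vs <- if (mx > 0 && cella[1] > 0) cella[1] / mx else 1
  vs <- signif(vs, 7)
  volume3d(array(dat, dim = c(nx, ny, nz)), voxel_size = vs,
           origin = signif(orig, 7))
}

#' Write a volume as MRC2014 (mode 2, float32)
#'
#' @param vol a [volume3d].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume3d(vol)
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                               # nx ny nz
  wi(2L)                              # mode 2: float32
  wi(c(0L, 0L, 0L))                   # nxstart..
  wi(d)                               # mx my mz
  wf(d * vol$voxel_size)              # cella
  wf(c(90, 90, 90))                   # cellb
  wi(c(1L, 2L, 3L))                   # mapc mapr maps
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))  # dmin dmax dmean
  wi(1L)                              # ispg: volume
  wi(0L)                              # nsymbt
  wi(rep(0L, 25L))                    # extra (words 26-50... up to word 49)
  wf(vol$origin)                      # origin x y z (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # machst, little endian
  wf(stats::sd(vol$data))             # rms
  wi(0L)                              # nlabl
  writeBin(raw(800L), con)            # labels
  writeBin(as.vector(vol$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Block-average (bin) a volume by an integer factor
#'
#' Trailing voxels that do not fill a complete block are dropped. The voxel
#' size is scaled by the factor.
#'
#' @param vol a [volume3d].
#' @param factor integer binning factor (>= 1).
#' @return A binned [volume3d].
#' @export
bin_volume <- function(vol, factor = 2L) {
  vol <- as_volume3d(vol)
  f <- as.integer(factor)
  if (f < 1L) stop("bin_volume: factor must be >= 1")
  if (f == 1L) return(vol)
  d <- dim(vol$data)
  nd <- d %/% f
  x <- vol$data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f), drop = FALSE]
  dim(x) <- c(f, nd[1], f, nd[2], f, nd[3])
  out <- apply(x, c(2, 4, 6), mean)
  volume3d(out, voxel_size = vol$voxel_size * f, origin = vol$origin)
}
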