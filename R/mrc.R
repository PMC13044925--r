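# MRC2014 volume/stack input-output. Volumes map between the MRC file
# (x fastest, column-major) and R arrays [nx, ny, nz] directly; voxel
# size round-trips through the cell dimensions. Only the common modes
# (0: int8, 1: int16, 2: float32, 6: uint16) are read; files are always
# written as mode 2.

mrc_mode_info <- function(mode) {
  switch(as.character(mode),
         "0" = list(what = "integer", size = 1L, signed = TRUE),
         "1" = list(what = "integer", size = 2L, signed = TRUE),
         "2" = list(what = "numeric", size = 4L, signed = TRUE),
         "6" = list(what = "integer", size = 2L, signed = FALSE),
         stop(sprintf("unsupported MRC mode %s (supported: 0, 1, 2, 6)",
                      mode), call. = FALSE))
}

#' Read an MRC volume or stack
#'
#' @param path file path.
#' @return List with `data` (3D array `[nx, ny, nz]`), `voxel_size`
#'   (Angstrom, from cell length / grid size), and `header` (named list
#'   of the main header fields).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mxyz <- ints[8:10]
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (any(c(nx, ny, nz) <= 0) || anyNA(c(nx, ny, nz)) || is.na(mode))
    stop(sprintf("malformed MRC header in %s: nx/ny/nz/mode = %s %s %s %s",
                 path, nx, ny, nz, mode), call. = FALSE)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop(sprintf("%s: unsupported axis order mapc/mapr/maps = %s",
                 path, paste(mapcrs, collapse = "/")), call. = FALSE)
  info <- mrc_mode_info(mode)
  seek(con, 1024 + max(nsymbt, 0))
  n <- as.numeric(nx) * ny * nz
  vals <- readBin(con, info$what, n, size = info$size, signed = info$signed,
                  endian = "little")
  if (length(vals) < n)
    stop(sprintf("%s: truncated data section (%d of %d values)",
                 path, length(vals), n), call. = FALSE)
  vs <- ifelse(mxyz > 0, cella / mxyz, 1)
  list(data = array(as.numeric(vals), c(nx, ny, nz)),
       voxel_size = vs[1],
       header = list(nx = nx, ny = ny, nz = nz, mode = mode,
                     mx = mxyz[1], my = mxyz[2], mz = mxyz[3],
                     cella = cella, cellb = cellb, ispg = ispg,
                     dmin = dstats[1], dmax = dstats[2], dmean = dstats[3]))
}

#' Write a volume or stack as MRC (mode 2, float32)
#'
#' @param v 3D array `[nx, ny, nz]`.
#' @param path destination file.
#' @param voxel_size voxel edge in Angstrom (isotropic).
#' @param is_stack write as an image stack (`ispg = 0`, e.g. a tilt
#'   series with one section per angle) rather than a volume (`ispg = 1`).
#' @export
write_mrc <- function(v, path, voxel_size = 1, is_stack = FALSE) {
  assert_volume(v)
  d <- dim(v)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(d, 2))                       # nx ny nz mode
  wi(c(0, 0, 0))                    # nxstart
  wi(d)                             # mx my mz
  wf(d * voxel_size)                # cella
  wf(c(90, 90, 90))                 # cellb
  wi(c(1, 2, 3))                    # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))    # dmin dmax dmean
  wi(c(if (is_stack) 0 else 1, 0))  # ispg, nsymbt
  writeBin(raw(100), con)           # extra
  wf(c(0, 0, 0))                    # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # little-endian stamp
  wf(sd(v))                         # rms
  wi(1)                             # nlabl
  lab <- sprintf("%-80s", "equitomo")
  writeChar(substr(lab, 1, 80), con, 80, eos = NULL)
  writeBin(raw(80 * 9), con)
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' Read/write a tilt-angle sidecar file
#'
#' Plain text, one angle in degrees per line, matching the section order
#' of the companion tilt-series MRC stack.
#'
#' @param path file path.
#' @return `read_angles`: numeric vector of angles.
#' @export
read_angles <- function(path) {
  a <- suppressWarnings(as.numeric(readLines(path)))
  a <- a[!is.na(a)]
  if (length(a) == 0) stop("no angles found in ", path, call. = FALSE)
  a
}

#' @rdname read_angles
#' @param angles numeric vector of angles in degrees.
#' @export
write_angles <- function(angles, path) {
  writeLines(sprintf("%.4f", angles), path)
  invisible(path)
}
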