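#' Density volume on a cubic voxel grid
#'
#' @param data 3D numeric array (nx x ny x nz) of density values.
#' @param voxel_A Voxel edge length in Angstrom (> 0).
#' @param origin Physical coordinate of voxel (1,1,1) center (Angstrom);
#'   defaults to centering the box on the coordinate origin.
#' @return Object of class `"density_volume"`.
#' @export
density_volume <- function(data, voxel_A, origin = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  stopifnot(is.numeric(voxel_A), voxel_A > 0)
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * voxel_A
  structure(list(data = data, voxel_A = voxel_A, origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Density volume: %d x %d x %d voxels at %.3f A/voxel (%.0f A box)\n",
              d[1], d[2], d[3], x$voxel_A, d[1] * x$voxel_A))
  cat(sprintf("  range [%.4g, %.4g], sum %.4g\n",
              min(x$data), max(x$data), sum(x$data)))
  invisible(x)
}

#' @export
plot.density_volume <- function(x, slice = NULL, axis = c("z", "y", "x"), ...) {
  axis <- match.arg(axis)
  d <- dim(x$data)
  if (is.null(slice)) slice <- ceiling(d[[match(axis, c("x", "y", "z"))]] / 2)
  img <- switch(axis,
                x = x$data[slice, , ],
                y = x$data[, slice, ],
                z = x$data[, , slice])
  graphics::image(img, col = grDevices::gray(seq(0, 1, length.out = 128)),
                  asp = 1, axes = FALSE,
                  main = sprintf("%s-slice %d", axis, slice), ...)
  invisible(x)
}

# internal: dims of a density_volume
vol_dim <- function(vol) dim(vol$data)

#' Write a volume or image stack in MRC2014 format
#'
#' Writes 32-bit float (mode 2) MRC with correct cell dimensions so that the
#' voxel size round-trips. A 2D image or a 3D stack/volume is accepted.
#'
#' @param x A `density_volume`, a 3D array, or a 2D matrix.
#' @param path Output file path.
#' @param voxel_A Voxel size (taken from the object when `x` is a
#'   `density_volume`).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, voxel_A = NULL) {
  if (inherits(x, "density_volume")) {
    voxel_A <- x$voxel_A
    arr <- x$data
  } else arr <- x
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  stopifnot(length(dim(arr)) == 3)
  if (is.null(voxel_A)) stop("voxel_A required")
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                    # NX NY NZ
  wi(2L)                   # MODE 2 = float32
  wi(c(0L, 0L, 0L))        # NXSTART..
  wi(d)                    # MX MY MZ
  wf(d * voxel_A)          # CELLA
  wf(c(90, 90, 90))        # CELLB
  wi(c(1L, 2L, 3L))        # MAPC MAPR MAPS
  wf(c(min(arr), max(arr), mean(arr)))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))            # ISPG, NSYMBT
  writeBin(raw(100), con)  # EXTRA (words 25-49)
  wf(c(0, 0, 0))           # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(as.numeric(arr)))                    # RMS
  wi(0L)                   # NLABL
  writeBin(raw(800), con)  # labels
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 volume or stack
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32), 6 (uint16).
#'
#' @param path MRC file path.
#' @return A list with `data` (3D array), `voxel_A`, `dim`, `mode`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)            # nxstart
  m <- ri(3)       # mx my mz
  cella <- rf(3)
  seek(con, 92)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  n <- prod(d)
  vals <- switch(as.character(mode),
                 "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
                 "1" = as.numeric(readBin(con, "integer", n, size = 2,
                                          endian = "little")),
                 "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
                 "6" = as.numeric(readBin(con, "integer", n, size = 2,
                                          signed = FALSE, endian = "little")),
                 stop("unsupported MRC mode: ", mode))
  voxel <- if (all(m > 0)) cella[1] / m[1] else NA_real_
  list(data = array(vals, d), voxel_A = voxel, dim = d, mode = mode)
}

#' Read an MRC file as a density volume
#' @param path MRC file path.
#' @return A [density_volume()].
#' @export
read_volume <- function(path) {
  m <- read_mrc(path)
  density_volume(m$data, m$voxel_A)
}
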