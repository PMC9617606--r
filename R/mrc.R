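#' Read an MRC2014 volume
#'
#' Reads a 3D volume in MRC format (modes 0, 1, 2 and 6; volumes are always
#' returned as double precision).  The voxel ordering follows the file: X is
#' the fastest axis, so `vol$data[x, y, z]`.  The pixel size is taken from the
#' header cell dimensions divided by the grid size.
#'
#' @param path path to an existing MRC file.
#' @return A [tomogram] object.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]
  mode <- hdr_ints[4]
  mx <- hdr_ints[8]; my <- hdr_ints[9]; mz <- hdr_ints[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", n = 3, size = 4, endian = "little")) # cellb
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", n = 3, size = 4, endian = "little")) # dmin/dmax/dmean
  ispg_nsymbt <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  nsymbt <- ispg_nsymbt[2]
  # skip extra (25 words) then origin
  invisible(readBin(con, "integer", n = 25, size = 4, endian = "little"))
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  # remaining header: MAP stamp, machine stamp, rms, nlabl + labels
  seek(con, where = 1024 + max(0, nsymbt), origin = "start")

  if (nx < 1 || ny < 1 || nz < 1)
    stop("malformed MRC header: non-positive dimensions")
  if (nz == 1) stop("expected a 3D volume, got a 2D image (nz = 1)")
  if (!mode %in% c(0L, 1L, 2L, 6L))
    stop("unsupported MRC mode: ", mode)
  if (!identical(mapcrs, c(1L, 2L, 3L)) && !all(mapcrs == 0L))
    stop("only axis order mapc,mapr,maps = 1,2,3 is supported")

  n <- as.double(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = as.double(readBin(con, "integer", n = n, size = 1, signed = TRUE,
                            endian = "little")),
    "1" = as.double(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                            endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = as.double(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                            endian = "little")))
  if (length(data) != n) stop("MRC file truncated: expected ", n, " voxels")
  dim(data) <- c(nx, ny, nz)
  px <- if (mx > 0 && cella[1] > 0) cella[1] / mx else NA_real_
  if (is.na(px)) {
    warning("MRC header has no usable pixel size; set it explicitly")
    px <- 1
  }
  tomogram(data, pixel_size = px, origin = origin,
           name = basename(path))
}

#' Write a volume as MRC2014 (mode 2, float32)
#'
#' @param vol a [tomogram] or 3D numeric array.
#' @param path output path.
#' @param pixel_size pixel size in Angstrom; defaults to the tomogram's own.
#' @param overwrite logical; refuse to clobber an existing file unless TRUE.
#' @return Invisibly, `path`.
#' @export
write_mrc <- function(vol, path, pixel_size = NULL, overwrite = TRUE) {
  data <- as_volume(vol)
  if (any(!is.finite(data)))
    stop("refusing to write non-finite voxel values to MRC")
  if (is.null(pixel_size))
    pixel_size <- if (inherits(vol, "tomogram")) vol$pixel_size else 1
  origin <- if (inherits(vol, "tomogram")) vol$origin else c(0, 0, 0)
  if (file.exists(path) && !overwrite) stop("file exists: ", path)
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                     # nx ny nz
  wi(2)                     # mode 2 = float32
  wi(c(0, 0, 0))            # nxstart
  wi(d)                     # mx my mz
  wf(d * pixel_size)        # cella
  wf(c(90, 90, 90))         # cellb
  wi(c(1, 2, 3))            # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))
  wi(c(1, 0))               # ispg, nsymbt
  wi(rep(0, 25))            # extra
  wf(origin)                # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(data))       # rms
  wi(0)                     # nlabl
  writeBin(raw(800), con)   # labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}
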