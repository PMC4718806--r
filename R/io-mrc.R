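# MRC2014 reader/writer (little-endian).  Written from the format
# definition because no installed R package handles MRC maps or stacks.
# Write mode is always 2 (32-bit float); modes 0, 1 and 2 are accepted on
# read.  Pixel size is taken as CELLA_x / NX; origin fields are ignored on
# read and zeroed on write.

.mrc_read_header <- function(con) {
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  stats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg_nsym <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  seek(con, 52 * 4)
  maptag <- readChar(con, 4, useBytes = TRUE)
  seek(con, 1024)
  list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
       mx = ints[8], my = ints[9], mz = ints[10], cella = cella,
       nsymbt = ispg_nsym[2], maptag = maptag)
}

.mrc_read_data <- function(con, h) {
  nvox <- as.numeric(h$nx) * h$ny * h$nz
  if (h$nsymbt > 0) seek(con, 1024 + h$nsymbt)
  if (h$mode == 2L) {
    readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  } else if (h$mode == 1L) {
    readBin(con, "integer", n = nvox, size = 2, endian = "little")
  } else if (h$mode == 0L) {
    readBin(con, "integer", n = nvox, size = 1, signed = TRUE)
  } else {
    stop("unsupported MRC mode ", h$mode, " (modes 0, 1, 2 are supported)")
  }
}

.mrc_write <- function(data, dims, pixel_size, path, mz) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(dims, 2L)), con, size = 4, endian = "little")
  writeBin(integer(3), con, size = 4, endian = "little")     # nxstart..
  writeBin(as.integer(c(dims[1], dims[2], mz)), con, size = 4,
           endian = "little")                                # mx my mz
  writeBin(as.numeric(c(dims[1], dims[2], mz) * pixel_size), con, size = 4,
           endian = "little")                                # cella
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(1:3, con, size = 4, endian = "little")            # mapc/r/s
  rng <- range(data)
  writeBin(as.numeric(c(rng[1], rng[2], mean(data))), con, size = 4,
           endian = "little")
  ispg <- if (mz == dims[3]) 1L else 0L                      # volume/stack
  writeBin(c(ispg, 0L), con, size = 4, endian = "little")    # ispg, nsymbt
  writeBin(integer(2), con, size = 4, endian = "little")     # extra 25-26
  writeChar("MRC ", con, nchars = 4, eos = NULL)             # exttyp
  writeBin(20140L, con, size = 4, endian = "little")         # nversion
  writeBin(integer(21), con, size = 4, endian = "little")    # extra
  writeBin(numeric(3), con, size = 4, endian = "little")     # origin = 0
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(c(68L, 68L, 0L, 0L), con, size = 1)               # machst LE
  writeBin(as.numeric(sd(as.vector(data))), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")             # nlabl
  writeBin(raw(800), con)                                    # labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read and write MRC2014 density maps
#'
#' `read_volume()` reads a cubic map; `write_volume()` writes one in mode 2
#' (32-bit float), so a write/read round trip is bit-exact.
#'
#' @param path file path.
#' @return `read_volume()` returns a [volume_grid()] with the pixel size
#'   taken from the header cell dimensions divided by the grid size.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .mrc_read_header(con)
  if (h$nx != h$ny || h$nx != h$nz)
    stop("map is not cubic: ", h$nx, "x", h$ny, "x", h$nz)
  dat <- .mrc_read_data(con, h)
  px <- h$cella[1] / h$nx
  volume_grid(array(as.numeric(dat), dim = c(h$nx, h$ny, h$nz)), px)
}

#' @rdname read_volume
#' @param vol a [volume_grid()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  n <- box_size(vol)
  .mrc_write(vol$data, c(n, n, n), vol$pixel_size, path, mz = n)
}

#' Read and write MRC image stacks
#'
#' Stacks store `n` square images as sections along z (`NZ = n`, `MZ = 1`).
#'
#' @param path file path.
#' @return `read_stack()` returns an [image_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .mrc_read_header(con)
  if (h$nx != h$ny) stop("stack images are not square")
  dat <- .mrc_read_data(con, h)
  px <- h$cella[1] / h$nx
  image_stack(array(as.numeric(dat), dim = c(h$nx, h$ny, h$nz)), px)
}

#' @rdname read_stack
#' @param images an [image_stack()].
#' @export
write_stack <- function(images, path) {
  stopifnot(inherits(images, "image_stack"))
  d <- dim(images$data)
  .mrc_write(images$data, d, images$pixel_size, path, mz = 1L)
}
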