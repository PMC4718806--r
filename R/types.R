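#' Cubic density map with physical pixel size
#'
#' A `volume_grid` is the package's container for a 3D density map: a cubic
#' array of side `N` voxels (N even, >= 8) with a pixel size in Angstrom per
#' voxel.  The rotation center is the voxel at index `N/2` in 0-based
#' indexing (i.e. `N/2 + 1` in R's 1-based indexing) along every axis.
#'
#' @param data numeric 3D array, cubic, all values finite.
#' @param pixel_size voxel edge length in Angstrom; must be positive.
#' @return An object of class `volume_grid`: a list with elements `data`
#'   and `pixel_size`.
#' @examples
#' v <- volume_grid(array(0, dim = c(16, 16, 16)), pixel_size = 1.4)
#' box_size(v)
#' @export
volume_grid <- function(data, pixel_size) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  d <- dim(data)
  if (d[1] != d[2] || d[1] != d[3])
    stop("volume must be cubic, got dimensions ", paste(d, collapse = "x"))
  if (d[1] < 8L || d[1] %% 2L != 0L)
    stop("box size must be even and >= 8, got ", d[1])
  if (!all(is.finite(data)))
    stop("volume contains non-finite values")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("<volume_grid> %d^3 voxels, %.4g A/px, range [%.4g, %.4g]\n",
              n, x$pixel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' Box size of a volume or image stack
#' @param x a `volume_grid` or `image_stack`.
#' @return integer edge length in pixels.
#' @export
box_size <- function(x) UseMethod("box_size")

#' @export
box_size.volume_grid <- function(x) dim(x$data)[1]

#' @export
box_size.image_stack <- function(x) dim(x$data)[1]

#' Stack of square particle images
#'
#' An `image_stack` holds `n` square images of side `N` pixels sharing one
#' pixel size, stored as an `N x N x n` array.  Individual images are plain
#' matrices obtained with [get_image()].
#'
#' @param data numeric array `N x N x n` (a single matrix is promoted to a
#'   one-image stack); all values finite.
#' @param pixel_size pixel size in Angstrom.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be an N x N x n array")
  d <- dim(data)
  if (d[1] != d[2]) stop("images must be square")
  if (!all(is.finite(data))) stop("stack contains non-finite values")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d images of %dx%d px, %.4g A/px\n",
              d[3], d[1], d[2], x$pixel_size))
  invisible(x)
}

#' @rdname image_stack
#' @param stack an `image_stack`.
#' @param i image index (1-based).
#' @export
get_image <- function(stack, i) stack$data[, , i]

#' Number of images in a stack
#' @param stack an `image_stack`.
#' @export
n_images <- function(stack) dim(stack$data)[3]

# columns every particle_set must carry
.particle_cols <- c("image_name", "image_index", "rot", "tilt", "psi",
                    "origin_x", "origin_y", "defocus_u", "defocus_v",
                    "astig_angle", "voltage", "cs", "amplitude_contrast",
                    "phase_shift")

#' Per-particle metadata table
#'
#' A `particle_set` is a data frame with one row per particle carrying the
#' image reference (`image_name`, 1-based `image_index`), ZYZ Euler angles
#' in degrees (`rot`, `tilt`, `psi`), in-plane offsets in pixels
#' (`origin_x`, `origin_y`) and CTF parameters (`defocus_u`, `defocus_v`,
#' `astig_angle` in degrees, `voltage` in kV, `cs` in mm,
#' `amplitude_contrast`, `phase_shift` in degrees).  Optional columns:
#' `class_label` (integer ground truth or assignment) and `random_subset`
#' (gold-standard half, 1 or 2).  The box size and pixel size shared by all
#' particles are stored as attributes.
#'
#' @param df data frame with the columns above.
#' @param pixel_size shared pixel size in Angstrom.
#' @param box shared box size in pixels.
#' @return An object of class `particle_set` (also a data frame).
#' @export
particle_set <- function(df, pixel_size, box) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(.particle_cols, names(df))
  if (length(missing))
    stop("particle table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("particle set must be non-empty")
  ps <- structure(df, class = c("particle_set", "data.frame"),
                  pixel_size = as.numeric(pixel_size), box = as.integer(box))
  validate_particle_set(ps)
  ps
}

#' @rdname particle_set
#' @param x a `particle_set`.
#' @export
validate_particle_set <- function(x) {
  num_cols <- setdiff(.particle_cols, "image_name")
  for (cc in num_cols)
    if (!all(is.finite(x[[cc]])))
      stop("non-finite values in column ", cc)
  if (any(x$tilt < 0 | x$tilt > 180))
    stop("tilt angles must lie in [0, 180] degrees")
  if (any(x$rot < -180 | x$rot >= 180) || any(x$psi < -180 | x$psi >= 180))
    stop("rot and psi must lie in [-180, 180) degrees")
  box <- attr(x, "box")
  if (any(abs(x$origin_x) >= box / 4) || any(abs(x$origin_y) >= box / 4))
    stop("offsets must satisfy |offset| < box/4 pixels")
  ref <- paste(x$image_name, x$image_index)
  if (anyDuplicated(ref))
    stop("duplicate image references in particle set")
  invisible(x)
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles, box %d px, %.4g A/px\n",
              nrow(x), attr(x, "box"), attr(x, "pixel_size")))
  NextMethod()
}

#' @export
`[.particle_set` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out) && all(.particle_cols %in% names(out))) {
    attr(out, "pixel_size") <- attr(x, "pixel_size")
    attr(out, "box") <- attr(x, "box")
    class(out) <- class(x)
  }
  out
}

# wrap an angle into [-180, 180)
wrap_angle <- function(a) ((a + 180) %% 360) - 180
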