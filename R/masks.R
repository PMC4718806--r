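#' Build a soft-edged mask from a density map
#'
#' Follows the standard mask-construction recipe: binarize the map at a
#' threshold, dilate the binary region by `extend_px` voxels, then add a
#' raised-cosine falloff from 1 to 0 over `soft_edge_px` voxels of
#' Euclidean distance beyond the dilated surface.  The result is a
#' `soft_mask`: a [volume_grid()] with values in `[0, 1]` that multiplies
#' references during focused classification.
#'
#' @param map a [volume_grid()].
#' @param threshold binarization threshold; must lie within the map's value
#'   range and leave a non-empty region.
#' @param extend_px dilation in voxels (>= 0).
#' @param soft_edge_px width of the cosine edge in voxels (>= 0).
#' @return An object of class `c("soft_mask", "volume_grid")`, with the
#'   construction parameters stored as attributes.
#' @export
make_soft_mask <- function(map, threshold, extend_px = 3, soft_edge_px = 6) {
  stopifnot(inherits(map, "volume_grid"), extend_px >= 0, soft_edge_px >= 0)
  if (threshold < min(map$data) || threshold > max(map$data))
    stop("threshold outside the map's value range")
  binary <- map$data >= threshold
  if (!any(binary)) stop("mask is empty after thresholding")
  d <- edt_outside(binary)           # Euclidean distance to the region
  vals <- numeric(length(d))
  vals[d <= extend_px] <- 1
  edge <- d > extend_px & d <= extend_px + soft_edge_px & soft_edge_px > 0
  vals[edge] <- 0.5 * (1 + cos(pi * (d[edge] - extend_px) / soft_edge_px))
  out <- volume_grid(array(vals, dim = dim(map$data)), map$pixel_size)
  class(out) <- c("soft_mask", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "extend_px") <- extend_px
  attr(out, "soft_edge_px") <- soft_edge_px
  out
}

# exact Euclidean distance transform to the TRUE region of a logical 3D
# array (0 inside), by the separable squared-distance algorithm of
# Felzenszwalb & Huttenlocher run along each axis
edt_outside <- function(binary) {
  d <- dim(binary)
  inf <- .Machine$double.xmax / 4
  f <- array(ifelse(binary, 0, inf), dim = d)
  for (axis in 1:3) {
    f <- apply(f, setdiff(1:3, axis), edt_1d, inf = inf)
    # apply() returns the processed axis first; rotate back
    f <- aperm(array(f, dim = c(d[axis], d[setdiff(1:3, axis)])),
               order(c(axis, setdiff(1:3, axis))))
  }
  array(sqrt(f), dim = d)
}

# 1D squared-distance transform (lower envelope of parabolas)
edt_1d <- function(f, inf) {
  n <- length(f)
  if (all(f >= inf)) return(f)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  out <- numeric(n); k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    out[q] <- (q - v[k])^2 + f[v[k]]
  }
  out
}

#' Subtract one mask from another
#'
#' Voxelwise `clip(whole - part, 0, 1)` — the operation that turns a mask
#' of an entire complex and a mask of the subunit of interest into the mask
#' of everything else (the region whose signal is subtracted).
#'
#' @param whole,part soft masks on the same grid.
#' @return a `soft_mask`.
#' @export
mask_subtract <- function(whole, part) {
  stopifnot(inherits(whole, "volume_grid"), inherits(part, "volume_grid"))
  if (!identical(dim(whole$data), dim(part$data)) ||
      whole$pixel_size != part$pixel_size)
    stop("masks are on different grids")
  out <- volume_grid(pmin(pmax(whole$data - part$data, 0), 1),
                     whole$pixel_size)
  class(out) <- c("soft_mask", class(out))
  out
}

#' Multiply a map by a soft mask
#'
#' @param vol a [volume_grid()].
#' @param mask a mask on the same grid.
#' @return the masked [volume_grid()].
#' @export
apply_mask <- function(vol, mask) {
  stopifnot(inherits(vol, "volume_grid"), inherits(mask, "volume_grid"))
  if (!identical(dim(vol$data), dim(mask$data)) ||
      vol$pixel_size != mask$pixel_size)
    stop("volume and mask are on different grids")
  volume_grid(vol$data * mask$data, vol$pixel_size)
}

#' Render Gaussian pseudo-atoms into a density map
#'
#' A light-weight stand-in for atomic-model-to-density conversion: each
#' pseudo-atom contributes an isotropic Gaussian of standard deviation
#' `radius / 2` and peak proportional to `weight`, sampled on the voxel
#' grid.  Coordinates are in Angstrom relative to the box center (the
#' rotation center).
#'
#' @param centers data frame (or 5-column matrix) with columns
#'   `x`, `y`, `z` (Angstrom), `radius` (Angstrom), `weight`; may have zero
#'   rows, giving a zero map.  Pseudo-atom lists can also be read from
#'   5-column whitespace-separated text via [read_pseudo_atoms()].
#' @param n box size in voxels.
#' @param pixel_size voxel size in Angstrom.
#' @return a [volume_grid()].
#' @export
pseudo_atoms_to_map <- function(centers, n, pixel_size) {
  centers <- as.data.frame(centers)
  if (ncol(centers) >= 5 &&
      !all(c("x", "y", "z", "radius", "weight") %in% names(centers)))
    names(centers)[1:5] <- c("x", "y", "z", "radius", "weight")
  out <- array(0, dim = c(n, n, n))
  if (nrow(centers) == 0)
    return(volume_grid(out, pixel_size))
  half <- n / 2 * pixel_size
  if (any(abs(centers$x) >= half | abs(centers$y) >= half |
          abs(centers$z) >= half))
    stop("pseudo-atom center outside the box")
  coord <- (seq_len(n) - 1 - n / 2) * pixel_size
  for (a in seq_len(nrow(centers))) {
    sigma <- centers$radius[a] / 2
    gx <- exp(-(coord - centers$x[a])^2 / (2 * sigma^2))
    gy <- exp(-(coord - centers$y[a])^2 / (2 * sigma^2))
    gz <- exp(-(coord - centers$z[a])^2 / (2 * sigma^2))
    out <- out + centers$weight[a] * outer(outer(gx, gy), gz)
  }
  volume_grid(out, pixel_size)
}

#' Soft spherical mask
#'
#' Convenience wrapper building a soft-edged ball: 1 inside `radius`,
#' raised-cosine falloff over `soft_edge_px` voxels.
#'
#' @param center sphere center in Angstrom relative to the box center.
#' @param radius sphere radius in Angstrom.
#' @param n box size in voxels.
#' @param pixel_size voxel size in Angstrom.
#' @param soft_edge_px cosine edge width in voxels.
#' @return a `soft_mask`.
#' @export
make_spherical_mask <- function(center, radius, n, pixel_size,
                                soft_edge_px = 4) {
  coord <- (seq_len(n) - 1 - n / 2) * pixel_size
  dx2 <- (coord - center[1])^2
  dy2 <- (coord - center[2])^2
  dz2 <- (coord - center[3])^2
  r <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  ball <- volume_grid(array(as.numeric(r <= radius), dim = c(n, n, n)),
                      pixel_size)
  make_soft_mask(ball, 0.5, extend_px = 0, soft_edge_px = soft_edge_px)
}

#' @rdname pseudo_atoms_to_map
#' @param path path of a 5-column text file (x y z radius weight, Angstrom).
#' @export
read_pseudo_atoms <- function(path) {
  utils::read.table(path, header = FALSE,
                    col.names = c("x", "y", "z", "radius", "weight"))
}
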