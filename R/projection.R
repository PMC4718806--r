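#' Oversampled Fourier transform of a volume
#'
#' Zero-pads a volume by `pad` (default 2), centered, and returns its
#' centered 3D Fourier transform, from which central slices are extracted
#' by trilinear interpolation during projection.  Precompute this once when
#' projecting the same volume at many orientations.
#'
#' @param vol a [volume_grid()].
#' @param pad integer oversampling (padding) factor, >= 1.
#' @return An object of class `fourier_volume`: list with the complex
#'   transform `ft` (side `pad * N`), `pad`, `n` (original box) and
#'   `pixel_size`.
#' @export
fourier_volume <- function(vol, pad = 2L) {
  stopifnot(inherits(vol, "volume_grid"), pad >= 1)
  n <- box_size(vol)
  m <- as.integer(pad * n)
  padded <- array(0, dim = c(m, m, m))
  lo <- m / 2 - n / 2 + 1
  hi <- m / 2 + n / 2
  padded[lo:hi, lo:hi, lo:hi] <- vol$data
  structure(list(ft = cfft3(padded), pad = as.integer(pad), n = n,
                 pixel_size = vol$pixel_size),
            class = "fourier_volume")
}

# maximum usable image-frequency radius for a box of side n: stays one
# padded voxel inside the cube for any orientation
.slice_rmax <- function(n) n / 2 - 1

# shifts matrix (2 x n) from a particle_set or explicit offsets
.shift_matrix <- function(ox, oy) rbind(as.numeric(ox), as.numeric(oy))

#' Project a volume at a fixed orientation
#'
#' Forward projection by central-slice extraction from the oversampled
#' Fourier transform (Fourier-slice theorem), followed by an in-plane phase
#' shift of `origin_x`/`origin_y` pixels (the projection is shifted toward
#' the particle frame) and optional multiplication by the CTF.  Image
#' frequencies outside the Nyquist ball (radius `N/2 - 1` pixels) are set
#' to zero.
#'
#' @param vol a [volume_grid()] or a precomputed [fourier_volume()].
#' @param rotation 3x3 rotation matrix from [euler_to_matrix()].
#' @param origin_x,origin_y in-plane offsets in pixels.
#' @param ctf optional [ctf_params()]; `NULL` for no CTF.
#' @param pad oversampling factor (used only when `vol` is a
#'   `volume_grid`).
#' @return `N x N` numeric matrix (the projected image).
#' @export
project <- function(vol, rotation = diag(3), origin_x = 0, origin_y = 0,
                    ctf = NULL, pad = 2L) {
  fv <- if (inherits(vol, "fourier_volume")) vol else fourier_volume(vol, pad)
  n <- fv$n
  ctf_mat <- if (is.null(ctf)) NULL else
    matrix(as.vector(ctf_image(ctf, n, fv$pixel_size)), n * n, 1)
  sl <- cf_project_slices(fv$ft, fv$pad * n, n, fv$pad,
                          array(rotation, dim = c(3, 3, 1)),
                          .shift_matrix(origin_x, origin_y),
                          ctf_mat, .slice_rmax(n))
  Re(cifft2(matrix(sl[, 1], n, n)))
}

# Fourier-domain slices for a whole particle set (N^2 x n complex matrix);
# apply_ctf toggles per-particle CTF multiplication
project_particles_ft <- function(fv, particles, apply_ctf = TRUE) {
  n <- fv$n
  ctf_mat <- if (apply_ctf)
    particle_ctf_matrix(particles, n, fv$pixel_size) else NULL
  cf_project_slices(fv$ft, fv$pad * n, n, fv$pad,
                    particle_rotations(particles),
                    .shift_matrix(particles$origin_x, particles$origin_y),
                    ctf_mat, .slice_rmax(n))
}

# real-space projections of a whole particle set as an image_stack
project_particles <- function(vol, particles, apply_ctf = TRUE, pad = 2L) {
  fv <- if (inherits(vol, "fourier_volume")) vol else fourier_volume(vol, pad)
  sl <- project_particles_ft(fv, particles, apply_ctf)
  n <- fv$n
  out <- array(0, dim = c(n, n, ncol(sl)))
  for (i in seq_len(ncol(sl)))
    out[, , i] <- Re(cifft2(matrix(sl[, i], n, n)))
  image_stack(out, fv$pixel_size)
}

#' Create an empty backprojection accumulator
#'
#' Holds the Wiener numerator (complex) and denominator (CTF^2 weights) on
#' the padded Fourier grid, to be filled by [backproject_accumulate()] and
#' turned into a map by [reconstruct_finalize()].
#'
#' @param n box size in pixels.
#' @param pixel_size pixel size in Angstrom.
#' @param pad oversampling factor.
#' @return An object of class `bp_accumulator`.
#' @export
new_accumulator <- function(n, pixel_size, pad = 2L) {
  m <- as.integer(pad * n)
  structure(list(num = complex(m^3), den = numeric(m^3), n = as.integer(n),
                 m = m, pad = as.integer(pad), pixel_size = pixel_size,
                 total_weight = 0),
            class = "bp_accumulator")
}

#' Accumulate one image into a backprojection accumulator
#'
#' Adds `weight * CTF * image` into the numerator and `weight * CTF^2` into
#' the denominator along the rotated central plane (the adjoint of
#' [project()]).  The full slice plane is inserted, which covers both
#' Friedel mates of every in-plane frequency, so the accumulated grid is
#' Hermitian.  Offsets are undone (the image is shifted back to the
#' reference frame) before insertion.
#'
#' @param acc a [new_accumulator()].
#' @param image `N x N` numeric matrix.
#' @param rotation 3x3 rotation matrix.
#' @param origin_x,origin_y offsets in pixels (as stored in the metadata).
#' @param ctf optional [ctf_params()].
#' @param weight non-negative finite weight (e.g. a class responsibility).
#' @return the updated accumulator.
#' @export
backproject_accumulate <- function(acc, image, rotation = diag(3),
                                   origin_x = 0, origin_y = 0, ctf = NULL,
                                   weight = 1) {
  stopifnot(inherits(acc, "bp_accumulator"))
  if (!is.finite(weight)) stop("weight must be finite")
  n <- acc$n
  ctf_mat <- if (is.null(ctf)) NULL else
    matrix(as.vector(ctf_image(ctf, n, acc$pixel_size)), n * n, 1)
  dataft <- matrix(as.vector(cfft2(image)), n * n, 1)
  cf_backproject_many(acc$num, acc$den, acc$m, n, acc$pad,
                      array(rotation, dim = c(3, 3, 1)),
                      .shift_matrix(origin_x, origin_y), dataft, ctf_mat,
                      weight, .slice_rmax(n), FALSE)
  acc$total_weight <- acc$total_weight + weight
  acc
}

# gridding correction: transform of the trilinear interpolation kernel,
# evaluated over the original box inside the padded grid
.gridding_correction <- function(n, m) {
  r <- freq_axis(n) / m
  s <- (sinc_sq <- function(x) ifelse(x == 0, 1, (sin(pi * x) / (pi * x))^2))(r)
  outer(outer(s, s), s)
}

#' Turn an accumulator into a real-space map
#'
#' Wiener-style division `num / (den + eps)`, inverse Fourier transform,
#' division by the trilinear-kernel transform (gridding correction), and
#' cropping to the original box.
#'
#' @param acc a filled [new_accumulator()].
#' @param eps regularization constant; default `eps_scale` times the mean
#'   of the nonzero denominator cells.
#' @param eps_scale used when `eps` is `NULL`.
#' @param grid_correct divide by the interpolation-kernel transform.  Keep
#'   `TRUE` for maps meant for viewing or validation; the EM classifier
#'   sets `FALSE` internally so that projecting a reconstruction through
#'   the (uncorrected) Fourier-slice projector reproduces the accumulated
#'   slices self-consistently.
#' @return a [volume_grid()].
#' @export
reconstruct_finalize <- function(acc, eps = NULL, eps_scale = 1e-3,
                                 grid_correct = TRUE) {
  stopifnot(inherits(acc, "bp_accumulator"))
  if (acc$total_weight <= 0) stop("accumulator holds no weighted data")
  if (is.null(eps)) {
    nz <- acc$den[acc$den > 0]
    if (!length(nz)) stop("empty accumulator")
    eps <- eps_scale * mean(nz)
  }
  m <- acc$m; n <- acc$n
  fgrid <- array(acc$num / (acc$den + eps), dim = c(m, m, m))
  vol_pad <- Re(cifft3(fgrid))
  lo <- m / 2 - n / 2 + 1
  hi <- m / 2 + n / 2
  cropped <- vol_pad[lo:hi, lo:hi, lo:hi]
  if (grid_correct) cropped <- cropped / .gridding_correction(n, m)
  volume_grid(cropped, acc$pixel_size)
}

#' Direct Fourier reconstruction from oriented images
#'
#' Backprojects every image at its recorded orientation and offsets with
#' its CTF (numerator `sum w CTF D`, denominator `sum w CTF^2`), then
#' applies the Wiener-style division and gridding correction of
#' [reconstruct_finalize()].  Orientations are taken as given: there is no
#' alignment search.
#'
#' @param particles a [particle_set()].
#' @param images an [image_stack()] with one image per particle.
#' @param weights per-particle weights (default all 1); at least one must
#'   be positive.
#' @param apply_ctf multiply by each particle's CTF during accumulation.
#' @param pad oversampling factor.
#' @param eps,eps_scale regularization, see [reconstruct_finalize()].
#' @return a [volume_grid()].
#' @export
reconstruct <- function(particles, images, weights = NULL, apply_ctf = TRUE,
                        pad = 2L, eps = NULL, eps_scale = 1e-3,
                        grid_correct = TRUE) {
  n <- box_size(images)
  np <- nrow(particles)
  if (n_images(images) != np)
    stop("particle set and image stack sizes differ")
  if (is.null(weights)) weights <- rep(1, np)
  if (all(weights == 0)) stop("all weights are zero")
  dataft <- stack_fft(images)
  acc <- reconstruct_accumulate_ft(
    new_accumulator(n, images$pixel_size, pad), particles, dataft, weights,
    apply_ctf)
  reconstruct_finalize(acc, eps = eps, eps_scale = eps_scale,
                       grid_correct = grid_correct)
}

# centered 2D FFTs of all images, as an N^2 x n complex matrix
stack_fft <- function(images) {
  n <- box_size(images)
  nim <- n_images(images)
  out <- matrix(complex(1), n * n, nim)
  for (i in seq_len(nim))
    out[, i] <- as.vector(cfft2(images$data[, , i, drop = TRUE]))
  out
}

# bulk accumulation from precomputed image FTs (used by reconstruct and the
# EM M-step, where the FTs are already in memory)
reconstruct_accumulate_ft <- function(acc, particles, dataft, weights,
                                      apply_ctf = TRUE, ctf_mat = NULL,
                                      rot = NULL, shifts = NULL) {
  n <- acc$n
  if (apply_ctf && is.null(ctf_mat))
    ctf_mat <- particle_ctf_matrix(particles, n, acc$pixel_size)
  if (is.null(rot)) rot <- particle_rotations(particles)
  if (is.null(shifts))
    shifts <- .shift_matrix(particles$origin_x, particles$origin_y)
  cf_backproject_many(acc$num, acc$den, acc$m, n, acc$pad, rot, shifts,
                      dataft, if (apply_ctf) ctf_mat else NULL,
                      as.numeric(weights), .slice_rmax(n), FALSE)
  acc$total_weight <- acc$total_weight + sum(weights)
  acc
}

#' Adjoint of the projector (for a single image)
#'
#' Returns the volume `t(P) %*% image` where `P` is the linear operator of
#' [project()] (no CTF, no gridding correction), satisfying the
#' inner-product identity `sum(project(V) * I) == sum(V * backproject_volume(I))`
#' up to floating-point rounding.  Mainly a building block for tests and
#' diagnostics; use [reconstruct()] to build maps.
#'
#' @param image `N x N` numeric matrix.
#' @param rotation 3x3 rotation matrix.
#' @param origin_x,origin_y offsets in pixels.
#' @param pixel_size pixel size in Angstrom.
#' @param pad oversampling factor.
#' @return a [volume_grid()].
#' @export
backproject_volume <- function(image, rotation = diag(3), origin_x = 0,
                               origin_y = 0, pixel_size = 1, pad = 2L) {
  n <- nrow(image)
  m <- as.integer(pad * n)
  num <- complex(m^3)
  den <- numeric(m^3)
  dataft <- matrix(as.vector(cfft2(image)), n * n, 1)
  cf_backproject_many(num, den, m, n, pad, array(rotation, dim = c(3, 3, 1)),
                      .shift_matrix(origin_x, origin_y), dataft, NULL, 1,
                      .slice_rmax(n), FALSE)
  # adjoint bookkeeping: project = (1/N^2) C2^H S C3, so
  # t(project) = (M^3/N^2) * icfft3 o t(S) o cfft2
  vol_pad <- Re(cifft3(array(num, dim = c(m, m, m)))) * (m^3 / n^2)
  lo <- m / 2 - n / 2 + 1
  hi <- m / 2 + n / 2
  volume_grid(vol_pad[lo:hi, lo:hi, lo:hi], pixel_size)
}
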