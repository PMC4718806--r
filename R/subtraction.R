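#' Subtract the projection of a masked map from particle images
#'
#' The core operation of focused classification with signal subtraction:
#' for every particle `i`, the CTF-affected 2D projection of the "ignore"
#' map `v1` (the consensus map multiplied by the mask of everything outside
#' the region of interest) is computed at the particle's recorded
#' orientation and offsets and subtracted from its image:
#' `out_i = D_i - CTF_i * P(v1)`.  What remains is, up to noise, the
#' CTF-affected projection of the region of interest only.  Metadata are
#' copied verbatim (particle order preserved); `image_name` is repointed at
#' the new stack.  There is no per-particle intensity fitting and no
#' re-normalization: the images are modified by pure subtraction.
#'
#' @param particles a [particle_set()] with angles, offsets and CTF
#'   parameters from a consensus refinement.
#' @param images an [image_stack()], one image per particle.
#' @param v1 the [volume_grid()] whose signal is to be removed; must match
#'   the particle box and pixel size.
#' @param apply_ctf multiply the subtracted projection by each particle's
#'   CTF (the normal case); set `FALSE` only for CTF-free data.
#' @param pad projector oversampling factor.
#' @param output_name stack name recorded in the returned metadata.
#' @return list with elements `images` (the subtracted [image_stack()]) and
#'   `particles` (the updated [particle_set()]).
#' @export
subtract_signal <- function(particles, images, v1, apply_ctf = TRUE,
                            pad = 2L, output_name = "subtracted.mrcs") {
  stopifnot(inherits(particles, "particle_set"),
            inherits(images, "image_stack"),
            inherits(v1, "volume_grid"))
  n <- box_size(images)
  if (box_size(v1) != n)
    stop("map box (", box_size(v1), ") does not match image box (", n, ")")
  if (abs(v1$pixel_size - images$pixel_size) > 1e-6)
    stop("map and image pixel sizes differ")
  if (nrow(particles) != n_images(images))
    stop("particle set and image stack sizes differ")
  proj <- project_particles(v1, particles, apply_ctf = apply_ctf, pad = pad)
  out <- images$data - proj$data
  new_particles <- particles
  new_particles$image_name <- output_name
  new_particles$image_index <- seq_len(nrow(particles))
  list(images = image_stack(out, images$pixel_size),
       particles = new_particles)
}
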