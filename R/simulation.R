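#' Two-class phantom: a common body plus a mobile rod
#'
#' Builds a pair of phantoms that emulate the conformational-heterogeneity
#' scenario the method targets: both share an identical multi-lobed "body"
#' (the rigid bulk of a complex), and class A additionally contains a short
#' rod of pseudo-atoms (a helix-sized element, ordered in one class only)
#' lying inside a focus region.  Outside the focus region the two phantoms
#' are identical by construction.
#'
#' @param n box size in voxels.
#' @param pixel_size voxel size in Angstrom.
#' @param rod_length rod length in Angstrom (0 gives identical phantoms).
#' @param rod_offset distance from the box center to the rod's inner end,
#'   Angstrom, along +x.
#' @param rod_weight peak density of each rod pseudo-atom relative to the
#'   body atoms.
#' @return list with elements `a`, `b` (class `phantom`: a `map`
#'   [volume_grid()] plus a `parts` registry of pseudo-atom tables) and
#'   `focus` (list `center` (Angstrom), `radius` (Angstrom) describing a
#'   spherical focus region enclosing the rod with margin).
#' @export
build_two_class_phantom <- function(n = 64, pixel_size = 2.8,
                                    rod_length = 30, rod_offset = 14,
                                    rod_weight = 1) {
  half <- n / 2 * pixel_size
  # body: fixed, roughly globular arrangement of blobs around the center,
  # shifted away from the rod side so the rod stays resolvable
  body_r <- 0.22 * n * pixel_size
  golden <- pi * (3 - sqrt(5))
  nb <- 24
  k <- seq_len(nb)
  zs <- (2 * k - 1) / nb - 1
  rs <- sqrt(pmax(0, 1 - zs^2))
  body <- data.frame(
    x = body_r * rs * cos(golden * k) * 0.85 - 0.05 * n * pixel_size,
    y = body_r * rs * sin(golden * k) * 0.85,
    z = body_r * zs * 0.85,
    radius = 7, weight = 1)
  body <- rbind(body, data.frame(x = -0.05 * n * pixel_size, y = 0, z = 0,
                                 radius = 10, weight = 1.5))
  # rod: pseudo-atoms every ~7.5 A along +x, starting rod_offset from center
  n_rod <- max(0L, as.integer(round(rod_length / 7.5)) + ifelse(rod_length > 0, 1L, -1L))
  rod <- if (n_rod > 0) {
    xs <- rod_offset + seq(0, rod_length, length.out = n_rod)
    data.frame(x = xs, y = 0, z = 0, radius = 7, weight = rod_weight)
  } else data.frame(x = numeric(), y = numeric(), z = numeric(),
                    radius = numeric(), weight = numeric())
  if (nrow(rod) && max(rod$x) >= half - 2 * pixel_size)
    stop("rod extends outside the box")
  map_body <- pseudo_atoms_to_map(body, n, pixel_size)
  map_rod <- pseudo_atoms_to_map(rod, n, pixel_size)
  a <- structure(list(map = volume_grid(map_body$data + map_rod$data,
                                        pixel_size),
                      parts = list(body = body, rod = rod)),
                 class = "phantom")
  b <- structure(list(map = map_body, parts = list(body = body)),
                 class = "phantom")
  focus <- list(center = c(rod_offset + rod_length / 2, 0, 0),
                radius = rod_length / 2 + 12)
  list(a = a, b = b, focus = focus)
}

#' Simulation recipe
#'
#' Bundles the controls of the forward simulator: per-class particle
#' counts, CTF parameter ranges, pixel size and the noise spectrum.  Noise
#' is specified either as a flat real-space standard deviation
#' (`noise_sd`), or as a per-shell table of Fourier variances
#' (`noise_spectrum`, length `N/2 + 1`, in units of `|FFT|^2` of the
#' unnormalized centered transform).
#'
#' @param n_per_class particles per class (>= 1).
#' @param defocus_range defocus range in micrometer, within (0, 10].
#' @param voltage kV.  @param cs mm.  @param amplitude_contrast Q.
#' @param pixel_size Angstrom.
#' @param noise_sd flat-spectrum real-space noise standard deviation; 0 for
#'   noise-free data.
#' @param noise_spectrum optional per-shell Fourier variance table
#'   overriding `noise_sd`.
#' @param seed RNG seed recorded with the recipe.
#' @return An object of class `sim_recipe`.
#' @export
sim_recipe <- function(n_per_class = 2000, defocus_range = c(0.7, 3.2),
                       voltage = 300, cs = 2.7, amplitude_contrast = 0.1,
                       pixel_size = 2.8, noise_sd = 0,
                       noise_spectrum = NULL, seed = 42) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (any(defocus_range <= 0) || any(defocus_range > 10))
    stop("defocus range must lie within (0, 10] micrometer")
  structure(list(n_per_class = as.integer(n_per_class),
                 defocus_range = defocus_range, voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size, noise_sd = noise_sd,
                 noise_spectrum = noise_spectrum, seed = as.integer(seed)),
            class = "sim_recipe")
}

# per-shell Fourier variance vector (length n/2 + 1) implied by a recipe
recipe_spectrum <- function(recipe, n) {
  if (!is.null(recipe$noise_spectrum)) {
    stopifnot(length(recipe$noise_spectrum) == n / 2 + 1)
    recipe$noise_spectrum
  } else {
    rep(n^2 * recipe$noise_sd^2, n / 2 + 1)
  }
}

# one real-space noise image with the given per-shell Fourier variance:
# white Gaussian noise shaped shell-wise in Fourier space (Hermitian by
# construction since the white field is real)
draw_noise_image <- function(n, spectrum, shell_idx) {
  if (all(spectrum == 0)) return(matrix(0, n, n))
  g <- matrix(rnorm(n * n), n, n)
  gf <- cfft2(g)
  si <- shell_idx
  si[si < 0L] <- length(spectrum) - 1L  # corners: extend the last shell
  amp <- matrix(sqrt(spectrum[si + 1L]) / n, n, n)
  Re(cifft2(gf * amp))
}

#' Simulate a particle stack from labelled phantoms
#'
#' For each particle: draw a uniform SO(3) orientation and a defocus from
#' the recipe range, project the phantom of its class through the CTF at
#' that orientation, and add colored Gaussian noise shaped shell-wise to
#' the recipe's spectrum.  Offsets are zero (simulated particles are
#' centered).  The generating parameters, class labels and the exact noise
#' realizations are returned, so that downstream operations can be checked
#' against ground truth; everything is deterministic given the seed.
#'
#' @param phantoms list of [volume_grid()]s (or `phantom` objects), one per
#'   class, sharing one grid.
#' @param recipe a [sim_recipe()].
#' @return list with `images` ([image_stack()]), `particles`
#'   ([particle_set()] with `class_label` ground truth) and `noise`
#'   ([image_stack()] of the stored noise realizations).
#' @export
simulate_particles <- function(phantoms, recipe) {
  stopifnot(inherits(recipe, "sim_recipe"))
  vols <- lapply(phantoms, function(p)
    if (inherits(p, "phantom")) p$map else p)
  n <- box_size(vols[[1]])
  px <- recipe$pixel_size
  for (v in vols)
    if (box_size(v) != n) stop("phantoms are on different grids")
  n_cls <- length(vols)
  n_tot <- n_cls * recipe$n_per_class
  set.seed(recipe$seed)
  labels <- rep(seq_len(n_cls), each = recipe$n_per_class)
  df <- data.frame(
    image_name = "simulated.mrcs",
    image_index = seq_len(n_tot),
    rot = runif(n_tot, -180, 180),
    tilt = acos(runif(n_tot, -1, 1)) * 180 / pi,
    psi = runif(n_tot, -180, 180),
    origin_x = 0, origin_y = 0,
    defocus_u = runif(n_tot, recipe$defocus_range[1] * 1e4,
                      recipe$defocus_range[2] * 1e4),
    astig_angle = 0,
    voltage = recipe$voltage, cs = recipe$cs,
    amplitude_contrast = recipe$amplitude_contrast,
    phase_shift = 0,
    class_label = labels)
  df$defocus_v <- df$defocus_u
  particles <- particle_set(df, pixel_size = px, box = n)

  spectrum <- recipe_spectrum(recipe, n)
  shell_idx <- shell_index_2d(n)
  imgs <- array(0, dim = c(n, n, n_tot))
  noise <- array(0, dim = c(n, n, n_tot))
  for (k in seq_len(n_cls)) {
    sel <- which(labels == k)
    fv <- fourier_volume(volume_grid(vols[[k]]$data, px), pad = 2L)
    proj <- project_particles(fv, particles[sel, ], apply_ctf = TRUE)
    imgs[, , sel] <- proj$data
  }
  for (i in seq_len(n_tot)) {
    ni <- draw_noise_image(n, spectrum, shell_idx)
    noise[, , i] <- ni
    imgs[, , i] <- imgs[, , i] + ni
  }
  list(images = image_stack(imgs, px), particles = particles,
       noise = image_stack(noise, px))
}

#' Classification accuracy against ground truth
#'
#' Fraction of particles whose hard (argmax, lowest index on ties) class
#' assignment agrees with the generating label, maximized over all
#' label-to-class bijections to absorb EM label switching.
#'
#' @param resp `n x K` responsibility matrix (or a hard assignment vector
#'   of length `n`).
#' @param truth integer ground-truth labels (values `1..L`, `L <= K`).
#' @return accuracy in `[0, 1]`.
#' @export
score_classification <- function(resp, truth) {
  assign <- if (is.matrix(resp)) max.col(resp, ties.method = "first")
            else as.integer(resp)
  if (length(assign) != length(truth))
    stop("responsibilities and truth labels differ in length")
  k <- if (is.matrix(resp)) ncol(resp) else max(assign, truth)
  l <- max(truth)
  if (l > k) stop("more truth labels than classes")
  conf <- matrix(0L, l, k)
  for (i in seq_along(truth))
    conf[truth[i], assign[i]] <- conf[truth[i], assign[i]] + 1L
  perms <- all_injections(l, k)
  best <- 0L
  for (p in perms)
    best <- max(best, sum(conf[cbind(seq_len(l), p)]))
  best / length(truth)
}

# all injective maps from 1..l into 1..k (l <= k, small)
all_injections <- function(l, k) {
  if (l == 1) return(lapply(seq_len(k), identity))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == l) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in remaining) rec(c(prefix, v), setdiff(remaining, v))
  }
  rec(integer(), seq_len(k))
  out
}
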