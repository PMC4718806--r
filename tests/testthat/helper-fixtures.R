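# Shared fixtures.  All test phantoms are built from Gaussian pseudo-atoms
# with sigma >= 1.5 px, i.e. band-limited well inside Nyquist, so that
# Fourier-slice and real-space oracles agree to interpolation accuracy.

rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

# a small asymmetric multi-blob phantom; atoms stay within +/- 10 % of the
# box so truncation leakage does not swamp interpolation-accuracy checks
test_phantom <- function(n = 16, pixel_size = 2, n_atoms = 3, seed = 7,
                         sigma_px = 1.5) {
  set.seed(seed)
  lim <- 0.10 * n * pixel_size
  at <- data.frame(x = runif(n_atoms, -lim, lim),
                   y = runif(n_atoms, -lim, lim),
                   z = runif(n_atoms, -lim, lim),
                   radius = 2 * sigma_px * pixel_size,
                   weight = runif(n_atoms, 0.5, 1.5))
  list(atoms = at, vol = pseudo_atoms_to_map(at, n, pixel_size))
}

# particle set with uniform orientations; defocus_range in Angstrom or
# NULL for CTF-free records (zero defocus, zero Q, zero Cs)
test_particles <- function(np, n, pixel_size, seed = 1,
                           defocus_range = NULL, offsets = FALSE) {
  set.seed(seed)
  ctf_free <- is.null(defocus_range)
  df <- data.frame(
    image_name = "test.mrcs", image_index = seq_len(np),
    rot = runif(np, -180, 180),
    tilt = acos(runif(np, -1, 1)) * 180 / pi,
    psi = runif(np, -180, 180),
    origin_x = if (offsets) runif(np, -2, 2) else 0,
    origin_y = if (offsets) runif(np, -2, 2) else 0,
    defocus_u = if (ctf_free) 0 else runif(np, defocus_range[1],
                                           defocus_range[2]),
    astig_angle = 0, voltage = 300,
    cs = if (ctf_free) 0 else 2.7,
    amplitude_contrast = if (ctf_free) 0 else 0.1,
    phase_shift = 0)
  df$defocus_v <- df$defocus_u
  particle_set(df, pixel_size, n)
}

# real-space rotation of a volume by exact re-rendering of its pseudo-atoms
rotate_phantom <- function(atoms, R, n, pixel_size) {
  atr <- atoms
  atr[, 1:3] <- t(R %*% t(as.matrix(atoms[, c("x", "y", "z")])))
  pseudo_atoms_to_map(atr, n, pixel_size)
}

# real-space trilinear rotation (V_rot(r) = V(R^T r)) for rotation oracles
# on arbitrary volumes
rotate_trilinear <- function(V, R) {
  n <- dim(V)[1]
  c0 <- n / 2 + 1
  g <- as.matrix(expand.grid(x = seq_len(n), y = seq_len(n),
                             z = seq_len(n))) - c0
  src <- g %*% R + c0
  x0 <- floor(src)
  fr <- src - x0
  ok <- rowSums(x0 >= 1 & x0 < n) == 3L
  o <- which(ok)
  val <- numeric(nrow(src))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[o, 1] else 1 - fr[o, 1]) *
         (if (dy) fr[o, 2] else 1 - fr[o, 2]) *
         (if (dz) fr[o, 3] else 1 - fr[o, 3])
    val[o] <- val[o] + w * V[cbind(x0[o, 1] + dx, x0[o, 2] + dy,
                                   x0[o, 3] + dz)]
  }
  array(val, dim = c(n, n, n))
}

# z-sum projection of a volume array
zsum <- function(V) apply(V, c(1, 2), sum)

# solid binary sphere volume
sphere_vol <- function(n, pixel_size, radius_px, center_px = c(0, 0, 0)) {
  coord <- seq_len(n) - 1 - n / 2
  r <- sqrt(outer(outer((coord - center_px[1])^2,
                        (coord - center_px[2])^2, `+`),
                  (coord - center_px[3])^2, `+`))
  volume_grid(array(as.numeric(r <= radius_px), dim = c(n, n, n)),
              pixel_size)
}
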