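#' Contrast transfer function parameters
#'
#' Microscope and defocus parameters of the weak-phase-object CTF.
#' Underfocus is positive, following the particle-metadata convention.
#'
#' @param voltage acceleration voltage in kV (> 0).
#' @param cs spherical aberration in mm.
#' @param amplitude_contrast amplitude-contrast fraction Q in `[0, 1)`.
#' @param defocus_u,defocus_v defocus along the astigmatism major/minor
#'   axes in Angstrom.
#' @param astig_angle azimuth of the `defocus_u` axis, degrees.
#' @param phase_shift additional phase shift (phase plate), degrees.
#' @return An object of class `ctf_params`.
#' @export
ctf_params <- function(voltage = 300, cs = 2.7, amplitude_contrast = 0.1,
                       defocus_u = 10000, defocus_v = defocus_u,
                       astig_angle = 0, phase_shift = 0) {
  if (voltage <= 0) stop("voltage must be positive")
  if (amplitude_contrast < 0 || amplitude_contrast >= 1)
    stop("amplitude_contrast must lie in [0, 1)")
  if (!is.finite(defocus_u) || !is.finite(defocus_v))
    stop("defoci must be finite")
  structure(list(voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 defocus_u = defocus_u, defocus_v = defocus_v,
                 astig_angle = astig_angle, phase_shift = phase_shift),
            class = "ctf_params")
}

#' Relativistic electron wavelength
#'
#' @param voltage_kv acceleration voltage in kV.
#' @return wavelength in Angstrom, from
#'   `h / sqrt(2 m0 e V (1 + e V / (2 m0 c^2)))` with CODATA constants.
#' @export
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  h <- 6.62607015e-34
  m0 <- 9.1093837015e-31
  e <- 1.602176634e-19
  c <- 299792458
  h / sqrt(2 * m0 * e * v * (1 + e * v / (2 * m0 * c^2))) * 1e10
}

#' Evaluate the CTF at given spatial frequencies
#'
#' The weak-phase model with amplitude contrast Q:
#' `CTF(f) = -(sqrt(1 - Q^2) * sin(gamma) + Q * cos(gamma))`, where
#' `gamma = pi * lambda * dz(theta) * |f|^2 - pi/2 * Cs * lambda^3 * |f|^4
#' + phase_shift` and `dz(theta)` is the astigmatic defocus at azimuth
#' `theta = atan2(fy, fx)`.  With this sign convention `CTF(0) = -Q`, so a
#' positive (protein) density projected and CTF-multiplied produces
#' negative (dark) contrast; the simulator and the subtraction operator
#' share the convention, which is what makes subtraction self-consistent.
#'
#' @param ctf a [ctf_params()] object.
#' @param fx,fy spatial frequency components in 1/Angstrom (vectors).
#' @return numeric vector of CTF gains in `[-1, 1]`.
#' @export
ctf_eval <- function(ctf, fx, fy) {
  lambda <- electron_wavelength(ctf$voltage)
  f2 <- fx^2 + fy^2
  theta <- atan2(fy, fx)
  ang <- theta - ctf$astig_angle * pi / 180
  dz <- 0.5 * (ctf$defocus_u + ctf$defocus_v +
               (ctf$defocus_u - ctf$defocus_v) * cos(2 * ang))
  cs_a <- ctf$cs * 1e7  # mm -> Angstrom
  gamma <- pi * lambda * dz * f2 - 0.5 * pi * cs_a * lambda^3 * f2^2 +
    ctf$phase_shift * pi / 180
  q <- ctf$amplitude_contrast
  -(sqrt(1 - q^2) * sin(gamma) + q * cos(gamma))
}

# CTF evaluated on the centered N x N Fourier grid of an image
# (frequencies h/(N * pixel_size)); returns an N x N matrix
ctf_image <- function(ctf, n, pixel_size) {
  h <- freq_axis(n) / (n * pixel_size)
  fx <- matrix(h, n, n)
  fy <- matrix(h, n, n, byrow = TRUE)
  matrix(ctf_eval(ctf, as.vector(fx), as.vector(fy)), n, n)
}

# row i of a particle_set as ctf_params
ctf_from_particle <- function(particles, i) {
  ctf_params(voltage = particles$voltage[i], cs = particles$cs[i],
             amplitude_contrast = particles$amplitude_contrast[i],
             defocus_u = particles$defocus_u[i],
             defocus_v = particles$defocus_v[i],
             astig_angle = particles$astig_angle[i],
             phase_shift = particles$phase_shift[i])
}

# N^2 x n matrix of per-particle CTFs on the centered grid
particle_ctf_matrix <- function(particles, n, pixel_size) {
  out <- matrix(0, n * n, nrow(particles))
  for (i in seq_len(nrow(particles)))
    out[, i] <- as.vector(ctf_image(ctf_from_particle(particles, i),
                                    n, pixel_size))
  out
}
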