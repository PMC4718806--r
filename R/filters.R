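#' Tabulated radial Fourier filter
#'
#' A `radial_filter` stores gain as a function of spatial frequency
#' (1/Angstrom) on a strictly increasing grid starting at 0 and is applied
#' by linear interpolation; beyond the last tabulated frequency the last
#' gain is held.  Detector MTF curves supplied as two-column text files use
#' the same representation (see [read_radial_filter()]).
#'
#' @param freq numeric vector of frequencies in 1/Angstrom, strictly
#'   increasing from 0.
#' @param gain numeric vector of finite gains, same length.
#' @return An object of class `radial_filter`.
#' @export
radial_filter <- function(freq, gain) {
  if (length(freq) != length(gain)) stop("freq and gain lengths differ")
  if (freq[1] != 0 || any(diff(freq) <= 0))
    stop("frequency grid must increase strictly from 0")
  if (!all(is.finite(gain))) stop("gains must be finite")
  structure(list(freq = as.numeric(freq), gain = as.numeric(gain)),
            class = "radial_filter")
}

#' @rdname radial_filter
#' @param filter a `radial_filter`.
#' @param nu frequencies (1/Angstrom) at which to evaluate the gain.
#' @export
filter_gain <- function(filter, nu) {
  approx(filter$freq, filter$gain, xout = nu, rule = 2)$y
}

#' Cosine-edged low-pass filter
#'
#' Gain is 1 up to the cutoff frequency, falls along a cosine half-cycle,
#' and reaches exactly 0 two reciprocal pixels beyond the cutoff (one
#' reciprocal pixel is `1/(N * pixel_size)` in 1/Angstrom).  A cutoff at or
#' beyond Nyquist yields an all-pass filter.
#'
#' @param cutoff_resolution cutoff as a resolution in Angstrom (> 0); the
#'   cutoff frequency is its reciprocal.
#' @param n box size in pixels.
#' @param pixel_size pixel size in Angstrom.
#' @return a [radial_filter()].
#' @export
make_lowpass <- function(cutoff_resolution, n, pixel_size) {
  if (!is.finite(cutoff_resolution) || cutoff_resolution <= 0)
    stop("cutoff resolution must be positive")
  nu_c <- 1 / cutoff_resolution
  rp <- 1 / (n * pixel_size)            # one reciprocal pixel
  nyq <- 1 / (2 * pixel_size)
  if (nu_c >= nyq)                      # clamp to all-pass
    return(radial_filter(c(0, nyq * 2), c(1, 1)))
  # tabulate the cosine edge densely, with the breakpoints on-grid
  edge <- nu_c + seq(0, 2, by = 1 / 16) * rp
  gain_edge <- 0.5 * (1 + cos(pi * (edge - nu_c) / (2 * rp)))
  gain_edge[length(gain_edge)] <- 0
  freq <- c(0, edge, nu_c + 4 * rp, 2 * nyq)
  gain <- c(1, gain_edge, 0, 0)
  radial_filter(freq, gain)
}

# gain per voxel of a centered cubic/square Fourier grid
.filter_grid <- function(filter, dims, pixel_size) {
  n <- dims[1]
  r <- if (length(dims) == 3L) radius_grid_3d(n) else radius_grid_2d(n)
  g <- filter_gain(filter, as.vector(r) / (n * pixel_size))
  array(g, dim = dims)
}

#' Apply a radial filter to a volume or image
#'
#' Scales the Fourier amplitudes shell-wise by the filter gain
#' (`mode = "multiply"`) or its reciprocal (`mode = "divide"`, e.g. for
#' detector-MTF correction).  The output is real; Hermitian symmetry is
#' preserved because the gain is purely radial.
#'
#' @param x a [volume_grid()] or [image_stack()].
#' @param filter a [radial_filter()].
#' @param mode `"multiply"` or `"divide"`.
#' @return same type as `x`.
#' @export
apply_radial_filter <- function(x, filter, mode = c("multiply", "divide")) {
  mode <- match.arg(mode)
  apply_one <- function(a, px) {
    g <- .filter_grid(filter, dim(a), px)
    if (mode == "divide") {
      n <- dim(a)[1]
      max_nu <- sqrt(length(dim(a))) * (n / 2) / (n * px)
      if (any(g <= 0) || any(filter$gain <= 0 & filter$freq <= max_nu))
        stop("divide mode requires strictly positive gains on the support")
      g <- 1 / g
    }
    Re(cifftn(cfftn(a) * g))
  }
  if (inherits(x, "volume_grid")) {
    volume_grid(apply_one(x$data, x$pixel_size), x$pixel_size)
  } else if (inherits(x, "image_stack")) {
    out <- x$data
    for (i in seq_len(dim(out)[3]))
      out[, , i] <- apply_one(x$data[, , i, drop = TRUE], x$pixel_size)
    image_stack(out, x$pixel_size)
  } else stop("`x` must be a volume_grid or image_stack")
}

#' B-factor sharpening (or blurring) of a map
#'
#' Scales Fourier amplitudes by `exp(-B * nu^2 / 4)`; a negative B-factor
#' boosts high-resolution amplitudes (sharpening) and is normally combined
#' with a low-pass filter to keep noise beyond the resolution limit down.
#'
#' @param vol a [volume_grid()].
#' @param b_factor B in Angstrom^2; negative sharpens, positive blurs.
#' @param lowpass optional resolution in Angstrom for a cosine low-pass
#'   applied after scaling (see [make_lowpass()]); `NULL` for none.
#' @return sharpened [volume_grid()].
#' @export
sharpen <- function(vol, b_factor, lowpass = NULL) {
  stopifnot(inherits(vol, "volume_grid"))
  n <- box_size(vol)
  nu <- radius_grid_3d(n) / (n * vol$pixel_size)
  out <- volume_grid(Re(cifft3(cfft3(vol$data) * exp(-b_factor * nu^2 / 4))),
                     vol$pixel_size)
  if (!is.null(lowpass))
    out <- apply_radial_filter(out, make_lowpass(lowpass, n, vol$pixel_size))
  out
}

#' Read / write a radial filter as two-column text
#'
#' The format is plain whitespace-separated text: frequency in 1/Angstrom
#' and gain, one pair per line, as used for user-supplied detector MTF
#' curves.
#'
#' @param path file path.
#' @return [read_radial_filter()] returns a [radial_filter()];
#'   `write_radial_filter` returns `path` invisibly.
#' @export
read_radial_filter <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("freq", "gain"))
  radial_filter(tab$freq, tab$gain)
}

#' @rdname read_radial_filter
#' @param filter a [radial_filter()].
#' @export
write_radial_filter <- function(filter, path) {
  utils::write.table(data.frame(filter$freq, filter$gain), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
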