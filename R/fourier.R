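# Centered FFT helpers.  All Fourier-domain arrays in this package use the
# "centered" layout: 1-based index i along an axis of length n corresponds
# to integer frequency h = i - 1 - n/2, so DC sits at index n/2 + 1.  Sizes
# are always even, for which fftshift and its inverse coincide.

fftshiftn <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    stopifnot(n %% 2 == 0)
    c((n / 2 + 1):n, 1:(n / 2))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# checkerboard (-1)^(i1+i2+...) masks, cached per shape; for sizes
# divisible by 4 the centered transform is cb * fft(cb * x), which avoids
# the two index-shuffle copies of the fftshift route
.cb_cache <- new.env(parent = emptyenv())
checkerboard <- function(d) {
  key <- paste(d, collapse = "x")
  cb <- .cb_cache[[key]]
  if (is.null(cb)) {
    cb <- Reduce(function(a, n) outer(a, (-1)^(seq_len(n) - 1)),
                 d[-1], (-1)^(seq_len(d[1]) - 1))
    dim(cb) <- d
    .cb_cache[[key]] <- cb
  }
  cb
}

# centered forward / inverse transforms (forward unnormalized, inverse 1/M)
cfftn <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (all(d %% 4 == 0)) {
    cb <- checkerboard(d)
    cb * fft(cb * x)
  } else {
    fftshiftn(fft(fftshiftn(x)))
  }
}

cifftn <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (all(d %% 4 == 0)) {
    cb <- checkerboard(d)
    cb * fft(cb * x, inverse = TRUE) / length(x)
  } else {
    fftshiftn(fft(fftshiftn(x), inverse = TRUE)) / length(x)
  }
}

cfft2 <- function(x) cfftn(x)
cifft2 <- function(x) cifftn(x)
cfft3 <- function(x) cfftn(x)
cifft3 <- function(x) cifftn(x)

# integer frequencies along one axis of length n (centered layout)
freq_axis <- function(n) seq.int(-n / 2, n / 2 - 1)

# |h| for every pixel of an N x N centered Fourier grid
radius_grid_2d <- function(n) {
  h <- freq_axis(n)
  sqrt(outer(h^2, h^2, `+`))
}

radius_grid_3d <- function(n) {
  h <- freq_axis(n)
  r2 <- outer(h^2, h^2, `+`)
  sqrt(outer(as.vector(r2), h^2, `+`)) |> array(dim = c(n, n, n))
}

# shell index (0..n/2) per pixel; -1 where outside the Nyquist ball
shell_index_2d <- function(n, max_shell = n / 2) {
  s <- as.integer(round(radius_grid_2d(n)))
  s[s > max_shell] <- -1L
  matrix(s, n, n)
}

shell_index_3d <- function(n, max_shell = n / 2) {
  s <- as.integer(round(radius_grid_3d(n)))
  s[s > max_shell] <- -1L
  array(s, dim = c(n, n, n))
}

# counts of Fourier components per shell
shell_counts <- function(shell_idx, n_shells) {
  tabulate(shell_idx + 1L, nbins = n_shells)
}
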