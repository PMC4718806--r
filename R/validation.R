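#' Fourier shell correlation between two maps
#'
#' Shell-wise normalized cross-correlation of the Fourier coefficients of
#' two (optionally soft-masked) maps on the same grid.  Shells where either
#' map has zero power are reported as 0 and flagged.
#'
#' @param v1,v2 [volume_grid()]s on the same grid.
#' @param mask optional soft mask multiplied into both maps first.
#' @return An object of class `fsc_curve`: a data frame with columns
#'   `shell`, `freq` (1/Angstrom), `fsc`, `n_voxels` and `flagged`.
#' @export
compute_fsc <- function(v1, v2, mask = NULL) {
  stopifnot(inherits(v1, "volume_grid"), inherits(v2, "volume_grid"))
  if (!identical(dim(v1$data), dim(v2$data)) ||
      v1$pixel_size != v2$pixel_size)
    stop("maps are on different grids")
  if (!is.null(mask)) {
    v1 <- apply_mask(v1, mask)
    v2 <- apply_mask(v2, mask)
  }
  n <- box_size(v1)
  f1 <- cfft3(v1$data)
  f2 <- cfft3(v2$data)
  sh <- shell_index_3d(n, n / 2)
  ok <- sh >= 0L
  idx <- sh[ok] + 1L
  cross <- Re(f1[ok] * Conj(f2[ok]))
  p1 <- Mod(f1[ok])^2
  p2 <- Mod(f2[ok])^2
  idxf <- factor(idx, levels = seq_len(n / 2 + 1L))
  num <- as.numeric(tapply(cross, idxf, sum, default = 0))
  d1 <- as.numeric(tapply(p1, idxf, sum, default = 0))
  d2 <- as.numeric(tapply(p2, idxf, sum, default = 0))
  nv <- as.numeric(table(idxf))
  flagged <- d1 <= 0 | d2 <= 0
  fsc <- ifelse(flagged, 0, num / sqrt(pmax(d1, 1e-300) * pmax(d2, 1e-300)))
  shells <- 0:(n / 2)
  structure(data.frame(shell = shells,
                       freq = shells / (n * v1$pixel_size),
                       fsc = fsc, n_voxels = nv, flagged = flagged),
            class = c("fsc_curve", "data.frame"),
            pixel_size = v1$pixel_size, box = n)
}

#' Resolution at an FSC threshold
#'
#' Finds the first downward crossing of the threshold along the curve and
#' linearly interpolates the crossing frequency between the bracketing
#' shells.  The conventional threshold for independent (gold-standard)
#' half-maps is 0.143.
#'
#' @param curve an [compute_fsc()] curve that starts above the threshold.
#' @param threshold FSC threshold.
#' @return resolution in Angstrom.  If the curve never drops below the
#'   threshold, the Nyquist resolution (`2 * pixel_size`) is returned with
#'   attribute `flagged = TRUE`.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  stopifnot(inherits(curve, "fsc_curve"))
  f <- curve$fsc
  nu <- curve$freq
  if (f[1] <= threshold) stop("FSC curve starts at or below the threshold")
  below <- which(f < threshold)
  if (!length(below)) {
    res <- 2 * attr(curve, "pixel_size")
    attr(res, "flagged") <- TRUE
    return(res)
  }
  j <- below[1]
  # linear interpolation on the segment (j-1, j)
  t <- (f[j - 1] - threshold) / (f[j - 1] - f[j])
  nu_c <- nu[j - 1] + t * (nu[j] - nu[j - 1])
  1 / nu_c
}

# randomize Fourier phases beyond a shell, preserving amplitudes and
# Hermitian symmetry (random phases come from the transform of a real
# white-noise volume)
phase_randomize <- function(vol, from_shell) {
  n <- box_size(vol)
  f <- cfft3(vol$data)
  w <- cfft3(array(rnorm(n^3), dim = c(n, n, n)))
  ph <- w / pmax(Mod(w), 1e-300)
  sh <- shell_index_3d(n, max_shell = .Machine$integer.max)
  sel <- sh > from_shell
  f[sel] <- Mod(f[sel]) * ph[sel]
  volume_grid(Re(cifft3(f)), vol$pixel_size)
}

#' Mask-corrected FSC by high-resolution noise substitution
#'
#' Soft masks inflate FSC values; this correction phase-randomizes both
#' half-maps beyond `randomize_from`, measures the FSC of the masked
#' randomized maps (`fsc_n`, pure mask-induced correlation), and reports
#' `(fsc_t - fsc_n) / (1 - fsc_n)` for shells beyond the randomization
#' frequency, where `fsc_t` is the masked FSC of the true maps.  Shells at
#' or before `randomize_from` are returned unmodified.
#'
#' @param half1,half2 independent half-maps.
#' @param mask the soft mask whose effect is being corrected.
#' @param randomize_from resolution (Angstrom) beyond which phases are
#'   randomized; the default is the frequency where the unmasked FSC first
#'   drops below 0.8.
#' @param seed RNG seed for the phase randomization.
#' @return an `fsc_curve` with extra columns `fsc_masked` (uncorrected) and
#'   `fsc_noise`; `fsc` holds the corrected curve.  Shells where
#'   `fsc_n = 1` are flagged invalid (NA).
#' @export
fsc_noise_substitution <- function(half1, half2, mask,
                                   randomize_from = NULL, seed = 1) {
  n <- box_size(half1)
  px <- half1$pixel_size
  if (is.null(randomize_from)) {
    plain <- compute_fsc(half1, half2)
    drop8 <- which(plain$fsc < 0.8)
    s0 <- if (length(drop8)) max(2L, plain$shell[drop8[1]]) else n %/% 4
  } else {
    s0 <- max(2L, floor(n * px / randomize_from))
  }
  fsc_t <- compute_fsc(half1, half2, mask)
  set.seed(seed)
  r1 <- phase_randomize(half1, s0)
  r2 <- phase_randomize(half2, s0)
  fsc_n <- compute_fsc(r1, r2, mask)
  out <- fsc_t
  out$fsc_masked <- fsc_t$fsc
  out$fsc_noise <- fsc_n$fsc
  beyond <- out$shell > s0
  denom <- 1 - fsc_n$fsc
  corrected <- (fsc_t$fsc - fsc_n$fsc) / denom
  invalid <- beyond & abs(denom) < 1e-9
  corrected[invalid] <- NA_real_
  out$fsc[beyond] <- corrected[beyond]
  out$flagged <- out$flagged | invalid
  attr(out, "randomize_from_shell") <- s0
  out
}

#' Split a particle set into gold-standard halves
#'
#' Assigns each particle to half 1 or 2 by even/odd position after a
#' seeded shuffle, recording the result in the `random_subset` column.
#'
#' @param particles a [particle_set()].
#' @param seed RNG seed.
#' @return the particle set with a `random_subset` column (values 1, 2).
#' @export
split_halves <- function(particles, seed = 1) {
  set.seed(seed)
  ord <- sample.int(nrow(particles))
  subset <- integer(nrow(particles))
  subset[ord] <- rep_len(1:2, nrow(particles))
  particles$random_subset <- subset
  particles
}

#' Structured report of a classification run
#'
#' Aggregates class fractions, per-class particle counts, optional
#' per-class resolutions, classification accuracy and run parameters into
#' a machine-readable list that serializes cleanly to JSON.
#'
#' @param model a `class_model`.
#' @param resp n x K responsibility matrix.
#' @param history iteration history from [classify()] (must be non-empty).
#' @param fsc optional named list of `fsc_curve`s (e.g. one per class);
#'   resolutions at 0.143 are included.
#' @param accuracy optional accuracy from [score_classification()].
#' @param seed seed used for the run.
#' @param extra optional named list merged into the report.
#' @return An object of class `run_report` (a list).
#' @export
run_report <- function(model, resp, history, fsc = NULL, accuracy = NULL,
                       seed = NULL, extra = NULL) {
  if (is.null(history) || nrow(history) == 0)
    stop("classification history is empty")
  sel <- select_classes(model, resp)
  rep <- list(
    n_particles = nrow(resp),
    n_classes = ncol(resp),
    iterations = model$iteration,
    class_fractions = as.numeric(model$fractions),
    hard_fractions = as.numeric(sel$fractions),
    class_counts = as.integer(tabulate(sel$assignment, ncol(resp))),
    mean_log_evidence = history$mean_log_evidence[nrow(history)],
    max_shell = model$max_shell,
    pixel_size = model$pixel_size,
    seed = seed)
  if (!is.null(fsc))
    rep$resolutions <- lapply(fsc, function(cv) as.numeric(resolution_at(cv)))
  if (!is.null(accuracy)) rep$accuracy <- accuracy
  if (!is.null(extra)) rep <- c(rep, extra)
  structure(rep, class = "run_report")
}

#' @rdname run_report
#' @param report a `run_report`.
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname compute_fsc
#' @param curve an `fsc_curve`.
#' @param path two-column text output (frequency, FSC).
#' @export
write_fsc <- function(curve, path) {
  utils::write.table(data.frame(curve$freq, curve$fsc), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
plot.fsc_curve <- function(x, threshold = 0.143, ...) {
  graphics::plot(x$freq, x$fsc, type = "l", xlab = "frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}
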