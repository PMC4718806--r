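# Masked multi-reference maximum-likelihood classification with fixed
# orientations ("no image alignment").  Each particle image D_i is compared
# in Fourier space to the CTF-affected projection of each soft-masked
# reference V_k at the particle's recorded orientation; responsibilities
# are posterior class probabilities under a shell-wise Gaussian noise
# model, and references, class fractions and the noise spectrum are
# re-estimated by expectation-maximization.

# cached per-run quantities: image FTs, CTF matrix, rotations, shifts,
# shell geometry
classification_precomp <- function(particles, images, max_shell) {
  n <- box_size(images)
  shell <- shell_index_2d(n, max_shell)
  list(dataft = stack_fft(images),
       ctf_mat = particle_ctf_matrix(particles, n, images$pixel_size),
       rot = particle_rotations(particles),
       shifts = .shift_matrix(particles$origin_x, particles$origin_y),
       shell = shell,
       counts = shell_counts(shell, max_shell + 1L),
       n = n, max_shell = max_shell)
}

# default classification resolution limit: two shells below Nyquist
default_max_shell <- function(n, pixel_size, resolution_limit = NULL) {
  slim <- n / 2 - 2L
  if (!is.null(resolution_limit))
    slim <- min(slim, floor(n * pixel_size / resolution_limit))
  as.integer(max(2L, slim))
}

# centered padded FTs of the (already masked) references
model_fourier <- function(model) {
  lapply(model$references, function(v) fourier_volume(v, model$pad)$ft)
}

new_class_model <- function(references, fractions, noise_spectrum, mask,
                            pad, max_shell, iteration = 0L, flags = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= -1e-12))
  structure(list(references = references, fractions = fractions,
                 noise_spectrum = noise_spectrum, mask = mask, pad = pad,
                 max_shell = max_shell, iteration = iteration,
                 pixel_size = references[[1]]$pixel_size, flags = flags),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("<class_model> K = %d, iteration %d, fractions: %s\n",
              length(x$references), x$iteration,
              paste(sprintf("%.3f", x$fractions), collapse = " ")))
  invisible(x)
}

# floor for the per-shell noise variances (keeps likelihoods finite on
# noise-free data)
guard_sigma2 <- function(s2) {
  floor_val <- max(mean(s2) * 1e-12, 1e-300)
  pmax(s2, floor_val)
}

#' Initialize a classification model
#'
#' Particles are hard-partitioned into K groups by a seeded random shuffle
#' of the balanced assignment `rep(1:K, length.out = n)` (the documented
#' recipe is `sample(rep_len(seq_len(K), n))` after `set.seed(seed)`); each
#' reference is reconstructed from its group and multiplied by the focus
#' mask; class fractions are the group fractions; the noise spectrum is
#' estimated from the per-shell residuals of all particles against the
#' pooled (all-particle) reconstruction.
#'
#' @param particles a [particle_set()].
#' @param images an [image_stack()] (normally signal-subtracted).
#' @param K number of classes (1 <= K <= n).
#' @param mask focus [make_soft_mask()] (or any volume on the same grid);
#'   `NULL` for an unmasked run.
#' @param seed RNG seed for the partition.
#' @param pad projector oversampling factor.
#' @param resolution_limit optional classification resolution limit in
#'   Angstrom; the default uses all shells up to two below Nyquist.
#' @param precomp internal cache from a `classify()` run.
#' @return An object of class `class_model`.
#' @export
init_classes <- function(particles, images, K, mask = NULL, seed = 1,
                         pad = 2L, resolution_limit = NULL, precomp = NULL) {
  np <- nrow(particles)
  if (K < 1) stop("K must be >= 1")
  if (K > np) stop("more classes than particles")
  n <- box_size(images)
  max_shell <- default_max_shell(n, images$pixel_size, resolution_limit)
  if (is.null(precomp))
    precomp <- classification_precomp(particles, images, max_shell)
  set.seed(seed)
  groups <- sample(rep_len(seq_len(K), np))
  refs <- vector("list", K)
  for (k in seq_len(K)) {
    acc <- new_accumulator(n, images$pixel_size, pad)
    acc <- reconstruct_accumulate_ft(acc, particles, precomp$dataft,
                                     as.numeric(groups == k),
                                     ctf_mat = precomp$ctf_mat,
                                     rot = precomp$rot,
                                     shifts = precomp$shifts)
    refs[[k]] <- reconstruct_finalize(acc, grid_correct = FALSE)
    if (!is.null(mask)) refs[[k]] <- apply_mask(refs[[k]], mask)
  }
  fractions <- tabulate(groups, K) / np
  # pooled reference for the initial noise spectrum
  acc <- new_accumulator(n, images$pixel_size, pad)
  acc <- reconstruct_accumulate_ft(acc, particles, precomp$dataft,
                                   rep(1, np), ctf_mat = precomp$ctf_mat,
                                   rot = precomp$rot,
                                   shifts = precomp$shifts)
  pooled <- reconstruct_finalize(acc, grid_correct = FALSE)
  if (!is.null(mask)) pooled <- apply_mask(pooled, mask)
  pooled_ft <- fourier_volume(pooled, pad)$ft
  es <- cf_estep(list(pooled_ft), pad * n, n, pad, precomp$rot,
                 precomp$shifts, precomp$dataft, precomp$ctf_mat,
                 rep(1, max_shell + 1L), precomp$shell)
  res_tot <- apply(array(es$shell_res, dim = c(max_shell + 1L, 1L, np)),
                   1, sum)
  sigma2 <- guard_sigma2(res_tot / (np * pmax(precomp$counts, 1L)))
  new_class_model(refs, fractions, sigma2, mask, pad, max_shell)
}

#' Expectation step: posterior class probabilities
#'
#' For each particle and class computes the Gaussian log-likelihood
#' `-sum_f |D_i(f) - CTF_i(f) P_{r_i}(V_k)(f)|^2 / (2 sigma^2(nu))` over
#' Fourier shells up to the classification resolution limit (plus the
#' `-m_s/2 log(2 pi sigma_s^2)` normalization shared by all classes), then
#' the responsibilities `r_ik` as the softmax of `log pi_k + log L_ik` over
#' classes.
#'
#' @param model a `class_model`.
#' @param particles a [particle_set()].
#' @param images an [image_stack()].
#' @param precomp internal cache from a `classify()` run.
#' @return list with `resp` (n x K responsibilities, rows summing to 1),
#'   `log_evidence` (per-particle marginal log-likelihood), `loglik`
#'   (n x K quadratic terms) and `shell_res` (per-shell residual power,
#'   S x K x n, consumed by [m_step()]).
#' @export
e_step <- function(model, particles, images = NULL, precomp = NULL) {
  if (is.null(precomp))
    precomp <- classification_precomp(particles, images, model$max_shell)
  n <- precomp$n
  np <- nrow(particles)
  K <- length(model$references)
  s2 <- guard_sigma2(model$noise_spectrum)
  es <- cf_estep(model_fourier(model), model$pad * n, n, model$pad,
                 precomp$rot, precomp$shifts, precomp$dataft,
                 precomp$ctf_mat, s2, precomp$shell)
  loglik <- es$loglik
  lpi <- ifelse(model$fractions > 0, log(model$fractions), -Inf)
  z <- sweep(loglik, 2, lpi, `+`)
  zmax <- apply(z, 1, max)
  lse <- zmax + log(rowSums(exp(z - zmax)))
  resp <- exp(z - lse)
  norm_const <- -0.5 * sum(precomp$counts * log(2 * pi * s2))
  list(resp = resp, log_evidence = lse + norm_const, loglik = loglik,
       shell_res = array(es$shell_res,
                         dim = c(model$max_shell + 1L, K, np)))
}

#' Maximization step: update references, fractions and noise spectrum
#'
#' Each reference is rebuilt by responsibility-weighted direct Fourier
#' reconstruction and re-multiplied by the focus mask; class fractions
#' become the mean responsibilities; the per-shell noise variances are
#' re-estimated from the responsibility-weighted residuals pooled over
#' classes.  The noise update uses the residuals computed during the
#' expectation step (i.e. against the pre-update references), so each
#' update is an exact coordinate-ascent step at the point where it is
#' applied.  A class with (near-)zero total responsibility keeps its
#' previous reference, gets fraction 0 and is flagged in `model$flags`.
#'
#' @param model the current `class_model`.
#' @param particles a [particle_set()].
#' @param images an [image_stack()].
#' @param resp n x K responsibility matrix from [e_step()].
#' @param shell_res optional `shell_res` array from the same [e_step()]
#'   call (recomputed if missing).
#' @param precomp internal cache from a `classify()` run.
#' @return the updated `class_model`.
#' @export
m_step <- function(model, particles, images = NULL, resp,
                   shell_res = NULL, precomp = NULL) {
  if (is.null(precomp))
    precomp <- classification_precomp(particles, images, model$max_shell)
  n <- precomp$n
  np <- nrow(particles)
  K <- length(model$references)
  if (is.null(shell_res))
    shell_res <- e_step(model, particles, precomp = precomp)$shell_res
  refs <- model$references
  flags <- NULL
  weight_sums <- colSums(resp)
  for (k in seq_len(K)) {
    if (weight_sums[k] < 1e-8) {
      flags <- c(flags, sprintf("class %d received no particles", k))
      next
    }
    acc <- new_accumulator(n, images$pixel_size %||% model$pixel_size,
                           model$pad)
    acc <- reconstruct_accumulate_ft(acc, particles, precomp$dataft,
                                     resp[, k], ctf_mat = precomp$ctf_mat,
                                     rot = precomp$rot,
                                     shifts = precomp$shifts)
    refs[[k]] <- reconstruct_finalize(acc, grid_correct = FALSE)
    if (!is.null(model$mask)) refs[[k]] <- apply_mask(refs[[k]], model$mask)
  }
  fractions <- weight_sums / np
  fractions[weight_sums < 1e-8] <- 0
  fractions <- fractions / sum(fractions)
  # sigma^2(s) = sum_ik r_ik * res_iks / (n * m_s), per Fourier component
  ns <- dim(shell_res)[1]
  wres <- numeric(ns)
  for (k in seq_len(K))
    wres <- wres + shell_res[, k, ] %*% resp[, k]
  sigma2 <- guard_sigma2(as.numeric(wres) / (np * pmax(precomp$counts, 1L)))
  new_class_model(refs, fractions, sigma2, model$mask, model$pad,
                  model$max_shell, model$iteration + 1L, flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Masked classification without image alignment
#'
#' Runs `n_iter` expectation-maximization iterations of masked
#' multi-reference classification with all orientations held fixed at the
#' values in `particles` (no alignment search).  Deterministic given
#' `seed`.
#'
#' @inheritParams init_classes
#' @param n_iter number of EM iterations (fixed count, no early exit).
#' @return list with `model` (final `class_model`), `resp` (final
#'   responsibilities), and `history` (data frame with one row per
#'   recorded iteration: mean log-evidence and class fractions).
#' @export
classify <- function(particles, images, K, mask = NULL, n_iter = 25,
                     seed = 1, resolution_limit = NULL, pad = 2L,
                     verbose = FALSE) {
  n <- box_size(images)
  max_shell <- default_max_shell(n, images$pixel_size, resolution_limit)
  precomp <- classification_precomp(particles, images, max_shell)
  model <- init_classes(particles, images, K, mask = mask, seed = seed,
                        pad = pad, resolution_limit = resolution_limit,
                        precomp = precomp)
  hist_ev <- numeric(0)
  hist_fr <- NULL
  for (t in seq_len(n_iter)) {
    es <- e_step(model, particles, images, precomp = precomp)
    hist_ev <- c(hist_ev, mean(es$log_evidence))
    hist_fr <- rbind(hist_fr, model$fractions)
    if (verbose)
      message(sprintf("iter %2d  mean log-evidence %.6g  fractions %s", t,
                      mean(es$log_evidence),
                      paste(sprintf("%.3f", model$fractions), collapse = " ")))
    model <- m_step(model, particles, images, es$resp,
                    shell_res = es$shell_res, precomp = precomp)
  }
  es <- e_step(model, particles, images, precomp = precomp)
  hist_ev <- c(hist_ev, mean(es$log_evidence))
  hist_fr <- rbind(hist_fr, model$fractions)
  history <- data.frame(iteration = seq_along(hist_ev) - 1L,
                        mean_log_evidence = hist_ev)
  colnames(hist_fr) <- paste0("fraction_", seq_len(K))
  history <- cbind(history, as.data.frame(hist_fr, row.names = FALSE))
  list(model = model, resp = es$resp, history = history)
}

#' Hard class assignment and class selection
#'
#' Assigns each particle to its maximum-responsibility class (lowest class
#' index on ties) and returns the per-class particle index lists, dropping
#' classes below a minimum fraction if requested.  Selection of "good"
#' classes beyond the fraction filter is left to the user.
#'
#' @param model a `class_model`.
#' @param resp n x K responsibility matrix.
#' @param min_fraction drop classes whose hard-assigned fraction is below
#'   this value (default 0: keep all).
#' @return list with `assignment` (length-n integer vector), `members`
#'   (list of particle index vectors for retained classes, named by class)
#'   and `fractions` (hard-assignment fractions for all K classes).
#' @export
select_classes <- function(model, resp, min_fraction = 0) {
  assign <- max.col(resp, ties.method = "first")
  K <- ncol(resp)
  fractions <- tabulate(assign, K) / nrow(resp)
  keep <- which(fractions >= min_fraction)
  members <- lapply(keep, function(k) which(assign == k))
  if (length(keep)) names(members) <- paste0("class_", keep)
  list(assignment = assign, members = members, fractions = fractions)
}
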