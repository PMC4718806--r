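#' End-to-end two-class simulation study
#'
#' Runs the package's complete workflow on simulated data in one call:
#' build two phantoms that differ only by a rod inside a focus region,
#' simulate CTF-affected particles with colored noise at ground-truth
#' orientations, reconstruct a consensus map from all particles, construct
#' the whole-complex and focus masks, subtract the CTF-affected projection
#' of the outside-focus part of the consensus map from every image, run
#' masked K=2 classification without alignment, and score the result
#' against the generating labels.
#'
#' The default conditions are the package's documented study conditions:
#' box 64 at 2.8 Angstrom/pixel, 2,000 particles per class, uniform
#' orientations, defocus uniform in 0.7-3.2 micrometer at 300 kV with
#' amplitude contrast 0.1, and flat-spectrum noise of standard deviation
#' 1.0, which puts the per-pixel image signal-to-noise ratio near 0.01.
#'
#' @param n_per_class simulated particles per class.
#' @param box box size in pixels.
#' @param pixel_size pixel size in Angstrom.
#' @param noise_sd real-space noise standard deviation (flat spectrum).
#' @param rod_length,rod_offset rod geometry in Angstrom, passed to
#'   [build_two_class_phantom()]; the defaults fit the default box.
#' @param defocus_range defocus range in micrometer.
#' @param n_iter EM iterations for the classification.
#' @param seed seed driving the whole study (simulation and
#'   classification).
#' @param subtract run the signal subtraction step (`FALSE` classifies the
#'   raw images with the same mask, for side-by-side comparisons).
#' @param mask_threshold consensus-map threshold for the whole-complex
#'   mask, as a fraction of the map maximum.
#' @param verbose print progress.
#' @return list with `accuracy`, `run` (the [classify()] output), `sim`
#'   (the simulation), `masks` (whole/focus/subtract), `v1` (the map that
#'   was subtracted) and `report` (a [run_report()]).
#' @export
run_simulation_study <- function(n_per_class = 2000, box = 64,
                                 pixel_size = 2.8, noise_sd = 1.0,
                                 rod_length = 30, rod_offset = 14,
                                 defocus_range = c(0.7, 3.2), n_iter = 25,
                                 seed = 42, subtract = TRUE,
                                 mask_threshold = 0.2, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ph <- build_two_class_phantom(n = box, pixel_size = pixel_size,
                                rod_length = rod_length,
                                rod_offset = rod_offset)
  recipe <- sim_recipe(n_per_class = n_per_class,
                       defocus_range = defocus_range,
                       pixel_size = pixel_size, noise_sd = noise_sd,
                       seed = seed)
  say("simulating 2 x %d particles at box %d", n_per_class, box)
  sim <- simulate_particles(list(ph$a, ph$b), recipe)
  say("reconstructing consensus map from %d particles", nrow(sim$particles))
  consensus <- reconstruct(sim$particles, sim$images)
  whole <- make_soft_mask(consensus, mask_threshold * max(consensus$data),
                          extend_px = 3, soft_edge_px = 6)
  focus <- make_spherical_mask(ph$focus$center, ph$focus$radius, box,
                               pixel_size, soft_edge_px = 4)
  outside <- mask_subtract(whole, focus)
  v1 <- apply_mask(consensus, outside)
  if (subtract) {
    say("subtracting the outside-focus consensus signal")
    sub <- subtract_signal(sim$particles, sim$images, v1)
  } else {
    sub <- list(particles = sim$particles, images = sim$images)
  }
  say("classifying K = 2, %d iterations, no alignment", n_iter)
  run <- classify(sub$particles, sub$images, K = 2, mask = focus,
                  n_iter = n_iter, seed = seed, verbose = verbose)
  accuracy <- score_classification(run$resp, sim$particles$class_label)
  say("accuracy %.4f", accuracy)
  report <- run_report(run$model, run$resp, run$history,
                       accuracy = accuracy, seed = seed,
                       extra = list(noise_sd = noise_sd,
                                    n_per_class = n_per_class,
                                    subtracted = subtract))
  list(accuracy = accuracy, run = run, sim = sim,
       masks = list(whole = whole, focus = focus, outside = outside),
       v1 = v1, report = report)
}
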