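test_that("FSC of a map with itself is 1, with its negation -1", {
  ph <- test_phantom(n = 24, pixel_size = 2, seed = 41)
  f1 <- compute_fsc(ph$vol, ph$vol)
  expect_true(all(abs(f1$fsc[!f1$flagged] - 1) < 1e-9))
  neg <- volume_grid(-ph$vol$data, 2)
  f2 <- compute_fsc(ph$vol, neg)
  expect_true(all(abs(f2$fsc[!f2$flagged] + 1) < 1e-9))
  # symmetry and scale invariance
  a <- volume_grid(ph$vol$data + 0.1, 2)
  b <- test_phantom(n = 24, pixel_size = 2, seed = 42)$vol
  expect_equal(compute_fsc(a, b)$fsc, compute_fsc(b, a)$fsc)
  expect_equal(compute_fsc(a, b)$fsc,
               compute_fsc(volume_grid(3 * a$data, 2),
                           volume_grid(0.5 * b$data, 2))$fsc,
               tolerance = 1e-12)
})

test_that("independent noise maps have near-zero mean FSC", {
  means <- sapply(1:10, function(s) {
    set.seed(100 + s)
    a <- volume_grid(array(rnorm(64^3), dim = c(64, 64, 64)), 1)
    b <- volume_grid(array(rnorm(64^3), dim = c(64, 64, 64)), 1)
    fc <- compute_fsc(a, b)
    mean(fc$fsc[fc$shell > 0])
  })
  expect_true(all(abs(means) < 0.05))
  expect_lt(abs(mean(means)), 0.02)
})

test_that("threshold crossings are interpolated between shells", {
  ph <- test_phantom(n = 32, pixel_size = 2, seed = 43)
  curve <- compute_fsc(ph$vol, ph$vol)
  # constant curve at 1 never crosses: Nyquist with a flag
  res <- resolution_at(curve)
  expect_equal(as.numeric(res), 2 * 2)
  expect_true(attr(res, "flagged"))
  # synthetic step 1 -> 0 between shells k and k+1
  k <- 8
  curve$fsc <- ifelse(curve$shell <= k, 1, 0)
  r <- resolution_at(curve, threshold = 0.143)
  nu_k <- curve$freq[curve$shell == k]
  nu_k1 <- curve$freq[curve$shell == k + 1]
  expected <- 1 / (nu_k + (1 - 0.143) * (nu_k1 - nu_k))
  expect_equal(as.numeric(r), expected, tolerance = 1e-12)
  curve$fsc <- rep(0.1, nrow(curve))
  expect_error(resolution_at(curve), "threshold")
})

test_that("half-map resolution degrades monotonically with noise", {
  n <- 32; px <- 2
  ph <- test_phantom(n, px, n_atoms = 5, seed = 44)
  parts <- split_halves(test_particles(400, n, px, seed = 45), seed = 45)
  clean <- cryofocus:::project_particles(ph$vol, parts, apply_ctf = FALSE)
  sh <- cryofocus:::shell_index_2d(n)
  res_by_noise <- sapply(c(0.02, 0.2, 0.8, 2, 6), function(sd) {
    resus <- sapply(1:5, function(s) {
      set.seed(1000 * sd + s)
      noisy <- clean$data +
        array(rnorm(length(clean$data), sd = sd), dim = dim(clean$data))
      st <- image_stack(noisy, px)
      h1 <- reconstruct(parts[parts$random_subset == 1, ],
                        image_stack(st$data[, , parts$random_subset == 1],
                                    px), apply_ctf = FALSE)
      h2 <- reconstruct(parts[parts$random_subset == 2, ],
                        image_stack(st$data[, , parts$random_subset == 2],
                                    px), apply_ctf = FALSE)
      as.numeric(resolution_at(compute_fsc(h1, h2)))
    })
    mean(resus)
  })
  expect_true(all(diff(res_by_noise) >= -1e-9))  # worse (larger A) with noise
  expect_gt(res_by_noise[5], res_by_noise[1])
})

test_that("shells at or before the randomization point are unmodified", {
  n <- 32
  ph <- test_phantom(n, 2, n_atoms = 4, seed = 46)
  set.seed(47)
  h1 <- volume_grid(ph$vol$data + array(rnorm(n^3, sd = .05), dim = c(n, n, n)), 2)
  h2 <- volume_grid(ph$vol$data + array(rnorm(n^3, sd = .05), dim = c(n, n, n)), 2)
  mask <- make_soft_mask(sphere_vol(n, 2, 10), 0.5, 1, 3)
  corr <- fsc_noise_substitution(h1, h2, mask, randomize_from = 8, seed = 3)
  s0 <- attr(corr, "randomize_from_shell")
  masked <- compute_fsc(h1, h2, mask)
  expect_equal(corr$fsc[corr$shell <= s0], masked$fsc[masked$shell <= s0])
  expect_false(all(corr$fsc[corr$shell > s0] ==
                   masked$fsc[masked$shell > s0]))
})

test_that("an all-pass mask leaves the corrected FSC unchanged", {
  n <- 32
  set.seed(48)
  h1 <- volume_grid(array(rnorm(n^3), dim = c(n, n, n)), 2)
  h2 <- volume_grid(array(rnorm(n^3), dim = c(n, n, n)), 2)
  ones <- volume_grid(array(1, dim = c(n, n, n)), 2)
  class(ones) <- c("soft_mask", class(ones))
  corr <- fsc_noise_substitution(h1, h2, ones, randomize_from = 10, seed = 5)
  plain <- compute_fsc(h1, h2)
  beyond <- corr$shell > attr(corr, "randomize_from_shell") & !corr$flagged
  expect_true(all(abs(corr$fsc[beyond] - plain$fsc[beyond]) < 0.05))
})

test_that("noise substitution removes mask-induced FSC inflation", {
  # half-maps share a band-limited signal (nothing beyond shell 8) plus
  # independent noise; a tight mask leaks the correlated low-frequency
  # signal into high shells, and the correction must take that back out
  n <- 48
  ph <- test_phantom(n, 2, n_atoms = 6, seed = 50, sigma_px = 2)
  sig <- apply_radial_filter(ph$vol, make_lowpass(12, n, 2))
  mask <- make_soft_mask(sphere_vol(n, 2, 6), 0.5, 1, 3)  # tight mask
  inflation <- numeric(10); corrected <- numeric(10)
  for (s in 1:10) {
    set.seed(300 + s)
    h1 <- volume_grid(sig$data * 40 + array(rnorm(n^3), dim = c(n, n, n)), 2)
    h2 <- volume_grid(sig$data * 40 + array(rnorm(n^3), dim = c(n, n, n)), 2)
    masked <- compute_fsc(h1, h2, mask)
    corr <- fsc_noise_substitution(h1, h2, mask, randomize_from = 12,
                                   seed = s)
    beyond <- corr$shell > attr(corr, "randomize_from_shell") & !corr$flagged
    inflation[s] <- mean(masked$fsc[masked$shell > 12])
    corrected[s] <- mean(corr$fsc[beyond], na.rm = TRUE)
  }
  expect_gt(mean(inflation), 0.2)          # the inflation the mask induces
  expect_lt(abs(mean(corrected)), 0.1)     # removed by the correction
  # the correction removes, never adds, correlation in this regime
  expect_lt(mean(corrected), mean(inflation) - 0.1)
})

test_that("run reports aggregate a classification consistently", {
  fx_ph <- build_two_class_phantom(n = 32, pixel_size = 2.8,
                                   rod_offset = 10, rod_length = 25)
  recipe <- sim_recipe(n_per_class = 15, pixel_size = 2.8, noise_sd = 0.3,
                       seed = 20)
  sim <- simulate_particles(list(fx_ph$a, fx_ph$b), recipe)
  sub <- subtract_signal(sim$particles, sim$images, fx_ph$b$map)
  focus <- make_spherical_mask(fx_ph$focus$center, fx_ph$focus$radius, 32,
                               2.8)
  run <- classify(sub$particles, sub$images, K = 2, mask = focus,
                  n_iter = 5, seed = 6)
  acc <- score_classification(run$resp, sim$particles$class_label)
  rep <- run_report(run$model, run$resp, run$history, accuracy = acc,
                    seed = 6)
  expect_equal(sum(rep$class_fractions), 1, tolerance = 1e-9)
  expect_equal(sum(rep$class_counts), nrow(sub$particles))
  expect_equal(rep$accuracy, acc)
  sel <- select_classes(run$model, run$resp)
  expect_equal(rep$class_counts, as.integer(tabulate(sel$assignment, 2)))
  expect_error(run_report(run$model, run$resp, run$history[0, ]), "empty")
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy, acc)
})
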