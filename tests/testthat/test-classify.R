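# Shared small classification fixture: two phantoms differing by a rod,
# simulated with CTFs, signal-subtracted, plus the focus mask.
classify_fixture <- function(n = 32, np = 60, noise_sd = 0.5, seed = 5) {
  ph <- build_two_class_phantom(n = n, pixel_size = 2.8, rod_offset = 10,
                                rod_length = 25)
  recipe <- sim_recipe(n_per_class = np, pixel_size = 2.8,
                       noise_sd = noise_sd, seed = seed)
  sim <- simulate_particles(list(ph$a, ph$b), recipe)
  sub <- subtract_signal(sim$particles, sim$images, ph$b$map)
  focus <- make_spherical_mask(ph$focus$center, ph$focus$radius, n, 2.8,
                               soft_edge_px = 4)
  list(ph = ph, sim = sim, sub = sub, focus = focus)
}

test_that("K = 1 reduces to the plain pooled reconstruction", {
  fx <- classify_fixture(np = 20, noise_sd = 0.3)
  model <- init_classes(fx$sub$particles, fx$sub$images, K = 1, seed = 1)
  plain <- reconstruct(fx$sub$particles, fx$sub$images,
                       grid_correct = FALSE)
  expect_lt(max(abs(model$references[[1]]$data - plain$data)), 1e-9)
  es <- e_step(model, fx$sub$particles, fx$sub$images)
  expect_true(all(es$resp == 1))
  expect_error(init_classes(fx$sub$particles, fx$sub$images, K = 1000),
               "classes")
})

test_that("duplicate references split responsibilities evenly", {
  fx <- classify_fixture(np = 10, noise_sd = 0.5)
  m1 <- init_classes(fx$sub$particles, fx$sub$images, K = 1, seed = 1,
                     mask = fx$focus)
  model <- cryofocus:::new_class_model(
    references = list(m1$references[[1]], m1$references[[1]]),
    fractions = c(0.5, 0.5), noise_spectrum = m1$noise_spectrum,
    mask = fx$focus, pad = 2L, max_shell = m1$max_shell)
  es <- e_step(model, fx$sub$particles, fx$sub$images)
  expect_lt(max(abs(es$resp - 0.5)), 1e-9)
  expect_equal(rowSums(es$resp), rep(1, nrow(es$resp)), tolerance = 1e-9)
})

test_that("truthful initialization classifies noise-free data perfectly", {
  fx <- classify_fixture(np = 25, noise_sd = 0)
  rodA <- apply_mask(volume_grid(fx$ph$a$map$data - fx$ph$b$map$data, 2.8),
                     fx$focus)
  zero <- apply_mask(volume_grid(array(0, dim = dim(rodA$data)), 2.8),
                     fx$focus)
  m1 <- init_classes(fx$sub$particles, fx$sub$images, K = 1, seed = 1)
  model <- cryofocus:::new_class_model(
    references = list(rodA, zero), fractions = c(0.5, 0.5),
    noise_spectrum = m1$noise_spectrum, mask = fx$focus, pad = 2L,
    max_shell = m1$max_shell)
  es <- e_step(model, fx$sub$particles, fx$sub$images)
  acc <- score_classification(es$resp, fx$sim$particles$class_label)
  expect_equal(acc, 1)
})

test_that("initialization partitions reproducibly by seeded RNG", {
  fx <- classify_fixture(np = 50, noise_sd = 0.5)
  m1 <- init_classes(fx$sub$particles, fx$sub$images, K = 2, seed = 7)
  m2 <- init_classes(fx$sub$particles, fx$sub$images, K = 2, seed = 7)
  expect_identical(m1$references[[1]]$data, m2$references[[1]]$data)
  expect_identical(m1$fractions, m2$fractions)
  # group sizes replay from an independent draw of the documented recipe
  set.seed(7)
  groups <- sample(rep_len(1:2, 100))
  expect_equal(m1$fractions, tabulate(groups, 2) / 100)
})

test_that("hard responsibilities reproduce per-group reconstructions", {
  fx <- classify_fixture(np = 15, noise_sd = 0.4)
  np <- nrow(fx$sub$particles)
  model <- init_classes(fx$sub$particles, fx$sub$images, K = 2, seed = 3,
                        mask = fx$focus)
  groups <- (seq_len(np) %% 2) + 1L
  resp <- cbind(as.numeric(groups == 1), as.numeric(groups == 2))
  m2 <- m_step(model, fx$sub$particles, fx$sub$images, resp)
  for (k in 1:2) {
    direct <- reconstruct(fx$sub$particles, fx$sub$images,
                          weights = resp[, k], grid_correct = FALSE)
    direct <- apply_mask(direct, fx$focus)
    expect_lt(max(abs(m2$references[[k]]$data - direct$data)), 1e-9)
  }
  expect_equal(sum(m2$fractions), 1, tolerance = 1e-9)
  expect_equal(m2$fractions, c(mean(groups == 1), mean(groups == 2)))
})

test_that("noise spectrum update recovers a known flat variance", {
  # pure-noise images around a zero reference: sigma^2 estimate per shell
  # must match the generating Fourier-domain variance within 5 %
  n <- 16; np <- 500
  parts <- test_particles(np, n, 2.8, seed = 8,
                          defocus_range = c(7000, 32000))
  spectrum <- rep(n^2 * 1.7^2, n / 2 + 1)
  sh <- cryofocus:::shell_index_2d(n)
  set.seed(9)
  imgs <- array(0, dim = c(n, n, np))
  for (i in seq_len(np))
    imgs[, , i] <- cryofocus:::draw_noise_image(n, spectrum, sh)
  stack <- image_stack(imgs, 2.8)
  zero <- volume_grid(array(0, dim = c(n, n, n)), 2.8)
  model <- cryofocus:::new_class_model(
    references = list(zero), fractions = 1,
    noise_spectrum = rep(1, n / 2 - 1), mask = NULL, pad = 2L,
    max_shell = n / 2 - 2L)
  es <- e_step(model, parts, stack)
  m2 <- m_step(model, parts, stack, es$resp, shell_res = es$shell_res)
  target <- spectrum[seq_len(n / 2 - 1)]
  # shell 0 holds a single Fourier component, so its estimate fluctuates
  # with relative sd sqrt(2/np) ~ 6 %; assert it loosely and the populated
  # shells at 5 %
  expect_true(all(abs(m2$noise_spectrum[-1] / target[-1] - 1) < 0.05))
  expect_lt(abs(m2$noise_spectrum[1] / target[1] - 1), 0.25)
})

test_that("EM objective is non-decreasing and the run is deterministic", {
  fx <- classify_fixture(np = 200, noise_sd = 1.0)
  run <- classify(fx$sub$particles, fx$sub$images, K = 2, mask = fx$focus,
                  n_iter = 12, seed = 11)
  ev <- run$history$mean_log_evidence
  expect_true(all(diff(ev) >= -1e-6 * abs(ev[-1])))
  run2 <- classify(fx$sub$particles, fx$sub$images, K = 2, mask = fx$focus,
                   n_iter = 12, seed = 11)
  expect_identical(run$resp, run2$resp)
  expect_identical(run$history, run2$history)
})

test_that("noise-free two-phantom classification is perfect", {
  fx <- classify_fixture(np = 50, noise_sd = 0)
  run <- classify(fx$sub$particles, fx$sub$images, K = 2, mask = fx$focus,
                  n_iter = 8, seed = 2)
  acc <- score_classification(run$resp, fx$sim$particles$class_label)
  expect_equal(acc, 1)
  expect_equal(sort(run$model$fractions), c(0.5, 0.5), tolerance = 0.02)
})

test_that("permuting the initial classes permutes the result", {
  fx <- classify_fixture(np = 100, noise_sd = 0.8)
  pc <- cryofocus:::classification_precomp(fx$sub$particles, fx$sub$images,
                                           14L)
  model <- init_classes(fx$sub$particles, fx$sub$images, K = 2,
                        mask = fx$focus, seed = 3, precomp = pc)
  swapped <- cryofocus:::new_class_model(
    rev(model$references), rev(model$fractions), model$noise_spectrum,
    model$mask, model$pad, model$max_shell)
  run_em <- function(m) {
    for (t in 1:6) {
      es <- e_step(m, fx$sub$particles, precomp = pc)
      m <- m_step(m, fx$sub$particles, fx$sub$images, es$resp,
                  shell_res = es$shell_res, precomp = pc)
    }
    e_step(m, fx$sub$particles, precomp = pc)
  }
  a <- run_em(model)
  b <- run_em(swapped)
  expect_equal(a$resp, b$resp[, 2:1], tolerance = 1e-6)
  truth <- fx$sim$particles$class_label
  expect_equal(score_classification(a$resp, truth),
               score_classification(b$resp, truth))
})

test_that("hard selection partitions all particles and filters by fraction", {
  fx <- classify_fixture(np = 30, noise_sd = 0.5)
  run <- classify(fx$sub$particles, fx$sub$images, K = 2, mask = fx$focus,
                  n_iter = 6, seed = 1)
  sel <- select_classes(run$model, run$resp)
  all_members <- sort(unname(unlist(sel$members)))
  expect_identical(all_members, seq_len(nrow(fx$sub$particles)))
  expect_equal(sum(sel$fractions), 1)
  sel2 <- select_classes(run$model, run$resp, min_fraction = 0.9)
  expect_lte(length(sel2$members), 1)
})
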