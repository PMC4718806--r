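test_that("projection is linear and maps zero to zero", {
  n <- 16
  zero <- volume_grid(array(0, dim = c(n, n, n)), 2)
  R <- euler_to_matrix(40, 70, -10)
  expect_equal(max(abs(project(zero, R))), 0)
  a <- test_phantom(n, 2, seed = 1)$vol
  b <- test_phantom(n, 2, seed = 2)$vol
  ab <- volume_grid(2.5 * a$data - 0.7 * b$data, 2)
  expect_lt(rel_rms(project(ab, R),
                    2.5 * project(a, R) - 0.7 * project(b, R)), 1e-9)
})

test_that("identity projection equals the z-axis voxel sum", {
  # a compact, band-limited blob: on-lattice sampling of the Fourier
  # slice is exact, so the projection is the voxel sum
  at <- data.frame(x = c(0.8, -1.2), y = c(-0.9, 0.6), z = c(0.5, -0.4),
                   radius = 6, weight = c(1, 0.7))
  ph <- list(vol = pseudo_atoms_to_map(at, 16, 2))
  p <- project(ph$vol)
  expect_lt(rel_rms(p, zsum(ph$vol$data)), 1e-3)
  # total mass is preserved at identity rotation
  expect_equal(sum(p), sum(ph$vol$data), tolerance = 1e-6)
})

test_that("rotated projections match real-space rotate-then-sum oracles", {
  n <- 32; px <- 2
  ph <- test_phantom(n, px, n_atoms = 5, seed = 6)
  for (ang in list(c(20, 40, -30), c(70, 55, 110), c(-120, 130, 35))) {
    R <- euler_to_matrix(ang[1], ang[2], ang[3])
    p <- project(ph$vol, R)
    # exact rotation: re-render the pseudo-atoms at rotated centers
    oracle <- zsum(rotate_phantom(ph$atoms, R, n, px)$data)
    expect_lt(rel_rms(p, oracle), 0.02)
    # crude trilinear volume rotation agrees less tightly
    oracle2 <- zsum(rotate_trilinear(ph$vol$data, R))
    expect_lt(rel_rms(p, oracle2), 0.06)
  }
  # a small box inflates the interpolation error but stays within a few %
  ph16 <- test_phantom(16, px, n_atoms = 4, seed = 6)
  R <- euler_to_matrix(20, 40, -30)
  expect_lt(rel_rms(project(ph16$vol, R),
                    zsum(rotate_phantom(ph16$atoms, R, 16, px)$data)), 0.06)
})

test_that("Fourier transform of the projection is the central slice", {
  n <- 32; px <- 2
  ph <- test_phantom(n, px, seed = 8)
  R <- euler_to_matrix(15, 65, 40)
  p <- project(ph$vol, R)
  # brute-force DFT of the volume at the rotated plane k = R^T (h1,h2,0)
  coord <- seq_len(n) - 1 - n / 2
  g <- as.matrix(expand.grid(coord, coord, coord))
  h <- as.matrix(expand.grid(coord, coord))
  K <- h %*% R[1:2, ]
  slice <- (exp(-2i * pi * (K %*% t(g)) / n) %*% as.vector(ph$vol$data))
  pf <- cryofocus:::cfft2(p)
  ball <- cryofocus:::radius_grid_2d(n) <= n / 2 - 1
  expect_lt(sqrt(mean(Mod(pf[ball] - slice[ball])^2)) /
            sqrt(mean(Mod(slice[ball])^2)), 0.02)
})

test_that("offsets shift the projection toward the particle frame", {
  n <- 16; px <- 2
  ph <- test_phantom(n, px, seed = 3)
  p0 <- project(ph$vol)
  p1 <- project(ph$vol, origin_x = 3, origin_y = -2)
  # integer shifts are cyclic row/column rolls of the unshifted image
  roll <- function(m, dx, dy) {
    ix <- ((seq_len(n) - 1 - dx) %% n) + 1
    iy <- ((seq_len(n) - 1 - dy) %% n) + 1
    m[ix, iy]
  }
  expect_lt(rel_rms(p1, roll(p0, 3, -2)), 1e-9)
})

test_that("backprojection is the exact adjoint of projection", {
  n <- 16
  ph <- test_phantom(n, 2, seed = 10)
  set.seed(23)
  for (i in 1:5) {
    R <- euler_to_matrix(runif(1, -180, 180), runif(1, 0, 180),
                         runif(1, -180, 180))
    ox <- runif(1, -2, 2); oy <- runif(1, -2, 2)
    I <- matrix(rnorm(n * n), n, n)
    lhs <- sum(project(ph$vol, R, ox, oy) * I)
    bp <- backproject_volume(I, R, ox, oy, pixel_size = 2)
    rhs <- sum(ph$vol$data * bp$data)
    expect_equal(lhs, rhs, tolerance = 1e-6 * abs(lhs))
  }
})

test_that("accumulation is linear and ignores zero weights", {
  n <- 16
  set.seed(24)
  I <- matrix(rnorm(n * n), n, n)
  R <- euler_to_matrix(10, 30, 50)
  ctf <- ctf_params(defocus_u = 12000)
  acc0 <- new_accumulator(n, 2)
  acc1 <- backproject_accumulate(acc0, I, R, ctf = ctf, weight = 0)
  expect_equal(acc1$num, acc0$num)
  expect_equal(acc1$den, acc0$den)
  # twice with weight 1 equals once with weight 2
  a2 <- backproject_accumulate(backproject_accumulate(
    new_accumulator(n, 2), I, R, ctf = ctf), I, R, ctf = ctf)
  b2 <- backproject_accumulate(new_accumulator(n, 2), I, R, ctf = ctf,
                               weight = 2)
  expect_lt(max(abs(a2$num - b2$num)), 1e-9 * max(1, max(abs(b2$num))))
  expect_lt(max(abs(a2$den - b2$den)), 1e-9 * max(b2$den))
  expect_error(backproject_accumulate(acc0, I, R, weight = NaN), "finite")
})

test_that("noise-free reconstruction recovers the phantom", {
  n <- 32; px <- 2
  ph <- test_phantom(n, px, n_atoms = 5, seed = 3)
  parts <- test_particles(1000, n, px, seed = 11)
  imgs <- cryofocus:::project_particles(ph$vol, parts, apply_ctf = FALSE)
  rec <- reconstruct(parts, imgs, apply_ctf = FALSE)
  expect_gt(cor(as.vector(rec$data), as.vector(ph$vol$data)), 0.99)
  fsc <- compute_fsc(rec, ph$vol)
  usable <- fsc$shell > 0 & fsc$shell <= 0.8 * n / 2
  expect_true(all(fsc$fsc[usable] > 0.9))
})

test_that("CTF^2-weighted accumulation fills CTF zeros across defoci", {
  n <- 32; px <- 2
  ph <- test_phantom(n, px, n_atoms = 5, seed = 3)
  parts <- test_particles(2000, n, px, seed = 12,
                          defocus_range = c(7000, 32000))
  imgs <- cryofocus:::project_particles(ph$vol, parts, apply_ctf = TRUE)
  rec <- reconstruct(parts, imgs, apply_ctf = TRUE)
  expect_gt(cor(as.vector(rec$data), as.vector(ph$vol$data)), 0.95)
})

test_that("strong regularization drives the reconstruction to zero", {
  n <- 16; px <- 2
  ph <- test_phantom(n, px, seed = 4)
  parts <- test_particles(1, n, px, seed = 13)
  imgs <- cryofocus:::project_particles(ph$vol, parts, apply_ctf = FALSE)
  rec <- reconstruct(parts, imgs, apply_ctf = FALSE, eps = 1e12)
  expect_lt(max(abs(rec$data)), 1e-6 * max(abs(ph$vol$data)))
  expect_error(reconstruct(parts, imgs, weights = 0), "zero")
})
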