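kB <- 0.008314462618

test_that("WHAM on one unbiased window equals direct Boltzmann inversion", {
  z <- seq(-1, 1, 0.01)
  prof <- free_energy_profile(z, 1.5 * z^2)
  win <- gen_umbrella_samples(prof, centers = 0, k_spring = 0,
                              n_per_window = 20000, temperature = 298,
                              seed = 12)
  g <- wham(win, bin_width = 0.1, reference = "both")
  h <- hist(win$samples[[1]],
            breaks = seq(floor(min(win$samples[[1]]) / 0.1) * 0.1,
                         ceiling(max(win$samples[[1]]) / 0.1) * 0.1,
                         by = 0.1), plot = FALSE)
  kt <- kB * 298 / 4.184
  g_direct <- -kt * log(h$counts)
  ok <- is.finite(g$g) & is.finite(g_direct)
  # compare mean-centered shapes (each estimate fixes its own gauge)
  expect_equal(g$g[ok] - mean(g$g[ok]),
               g_direct[ok] - mean(g_direct[ok]), tolerance = 1e-6)
})

test_that("a flat profile is recovered flat within sampling noise", {
  prof <- free_energy_profile(seq(-0.5, 2.5, 0.01), rep(0, 301))
  win <- gen_umbrella_samples(prof, centers = seq(0, 2, 0.1),
                              k_spring = 1000, n_per_window = 3000,
                              seed = 5)
  g <- wham(win, bin_width = 0.05)
  # assert flatness over the window-covered region (tail bins beyond the
  # outermost centers hold only a handful of samples)
  covered <- g$z >= 0 & g$z <= 2
  expect_lt(max(abs(g$g[covered]), na.rm = TRUE), 0.15)
})

test_that("recovered profiles are invariant to a constant offset in the truth", {
  z <- seq(-0.5, 2.5, 0.01)
  mk <- function(off) {
    prof <- free_energy_profile(z, 2 * exp(-(z - 1)^2 / 0.18) + off)
    win <- gen_umbrella_samples(prof, centers = seq(0, 2, 0.1),
                                k_spring = 1000, n_per_window = 2000,
                                seed = 9)
    wham(win, bin_width = 0.05)$g
  }
  expect_equal(mk(0), mk(3), tolerance = 1e-9)
})

test_that("generate-from-profile recovery hits the barrier within 0.3 kcal/mol", {
  prof <- gaussian_barrier_profile(3.0, width = 0.5, z_min = -0.5,
                                   z_max = 2.5)
  win <- gen_umbrella_samples(prof, centers = seq(0, 2, 0.1),
                              k_spring = 1000, n_per_window = 5000,
                              seed = 23)
  g <- symmetrize_profile(wham(win, bin_width = 0.05))
  expect_equal(barrier_height(g)$height, 3.0, tolerance = 0.3 / 3.0)
})

test_that("barrier estimates are monotone in the generating amplitude", {
  rec <- vapply(c(1, 3, 5), function(B) {
    prof <- gaussian_barrier_profile(B, width = 0.5, z_min = -0.5,
                                     z_max = 2.5)
    win <- gen_umbrella_samples(prof, centers = seq(0, 2, 0.1),
                                k_spring = 1000, n_per_window = 1500,
                                seed = 31)
    barrier_height(symmetrize_profile(wham(win, bin_width = 0.05)))$height
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("doubling the samples moves the barrier less than its uncertainty", {
  prof <- gaussian_barrier_profile(3.0, width = 0.5, z_min = -0.5,
                                   z_max = 2.5)
  b_of <- function(n, seed) {
    win <- gen_umbrella_samples(prof, centers = seq(0, 2, 0.1),
                                k_spring = 1000, n_per_window = n,
                                seed = seed)
    g <- wham(win, bin_width = 0.05, n_boot = 25)
    gs <- symmetrize_profile(g)
    i <- which.min(abs(g$z - barrier_height(gs)$z_at_max))
    c(barrier_height(gs)$height, g$uncertainty[i])
  }
  b1 <- b_of(1500, 41)
  b2 <- b_of(3000, 42)
  expect_lt(abs(b1[1] - b2[1]), 3 * sqrt(b1[2]^2 + b2[2]^2))
})

test_that("symmetrization mirrors half profiles and is idempotent", {
  z <- seq(0, 2, 0.05)
  prof <- free_energy_profile(z, 4 * exp(-z^2 / 0.5))
  sym <- symmetrize_profile(prof, center = 0)
  expect_equal(min(sym$z), -2, tolerance = 1e-9)
  expect_equal(sym$g, rev(sym$g), tolerance = 1e-9)
  sym2 <- symmetrize_profile(sym, center = 0)
  expect_equal(sym2$g, sym$g, tolerance = 1e-9)
  # symmetric truth + asymmetric noise: symmetrization reduces the error
  set.seed(6)
  zs <- seq(-2, 2, 0.05)
  truth <- 4 * exp(-zs^2 / 0.5)
  noisy <- free_energy_profile(zs, truth + rnorm(length(zs), 0, 0.3))
  symn <- symmetrize_profile(noisy, center = 0)
  rms <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rms(symn$g, 4 * exp(-symn$z^2 / 0.5)), rms(noisy$g, truth))
})

test_that("barrier extraction reports height and location", {
  z <- seq(-1, 1, 0.01)
  b <- barrier_height(free_energy_profile(z, rep(0, length(z))))
  expect_equal(b$height, 0)
  b2 <- barrier_height(free_energy_profile(z, 2 - 4 * (z - 0.25)^2))
  expect_equal(b2$height, 2, tolerance = 1e-9)
  expect_equal(b2$z_at_max, 0.25, tolerance = 1e-9)
  expect_error(barrier_height(free_energy_profile(z, rep(NA_real_,
                                                         length(z)))),
               "reference")
})

test_that("non-convergence raises an error carrying the constants trace", {
  prof <- gaussian_barrier_profile(3.0, width = 0.5, z_min = -0.5,
                                   z_max = 2.5)
  win <- gen_umbrella_samples(prof, centers = seq(0, 2, 0.1),
                              k_spring = 1000, n_per_window = 500,
                              seed = 3)
  err <- tryCatch(wham(win, max_iter = 5), error = identity)
  expect_s3_class(err, "wham_convergence_error")
})

test_that("poorly overlapping windows trigger the histogram-mass warning", {
  prof <- free_energy_profile(seq(-2, 4, 0.01), rep(0, 601))
  expect_warning(
    gen_umbrella_samples(prof, centers = c(0, 2), k_spring = 5000,
                         n_per_window = 500, seed = 8),
    "histogram mass")
})

test_that("umbrella windows round-trip through per-window files", {
  prof <- free_energy_profile(seq(-1, 1, 0.01), rep(0, 201))
  win <- gen_umbrella_samples(prof, centers = c(-0.05, 0.05),
                              k_spring = 1000, n_per_window = 50,
                              seed = 14)
  d <- file.path(tempdir(), "umb")
  write_umbrella_dir(win, d)
  win2 <- read_umbrella_dir(d)
  expect_equal(win2$centers, win$centers)
  expect_equal(win2$samples[[1]], win$samples[[1]], tolerance = 1e-9)
  expect_equal(win2$k_spring, win$k_spring)
})
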