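test_that("area per lipid is box area over leaflet count", {
  tr <- make_traj("P", matrix(c(1, 1, 2), 1), box = c(6.3, 6.4, 8))
  apl <- area_per_lipid(tr, 64)
  expect_equal(apl$mean, 6.3 * 6.4 / 64)
  # constant box across frames -> zero-variance series
  tr2 <- make_traj("P", array(1, c(1, 3, 5)), box = c(6.3, 6.4, 8))
  expect_equal(area_per_lipid(tr2, 64)$sd, 0)
})

test_that("MSD estimator equals the brute-force double loop on tiny trajectories", {
  set.seed(21)
  n_p <- 5
  n_f <- 20
  coords <- array(0, c(n_p, 3, n_f))
  for (f in 2:n_f) {
    coords[, 1, f] <- coords[, 1, f - 1] + rnorm(n_p, 0, 0.2)
    coords[, 2, f] <- coords[, 2, f - 1] + rnorm(n_p, 0, 0.2)
  }
  coords[, 1, ] <- coords[, 1, ] + 3  # keep inside the box
  coords[, 2, ] <- coords[, 2, ] + 3
  tr <- make_traj(rep("P", n_p), coords, molecule_id = 1:n_p,
                  leaflet = rep("upper", n_p))
  got <- lateral_msd(tr, "P", remove_com = FALSE)
  want <- brute_msd(matrix(coords[, 1, ], n_p), matrix(coords[, 2, ], n_p))
  expect_equal(got$msd, want, tolerance = 1e-12)
})

test_that("immobile particles have zero diffusion coefficient", {
  coords <- array(2, c(4, 3, 120))
  tr <- make_traj(rep("P", 4), coords, molecule_id = 1:4,
                  leaflet = rep("upper", 4))
  d <- lateral_diffusion(tr, remove_com = FALSE)
  expect_equal(d$d_coeff, 0, tolerance = 1e-15)
})

test_that("Brownian trajectories recover the generating diffusion coefficient", {
  sp <- bilayer_spec(n_lipids_per_leaflet = 64, n_solutes = 0,
                     target_D = 5.45e-8, n_frames = 300,
                     target_scd = 0.14, seed = 31)
  tr <- gen_bilayer_trajectory(sp)
  d <- lateral_diffusion(tr, remove_com = FALSE)
  expect_equal(d$d_coeff, 5.45e-8, tolerance = 0.15)
  # closed-form MSD(lag) = 4 D lag on early lags, away from the noise tail
  msd <- lateral_msd(tr, remove_com = FALSE)
  d_nm2ps <- convert_diffusion(5.45e-8, "cm2_s", "nm2_ps")
  sel <- msd$lag > 0 & msd$lag <= 5000
  expect_equal(msd$msd[sel], 4 * d_nm2ps * msd$lag[sel], tolerance = 0.1)
})

test_that("diffusion unit conversion matches 5.45e-8 cm2/s = 5.45e-6 nm2/ps", {
  expect_equal(convert_diffusion(5.45e-8, "cm2_s", "nm2_ps"), 5.45e-6)
  expect_equal(convert_diffusion(5.45e-6, "nm2_ps", "cm2_s"), 5.45e-8)
})

test_that("unwrapping reconstructs displacements across the periodic boundary", {
  # one particle drifting +0.4 nm/frame in x through the boundary of a 2 nm box
  n_f <- 12
  coords <- array(0, c(1, 3, n_f))
  coords[1, 1, ] <- (0.3 + 0.4 * (seq_len(n_f) - 1)) %% 2
  coords[1, 2, ] <- 1
  tr <- labeled_trajectory(
    particles = data.frame(particle_id = 1, molecule_id = 1, role = "P",
                           leaflet = "upper", mass = 31),
    coords = coords, box = matrix(c(2, 2, 8), 1), time = seq_len(n_f) - 1)
  msd <- lateral_msd(tr, remove_com = FALSE)
  expect_equal(msd$msd[2], 0.4^2, tolerance = 1e-9)
  expect_equal(msd$msd[n_f], (0.4 * (n_f - 1))^2, tolerance = 1e-9)
})

test_that("order parameters reproduce the analytic angle cases", {
  expect_equal(order_parameters(make_cd_traj(90))$s_cd, -0.5,
               tolerance = 1e-9)
  expect_equal(order_parameters(make_cd_traj(acos(sqrt(1 / 3)) * 180 / pi))$s_cd,
               0, tolerance = 1e-9)
  expect_equal(order_parameters(make_cd_traj(0))$s_cd, 1, tolerance = 1e-9)
  th <- acos(sqrt(0.24)) * 180 / pi
  op <- order_parameters(make_cd_traj(th))
  expect_equal(op$s_cd, -0.14, tolerance = 1e-9)
  expect_equal(op$abs_s_cd, 0.14, tolerance = 1e-9)
})

test_that("order parameters stay within their physical bounds for random bonds", {
  set.seed(77)
  for (i in 1:10) {
    tr <- make_cd_traj(runif(1, 0, 180), runif(1, 0, 360))
    s <- order_parameters(tr)$s_cd
    expect_gte(s, -0.5)
    expect_lte(s, 1.0)
  }
})

test_that("missing deuterium partners are reported with molecule ids", {
  tr <- make_traj(c("CD_C_1", "CD_H_1", "CD_C_1"),
                  matrix(c(1, 1, 1, 1, 1, 1.1, 2, 2, 1), 3, byrow = TRUE),
                  molecule_id = c(1, 1, 7),
                  leaflet = c("upper", "upper", "upper"))
  expect_error(order_parameters(tr), "7")
})

test_that("thickness averages phosphate planes and tolerates symmetric noise", {
  coords <- array(0, c(4, 3, 1))
  coords[, 3, 1] <- c(2.02, 2.02, -2.02, -2.02)
  tr <- make_traj(rep("P", 4), coords, molecule_id = 1:4,
                  leaflet = c("upper", "upper", "lower", "lower"))
  expect_equal(membrane_thickness(tr)$mean, 4.04)
  # symmetric z-noise leaves the mean unbiased
  sp0 <- bilayer_spec(n_lipids_per_leaflet = 32, n_solutes = 0,
                      target_thickness = 4.04, z_noise_sd = 0.05,
                      n_frames = 200, target_scd = 0.14, seed = 13)
  th <- membrane_thickness(gen_bilayer_trajectory(sp0))
  expect_equal(th$mean, 4.04, tolerance = 0.01)
  # one empty leaflet is an error
  tr_bad <- make_traj(rep("P", 2), coords[1:2, , , drop = FALSE],
                      molecule_id = 1:2, leaflet = c("upper", "upper"))
  expect_error(membrane_thickness(tr_bad), "leaflet")
})

test_that("density profile conserves mass and symmetrization is idempotent", {
  sp <- bilayer_spec(n_lipids_per_leaflet = 16, n_solutes = 5,
                     n_frames = 20, target_scd = 0.14, seed = 3)
  tr <- gen_bilayer_trajectory(sp)
  dp <- density_profile(tr, bin_width = 0.1)
  # integral * area recovers the group mass (kg m^-3 -> amu bookkeeping)
  for (g in colnames(dp$density)) {
    sel <- if (g == "phosphate") "P" else toupper(g)
    idx <- which(tr$particles$role == switch(g, phosphate = "P",
                                             carbonyl = "CARBONYL",
                                             terminal_ch3 = "TERMINAL_CH3",
                                             solute = "SOLUTE"))
    total_amu <- sum(dp$density[, g]) * dp$bin_width * dp$area /
      1.66053906660
    expect_equal(total_amu, sum(tr$particles$mass[idx]), tolerance = 1e-6)
  }
  dps <- density_profile(tr, bin_width = 0.1, symmetrize = TRUE)
  resym <- (dps$density + dps$density[rev(seq_len(nrow(dps$density))), ]) / 2
  expect_equal(dps$density, resym, tolerance = 1e-12)
})

test_that("solute density overlaps the carbonyl band more than the terminal methyls", {
  sp <- bilayer_spec(n_frames = 40, seed = 17)
  tr <- gen_bilayer_trajectory(sp)
  dp <- density_profile(tr, bin_width = 0.1, symmetrize = TRUE)
  norm1 <- function(v) v / sum(v)
  ov <- function(a, b) sum(pmin(norm1(a), norm1(b)))
  d <- dp$density
  expect_gt(ov(d[, "solute"], d[, "carbonyl"]),
            ov(d[, "solute"], d[, "terminal_ch3"]))
})

test_that("cluster components follow the cutoff geometry", {
  # all pairwise > cutoff -> all monomers
  fr <- list(rbind(c(1, 1, 0), c(3, 3, 0), c(5, 5, 0)))
  expect_equal(cluster_stats(solute_traj(fr))$percent_monomers, 100)
  # one pair at 0.2 nm among 3 -> sizes {2, 1}, 33.3% monomers
  fr2 <- list(rbind(c(1, 1, 0), c(1.2, 1, 0), c(4, 4, 0)))
  cs <- cluster_stats(solute_traj(fr2))
  expect_equal(cs$percent_monomers, 100 / 3, tolerance = 1e-9)
  expect_equal(cs$size_histogram$n_clusters[1:2], c(1L, 1L))
  # periodic image: particles at opposite box edges are neighbors
  fr3 <- list(rbind(c(0.05, 1, 0), c(5.95, 1, 0)))
  expect_equal(cluster_stats(solute_traj(fr3))$percent_monomers, 0)
})

test_that("monomer fraction is nonincreasing in the cutoff", {
  set.seed(55)
  frames <- lapply(1:5, function(i)
    cbind(runif(10, 0, 6), runif(10, 0, 6), runif(10, -1, 1)))
  tr <- solute_traj(frames)
  cuts <- c(0.2, 0.5, 1.0, 2.0, 4.0)
  mono <- vapply(cuts, function(ct)
    cluster_stats(tr, ct)$percent_monomers, numeric(1))
  expect_true(all(diff(mono) <= 1e-9))
})

test_that("observables are invariant under global translation", {
  sp <- bilayer_spec(n_lipids_per_leaflet = 8, n_solutes = 3,
                     n_frames = 15, target_scd = 0.14, seed = 19)
  tr <- gen_bilayer_trajectory(sp)
  tr2 <- tr
  tr2$coords[, 1, ] <- tr2$coords[, 1, ] + 1.3
  tr2$coords[, 3, ] <- tr2$coords[, 3, ] + 0.7
  tr2$coords_unwrapped[, 1, ] <- tr2$coords_unwrapped[, 1, ] + 1.3
  tr2$coords_unwrapped[, 3, ] <- tr2$coords_unwrapped[, 3, ] + 0.7
  expect_equal(membrane_thickness(tr2)$mean, membrane_thickness(tr)$mean,
               tolerance = 1e-9)
  expect_equal(order_parameters(tr2)$s_cd, order_parameters(tr)$s_cd,
               tolerance = 1e-9)
  expect_equal(lateral_msd(tr2)$msd, lateral_msd(tr)$msd, tolerance = 1e-9)
  d1 <- density_profile(tr, bin_width = 0.2)
  d2 <- density_profile(tr2, bin_width = 0.2)
  expect_equal(d1$density, d2$density, tolerance = 1e-9)
})
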