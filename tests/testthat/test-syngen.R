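test_that("trajectory generation is deterministic in spec + seed", {
  sp <- bilayer_spec(n_lipids_per_leaflet = 8, n_solutes = 3,
                     n_frames = 10, target_scd = 0.14, seed = 42)
  t1 <- gen_bilayer_trajectory(sp)
  t2 <- gen_bilayer_trajectory(sp)
  expect_identical(t1, t2)
  t3 <- gen_bilayer_trajectory(bilayer_spec(n_lipids_per_leaflet = 8,
                                            n_solutes = 3, n_frames = 10,
                                            target_scd = 0.14, seed = 43))
  expect_false(identical(t1$coords, t3$coords))
})

test_that("zero diffusion target freezes all lateral motion", {
  sp <- bilayer_spec(n_lipids_per_leaflet = 8, n_solutes = 0,
                     target_D = 0, n_frames = 12, target_scd = 0.14,
                     seed = 1)
  tr <- gen_bilayer_trajectory(sp)
  p <- which(tr$particles$role == "P")
  expect_equal(tr$coords_unwrapped[p, 1, 12], tr$coords_unwrapped[p, 1, 1])
  expect_equal(tr$coords_unwrapped[p, 2, 12], tr$coords_unwrapped[p, 2, 1])
})

test_that("noiseless phosphate planes reproduce the target thickness exactly", {
  sp <- bilayer_spec(n_lipids_per_leaflet = 8, n_solutes = 0,
                     target_thickness = 4.04, z_noise_sd = 0,
                     n_frames = 5, target_scd = 0.14, seed = 1)
  th <- membrane_thickness(gen_bilayer_trajectory(sp))
  expect_equal(th$mean, 4.04, tolerance = 1e-12)
  expect_equal(th$sd, 0)
})

test_that("box area equals lipids per leaflet times target area per lipid", {
  sp <- bilayer_spec(n_lipids_per_leaflet = 16, n_solutes = 0,
                     target_apl = 0.63, n_frames = 3,
                     target_scd = 0.14, seed = 1)
  tr <- gen_bilayer_trajectory(sp)
  expect_equal(tr$box[1, 1] * tr$box[1, 2], 16 * 0.63, tolerance = 1e-12)
})

test_that("impossible solute packing raises an explicit error", {
  sp <- bilayer_spec(n_lipids_per_leaflet = 2, n_solutes = 40,
                     n_frames = 1, target_scd = 0.14, seed = 1)
  expect_error(gen_bilayer_trajectory(sp), "unsatisfiable packing")
})

test_that("partition generator honors the half-saturation and origin identities", {
  d <- gen_partition_data(0.30, 1.2, c(0, 1.2), noise_sd = 0, seed = 1)
  expect_equal(d$r_mem[d$x == 0], 0)
  expect_equal(d$r_mem[d$x == 1.2], 0.15)
  expect_error(gen_partition_data(0.3, 1.2, 1, noise_sd = -0.1),
               "noise_sd")
})

test_that("partition generator is deterministic and truncates at zero", {
  d1 <- gen_partition_data(0.30, 1.2, c(0.25, 1, 4), 0.01, 3, seed = 9)
  d2 <- gen_partition_data(0.30, 1.2, c(0.25, 1, 4), 0.01, 3, seed = 9)
  expect_identical(d1, d2)
  dn <- gen_partition_data(0.05, 1.2, rep(0.01, 50), 0.2, 1, seed = 3)
  expect_true(all(dn$r_mem >= 0))
  expect_gt(attr(dn, "n_clipped"), 0)
})

test_that("leakage trace starts at zero and approaches its plateau", {
  par <- leakage_sim_params(plateau_percent = 70, rate_constant = 0.02,
                            noise_sd = 0)
  tg <- seq(0, 2000, by = 10)
  tr <- gen_leakage_trace(par, tg)
  pct <- percent_leakage(tr$f_t, tr$f_i, tr$f_d)
  expect_equal(pct[1], 0)
  expect_equal(pct[length(pct)], 70, tolerance = 1e-6)
})

test_that("composition modifiers order the leakage traces PG > baseline > PE", {
  tg <- seq(0, 600, by = 5)
  mk <- function(mod) {
    par <- leakage_sim_params(plateau_percent = 80, rate_constant = 0.01,
                              composition_modifier = mod, noise_sd = 0)
    tr <- gen_leakage_trace(par, tg)
    percent_leakage(tr$f_t, tr$f_i, tr$f_d)
  }
  pg <- mk(2); base <- mk(1); pe <- mk(0.5)
  mid <- 2:length(tg)
  expect_true(all(pg[mid] > base[mid]))
  expect_true(all(base[mid] > pe[mid]))
})

test_that("umbrella samples from a flat profile have the analytic Gaussian moments", {
  prof <- free_energy_profile(seq(-1, 1, 0.01), rep(0, 201))
  kt <- 0.008314462618 * 298
  w <- gen_umbrella_samples(prof, centers = 0.2, k_spring = 1000,
                            n_per_window = 40000, temperature = 298,
                            seed = 3)
  s <- w$samples[[1]]
  expect_equal(mean(s), 0.2, tolerance = 0.002)
  expect_equal(var(s), kt / 1000, tolerance = 0.03)
})

test_that("a very stiff spring collapses samples onto the window center", {
  prof <- free_energy_profile(seq(-1, 1, 0.001), rep(0, 2001))
  w <- gen_umbrella_samples(prof, centers = 0.3, k_spring = 1e7,
                            n_per_window = 500, seed = 2)
  expect_lt(max(abs(w$samples[[1]] - 0.3)), 0.01)
})

test_that("umbrella sampling is deterministic and checks profile coverage", {
  prof <- free_energy_profile(seq(-1, 1, 0.01), rep(0, 201))
  w1 <- gen_umbrella_samples(prof, centers = 0, n_per_window = 100, seed = 5)
  w2 <- gen_umbrella_samples(prof, centers = 0, n_per_window = 100, seed = 5)
  expect_identical(w1$samples, w2$samples)
  expect_error(gen_umbrella_samples(prof, centers = 1.0, k_spring = 1000,
                                    n_per_window = 10, seed = 1),
               "3 sigma")
})

test_that("scattering peaks sit at n/d and the calibration curve at 1/48.8", {
  cv <- gen_scattering_curve(59.6, 3, noise_sd = 0, background = 0, seed = 1)
  pk <- find_reflections(cv)
  expect_equal(pk, c(1, 2, 3) / 59.6, tolerance = 1e-3)
  ref <- gen_scattering_curve(48.8, 1, noise_sd = 0, background = 0, seed = 1)
  expect_equal(find_reflections(ref), 1 / 48.8, tolerance = 1e-3)
})

test_that("reflections outside the instrument s range warn", {
  expect_warning(gen_scattering_curve(59.6, n_orders = 5, seed = 1),
                 "outside the s range")
})
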