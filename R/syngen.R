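# Synthetic-data generators with known ground truth.
#
# Each generator emulates one input of the analysis pipeline (bilayer
# trajectories, partition points, dye-leakage traces, umbrella windows,
# lamellar scattering curves) so every downstream estimator can be
# validated by parameter recovery. The generators are deliberately
# simple statistical emulators, not molecular dynamics.

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic bilayer trajectory
#'
#' Defaults emulate the fluid POPC system of the study design: 64
#' lipids per leaflet (128 total) with 14 solute molecules at 298 K,
#' targeting an area per lipid of 0.63 nm^2, a phosphate-phosphate
#' thickness of 4.04 nm, a lateral diffusion coefficient of
#' 5.45e-8 cm^2/s, per-carbon |S_CD| of 0.14 and 66.6% solute monomers.
#'
#' @param n_lipids_per_leaflet lipids per leaflet (> 0).
#' @param n_solutes solute molecules (0 allowed).
#' @param target_apl area per lipid, nm^2.
#' @param target_thickness phosphate-phosphate distance, nm.
#' @param target_D lateral diffusion coefficient, cm^2/s.
#' @param target_scd per-carbon |S_CD| magnitudes (each in [0, 0.5]).
#' @param monomer_fraction expected percentage of solute monomers.
#' @param n_frames frames to generate.
#' @param dt frame spacing, ps.
#' @param temperature K (298 for POPC-like, 312 for DMPC-like systems).
#' @param z_noise_sd Gaussian noise on phosphate z-planes, nm.
#' @param seed RNG seed.
#' @return object of class `bilayer_spec`.
#' @export
bilayer_spec <- function(n_lipids_per_leaflet = 64, n_solutes = 14,
                         target_apl = 0.63, target_thickness = 4.04,
                         target_D = 5.45e-8, target_scd = rep(0.14, 4),
                         monomer_fraction = 66.6, n_frames = 300,
                         dt = 100, temperature = 298, z_noise_sd = 0.05,
                         seed = 1L) {
  stopifnot(n_lipids_per_leaflet > 0, n_solutes >= 0, target_apl > 0,
            target_thickness > 0, target_D >= 0, dt > 0, n_frames > 0,
            monomer_fraction >= 0, monomer_fraction <= 100,
            z_noise_sd >= 0, all(target_scd >= 0), all(target_scd <= 0.5))
  structure(as.list(environment()), class = "bilayer_spec")
}

#' Generate a synthetic bilayer trajectory
#'
#' Builds a [labeled_trajectory()] whose observables match the targets
#' in `spec` by construction:
#' * lateral lipid motion is an independent 2-D Brownian walk with
#'   per-step displacement variance `4 * D * dt` (per-coordinate
#'   variance `2 * D * dt`), periodic-wrapped with the unwrapped path
#'   retained for MSD estimation;
#' * leaflet phosphate planes sit at +/- `target_thickness / 2` with
#'   Gaussian z-noise `z_noise_sd`;
#' * every C-D bond of carbon k points at the polar angle solving
#'   `(3 cos^2 theta - 1) / 2 = -target_scd[k]`, azimuth uniform;
#' * solutes are re-assigned each frame to clusters of size 1-3 so the
#'   expected monomer percentage equals `monomer_fraction` exactly;
#'   clustered molecules are placed < 0.30 nm apart and monomers
#'   > 0.60 nm from every other solute;
#' * the lateral box area is `n_lipids_per_leaflet * target_apl`.
#'
#' @param spec a [bilayer_spec()].
#' @return a `labeled_trajectory`.
#' @export
gen_bilayer_trajectory <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  with_seed(spec$seed, gen_bilayer_trajectory_impl(spec))
}

gen_bilayer_trajectory_impl <- function(spec) {
  n_leaf <- spec$n_lipids_per_leaflet
  n_lip <- 2L * n_leaf
  n_cd <- length(spec$target_scd)
  n_f <- spec$n_frames
  lx <- sqrt(n_leaf * spec$target_apl)
  box <- c(lx, lx, spec$target_thickness + 4)
  half_t <- spec$target_thickness / 2
  z_carb <- half_t - 0.55          # carbonyl plane offset from center
  d_nm2ps <- convert_diffusion(spec$target_D, "cm2_s", "nm2_ps")
  step_sd <- sqrt(2 * d_nm2ps * spec$dt)

  # particle table: per lipid P, CARBONYL, n_cd CD pairs, TERMINAL_CH3
  per_lip <- 2L + 2L * n_cd + 1L
  roles_lip <- c("P", "CARBONYL",
                 as.vector(rbind(paste0("CD_C_", seq_len(n_cd)),
                                 paste0("CD_H_", seq_len(n_cd)))),
                 "TERMINAL_CH3")
  leaflet_lip <- rep(c("upper", "lower"), each = n_leaf)
  particles <- data.frame(
    particle_id = seq_len(n_lip * per_lip + spec$n_solutes),
    molecule_id = c(rep(seq_len(n_lip), each = per_lip),
                    if (spec$n_solutes > 0) n_lip + seq_len(spec$n_solutes)),
    role = c(rep(roles_lip, n_lip),
             rep("SOLUTE", spec$n_solutes)),
    leaflet = c(rep(leaflet_lip, each = per_lip),
                rep("none", spec$n_solutes)),
    stringsAsFactors = FALSE
  )
  mass_table <- default_role_masses()
  particles$mass <- unname(mass_table[sub("^(CD_[CH])_.*$", "\\1",
                                          particles$role)])

  n_p <- nrow(particles)
  unwrapped <- array(0, c(n_p, 3, n_f))

  # lipid lateral Brownian walks (one walk per lipid, shared by its atoms)
  x0 <- matrix(stats::runif(n_lip * 2, 0, lx), n_lip, 2)
  if (n_f > 1L) {
    steps_x <- matrix(stats::rnorm(n_lip * (n_f - 1), 0, step_sd), n_lip)
    steps_y <- matrix(stats::rnorm(n_lip * (n_f - 1), 0, step_sd), n_lip)
    walk_x <- cbind(x0[, 1], x0[, 1] + row_cumsum(steps_x))
    walk_y <- cbind(x0[, 2], x0[, 2] + row_cumsum(steps_y))
  } else {
    walk_x <- x0[, 1, drop = FALSE]
    walk_y <- x0[, 2, drop = FALSE]
  }

  lip_sign <- rep(c(1, -1), each = n_leaf)
  lip_rows <- matrix(seq_len(n_lip * per_lip), nrow = per_lip)  # [atom, lipid]
  cos_th <- sqrt((1 - 2 * spec$target_scd) / 3)
  sin_th <- sqrt(1 - cos_th^2)
  bond_len <- 0.109  # nm, C-H/C-D bond

  frac <- seq_len(n_cd) / (n_cd + 1)
  for (f in seq_len(n_f)) {
    bx <- walk_x[, f]
    by <- walk_y[, f]
    unwrapped[as.vector(lip_rows), 1, f] <- rep(bx, each = per_lip)
    unwrapped[as.vector(lip_rows), 2, f] <- rep(by, each = per_lip)
    # z placements: phosphate plane, carbonyl plane, terminal methyl
    unwrapped[lip_rows[1, ], 3, f] <-
      lip_sign * (half_t + stats::rnorm(n_lip, 0, spec$z_noise_sd))
    unwrapped[lip_rows[2, ], 3, f] <-
      lip_sign * (z_carb + stats::rnorm(n_lip, 0, 0.05))
    unwrapped[lip_rows[per_lip, ], 3, f] <-
      lip_sign * 0.12 + stats::rnorm(n_lip, 0, 0.08)
    # acyl CD carbons spread between carbonyl and terminal methyl
    for (k in seq_len(n_cd)) {
      rc <- lip_rows[1L + 2L * k, ]   # CD_C_k of every lipid
      rh <- lip_rows[2L + 2L * k, ]   # CD_H_k
      phi <- stats::runif(n_lip, 0, 2 * pi)
      zk <- lip_sign * (z_carb * (1 - frac[k]) + 0.12 * frac[k])
      unwrapped[rc, 3, f] <- zk
      unwrapped[rh, 1, f] <- bx + bond_len * sin_th[k] * cos(phi)
      unwrapped[rh, 2, f] <- by + bond_len * sin_th[k] * sin(phi)
      unwrapped[rh, 3, f] <- zk + bond_len * cos_th[k]
    }
    if (spec$n_solutes > 0) {
      sol <- place_solutes(spec$n_solutes, spec$monomer_fraction, box,
                           z_mean = 0.7 * z_carb, z_sd = 0.25)
      srows <- n_lip * per_lip + seq_len(spec$n_solutes)
      unwrapped[srows, , f] <- sol
    }
  }

  wrapped <- unwrapped
  wrapped[, 1, ] <- wrapped[, 1, ] %% box[1]
  wrapped[, 2, ] <- wrapped[, 2, ] %% box[2]

  labeled_trajectory(particles, wrapped,
                     box = matrix(box, 1), time = (seq_len(n_f) - 1) * spec$dt,
                     coords_unwrapped = unwrapped)
}

row_cumsum <- function(m) {
  if (ncol(m) == 1L) m else t(apply(m, 1, cumsum))
}

# one frame of solute positions honoring the cluster-size scheme:
# m ~ Binomial(n, p) monomers (adjusted off m = n-1 preserving the mean),
# remainder split into trimers/dimers; cluster centers kept >= 0.9 nm
# apart (minimum image) so monomers are > 0.60 nm from everything and
# cluster members (<= 0.13 nm offsets) are < 0.30 nm apart.
place_solutes <- function(n, monomer_pct, box, z_mean, z_sd,
                          max_attempts = 5000L) {
  p <- monomer_pct / 100
  if (n == 1L && monomer_pct < 100)
    stop("a single solute cannot aggregate; monomer_fraction must be 100")
  m <- if (n == 1L) 1L else stats::rbinom(1, n, p)
  if (m == n - 1L) m <- if (stats::runif(1) < 0.5) n else n - 2L
  r <- n - m
  sizes <- c(rep(1L, m),
             if (r %% 2L == 1L) 3L,
             rep(2L, (r - if (r %% 2L == 1L) 3L else 0L) %/% 2L))
  n_cl <- length(sizes)
  centers <- matrix(NA_real_, n_cl, 3)
  for (i in seq_len(n_cl)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]),
                sample(c(-1, 1), 1) * stats::rnorm(1, z_mean, z_sd))
      if (i == 1L || min(min_image_dist(cand, centers[seq_len(i - 1L), ,
                                                      drop = FALSE],
                                        box)) >= 0.9) {
        centers[i, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("unsatisfiable packing: cannot place ", n,
                  " solutes at the required separations in a ",
                  signif(box[1], 3), " x ", signif(box[2], 3), " nm box")
  }
  pos <- matrix(NA_real_, n, 3)
  row <- 1L
  for (i in seq_len(n_cl)) {
    sz <- sizes[i]
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    offs <- switch(sz, 0, c(-0.11, 0.11), c(-0.13, 0, 0.13))
    for (j in seq_len(sz)) {
      pos[row, ] <- centers[i, ] + offs[j] * u
      row <- row + 1L
    }
  }
  pos
}

# minimum-image distances from point p to rows of mat (orthorhombic box)
min_image_dist <- function(p, mat, box) {
  d <- sweep(mat, 2, p)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  sqrt(rowSums(d^2))
}

#' Generate synthetic partition-isotherm data
#'
#' Points follow the saturating hyperbola
#' `r_mem = r_sat * x / (r_50 + x)` plus Gaussian noise, truncated at 0
#' (negative noisy ratios are not physical).
#'
#' @param r_sat saturation membrane molar ratio (> 0).
#' @param r_50 total-solute ratio at half saturation (> 0).
#' @param x_values total solute / lipid molar ratios.
#' @param noise_sd Gaussian noise SD on `r_mem` (>= 0).
#' @param n_reps replicates per x value.
#' @param seed RNG seed.
#' @return data.frame of class `partition_dataset` with columns `x`,
#'   `r_mem`, `rep`; attribute `truth` records the generating
#'   parameters and `n_clipped` how many points were truncated at 0.
#' @export
gen_partition_data <- function(r_sat, r_50, x_values, noise_sd = 0,
                               n_reps = 1L, seed = 1L) {
  stopifnot(r_sat > 0, r_50 > 0, n_reps >= 1)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  with_seed(seed, {
    x <- rep(x_values, each = n_reps)
    mu <- r_sat * x / (r_50 + x)
    r <- mu + stats::rnorm(length(x), 0, noise_sd)
    n_clip <- sum(r < 0)
    r <- pmax(r, 0)
    out <- data.frame(x = x, r_mem = r,
                      rep = rep(seq_len(n_reps), length(x_values)))
    attr(out, "truth") <- list(r_sat = r_sat, r_50 = r_50)
    attr(out, "n_clipped") <- n_clip
    class(out) <- c("partition_dataset", "data.frame")
    out
  })
}

#' Parameters of a synthetic dye-leakage trace
#'
#' The underlying kinetic law is a mono-exponential rise to plateau,
#' `%L(t) = plateau * (1 - exp(-modifier * k * t))` — the simplest
#' monotone model with the observed shape; it is a synthetic-only
#' construct, not a mechanistic claim. `composition_modifier` is a
#' multiplicative factor on the rate constant modelling head-group
#' effects (anionic PG-like > 1, PE-like < 1).
#'
#' @param plateau_percent leakage plateau, 0-100.
#' @param rate_constant first-order rate, 1/s (>= 0).
#' @param lipid_conc lipid concentration, uM (assay bookkeeping).
#' @param cpt_ratio total solute / lipid molar ratio (bookkeeping).
#' @param composition_modifier multiplicative rate factor.
#' @param noise_sd fluorescence noise SD.
#' @param f_i,f_d initial and post-detergent fluorescence calibration.
#' @param seed RNG seed.
#' @return list of class `leakage_sim_params`.
#' @export
leakage_sim_params <- function(plateau_percent = 80, rate_constant = 0.01,
                               lipid_conc = 20, cpt_ratio = 0.5,
                               composition_modifier = 1, noise_sd = 0,
                               f_i = 50, f_d = 1050, seed = 1L) {
  stopifnot(plateau_percent >= 0, plateau_percent <= 100,
            rate_constant >= 0, f_d > f_i, noise_sd >= 0)
  structure(as.list(environment()), class = "leakage_sim_params")
}

#' Generate a synthetic carboxyfluorescein leakage trace
#'
#' Emits raw fluorescence `f(t) = f_i + (f_d - f_i) * L(t) / 100` (plus
#' noise) so that [percent_leakage()] exactly inverts the underlying
#' percent-leakage law.
#'
#' @param params a [leakage_sim_params()].
#' @param t_grid increasing time grid in s, starting at 0.
#' @param label trace tag (composition / dose).
#' @return a [leakage_trace()].
#' @export
gen_leakage_trace <- function(params, t_grid, label = "synthetic") {
  stopifnot(inherits(params, "leakage_sim_params"),
            t_grid[1] == 0, all(diff(t_grid) > 0))
  with_seed(params$seed, {
    pct <- params$plateau_percent *
      (1 - exp(-params$composition_modifier * params$rate_constant * t_grid))
    f <- params$f_i + (params$f_d - params$f_i) * pct / 100 +
      stats::rnorm(length(t_grid), 0, params$noise_sd)
    leakage_trace(t = t_grid, f_t = f, f_i = params$f_i, f_d = params$f_d,
                  label = label)
  })
}

#' Draw Boltzmann-distributed umbrella-window samples from a profile
#'
#' For each window center `z_i`, samples the biased density
#' `p_i(z) proportional to exp(-(G(z) + k/2 (z - z_i)^2) / kT)` by
#' inverse-CDF sampling on a refined profile grid.
#'
#' @param profile a [free_energy_profile()] (G in kcal/mol). Must cover
#'   every center +/- 3 thermal widths `sigma = sqrt(kT / k_spring)`.
#' @param centers window centers, nm.
#' @param k_spring harmonic spring constant, kJ mol^-1 nm^-2.
#' @param n_per_window samples per window.
#' @param temperature K.
#' @param seed RNG seed.
#' @return an [umbrella_windows()] object.
#' @export
gen_umbrella_samples <- function(profile, centers, k_spring = 1000,
                                 n_per_window = 5000, temperature = 298,
                                 seed = 1L) {
  stopifnot(inherits(profile, "free_energy_profile"), k_spring >= 0,
            n_per_window > 0)
  kt <- KB_KJ * temperature
  if (k_spring > 0) {
    sigma <- sqrt(kt / k_spring)
    if (min(centers) - 3 * sigma < min(profile$z) ||
        max(centers) + 3 * sigma > max(profile$z))
      stop("profile grid must cover [min(centers) - 3 sigma, ",
           "max(centers) + 3 sigma]")
  }
  # refine the profile grid ~10x for smooth inverse-CDF sampling
  zf <- seq(min(profile$z), max(profile$z),
            length.out = max(2001L, 10L * length(profile$z)))
  gf <- stats::approx(profile$z, profile$g, zf)$y / KCAL_PER_KJ  # kJ/mol
  with_seed(seed, {
    samples <- lapply(centers, function(zi) {
      expo <- -(gf + 0.5 * k_spring * (zf - zi)^2) / kt
      expo <- expo - max(expo)
      dens <- exp(expo)
      keep <- dens > 1e-15
      if (sum(keep) < 2) stop("empty window support at center ", zi)
      zk <- zf[keep]
      # trapezoid CDF on the grid, inverted by linear interpolation
      dk <- dens[keep]
      cdf <- c(0, cumsum((dk[-1] + dk[-length(dk)]) / 2))
      cdf <- cdf / cdf[length(cdf)]
      u <- stats::runif(n_per_window)
      stats::approx(cdf, zk, u, rule = 2, ties = "ordered")$y
    })
    umbrella_windows(centers = centers, k_spring = k_spring,
                     samples = samples, temperature = temperature)
  })
}

#' Build a symmetric Gaussian-bump free-energy profile
#'
#' A smooth profile `G(z) = height * exp(-z^2 / (2 width^2))`, flat
#' (zero) in the aqueous phase, used as ground truth for umbrella /
#' WHAM recovery experiments.
#'
#' @param height barrier height, kcal/mol.
#' @param width Gaussian width, nm.
#' @param z_min,z_max grid limits, nm.
#' @param dz grid spacing, nm.
#' @return a [free_energy_profile()].
#' @export
gaussian_barrier_profile <- function(height, width = 0.8, z_min = -0.5,
                                     z_max = 4.5, dz = 0.01) {
  z <- seq(z_min, z_max, by = dz)
  free_energy_profile(z = z, g = height * exp(-z^2 / (2 * width^2)))
}

#' Generate a synthetic lamellar scattering curve
#'
#' Gaussian reflections at `s_n = n / d` with amplitudes decreasing as
#' `1 / n^2`, over constant background plus Gaussian noise. The s axis
#' follows the `s = 2 sin(theta) / lambda` convention, so `d = 1 / s_1`
#' (no 2 pi factor).
#'
#' @param d lamellar repeat distance, Angstrom (> 0).
#' @param n_orders number of reflection orders (>= 1).
#' @param peak_width Gaussian sigma of each reflection, 1/Angstrom.
#' @param background constant background intensity.
#' @param noise_sd Gaussian intensity noise SD.
#' @param seed RNG seed.
#' @param amplitude first-order peak amplitude.
#' @param s_grid s axis; default spans the instrument range
#'   0.0075-0.07 1/Angstrom.
#' @return a [scattering_curve()]; warns if a reflection falls outside
#'   the s range.
#' @export
gen_scattering_curve <- function(d, n_orders = 3, peak_width = 0.0012,
                                 background = 50, noise_sd = 0, seed = 1L,
                                 amplitude = 1000,
                                 s_grid = seq(0.0075, 0.07, length.out = 626)) {
  stopifnot(d > 0, n_orders >= 1)
  s_n <- seq_len(n_orders) / d
  if (any(s_n < min(s_grid) | s_n > max(s_grid)))
    warning("reflection(s) at s = ",
            paste(signif(s_n[s_n < min(s_grid) | s_n > max(s_grid)], 4),
                  collapse = ", "),
            " fall outside the s range [", min(s_grid), ", ", max(s_grid), "]")
  with_seed(seed, {
    intens <- rep(background, length(s_grid))
    for (n in seq_len(n_orders))
      intens <- intens + (amplitude / n^2) *
        exp(-(s_grid - s_n[n])^2 / (2 * peak_width^2))
    intens <- intens + stats::rnorm(length(s_grid), 0, noise_sd)
    scattering_curve(s = s_grid, intensity = intens,
                     calibration = list(material = "silver stearate",
                                        d_ref = 48.8))
  })
}
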