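# Small programmatic fixtures shared across test files.

# trajectory from an explicit coordinate array
make_traj <- function(roles, coords, box = c(6, 6, 8),
                      molecule_id = seq_along(roles),
                      leaflet = NULL, dt = 1, mass = NULL) {
  coords <- if (length(dim(coords)) == 2) array(coords, c(dim(coords), 1))
            else coords
  if (is.null(leaflet)) {
    leaflet <- ifelse(roles == "SOLUTE", "none",
                      ifelse(coords[, 3, 1] >= 0, "upper", "lower"))
  }
  if (is.null(mass)) {
    mt <- default_role_masses()
    mass <- unname(mt[sub("^(CD_[CH])_.*$", "\\1", roles)])
    mass[is.na(mass)] <- 1
  }
  labeled_trajectory(
    particles = data.frame(particle_id = seq_along(roles),
                           molecule_id = molecule_id, role = roles,
                           leaflet = leaflet, mass = mass),
    coords = coords, box = matrix(box, 1),
    time = (seq_len(dim(coords)[3]) - 1) * dt)
}

# one lipid carrying a single CD bond at polar angle theta (degrees)
make_cd_traj <- function(theta_deg, phi_deg = 0, n_frames = 1) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  bond <- 0.109 * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  c_pos <- c(1, 1, 1)
  coords <- array(NA_real_, c(2, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1, , f] <- c_pos
    coords[2, , f] <- c_pos + bond
  }
  make_traj(c("CD_C_1", "CD_H_1"), coords, molecule_id = c(1, 1),
            leaflet = c("upper", "upper"))
}

# brute-force time-origin-averaged lateral MSD (double loop oracle)
brute_msd <- function(x, y) {
  n_f <- ncol(x)
  msd <- numeric(n_f)
  for (lag in seq_len(n_f - 1)) {
    acc <- 0
    cnt <- 0
    for (t0 in seq_len(n_f - lag)) {
      acc <- acc + sum((x[, t0 + lag] - x[, t0])^2 +
                       (y[, t0 + lag] - y[, t0])^2)
      cnt <- cnt + nrow(x)
    }
    msd[lag + 1] <- acc / cnt
  }
  msd
}

# solute-only trajectory from a list of per-frame position matrices
solute_traj <- function(frames, box = c(6, 6, 8)) {
  n <- nrow(frames[[1]])
  coords <- array(NA_real_, c(n, 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  make_traj(rep("SOLUTE", n), coords, box = box,
            molecule_id = seq_len(n), leaflet = rep("none", n))
}
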