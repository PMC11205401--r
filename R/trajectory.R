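# Labeled bilayer trajectory container and tabular / GRO I/O.

#' Construct a labeled trajectory
#'
#' A `labeled_trajectory` holds per-frame coordinates of role-labeled
#' particles in a bilayer system together with the (orthorhombic) box
#' dimensions. Roles follow the conventions of the analysis functions:
#' `"P"` (phosphate), `"CARBONYL"`, `"CD_C_<k>"` / `"CD_H_<k>"` (the two
#' atoms of the k-th acyl-chain C-D bond), `"TERMINAL_CH3"` and
#' `"SOLUTE"`. Leaflet labels are `"upper"`, `"lower"` or `"none"`,
#' consistent with the z sign at frame 1.
#'
#' @param particles data.frame with columns `particle_id`, `molecule_id`,
#'   `role`, `leaflet`, `mass` (amu).
#' @param coords numeric array `[n_particles, 3, n_frames]`, wrapped
#'   positions in nm.
#' @param box numeric matrix `[n_frames, 3]`, box lengths in nm.
#' @param time numeric vector of frame times in ps.
#' @param coords_unwrapped optional array like `coords` with positions not
#'   wrapped at the periodic boundary (used by diffusion estimators).
#' @return object of class `labeled_trajectory`.
#' @export
labeled_trajectory <- function(particles, coords, box, time,
                               coords_unwrapped = NULL) {
  stopifnot(is.data.frame(particles),
            all(c("particle_id", "molecule_id", "role", "leaflet", "mass")
                %in% names(particles)))
  coords <- as_coord_array(coords)
  n_p <- nrow(particles)
  n_f <- dim(coords)[3]
  if (dim(coords)[1] != n_p)
    stop("coords first dimension must match nrow(particles)")
  box <- matrix(as.numeric(box), ncol = 3)
  if (nrow(box) == 1L) box <- box[rep(1L, n_f), , drop = FALSE]
  if (nrow(box) != n_f) stop("box must have one row per frame")
  if (any(box <= 0)) stop("box dimensions must be positive")
  if (length(time) != n_f) stop("time must have one value per frame")
  if (!is.null(coords_unwrapped)) {
    coords_unwrapped <- as_coord_array(coords_unwrapped)
    if (!all(dim(coords_unwrapped) == dim(coords)))
      stop("coords_unwrapped must match coords dimensions")
  }
  structure(list(particles = particles, coords = coords, box = box,
                 time = as.numeric(time),
                 coords_unwrapped = coords_unwrapped),
            class = "labeled_trajectory")
}

as_coord_array <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L || dim(x)[2] != 3L)
    stop("coordinates must be an [n_particles, 3, n_frames] array")
  storage.mode(x) <- "double"
  x
}

#' @export
print.labeled_trajectory <- function(x, ...) {
  cat(sprintf("labeled_trajectory: %d particles x %d frames\n",
              nrow(x$particles), n_frames(x)))
  cat("roles:", paste(names(table(x$particles$role)), collapse = ", "), "\n")
  cat(sprintf("box (frame 1): %.3f x %.3f x %.3f nm\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `labeled_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

# indices of particles matching a role pattern (exact or regex)
role_index <- function(traj, role, regex = FALSE) {
  if (regex) grep(role, traj$particles$role)
  else which(traj$particles$role %in% role)
}

#' Write a trajectory as long-format tabular text
#'
#' One row per particle per frame with columns `frame, time_ps,
#' molecule_id, role, x, y, z, box_x, box_y, box_z` (positions in nm,
#' wrapped). Round-trips through [read_trajectory_table()].
#'
#' @param traj a `labeled_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(traj, path) {
  n_p <- nrow(traj$particles)
  n_f <- n_frames(traj)
  df <- data.frame(
    frame = rep(seq_len(n_f), each = n_p),
    time_ps = rep(traj$time, each = n_p),
    molecule_id = rep(traj$particles$molecule_id, n_f),
    role = rep(traj$particles$role, n_f),
    x = as.vector(traj$coords[, 1, ]),
    y = as.vector(traj$coords[, 2, ]),
    z = as.vector(traj$coords[, 3, ]),
    box_x = rep(traj$box[, 1], each = n_p),
    box_y = rep(traj$box[, 2], each = n_p),
    box_z = rep(traj$box[, 3], each = n_p)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory from long-format tabular text
#'
#' Inverse of [write_trajectory_table()]. Leaflet labels are
#' reconstructed from the z sign at the first frame (solutes and other
#' roles listed in `no_leaflet_roles` get `"none"`); masses are assigned
#' from `mass_table` by role.
#'
#' @param path file written by [write_trajectory_table()].
#' @param mass_table named numeric vector mapping role (CD roles
#'   collapse to `"CD_C"`/`"CD_H"`) to mass in amu.
#' @param no_leaflet_roles roles that carry no leaflet label.
#' @return a `labeled_trajectory`.
#' @export
read_trajectory_table <- function(path, mass_table = default_role_masses(),
                                  no_leaflet_roles = "SOLUTE") {
  df <- utils::read.csv(path)
  frames <- sort(unique(df$frame))
  n_f <- length(frames)
  f1 <- df[df$frame == frames[1], ]
  n_p <- nrow(f1)
  ord <- order(df$frame)
  df <- df[ord, ]
  coords <- array(NA_real_, c(n_p, 3, n_f))
  coords[, 1, ] <- df$x
  coords[, 2, ] <- df$y
  coords[, 3, ] <- df$z
  box <- cbind(df$box_x[seq(1, nrow(df), by = n_p)],
               df$box_y[seq(1, nrow(df), by = n_p)],
               df$box_z[seq(1, nrow(df), by = n_p)])
  time <- df$time_ps[seq(1, nrow(df), by = n_p)]
  base_role <- sub("^(CD_[CH])_.*$", "\\1", f1$role)
  mass <- unname(mass_table[base_role])
  mass[is.na(mass)] <- 1
  leaflet <- assign_leaflets(f1$molecule_id, f1$role, f1$z,
                             no_leaflet_roles)
  particles <- data.frame(particle_id = seq_len(n_p),
                          molecule_id = f1$molecule_id,
                          role = f1$role, leaflet = leaflet, mass = mass)
  labeled_trajectory(particles, coords, box, time)
}

# leaflet labels at frame 1: each molecule takes the side of its own
# phosphate (z relative to the median phosphate plane midpoint);
# molecules without a P particle fall back to their mean z sign
assign_leaflets <- function(molecule_id, role, z, no_leaflet_roles) {
  zc <- z - stats::median(z[role == "P"])
  pz <- tapply(zc[role == "P"], molecule_id[role == "P"], mean)
  mz <- tapply(zc, molecule_id, mean)
  key <- as.character(molecule_id)
  side <- ifelse(key %in% names(pz), unname(pz[key]), unname(mz[key]))
  ifelse(role %in% no_leaflet_roles, "none",
         ifelse(side >= 0, "upper", "lower"))
}

#' Default per-role particle masses (amu)
#'
#' Nominal masses for the coarse role set: phosphate P atom, carbonyl
#' C=O, acyl CH/H pairs of a C-D bond, terminal methyl and a one-bead
#' solute (the molecular mass of cryptotanshinone, 296.4).
#'
#' @return named numeric vector.
#' @export
default_role_masses <- function() {
  c(P = 30.974, CARBONYL = 28.010, CD_C = 13.019, CD_H = 1.008,
    TERMINAL_CH3 = 15.035, SOLUTE = 296.4)
}

#' Write a trajectory as a multi-frame GRO file
#'
#' Fixed-width GROMACS coordinate format (positions in nm, 3 decimal
#' places), one concatenated block per frame. Atom and residue names are
#' derived from roles via `role_to_atom`.
#'
#' @param traj a `labeled_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n_p <- nrow(traj$particles)
  atom <- substr(gsub("_", "", traj$particles$role), 1, 5)
  res <- ifelse(traj$particles$role == "SOLUTE", "SOL", "LIP")
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("bilayer frame t= %.3f", traj$time[f]), con)
    writeLines(sprintf("%5d", n_p), con)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     traj$particles$molecule_id %% 100000L, res, atom,
                     traj$particles$particle_id %% 100000L,
                     traj$coords[, 1, f], traj$coords[, 2, f],
                     traj$coords[, 3, f])
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame GRO file
#'
#' Minimal fixed-width reader for orthorhombic boxes. Roles are
#' recovered from atom names via `atom_to_role` (a named character
#' vector); unknown names map to `"SOLUTE"` when the residue name is
#' `"SOL"`, otherwise to the atom name itself.
#'
#' @param path GRO file (possibly multi-frame).
#' @param dt_ps frame spacing used if the title lines carry no time.
#' @return a `labeled_trajectory`.
#' @export
read_gro <- function(path, dt_ps = 1) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  boxes <- list()
  times <- numeric()
  while (i <= length(lines)) {
    title <- lines[i]
    n_p <- as.integer(lines[i + 1L])
    block <- lines[(i + 2L):(i + 1L + n_p)]
    resid <- as.integer(substr(block, 1, 5))
    resname <- trimws(substr(block, 6, 10))
    atom <- trimws(substr(block, 11, 15))
    xyz <- cbind(as.numeric(substr(block, 21, 28)),
                 as.numeric(substr(block, 29, 36)),
                 as.numeric(substr(block, 37, 44)))
    boxline <- strsplit(trimws(lines[i + 2L + n_p]), "\\s+")[[1]]
    tm <- regmatches(title, regexpr("t= *[0-9.eE+-]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t= *", "", tm))
               else (length(frames)) * dt_ps)
    frames[[length(frames) + 1L]] <- list(resid = resid, resname = resname,
                                          atom = atom, xyz = xyz)
    boxes[[length(boxes) + 1L]] <- as.numeric(boxline[1:3])
    i <- i + 3L + n_p
  }
  f1 <- frames[[1]]
  n_p <- nrow(f1$xyz)
  coords <- array(NA_real_, c(n_p, 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]$xyz
  role <- gro_atom_to_role(f1$atom, f1$resname)
  mass_table <- default_role_masses()
  base_role <- sub("^(CD_[CH])_.*$", "\\1", role)
  mass <- unname(mass_table[base_role])
  mass[is.na(mass)] <- 1
  leaflet <- assign_leaflets(f1$resid, role, f1$xyz[, 3], "SOLUTE")
  particles <- data.frame(particle_id = seq_len(n_p),
                          molecule_id = f1$resid, role = role,
                          leaflet = leaflet, mass = mass)
  labeled_trajectory(particles, coords, do.call(rbind, boxes), times)
}

# invert the atom-name mangling of write_gro
gro_atom_to_role <- function(atom, resname) {
  role <- atom
  role[atom == "P"] <- "P"
  role[atom == "CARBO"] <- "CARBONYL"
  role[atom == "TERMI"] <- "TERMINAL_CH3"
  role[resname == "SOL"] <- "SOLUTE"
  cd <- grepl("^CD[CH][0-9]+$", atom)
  role[cd] <- sub("^CD([CH])([0-9]+)$", "CD_\\1_\\2", atom[cd])
  role
}
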