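# Membrane trajectory observables: area per lipid, lateral diffusion
# (Einstein relation), deuterium order parameters, P-P thickness, mass
# density profiles and distance-cutoff cluster statistics.

#' Area per lipid
#'
#' Per-frame lateral box area divided by the number of lipids per
#' leaflet, `box_x * box_y / n_per_leaflet`, in nm^2.
#'
#' @param traj a `labeled_trajectory`.
#' @param n_per_leaflet lipids per leaflet (> 0).
#' @return list with `series` (per frame, nm^2), `mean`, `sd`.
#' @export
area_per_lipid <- function(traj, n_per_leaflet) {
  stopifnot(n_per_leaflet > 0)
  apl <- traj$box[, 1] * traj$box[, 2] / n_per_leaflet
  list(series = apl, mean = mean(apl), sd = stats::sd(apl))
}

# unwrapped lateral positions [n_sel, n_frames, 2]; uses stored
# unwrapped coordinates when present, otherwise accumulates
# minimum-image per-step displacements (asserting no step > box/2)
unwrap_lateral <- function(traj, idx) {
  n_f <- n_frames(traj)
  if (!is.null(traj$coords_unwrapped)) {
    x <- traj$coords_unwrapped[idx, 1, , drop = FALSE]
    y <- traj$coords_unwrapped[idx, 2, , drop = FALSE]
    return(list(x = matrix(x, length(idx)), y = matrix(y, length(idx))))
  }
  x <- matrix(traj$coords[idx, 1, ], length(idx))
  y <- matrix(traj$coords[idx, 2, ], length(idx))
  if (n_f > 1) {
    for (f in 2:n_f) {
      bx <- traj$box[f, 1]; by <- traj$box[f, 2]
      dx <- x[, f] - x[, f - 1]
      dy <- y[, f] - y[, f - 1]
      dx <- dx - bx * round(dx / bx)
      dy <- dy - by * round(dy / by)
      if (any(abs(dx) > bx / 2 + 1e-9) || any(abs(dy) > by / 2 + 1e-9))
        stop("unwrapping assumption violated: particle moved > box/2 in one frame")
      x[, f] <- x[, f - 1] + dx
      y[, f] <- y[, f - 1] + dy
    }
  }
  list(x = x, y = y)
}

#' Lateral mean square displacement
#'
#' Time-origin-averaged lateral MSD over the selected particles:
#' `MSD(L) = mean over t, particles of |r(t+L) - r(t)|^2` (x, y only).
#' By default the lateral center-of-mass motion of each leaflet group
#' is removed before computing displacements.
#'
#' @param traj a `labeled_trajectory`.
#' @param role role selector (exact match), default `"P"`.
#' @param remove_com remove per-leaflet lateral center-of-mass motion.
#' @return data.frame with `lag` (ps) and `msd` (nm^2); `msd[lag=0]` is 0.
#' @export
lateral_msd <- function(traj, role = "P", remove_com = TRUE) {
  idx <- role_index(traj, role)
  if (!length(idx)) stop("no particles with role ", role)
  uw <- unwrap_lateral(traj, idx)
  x <- uw$x
  y <- uw$y
  if (remove_com) {
    grp <- traj$particles$leaflet[idx]
    for (g in unique(grp)) {
      rows <- which(grp == g)
      if (length(rows) > 1) {
        x[rows, ] <- sweep(x[rows, , drop = FALSE], 2,
                           colMeans(x[rows, , drop = FALSE]))
        y[rows, ] <- sweep(y[rows, , drop = FALSE], 2,
                           colMeans(y[rows, , drop = FALSE]))
      }
    }
  }
  n_f <- ncol(x)
  msd <- numeric(n_f)
  for (lag in seq_len(n_f - 1)) {
    dx <- x[, (1 + lag):n_f, drop = FALSE] - x[, 1:(n_f - lag), drop = FALSE]
    dy <- y[, (1 + lag):n_f, drop = FALSE] - y[, 1:(n_f - lag), drop = FALSE]
    msd[lag + 1] <- mean(dx^2 + dy^2)
  }
  dt <- if (n_f > 1) diff(traj$time[1:2]) else 0
  data.frame(lag = (seq_len(n_f) - 1) * dt, msd = msd)
}

#' Lateral diffusion coefficient via the Einstein relation
#'
#' Fits a line to the time-origin-averaged lateral MSD over
#' `fit_window` and reports `D = slope / (2 d)` with `d = 2`
#' dimensions, converted to cm^2/s. The default fit window spans lags
#' from 10% to 50% of the trajectory length (bias/variance trade-off:
#' short lags are dominated by the crossover, long lags by noise).
#'
#' @param traj a `labeled_trajectory` with >= 100 frames.
#' @param role role selector, default `"P"` (phosphate, one per lipid).
#' @param fit_window lag range (ps) as `c(lo, hi)`; `NULL` for default.
#' @param remove_com remove per-leaflet lateral COM motion first.
#' @return object of class `msd_curve`: list with `lag`, `msd`,
#'   `d_dims = 2`, `d_coeff` (cm^2/s), `fit_window`.
#' @export
lateral_diffusion <- function(traj, role = "P", fit_window = NULL,
                              remove_com = TRUE) {
  if (n_frames(traj) < 100)
    stop("lateral_diffusion needs >= 100 frames; use lateral_msd() directly ",
         "for shorter trajectories")
  curve <- lateral_msd(traj, role, remove_com)
  max_lag <- max(curve$lag)
  if (is.null(fit_window)) fit_window <- c(0.1, 0.5) * max_lag
  sel <- curve$lag >= fit_window[1] & curve$lag <= fit_window[2]
  if (sum(sel) < 2) stop("fit_window outside available lags")
  fit <- stats::lm(msd ~ lag, data = curve[sel, ])
  slope <- stats::coef(fit)[["lag"]]            # nm^2 / ps
  d_nm2ps <- slope / (2 * 2)
  structure(list(lag = curve$lag, msd = curve$msd, d_dims = 2,
                 d_coeff = convert_diffusion(d_nm2ps, "nm2_ps", "cm2_s"),
                 fit_window = fit_window),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("lateral MSD over %d lags; D = %.3g cm^2/s (fit window %.0f-%.0f ps)\n",
              length(x$lag), x$d_coeff, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' Deuterium order parameters per acyl carbon
#'
#' For each carbon index k with `CD_C_k` / `CD_H_k` particle pairs,
#' computes `S_CD = <(3 cos^2 theta - 1) / 2>` over bonds and frames,
#' where theta is the angle between the C-D bond vector and the bilayer
#' normal (z axis). A value of -0.5 corresponds to bonds perpendicular
#' to the normal (perfectly ordered all-trans chains); Table-style
#' reports use the magnitude, returned alongside.
#'
#' @param traj a `labeled_trajectory` with CD bond pairs.
#' @return data.frame of class `order_profile` with columns
#'   `carbon_index`, `s_cd` (signed), `abs_s_cd`; attribute
#'   `chain_mean` holds the chain-averaged signed and absolute values.
#' @export
order_parameters <- function(traj) {
  roles <- traj$particles$role
  ck <- grep("^CD_C_", roles)
  if (!length(ck)) stop("no CD_C_k particles in trajectory")
  carbons <- sort(unique(as.integer(sub("^CD_C_", "", roles[ck]))))
  out <- data.frame(carbon_index = carbons, s_cd = NA_real_,
                    abs_s_cd = NA_real_)
  for (j in seq_along(carbons)) {
    k <- carbons[j]
    ic <- which(roles == paste0("CD_C_", k))
    ih <- which(roles == paste0("CD_H_", k))
    mc <- traj$particles$molecule_id[ic]
    mh <- traj$particles$molecule_id[ih]
    if (!setequal(mc, mh) || length(ic) != length(ih))
      stop("missing CD_H_", k, " partner for molecule(s) ",
           paste(setdiff(mc, mh), collapse = ", "))
    ih <- ih[match(mc, mh)]
    v <- traj$coords[ih, , , drop = FALSE] - traj$coords[ic, , , drop = FALSE]
    # minimum image (bond vectors are short; wrapping may split them)
    for (dim in 1:3) {
      b <- traj$box[, dim]
      v[, dim, ] <- v[, dim, ] -
        rep(b, each = length(ic)) * round(v[, dim, ] / rep(b, each = length(ic)))
    }
    cos2 <- v[, 3, ]^2 / (v[, 1, ]^2 + v[, 2, ]^2 + v[, 3, ]^2)
    out$s_cd[j] <- mean((3 * cos2 - 1) / 2)
  }
  out$abs_s_cd <- abs(out$s_cd)
  attr(out, "chain_mean") <- c(s_cd = mean(out$s_cd),
                               abs_s_cd = mean(out$abs_s_cd))
  class(out) <- c("order_profile", "data.frame")
  out
}

#' Phosphate-phosphate membrane thickness
#'
#' Per frame, the absolute distance between the mean z of upper-leaflet
#' and lower-leaflet phosphate particles, averaged over frames.
#'
#' @param traj a `labeled_trajectory`.
#' @return list with `series` (nm per frame), `mean`, `sd`.
#' @export
membrane_thickness <- function(traj) {
  p <- role_index(traj, "P")
  up <- p[traj$particles$leaflet[p] == "upper"]
  lo <- p[traj$particles$leaflet[p] == "lower"]
  if (!length(up) || !length(lo))
    stop("both leaflets must contain phosphate (P) particles")
  zu <- colMeans(matrix(traj$coords[up, 3, ], length(up)))
  zl <- colMeans(matrix(traj$coords[lo, 3, ], length(lo)))
  series <- abs(zu - zl)
  list(series = series, mean = mean(series), sd = stats::sd(series))
}

# particle indices for a group selector: exact role match, falling back
# to regex on the role string
group_index <- function(traj, selector) {
  idx <- which(traj$particles$role %in% selector)
  if (!length(idx))
    idx <- which(Reduce(`|`, lapply(selector, grepl,
                                    x = traj$particles$role)))
  idx
}

#' Mass density profile along the bilayer normal
#'
#' Histograms particle mass along z about the bilayer center (midpoint
#' of the two leaflet phosphate means, recomputed each frame),
#' normalized by bin volume, in kg/m^3. With `symmetrize = TRUE` the
#' profile is averaged with its mirror image about the center,
#' `rho(z) <- (rho(z) + rho(-z)) / 2`.
#'
#' @param traj a `labeled_trajectory`.
#' @param groups named list of role selectors (exact roles or regular
#'   expressions), e.g. `list(phosphate = "P", solute = "SOLUTE")`.
#' @param bin_width bin width in nm (> 0).
#' @param symmetrize mirror-average about the bilayer center.
#' @return object of class `density_profile`: list with `z_centers`
#'   (nm, origin at the bilayer center), `density` (matrix bins x
#'   groups, kg/m^3), `symmetrized`, `bin_width`, `area` (mean lateral
#'   box area, nm^2).
#' @export
density_profile <- function(traj,
                            groups = list(phosphate = "P",
                                          carbonyl = "CARBONYL",
                                          terminal_ch3 = "TERMINAL_CH3",
                                          solute = "SOLUTE"),
                            bin_width = 0.1, symmetrize = FALSE) {
  stopifnot(bin_width > 0)
  n_f <- n_frames(traj)
  p <- role_index(traj, "P")
  up <- p[traj$particles$leaflet[p] == "upper"]
  lo <- p[traj$particles$leaflet[p] == "lower"]
  if (!length(up) || !length(lo))
    stop("bilayer center requires phosphates in both leaflets")
  bz <- traj$box[, 3]
  half_bins <- ceiling(max(bz) / 2 / bin_width)
  edges <- seq(-half_bins * bin_width, half_bins * bin_width, by = bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- matrix(0, length(centers), length(groups),
                 dimnames = list(NULL, names(groups)))
  area <- mean(traj$box[, 1] * traj$box[, 2])
  for (f in seq_len(n_f)) {
    c_z <- (mean(traj$coords[up, 3, f]) + mean(traj$coords[lo, 3, f])) / 2
    for (g in seq_along(groups)) {
      idx <- group_index(traj, groups[[g]])
      if (!length(idx)) next
      z <- traj$coords[idx, 3, f] - c_z
      z <- z - bz[f] * round(z / bz[f])       # min image about the center
      bin <- findInterval(z, edges, rightmost.closed = TRUE)
      ok <- bin >= 1 & bin <= length(centers)
      tab <- tapply(traj$particles$mass[idx][ok], bin[ok], sum)
      dens[as.integer(names(tab)), g] <- dens[as.integer(names(tab)), g] + tab
    }
  }
  # amu per (nm^2 * nm * frames) -> kg/m^3
  dens <- dens / (n_f * area * bin_width) * AMU_PER_NM3_TO_KG_M3
  if (symmetrize) dens <- (dens + dens[rev(seq_len(nrow(dens))), ,
                                       drop = FALSE]) / 2
  structure(list(z_centers = centers, density = dens,
                 symmetrized = symmetrize, bin_width = bin_width,
                 area = area),
            class = "density_profile")
}

# pairwise minimum inter-particle distance between two sets of
# positions (matrices n1 x 3, n2 x 3) under minimum image
min_pair_dist <- function(a, b, box) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[i, ])
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    best <- min(best, min(rowSums(d^2)))
  }
  sqrt(best)
}

#' Solute cluster statistics under a distance cutoff
#'
#' Per frame, solute molecules are linked whenever the minimum
#' inter-particle distance between two molecules (minimum-image) is
#' below `cutoff`; single-linkage connected components define the
#' clusters. The monomer percentage is the mean fraction of molecules
#' in size-1 components across frames.
#'
#' @param traj a `labeled_trajectory` with >= 1 SOLUTE molecule.
#' @param cutoff linkage distance, nm (default 0.30).
#' @return object of class `cluster_report`: list with `cutoff`,
#'   `size_histogram` (data.frame `size`, `n_clusters` summed over
#'   frames), `percent_monomers`, `monomer_series` (per-frame %).
#' @export
cluster_stats <- function(traj, cutoff = 0.30) {
  idx <- role_index(traj, "SOLUTE")
  if (!length(idx)) stop("no SOLUTE particles in trajectory")
  mols <- split(idx, traj$particles$molecule_id[idx])
  n_mol <- length(mols)
  n_f <- n_frames(traj)
  size_counts <- integer(n_mol)
  mono <- numeric(n_f)
  for (f in seq_len(n_f)) {
    box <- traj$box[f, ]
    adj <- matrix(FALSE, n_mol, n_mol)
    pos <- lapply(mols, function(ii)
      matrix(traj$coords[ii, , f], length(ii), 3))
    if (n_mol > 1) {
      for (i in seq_len(n_mol - 1)) for (j in (i + 1):n_mol) {
        if (min_pair_dist(pos[[i]], pos[[j]], box) < cutoff)
          adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    comp <- connected_components(adj)
    sizes <- tabulate(tabulate(comp, nbins = n_mol), nbins = n_mol)
    size_counts <- size_counts + sizes
    mono[f] <- 100 * sizes[1] / n_mol
  }
  structure(list(cutoff = cutoff,
                 size_histogram = data.frame(size = seq_len(n_mol),
                                             n_clusters = size_counts),
                 percent_monomers = mean(mono),
                 monomer_series = mono),
            class = "cluster_report")
}

# labels of connected components of an undirected adjacency matrix
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster analysis (cutoff %.2f nm): %.1f%% monomers\n",
              x$cutoff, x$percent_monomers))
  occ <- x$size_histogram[x$size_histogram$n_clusters > 0, ]
  cat("cluster sizes observed:",
      paste(sprintf("%d (x%d)", occ$size, occ$n_clusters), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a two-column xvg-style plain-text file
#'
#' Simple `@`-commented two-column text for plotting compatibility.
#'
#' @param x,y numeric vectors.
#' @param path output path.
#' @param title,xlab,ylab labels written as comments.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(x, y, path, title = "", xlab = "x", ylab = "y") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("@ title \"%s\"", title),
               sprintf("@ xaxis label \"%s\"", xlab),
               sprintf("@ yaxis label \"%s\"", ylab)), con)
  utils::write.table(data.frame(x, y), con, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
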