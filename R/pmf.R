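# Free-energy profiles from umbrella sampling: WHAM self-consistent
# iteration, symmetrization about the bilayer center, and barrier
# extraction.

#' Construct a free-energy profile
#'
#' G(z) on a uniform grid, in kcal/mol, zero-referenced in the aqueous
#' phase.
#'
#' @param z uniform grid, nm.
#' @param g free energy, kcal/mol (NA allowed for masked bins).
#' @param uncertainty optional per-bin uncertainty, kcal/mol.
#' @return object of class `free_energy_profile`.
#' @export
free_energy_profile <- function(z, g, uncertainty = NULL) {
  stopifnot(length(z) == length(g), length(z) >= 2)
  dz <- diff(z)
  if (max(abs(dz - dz[1])) > 1e-8 * abs(dz[1]))
    stop("z grid must be uniform")
  structure(list(z = as.numeric(z), g = as.numeric(g),
                 uncertainty = uncertainty),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("free-energy profile on [%.2f, %.2f] nm (%d points), max G = %.2f kcal/mol\n",
              min(x$z), max(x$z), length(x$z), max(x$g, na.rm = TRUE)))
  invisible(x)
}

#' Construct an umbrella-window sample set
#'
#' Biased reaction-coordinate samples per harmonic window. Warns when
#' any adjacent pair of windows shares less than 1% histogram mass
#' (poor overlap degrades WHAM).
#'
#' @param centers window centers, nm.
#' @param k_spring spring constant, kJ mol^-1 nm^-2 (default 1000).
#' @param samples list of numeric sample vectors, one per center.
#' @param temperature K.
#' @return object of class `umbrella_windows`.
#' @export
umbrella_windows <- function(centers, k_spring = 1000, samples,
                             temperature = 298) {
  stopifnot(length(centers) == length(samples), k_spring >= 0,
            temperature > 0)
  if (any(vapply(samples, length, 1L) == 0))
    stop("every window must contain samples")
  ord <- order(centers)
  centers <- centers[ord]
  samples <- samples[ord]
  if (length(centers) > 1) {
    rng <- range(unlist(samples))
    brk <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 201)
    h <- lapply(samples, function(s)
      graphics::hist(s, breaks = brk, plot = FALSE)$counts /
        length(s))
    for (i in seq_len(length(centers) - 1)) {
      if (sum(pmin(h[[i]], h[[i + 1]])) < 0.01)
        warning(sprintf("windows at %.3f and %.3f nm share < 1%% histogram mass",
                        centers[i], centers[i + 1]))
    }
  }
  structure(list(centers = centers, k_spring = k_spring,
                 samples = samples, temperature = temperature),
            class = "umbrella_windows")
}

#' @export
print.umbrella_windows <- function(x, ...) {
  cat(sprintf("umbrella windows: %d centers on [%.2f, %.2f] nm, k = %g kJ/mol/nm^2, %d samples/window (median)\n",
              length(x$centers), min(x$centers), max(x$centers),
              x$k_spring,
              stats::median(vapply(x$samples, length, 1L))))
  invisible(x)
}

#' Weighted histogram analysis of umbrella windows
#'
#' Standard WHAM self-consistent iteration: with per-window bias
#' `U_i(z) = k/2 (z - z_i)^2`, the unbiased bin probabilities and
#' window constants are iterated as
#' `p(z_m) = sum_i n_im / sum_i N_i exp((f_i - U_i(z_m)) / kT)` and
#' `f_i = -kT ln sum_m exp(-U_i(z_m)/kT) p(z_m)` until the maximum
#' relative change in the `f_i` falls below `tol`. The profile is
#' `G(z) = -kT ln p(z)`, converted to kcal/mol and shifted so the
#' aqueous-phase plateau (outermost `reference_fraction` of the grid on
#' the chosen side) averages zero. Empty bins inside the sampled range
#' are masked (NA) with a warning.
#'
#' @param windows an [umbrella_windows()] object.
#' @param bin_width histogram bin width, nm (default 0.05).
#' @param tol relative convergence tolerance on the window constants
#'   (default 1e-7).
#' @param max_iter iteration cap (default 1e5); reaching it raises an
#'   error of class `wham_convergence_error` carrying the `f_trace`.
#' @param reference which end of the grid is the aqueous phase:
#'   `"upper"` (default; larger z is water), `"lower"` or `"both"`.
#' @param reference_fraction fraction of the z range treated as the
#'   aqueous plateau (default 0.15).
#' @param n_boot bootstrap resamples for per-bin uncertainty (0 = off).
#'   Resampling is by blocks within windows, warm-started from the
#'   converged constants.
#' @param boot_blocks number of blocks per window for the bootstrap.
#' @return a [free_energy_profile()] with attributes `converged`,
#'   `iterations`, `f_i` (kJ/mol) and, when `n_boot > 0`, an
#'   `uncertainty` element (per-bin SD, kcal/mol).
#' @export
wham <- function(windows, bin_width = 0.05, tol = 1e-7, max_iter = 1e5,
                 reference = c("upper", "lower", "both"),
                 reference_fraction = 0.15, n_boot = 0, boot_blocks = 20) {
  stopifnot(inherits(windows, "umbrella_windows"), bin_width > 0)
  reference <- match.arg(reference)
  kt <- KB_KJ * windows$temperature
  all_s <- unlist(windows$samples)
  lo <- floor(min(all_s) / bin_width) * bin_width
  hi <- ceiling(max(all_s) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  n_bin <- length(centers)
  n_win <- length(windows$centers)
  n_im <- vapply(windows$samples, function(s)
    graphics::hist(s, breaks = edges, plot = FALSE)$counts,
    integer(n_bin))                       # [n_bin, n_win]
  n_i <- vapply(windows$samples, length, 1L)
  bias <- outer(centers, windows$centers,
                function(z, zi) 0.5 * windows$k_spring * (z - zi)^2)
  cmat <- exp(-bias / kt)                 # [n_bin, n_win]
  m_m <- rowSums(n_im)

  core <- function(m_m, f_start = rep(0, n_win)) {
    f <- f_start
    it <- 0L
    f_trace <- list()
    repeat {
      it <- it + 1L
      denom <- cmat %*% (n_i * exp(f / kt))
      p <- m_m / pmax(denom, .Machine$double.xmin)
      f_new <- -kt * log(pmax(crossprod(cmat, p), .Machine$double.xmin))
      f_new <- f_new - f_new[1]           # gauge fix
      delta <- max(abs(f_new - f)) / max(1, max(abs(f_new)))
      f <- as.numeric(f_new)
      if (it %% 1000L == 0L) f_trace[[length(f_trace) + 1L]] <- f
      if (delta < tol) break
      if (it >= max_iter)
        stop(errorCondition(
          sprintf("WHAM did not converge in %d iterations (last delta %.3g)",
                  it, delta),
          f_trace = f_trace, class = "wham_convergence_error"))
    }
    list(p = as.numeric(p), f = f, iterations = it)
  }

  res <- core(m_m)
  g_kj <- -kt * log(res$p)
  sampled <- which(m_m > 0)
  inside_empty <- setdiff(seq(min(sampled), max(sampled)), sampled)
  if (length(inside_empty)) {
    warning(length(inside_empty),
            " empty bin(s) inside the sampled range were masked")
    g_kj[inside_empty] <- NA
  }
  g_kj[m_m == 0 & !seq_len(n_bin) %in% inside_empty] <- NA

  ref_idx <- reference_indices(centers, reference, reference_fraction)
  shift_ref <- function(g) g - mean(g[ref_idx], na.rm = TRUE)
  if (all(is.na(g_kj[ref_idx])))
    stop("reference region undefined: no sampled bins in the aqueous plateau")
  g <- shift_ref(g_kj) * KCAL_PER_KJ

  unc <- NULL
  if (n_boot > 0) {
    gb <- matrix(NA_real_, n_bin, n_boot)
    for (b in seq_len(n_boot)) {
      m_b <- rowSums(vapply(windows$samples, function(s) {
        blocks <- split(s, cut(seq_along(s), boot_blocks, labels = FALSE))
        sb <- unlist(blocks[sample.int(length(blocks), replace = TRUE)])
        graphics::hist(sb, breaks = edges, plot = FALSE)$counts
      }, integer(n_bin)))
      rb <- core(m_b, f_start = res$f)
      gi <- -kt * log(pmax(rb$p, .Machine$double.xmin))
      gi[m_b == 0] <- NA
      gb[, b] <- shift_ref(gi) * KCAL_PER_KJ
    }
    unc <- apply(gb, 1, stats::sd, na.rm = TRUE)
  }

  out <- free_energy_profile(centers, g, uncertainty = unc)
  attr(out, "converged") <- TRUE
  attr(out, "iterations") <- res$iterations
  attr(out, "f_i") <- res$f
  out
}

reference_indices <- function(z, reference, fraction) {
  rng <- diff(range(z))
  switch(reference,
         upper = which(z >= max(z) - fraction * rng),
         lower = which(z <= min(z) + fraction * rng),
         both = which(z >= max(z) - fraction * rng |
                      z <= min(z) + fraction * rng))
}

#' Symmetrize a free-energy profile about the bilayer center
#'
#' `G_sym(z) = (G(z) + G(2 center - z)) / 2`. Where only one side of
#' the profile exists (half-profile input) the available side is
#' mirrored, producing a full symmetric profile.
#'
#' @param profile a [free_energy_profile()].
#' @param center mirror point, nm (default 0).
#' @return a symmetric [free_energy_profile()] spanning both sides of
#'   `center`.
#' @export
symmetrize_profile <- function(profile, center = 0) {
  z <- profile$z
  dz <- z[2] - z[1]
  zmax <- max(abs(z - center))
  n_half <- ceiling(zmax / dz - 1e-9)
  z_out <- center + seq(-n_half, n_half) * dz
  # snap queries that land a rounding error outside the grid
  snap <- function(q) {
    q[abs(q - min(z)) < 1e-9] <- min(z)
    q[abs(q - max(z)) < 1e-9] <- max(z)
    q
  }
  g_direct <- stats::approx(z, profile$g, snap(z_out), rule = 1)$y
  g_mirror <- stats::approx(z, profile$g, snap(2 * center - z_out),
                            rule = 1)$y
  g_sym <- rowMeans(cbind(g_direct, g_mirror), na.rm = TRUE)
  g_sym[is.nan(g_sym)] <- NA
  free_energy_profile(z_out, g_sym)
}

#' Permeation barrier of a free-energy profile
#'
#' The maximum of G relative to the aqueous-phase reference (zero).
#' The profile must already be zero-referenced, as produced by
#' [wham()].
#'
#' @param profile a [free_energy_profile()].
#' @return list with `height` (kcal/mol) and `z_at_max` (nm).
#' @export
barrier_height <- function(profile) {
  ok <- is.finite(profile$g)
  if (!any(ok)) stop("reference region undefined: profile has no finite values")
  i <- which.max(ifelse(ok, profile$g, -Inf))
  list(height = profile$g[i], z_at_max = profile$z[i])
}

#' Write / read umbrella-window samples as per-window tabular files
#'
#' One two-column (time index, z) whitespace file per window, mirroring
#' common pull-output layout, plus a small `windows.csv` index with
#' centers, spring constant and temperature.
#'
#' @param windows an [umbrella_windows()].
#' @param dir output directory (created if missing).
#' @return the reader returns an `umbrella_windows`; the writer returns
#'   `dir` invisibly.
#' @export
write_umbrella_dir <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- data.frame(window = seq_along(windows$centers),
                    center = windows$centers,
                    k_spring = windows$k_spring,
                    temperature = windows$temperature,
                    file = sprintf("window_%03d.dat",
                                   seq_along(windows$centers)))
  utils::write.csv(idx, file.path(dir, "windows.csv"), row.names = FALSE,
                   quote = FALSE)
  for (i in seq_along(windows$samples)) {
    s <- windows$samples[[i]]
    utils::write.table(data.frame(seq_along(s), s),
                       file.path(dir, idx$file[i]), sep = " ",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_umbrella_dir
#' @export
read_umbrella_dir <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "windows.csv"))
  samples <- lapply(idx$file, function(f)
    utils::read.table(file.path(dir, f))[[2]])
  umbrella_windows(centers = idx$center, k_spring = idx$k_spring[1],
                   samples = samples, temperature = idx$temperature[1])
}
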