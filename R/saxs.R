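# Lamellar SAXS: axis calibration, reflection detection, 1:2:3
# indexing and repeat-distance extraction.
#
# The s axis follows the s = 2 sin(theta) / lambda convention, so the
# repeat distance is d = 1 / s_1 — there is NO factor of 2*pi (that
# belongs to the q = 2*pi/d convention).

#' Construct a scattering curve
#'
#' @param s scattering vector grid, 1/Angstrom, increasing
#'   (`s = 2 sin(theta) / lambda`).
#' @param intensity intensities (finite).
#' @param calibration list with `material` and `d_ref` (Angstrom);
#'   default silver stearate at 48.8 Angstrom.
#' @return object of class `scattering_curve`.
#' @export
scattering_curve <- function(s, intensity,
                             calibration = list(material = "silver stearate",
                                                d_ref = 48.8)) {
  stopifnot(length(s) == length(intensity), all(diff(s) > 0),
            all(is.finite(intensity)))
  structure(list(s = as.numeric(s), intensity = as.numeric(intensity),
                 calibration = calibration),
            class = "scattering_curve")
}

#' Calibrate a detector-channel axis to s
#'
#' Linear channel-to-s mapping anchored at `s(0) = 0` and
#' `s(ref_peak_channel) = 1 / d_ref`, where `d_ref` is the known
#' repeat distance of the reference material (silver stearate,
#' 48.8 Angstrom).
#'
#' @param raw_channels channel indices to convert.
#' @param ref_peak_channel channel of the reference first-order peak.
#' @param d_ref reference d-spacing, Angstrom (> 0).
#' @return s values, 1/Angstrom.
#' @export
calibrate_axis <- function(raw_channels, ref_peak_channel, d_ref = 48.8) {
  if (d_ref <= 0) stop("d_ref must be positive")
  stopifnot(ref_peak_channel > 0)
  raw_channels * (1 / d_ref) / ref_peak_channel
}

# prominence of each local maximum: height above the higher of the two
# valley minima separating it from higher ground
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p)]
    higher_l <- which(left > y[p])
    base_l <- if (length(higher_l)) min(left[max(higher_l):p]) else min(left)
    right <- y[p:length(y)]
    higher_r <- which(right > y[p])
    base_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    y[p] - max(base_l, base_r)
  }, numeric(1))
}

#' Detect reflections in a scattering curve
#'
#' Local maxima after light smoothing (5-point running mean) whose
#' prominence exceeds `min_prominence` of the curve's dynamic range;
#' positions are refined by a 3-point parabolic interpolation for
#' sub-bin accuracy.
#'
#' @param curve a [scattering_curve()].
#' @param min_prominence required prominence as a fraction of
#'   `max(intensity) - min(intensity)` (default 0.05).
#' @return numeric vector of peak positions (1/Angstrom), increasing;
#'   empty (with a warning) if no peak qualifies.
#' @export
find_reflections <- function(curve, min_prominence = 0.05,
                             smooth_window = 9) {
  stopifnot(inherits(curve, "scattering_curve"))
  y <- as.numeric(stats::filter(curve$intensity,
                                rep(1 / smooth_window, smooth_window),
                                sides = 2))
  y[is.na(y)] <- curve$intensity[is.na(y)]
  n <- length(y)
  half_w <- (smooth_window - 1L) %/% 2L
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  # candidates inside the smoothing margin cannot be localized reliably
  cand <- cand[cand > half_w + 1L & cand < n - half_w]
  if (length(cand)) {
    prom <- peak_prominence(y, cand)
    cand <- cand[prom >= min_prominence * (max(y) - min(y))]
  }
  if (!length(cand)) {
    warning("no reflections found above the prominence threshold")
    return(numeric(0))
  }
  ds <- curve$s[2] - curve$s[1]
  pos <- vapply(cand, function(p) {
    # sub-bin refinement: least-squares parabola on the raw intensities
    # over +/- refine_w bins (clipped halfway to the nearest candidate)
    refine_w <- 12L
    gap <- diff(sort(c(1L, cand, n)))
    refine_w <- min(refine_w, max(2L, min(gap[gap > 0]) %/% 2L))
    w <- max(1, p - refine_w):min(n, p + refine_w)
    co <- stats::coef(stats::lm(curve$intensity[w] ~ poly(w, 2,
                                                          raw = TRUE)))
    vertex <- if (is.finite(co[3]) && co[3] < 0) -co[2] / (2 * co[3]) else p
    if (abs(vertex - p) > refine_w / 2) vertex <- p
    curve$s[1] + (vertex - 1) * ds
  }, numeric(1))
  sort(pos)
}

#' Index reflections as lamellar orders and extract the d-spacing
#'
#' Assigns order `n = round(s_n / s_1)` to each reflection, computes
#' `d = mean(n / s_n)` and the indexing residual
#' `max |s_n / (n s_1) - 1|`. A residual above 2% flags the pattern as
#' non-lamellar (the 1:2:3 spacing ratio does not hold).
#'
#' @param peaks reflection positions, 1/Angstrom (>= 1 peak, smallest
#'   first-order).
#' @return object of class `lamellar_indexing`: list with
#'   `peak_positions`, `orders`, `d_spacing` (Angstrom),
#'   `ratio_residual`, `lamellar` flag.
#' @export
index_lamellar <- function(peaks) {
  if (!length(peaks)) stop("need at least one reflection to index")
  peaks <- sort(peaks)
  orders <- pmax(1L, as.integer(round(peaks / peaks[1])))
  d <- mean(orders / peaks)
  residual <- max(abs(peaks / (orders * peaks[1]) - 1))
  structure(list(peak_positions = peaks, orders = orders, d_spacing = d,
                 ratio_residual = residual, lamellar = residual <= 0.02),
            class = "lamellar_indexing")
}

#' @export
print.lamellar_indexing <- function(x, ...) {
  cat(sprintf("lamellar indexing: d = %.1f Angstrom from %d reflection(s) (orders %s)\n",
              x$d_spacing, length(x$peak_positions),
              paste(x$orders, collapse = ":")))
  if (!x$lamellar)
    cat(sprintf("WARNING: ratio residual %.1f%% > 2%% - not a lamellar 1:2:3 pattern\n",
                100 * x$ratio_residual))
  invisible(x)
}
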