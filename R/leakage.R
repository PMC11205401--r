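# Carboxyfluorescein leakage quantification and trace summaries.

#' Construct a leakage trace
#'
#' A fluorescence time series with its calibration: `f_i` the initial
#' fluorescence before solute injection and `f_d` the maximum after
#' detergent (Triton X-100) lysis, which defines 100% leakage.
#'
#' @param t time, s (strictly increasing).
#' @param f_t fluorescence readings.
#' @param f_i initial fluorescence.
#' @param f_d post-detergent maximum fluorescence (> `f_i`).
#' @param label composition / dose tag.
#' @return object of class `leakage_trace`.
#' @export
leakage_trace <- function(t, f_t, f_i, f_d, label = "") {
  stopifnot(length(t) == length(f_t), all(diff(t) > 0))
  if (f_d <= f_i) stop("invalid calibration: f_d must exceed f_i")
  structure(list(t = as.numeric(t), f_t = as.numeric(f_t),
                 f_i = f_i, f_d = f_d, label = label),
            class = "leakage_trace")
}

#' Percentage of dye leakage
#'
#' `100 * (f_t - f_i) / (f_d - f_i)`. The result is affine-invariant in
#' the fluorescence scale and equals 0 at `f_t = f_i`, 100 at
#' `f_t = f_d`. Values outside `[0, 100]` (noise, photobleaching) are
#' returned unchanged but flagged via the `"out_of_range"` attribute.
#'
#' @param f_t fluorescence at time t (vectorized).
#' @param f_i initial fluorescence.
#' @param f_d post-detergent maximum (> `f_i`).
#' @return percentage(s); attribute `out_of_range` is a logical vector
#'   marking points outside the calibrated range.
#' @export
percent_leakage <- function(f_t, f_i, f_d) {
  if (f_d <= f_i) stop("invalid calibration: f_d must exceed f_i")
  pct <- 100 * (f_t - f_i) / (f_d - f_i)
  oor <- pct < 0 | pct > 100
  if (any(oor))
    warning(sum(oor), " point(s) outside the calibrated [0, 100]% range")
  attr(pct, "out_of_range") <- oor
  pct
}

#' Summarize a leakage time course
#'
#' Reports the leakage extent at a requested time (nearest sample), the
#' initial rate (linear fit of % leakage over the first decile of
#' samples, at least 5 points) and a plateau estimate (mean over the
#' final decile).
#'
#' @param trace a [leakage_trace()].
#' @param t_report time at which to report the extent, s (within the
#'   observed range).
#' @return list of class `leakage_summary` with `extent_percent`,
#'   `t_report`, `initial_rate` (%/s), `plateau_percent`, `label`.
#' @export
summarize_trace <- function(trace, t_report) {
  stopifnot(inherits(trace, "leakage_trace"))
  n <- length(trace$t)
  if (n < 10) stop("need at least 10 samples to summarize a trace")
  if (t_report < 0 || t_report > max(trace$t))
    stop("t_report outside the observed time range")
  pct <- suppressWarnings(percent_leakage(trace$f_t, trace$f_i, trace$f_d))
  i_rep <- which.min(abs(trace$t - t_report))
  n_head <- max(5L, ceiling(0.1 * n))
  head_fit <- stats::lm(pct[seq_len(n_head)] ~ trace$t[seq_len(n_head)])
  n_tail <- max(1L, floor(0.1 * n))
  structure(list(extent_percent = as.numeric(pct[i_rep]),
                 t_report = trace$t[i_rep],
                 initial_rate = stats::coef(head_fit)[[2]],
                 plateau_percent = mean(pct[(n - n_tail + 1L):n]),
                 label = trace$label),
            class = "leakage_summary")
}

#' @export
print.leakage_summary <- function(x, ...) {
  cat(sprintf("leakage [%s]: %.1f%% at t = %.0f s; initial rate %.3g %%/s; plateau %.1f%%\n",
              x$label, x$extent_percent, x$t_report, x$initial_rate,
              x$plateau_percent))
  invisible(x)
}

#' Read / write leakage traces as CSV
#'
#' Two columns `time`, `fluorescence`; the calibration (`f_i`, `f_d`)
#' and label travel in `# key: value` header comment lines.
#'
#' @param trace a [leakage_trace()] to write.
#' @param path CSV path.
#' @return the reader returns a `leakage_trace`; the writer returns
#'   `path` invisibly.
#' @export
write_leakage_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# f_i: %.10g", trace$f_i),
               sprintf("# f_d: %.10g", trace$f_d),
               sprintf("# label: %s", trace$label),
               "time,fluorescence"), con)
  utils::write.table(data.frame(trace$t, trace$f_t), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_leakage_csv
#' @export
read_leakage_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: *", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  leakage_trace(t = df$time, f_t = df$fluorescence,
                f_i = as.numeric(get("f_i")), f_d = as.numeric(get("f_d")),
                label = get("label"))
}
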