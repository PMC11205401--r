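# Saturating membrane-partition isotherm: absorbance quantitation and
# nonlinear fit of r_mem = r_sat * x / (r_50 + x).

#' Solute concentration from absorbance
#'
#' Beer-Lambert quantitation of the solute at 450 nm after ethanol
#' addition: `c = a450 / (epsilon450 * path_length) * dilution_factor`,
#' in mM. The default molar extinction coefficient is 2.86 mM^-1 cm^-1
#' (cryptotanshinone at 450 nm in 4:1 ethanol/buffer).
#'
#' @param a450 absorbance at 450 nm (>= 0).
#' @param path_length cuvette path, cm (> 0).
#' @param dilution_factor fold dilution applied before reading (>= 1).
#' @param epsilon450 molar extinction coefficient, mM^-1 cm^-1.
#' @return concentration in mM.
#' @examples
#' concentration_from_absorbance(2.86)             # 1 mM
#' concentration_from_absorbance(0.572, dilution_factor = 5)  # 1 mM
#' @export
concentration_from_absorbance <- function(a450, path_length = 1,
                                          dilution_factor = 1,
                                          epsilon450 = 2.86) {
  stopifnot(all(a450 >= 0), path_length > 0, dilution_factor >= 1,
            epsilon450 > 0)
  a450 / (epsilon450 * path_length) * dilution_factor
}

#' Predict the partition isotherm
#'
#' The saturating hyperbola `r_mem(x) = r_sat * x / (r_50 + x)`:
#' monotone nondecreasing in x, bounded above by `r_sat`, with
#' `r_mem(r_50) = r_sat / 2`.
#'
#' @param iso a `partition_isotherm` (from [fit_isotherm()]) or a list
#'   with elements `r_sat`, `r_50`.
#' @param x total solute / lipid molar ratio(s), >= 0.
#' @return predicted membrane molar ratio(s).
#' @export
predict_isotherm <- function(iso, x) {
  if (any(x < 0)) stop("x must be non-negative")
  iso$r_sat * x / (iso$r_50 + x)
}

#' Fit the saturating partition isotherm
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `r_mem = r_sat * x / (r_50 + x)`, with starting values from the
#' double-reciprocal linearization `1/r_mem = (r_50 / r_sat) (1/x) +
#' 1/r_sat`. When `weights = "sd"` and the dataset carries a
#' `replicate_sd` column, points are weighted by `1 / sd^2`; the
#' default is unweighted.
#'
#' @param data data.frame with columns `x` and `r_mem` (optionally
#'   `replicate_sd`), e.g. from [gen_partition_data()].
#' @param weights `"none"` (default) or `"sd"`.
#' @return object of class `partition_isotherm`: list with `r_sat`,
#'   `r_50`, `r_sat_se`, `r_50_se`, `residual_ss`, and the underlying
#'   `fit`.
#' @export
fit_isotherm <- function(data, weights = c("none", "sd")) {
  weights <- match.arg(weights)
  stopifnot(all(c("x", "r_mem") %in% names(data)))
  if (length(unique(data$x)) < 3)
    stop("need >= 3 distinct x values to fit the isotherm")
  start <- isotherm_start(data$x, data$r_mem)
  w <- if (weights == "sd") {
    if (is.null(data$replicate_sd))
      stop("weights = 'sd' requires a replicate_sd column")
    1 / data$replicate_sd^2
  } else rep(1, nrow(data))
  fit <- minpack.lm::nlsLM(
    r_mem ~ r_sat * x / (r_50 + x),
    data = data, start = start, weights = w,
    lower = c(r_sat = 1e-12, r_50 = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- summary(fit)$coefficients
  structure(list(r_sat = co["r_sat", "Estimate"],
                 r_50 = co["r_50", "Estimate"],
                 r_sat_se = co["r_sat", "Std. Error"],
                 r_50_se = co["r_50", "Std. Error"],
                 residual_ss = sum(stats::resid(fit)^2),
                 fit = fit),
            class = "partition_isotherm")
}

# double-reciprocal starting values; robust fallback if degenerate
isotherm_start <- function(x, r) {
  ok <- x > 0 & r > 0
  if (sum(ok) >= 2) {
    lf <- stats::lm(I(1 / r[ok]) ~ I(1 / x[ok]))
    r_sat0 <- 1 / stats::coef(lf)[[1]]
    r_500 <- stats::coef(lf)[[2]] * r_sat0
    if (is.finite(r_sat0) && is.finite(r_500) && r_sat0 > 0 && r_500 > 0)
      return(list(r_sat = r_sat0, r_50 = r_500))
  }
  list(r_sat = max(r) * 1.2 + 1e-6, r_50 = stats::median(x[x > 0]))
}

#' @export
print.partition_isotherm <- function(x, ...) {
  cat(sprintf("partition isotherm: r_sat = %.4g +/- %.2g, r_50 = %.4g +/- %.2g\n",
              x$r_sat, x$r_sat_se, x$r_50, x$r_50_se))
  cat(sprintf("residual sum of squares: %.4g\n", x$residual_ss))
  invisible(x)
}

#' Read / write partition datasets as CSV
#'
#' Columns `x`, `r_mem` and optionally `replicate_sd`.
#'
#' @param data data.frame to write.
#' @param path CSV path.
#' @return `read_partition_csv` returns the data.frame; the writer
#'   returns `path` invisibly.
#' @export
write_partition_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition_csv
#' @export
read_partition_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "r_mem") %in% names(df)))
  df
}
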