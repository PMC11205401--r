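# Physical constants and unit conversions used throughout.
# Internal conventions: lengths nm, times ps, energies kJ/mol.
# Reported conventions: diffusion cm^2/s, free energies kcal/mol.

#' Physical constants and unit conversions
#'
#' Internal unit conventions are nanometres, picoseconds and kJ/mol.
#' Free energies are reported in kcal/mol (1 kcal = 4.184 kJ) and lateral
#' diffusion coefficients in cm^2/s. Because 1 cm^2 = 1e14 nm^2 and
#' 1 s = 1e12 ps, 1 cm^2/s = 100 nm^2/ps.
#'
#' @name units
#' @keywords internal
NULL

# Boltzmann constant in kJ mol^-1 K^-1
KB_KJ <- 0.008314462618

# kcal per kJ
KCAL_PER_KJ <- 1 / 4.184

# amu nm^-3 -> kg m^-3  (1 amu = 1.66053906660e-27 kg; 1 nm^3 = 1e-27 m^3)
AMU_PER_NM3_TO_KG_M3 <- 1.66053906660

#' Convert a diffusion coefficient between cm^2/s and nm^2/ps
#'
#' 1 cm^2/s equals 100 nm^2/ps (1e14 nm^2 per 1e12 ps).
#'
#' @param d numeric diffusion coefficient(s).
#' @param from,to units, one of `"cm2_s"` or `"nm2_ps"`.
#' @return numeric, converted coefficient.
#' @examples
#' convert_diffusion(5.45e-8, "cm2_s", "nm2_ps")  # 5.45e-6
#' @export
convert_diffusion <- function(d, from = c("cm2_s", "nm2_ps"),
                              to = c("nm2_ps", "cm2_s")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(d)
  if (from == "cm2_s") d * 100 else d / 100
}
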