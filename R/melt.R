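# Two-state bimolecular (heterodimer) thermal denaturation.
#
# A + B <-> AB with both peptides at the same total concentration C. Writing
# m for the free concentration of each monomer and d for the dimer,
# m + d = C and Kd(T) = m^2 / d. The melting temperature Tm is DEFINED as
# the temperature where the folded fraction f = d/C equals 1/2 at the stated
# concentration, which fixes Kd(Tm) = C/2; Kd at other temperatures follows
# the integrated van 't Hoff relation with unfolding enthalpy dH > 0.

GAS_CONSTANT_KCAL <- 1.98720425864083e-3 # kcal mol^-1 K^-1

#' Two-state melt parameters
#'
#' @param tm Melting temperature in deg C (folded fraction 1/2 at the stated
#'   concentration).
#' @param dh Van 't Hoff unfolding enthalpy, kcal/mol (> 0).
#' @param total_conc_uM Total concentration of EACH peptide, micromolar.
#' @param folded_mre,unfolded_mre Baseline MRE222 values
#'   (deg cm^2 dmol^-1) of the folded and unfolded states.
#' @param folded_slope,unfolded_slope Optional linear baseline slopes
#'   (MRE per deg C); default 0 (flat baselines).
#' @return Object of class `melt_params`.
#' @export
melt_params <- function(tm, dh = 45, total_conc_uM = 50,
                        folded_mre = -33000, unfolded_mre = -3000,
                        folded_slope = 0, unfolded_slope = 0) {
  if (dh <= 0) stop("dh must be > 0")
  if (total_conc_uM <= 0) stop("total_conc_uM must be > 0")
  structure(list(tm = tm, dh = dh, total_conc_uM = total_conc_uM,
                 folded_mre = folded_mre, unfolded_mre = unfolded_mre,
                 folded_slope = folded_slope, unfolded_slope = unfolded_slope),
            class = "melt_params")
}

# Kd (molar) at temperature T (deg C) under the van 't Hoff relation anchored
# at Kd(Tm) = C/2.
melt_kd <- function(temp_C, params) {
  C <- params$total_conc_uM * 1e-6
  TK <- temp_C + 273.15
  TmK <- params$tm + 273.15
  0.5 * C * exp((params$dh / GAS_CONSTANT_KCAL) * (1 / TmK - 1 / TK))
}

#' Fraction of peptide in the folded dimer
#'
#' Solves the bimolecular equilibrium in closed form at each temperature.
#' Monotonically non-increasing in temperature; equals 1/2 at `tm` by
#' definition; tends to 1 (low T) and 0 (high T).
#'
#' @param temp_C Temperature(s), deg C (vectorized).
#' @param params A [melt_params()].
#' @return Folded fraction in `[0, 1]`.
#' @export
fraction_folded <- function(temp_C, params) {
  stopifnot(inherits(params, "melt_params"))
  C <- params$total_conc_uM * 1e-6
  Kd <- melt_kd(temp_C, params)
  d <- ((2 * C + Kd) - sqrt((2 * C + Kd)^2 - 4 * C^2)) / 2
  pmin(pmax(d / C, 0), 1)
}

#' Simulate a CD melt curve (MRE222 vs temperature)
#'
#' `MRE222(T) = bf(T) + (bu(T) - bf(T)) * (1 - fraction_folded(T))` with the
#' (optionally sloped) folded/unfolded baselines of `params`.
#'
#' @param params A [melt_params()].
#' @param temperatures Ascending temperature grid, deg C.
#' @return Data frame (class `melt_curve`) with columns `temperature_C`,
#'   `mre222`; the peptide concentration is attached as attribute
#'   `total_conc_uM` (used by [tm_second_derivative()] for midpoint
#'   refinement).
#' @export
melt_curve <- function(params, temperatures = seq(5, 90, by = 1)) {
  stopifnot(inherits(params, "melt_params"))
  if (length(temperatures) == 0) stop("empty temperature grid")
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("temperature grid must be strictly ascending")
  }
  f <- fraction_folded(temperatures, params)
  bf <- params$folded_mre + params$folded_slope * temperatures
  bu <- params$unfolded_mre + params$unfolded_slope * temperatures
  out <- data.frame(temperature_C = temperatures,
                    mre222 = bf + (bu - bf) * (1 - f))
  class(out) <- c("melt_curve", "data.frame")
  attr(out, "total_conc_uM") <- params$total_conc_uM
  out
}
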