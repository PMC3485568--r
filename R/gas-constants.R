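#' Physiological and physical constants for blood gas and susceptibility models
#'
#' Container for the constants shared by the oxygen dissociation, blood
#' oxygen content and magnetic susceptibility calculations.  Volume and
#' molar susceptibilities are carried in units of 1e-6 (cgs), matching the
#' values commonly tabulated in the MR physics literature; pressures are in
#' mm Hg throughout the package.
#'
#' @param phi Oxygen-carrying capacity of haemoglobin, ml(O2)/g.
#' @param hb Haemoglobin concentration, g per dl of blood.
#' @param epsilon Solubility of oxygen in blood plasma, ml/(dl blood * mm Hg).
#' @param dchi_oxy Volume susceptibility of fully oxygenated haemoglobin
#'   relative to water, in 1e-6 cgs units (negative: diamagnetic).
#' @param dchi_deoxy Volume susceptibility of fully deoxygenated haemoglobin
#'   relative to water, in 1e-6 cgs units (positive: paramagnetic).
#' @param chi_m_o2 Molar susceptibility of O2 gas, 1e-6 cm^3/mol (cgs).
#' @param chi_m_n2 Molar susceptibility of N2 gas, 1e-6 cm^3/mol (cgs).
#' @param v_m Molar volume of an ideal gas at room temperature and
#'   atmospheric pressure, L/mol.
#' @param hct Haematocrit (volume fraction of red cells in blood).
#'
#' @return An object of class `gas_constants`, a named list of the above.
#' @examples
#' const <- gas_constants()
#' const$phi * const$hb   # ml O2 per dl blood when haemoglobin is saturated
#' @export
gas_constants <- function(phi = 1.34, hb = 15, epsilon = 0.0031,
                          dchi_oxy = -0.017, dchi_deoxy = 0.247,
                          chi_m_o2 = 3415, chi_m_n2 = -12,
                          v_m = 24.5, hct = 0.4) {
  stopifnot(
    phi > 0, hb > 0, epsilon > 0,
    dchi_oxy < 0, dchi_deoxy > 0,
    chi_m_o2 > 0, chi_m_n2 < 0,
    v_m > 0, hct > 0, hct < 1
  )
  structure(
    list(phi = phi, hb = hb, epsilon = epsilon,
         dchi_oxy = dchi_oxy, dchi_deoxy = dchi_deoxy,
         chi_m_o2 = chi_m_o2, chi_m_n2 = chi_m_n2,
         v_m = v_m, hct = hct),
    class = "gas_constants"
  )
}

#' @export
print.gas_constants <- function(x, ...) {
  cat("Blood gas / susceptibility constants\n")
  cat(sprintf("  phi      %7.4f ml(O2)/g      hb        %6.2f g/dl\n",
              x$phi, x$hb))
  cat(sprintf("  epsilon  %7.4f ml/(dl mmHg)  hct       %6.2f\n",
              x$epsilon, x$hct))
  cat(sprintf("  dchi_oxy %+7.3f e-6           dchi_deoxy %+6.3f e-6\n",
              x$dchi_oxy, x$dchi_deoxy))
  cat(sprintf("  chi_m(O2) %+6.0f e-6 cm3/mol  chi_m(N2) %+6.0f e-6 cm3/mol\n",
              x$chi_m_o2, x$chi_m_n2))
  cat(sprintf("  v_m      %7.2f L/mol\n", x$v_m))
  invisible(x)
}
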