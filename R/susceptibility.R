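#' Volume susceptibility of oxygen dissolved in blood plasma
#'
#' The dissolved oxygen content `epsilon * PaO2` (ml O2 per dl blood) is an
#' equivalent gas volume fraction of `epsilon * PaO2 / 100` (the explicit
#' dl-to-ml bridge), and pure O2 gas has volume susceptibility
#' `chi_m(O2) / V_m`.  The product is the (paramagnetic, positive)
#' contribution of plasma-dissolved oxygen to blood volume susceptibility,
#' linear in PaO2.
#'
#' @param pao2 Arterial PO2 in mm Hg (non-negative; vectorised).
#' @param const A [gas_constants()] object.
#' @return Volume susceptibility in 1e-6 cgs units.
#' @examples
#' dissolved_o2_chi(110)  # ~0.0005e-6 at normoxia
#' dissolved_o2_chi(500)  # ~0.0022e-6 at hyperoxia
#' @export
dissolved_o2_chi <- function(pao2, const = gas_constants()) {
  stopifnot(all(pao2 >= 0))
  # chi_m_o2 [1e-6 cm^3/mol] / (v_m [L/mol] * 1000 [cm^3/L]) = chi per unit
  # gas volume fraction; epsilon*pao2 [ml/dl] / 100 = volume fraction
  (const$chi_m_o2 / (const$v_m * 1000)) * (const$epsilon * pao2 / 100)
}

#' Blood susceptibility change from a haemoglobin saturation change
#'
#' A saturation increase `delta_y` makes whole blood less paramagnetic by
#' `delta_y * (dchi_deoxy - dchi_oxy) * Hct` (the fully-deoxy minus
#' fully-oxy haemoglobin susceptibility difference is 0.264e-6 with the
#' default constants).
#'
#' @param delta_y Change in haemoglobin oxygen saturation (fraction,
#'   |delta_y| <= 1; vectorised).
#' @param const A [gas_constants()] object.
#' @return Volume susceptibility change in 1e-6 cgs units (negative for a
#'   saturation increase).
#' @examples
#' hb_chi_change(0.017)   # arterial side on hyperoxia: ~-0.0018e-6
#' hb_chi_change(0.068)   # venous side on hyperoxia:   ~-0.0072e-6
#' @export
hb_chi_change <- function(delta_y, const = gas_constants()) {
  stopifnot(all(abs(delta_y) <= 1))
  -delta_y * (const$dchi_deoxy - const$dchi_oxy) * const$hct
}

#' Susceptibility change of air when its oxygen fraction changes
#'
#' The balance of the mixture is taken as N2, so
#' `dchi = (fo2_to - fo2_from) * (chi_m(O2) - chi_m(N2)) / V_m`.
#' Relevant to hyperoxia experiments because air spaces (frontal sinus,
#' oral cavity) become more paramagnetic when breathing oxygen-enriched
#' gas, perturbing the field near air-tissue interfaces.
#'
#' @param fo2_from,fo2_to Oxygen fractions of the gas mixture, in `[0, 1]`.
#' @param const A [gas_constants()] object.
#' @return Volume susceptibility change in 1e-6 cgs units.
#' @examples
#' air_chi_change(0.21, 0.60)  # ~0.054e-6
#' @export
air_chi_change <- function(fo2_from, fo2_to, const = gas_constants()) {
  stopifnot(all(fo2_from >= 0 & fo2_from <= 1),
            all(fo2_to >= 0 & fo2_to <= 1))
  (fo2_to - fo2_from) * (const$chi_m_o2 - const$chi_m_n2) /
    (const$v_m * 1000)
}

#' Volume susceptibility of blood relative to water/tissue
#'
#' Linear mix of the oxy- and deoxyhaemoglobin contributions, scaled by
#' haematocrit: `Hct * (y * dchi_oxy + (1 - y) * dchi_deoxy)`.  Strictly
#' decreasing in saturation `y`.  Tissue and blood plasma are assumed to
#' share the susceptibility of water, so this is also blood's
#' susceptibility relative to tissue -- the quantity whose
#' hyperoxia:normoxia ratio drives the phase-based OEF estimate.
#'
#' @param y Haemoglobin oxygen saturation fraction in `[0, 1]` (vectorised).
#' @param const A [gas_constants()] object.
#' @return Volume susceptibility in 1e-6 cgs units.
#' @examples
#' blood_chi(0.6)   # venous blood at OEF 0.4: ~0.035e-6
#' blood_chi(1.0)   # fully oxygenated: Hct * dchi_oxy
#' @export
blood_chi <- function(y, const = gas_constants()) {
  stopifnot(all(y >= 0 & y <= 1))
  const$hct * (y * const$dchi_oxy + (1 - y) * const$dchi_deoxy)
}

#' Hyperoxia susceptibility error budget
#'
#' Collects the arterial-side susceptibility perturbations that hyperoxia
#' introduces alongside the venous effect the method relies on: the
#' arterial haemoglobin saturation increase (diamagnetic shift), the
#' plasma-dissolved oxygen increase (paramagnetic shift), the venous
#' saturation change itself, and the air-space change.  All values in
#' 1e-6 cgs units.
#'
#' @param pao2_baseline,pao2_hyper Normoxic and hyperoxic PaO2, mm Hg.
#' @param oef Assumed resting oxygen extraction fraction.
#' @param fo2_from,fo2_to Inspired oxygen fractions at the two gas levels.
#' @param const A [gas_constants()] object.
#' @return Data frame with columns `quantity`, `value`, `units`.
#' @export
susceptibility_budget <- function(pao2_baseline = 110, pao2_hyper = 500,
                                  oef = 0.4, fo2_from = 0.21, fo2_to = 0.60,
                                  const = gas_constants()) {
  dsa <- sa_o2(pao2_hyper) - sa_o2(pao2_baseline)
  dyv <- venous_state(pao2_hyper, oef, pao2_baseline, const)$yv -
    venous_state(pao2_baseline, oef, pao2_baseline, const)$yv
  data.frame(
    quantity = c(
      "arterial saturation increase (dSaO2)",
      "arterial Hb susceptibility change",
      "dissolved O2 chi at baseline",
      "dissolved O2 chi at hyperoxia",
      "dissolved O2 chi increase",
      "venous saturation increase (dYv)",
      "venous Hb susceptibility change",
      sprintf("air susceptibility change (%.0f%% -> %.0f%% O2)",
              100 * fo2_from, 100 * fo2_to)
    ),
    value = c(
      dsa,
      hb_chi_change(dsa, const),
      dissolved_o2_chi(pao2_baseline, const),
      dissolved_o2_chi(pao2_hyper, const),
      dissolved_o2_chi(pao2_hyper, const) -
        dissolved_o2_chi(pao2_baseline, const),
      dyv,
      hb_chi_change(dyv, const),
      air_chi_change(fo2_from, fo2_to, const)
    ),
    units = c("fraction", "1e-6 cgs", "1e-6 cgs", "1e-6 cgs", "1e-6 cgs",
              "fraction", "1e-6 cgs", "1e-6 cgs")
  )
}
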