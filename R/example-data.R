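#' Published per-subject results bundled as worked-example inputs
#'
#' Two small tables of group-study results from a 7 T dual-gas motor
#' experiment, shipped as plain text under `extdata`.  `"bold_roi"` holds
#' per-subject rvCBV, q_act and dY_act for the BOLD-activation ROI;
#' `"combined"` holds, for the subjects with an ASL flow measurement, the
#' rCBF, q_act and rCMRO2 values under both an assumed Q0 of 0.4 and the
#' phase-measured Q0.  They serve as regression anchors for the
#' arithmetic identities (Fick's principle, dY_act = -Q0 q_act, Q0
#' rescaling), not as raw data: percent columns are percent, `dy_act` and
#' `q0_measured` are fractions.
#'
#' @param which `"bold_roi"` or `"combined"`.
#' @return A data frame.
#' @examples
#' tab <- example_results("combined")
#' fick_rcmro2(tab$q_act_assumed_pct / 100, tab$rcbf_pct / 100)$rcmro2
#' @export
example_results <- function(which = c("bold_roi", "combined")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("motor_study_", if (which == "bold_roi")
                     "bold_roi" else "combined", ".tsv"),
                   package = "hoxcal", mustWork = TRUE)
  utils::read.delim(f, sep = "\t", header = TRUE)
}
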