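#' ROI calibration pipeline: timecourse to calibration fit
#'
#' Runs the standard conditioning chain on a raw ROI timecourse --
#' baseline masking, linear detrending, normalisation to the normoxic
#' baseline, per-trial rest/active averaging -- then assembles the
#' per-trial calibration points and fits the two-condition regression.
#'
#' @param tc A raw [roi_timecourse()] (motion-corrected signal).
#' @param paradigm A [paradigm()].
#' @param contrast Per-block gas contrast from [hyperoxia_contrast()] (or
#'   a data frame with `block`, `q_h`).
#' @param te Echo time, seconds.
#' @param qc_keep Optional per-trial keep flags from [petco2_trial_qc()].
#' @param baseline Optional precomputed baseline mask; computed from the
#'   paradigm when `NULL`.
#' @param on_skip,rest_skip,post_trial Window margins in seconds, passed
#'   to [trial_summaries()] and [baseline_mask()].
#' @return A [fit_calibration()] result, with the trial summaries
#'   attached as attribute `summaries`.
#' @export
calibrate_timecourse <- function(tc, paradigm, contrast, te,
                                 qc_keep = NULL, baseline = NULL,
                                 on_skip = 6, rest_skip = 6,
                                 post_trial = 30) {
  if (is.null(baseline))
    baseline <- baseline_mask(paradigm, tc$time_s, post_trial)
  tc <- detrend_linear(tc, baseline)
  tc <- normalise_to_baseline(tc, baseline)
  summ <- trial_summaries(tc, paradigm, qc_keep = qc_keep,
                          on_skip = on_skip, rest_skip = rest_skip)
  pts <- calibration_points(summ, contrast, te)
  fit <- fit_calibration(pts, te)
  attr(fit, "summaries") <- summ
  fit
}

#' End-to-end dual-gas calibration run
#'
#' Orchestrates a complete analysis from file paths or in-memory objects:
#' end-tidal trace to per-block q_h, PCO2 trial QC, BOLD preprocessing and
#' calibration fit, optional phase-based Q0 (rescaling q_act), and
#' optional ASL-based rCBF and Fick rCMRO2.  Results carry explicit units
#' and the full configuration for provenance.
#'
#' @param bold A [roi_timecourse()] or path to a timecourse TSV.
#' @param endtidal An [endtidal_trace()] or path to an end-tidal TSV.
#' @param paradigm A [paradigm()] or path to a paradigm JSON.
#' @param te Echo time of the BOLD acquisition, seconds.
#' @param q0 Assumed resting OEF; ignored when `phase_profile` is given.
#' @param phase_profile Optional [phase_profile()] (or TSV path): switches
#'   Q0 to the phase-derived estimate.
#' @param asl Optional list with `tag`, `control` (vectors or a TSV path),
#'   `paradigm` (a [paradigm()] or path) and optionally `tr_image`;
#'   enables the rCMRO2 estimate.
#' @param qc_threshold PCO2 excursion threshold, mm Hg.
#' @param const A [gas_constants()] object.
#' @param out_dir Optional directory: results are written as JSON.
#' @return List of class `calibration_run`: `fit`, `contrast`, `qc`,
#'   `q0`, `q0_source`, and when available `rcbf`, `cmro2`.
#' @export
run_calibration <- function(bold, endtidal, paradigm, te = 0.025,
                            q0 = 0.4, phase_profile = NULL, asl = NULL,
                            qc_threshold = 1, const = gas_constants(),
                            out_dir = NULL) {
  if (is.character(bold)) bold <- read_timecourse(bold)
  if (is.character(endtidal)) endtidal <- read_endtidal(endtidal)
  if (is.character(paradigm)) paradigm <- read_paradigm(paradigm)

  q0_source <- "assumed"
  contrast <- hyperoxia_contrast(endtidal, paradigm, q0 = q0,
                                 const = const)
  if (!is.null(phase_profile)) {
    if (is.character(phase_profile))
      phase_profile <- read_phase_profile(phase_profile)
    hyper <- contrast$label == "hyperoxia"
    dq_h <- mean(contrast$dq_h[hyper])   # OEF-independent
    ratio <- fit_phase_ratio(phase_profile)
    q0 <- q0_from_ratio(ratio$a, dq_h, const)
    q0_source <- "phase"
    contrast <- hyperoxia_contrast(endtidal, paradigm, q0 = q0,
                                   const = const)
  }

  qc <- petco2_trial_qc(endtidal, paradigm, threshold = qc_threshold)
  fit <- calibrate_timecourse(bold, paradigm, contrast, te,
                              qc_keep = qc)

  out <- list(fit = fit, contrast = contrast, qc = qc, q0 = q0,
              q0_source = q0_source, te = te)
  if (!is.null(asl)) {
    if (is.character(asl$tag)) {
      streams <- read_asl(asl$tag)
      asl$tag <- streams$tag; asl$control <- streams$control
    }
    if (is.character(asl$paradigm))
      asl$paradigm <- read_paradigm(asl$paradigm)
    tri <- if (is.null(asl$tr_image)) 3 else asl$tr_image
    flow <- asl_rcbf(asl$tag, asl$control, asl$paradigm, tr_image = tri)
    out$rcbf <- flow$rcbf
    out$cmro2 <- fick_rcmro2(fit$q_act, flow$rcbf)
  }
  class(out) <- "calibration_run"
  if (!is.null(out_dir)) write_calibration_run(out, out_dir)
  out
}

#' @export
print.calibration_run <- function(x, ...) {
  cat(sprintf("Dual-gas calibration run (Q0 = %.3f, %s)\n",
              x$q0, x$q0_source))
  print(x$fit)
  if (!all(x$qc))
    cat("  discarded trials (PCO2 QC): ",
        paste(names(x$qc)[!x$qc], collapse = ", "), "\n", sep = "")
  if (!is.null(x$cmro2))
    cat(sprintf("  rCBF = %.1f%%  ->  rCMRO2 = %.1f%%\n",
                100 * x$rcbf, 100 * x$cmro2$rcmro2))
  invisible(x)
}
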