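#' End-tidal gas trace
#'
#' A validated table of end-tidal partial pressures over time.  End-tidal
#' PO2 is used throughout the package as a direct surrogate for arterial
#' PO2 (a stated model assumption: with sequential gas delivery, end-tidal
#' to arterial gradients are negligible for this purpose).
#'
#' @param times Sample times in seconds from paradigm start (strictly
#'   increasing).
#' @param peto2 End-tidal PO2 in mm Hg (positive).
#' @param petco2 End-tidal PCO2 in mm Hg (positive).
#'
#' @return A data frame of class `endtidal_trace` with columns `time_s`,
#'   `peto2_mmHg`, `petco2_mmHg`.
#' @export
endtidal_trace <- function(times, peto2, petco2) {
  times <- as.numeric(times); peto2 <- as.numeric(peto2)
  petco2 <- as.numeric(petco2)
  if (length(times) != length(peto2) || length(times) != length(petco2))
    stop("times, peto2 and petco2 must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(peto2 <= 0) || any(petco2 <= 0))
    stop("end-tidal pressures must be positive")
  structure(
    data.frame(time_s = times, peto2_mmHg = peto2, petco2_mmHg = petco2),
    class = c("endtidal_trace", "data.frame")
  )
}

#' Arterial haemoglobin oxygen saturation from PaO2
#'
#' Severinghaus-form oxygen dissociation curve at 310 K and pH 7.4:
#' `SaO2 = 1 / (23400 / (PaO2^3 + 150 PaO2) + 1)`.
#' Strictly increasing in PaO2 and bounded in (0, 1).
#'
#' @param pao2 Arterial oxygen partial pressure, mm Hg (positive; vectorised).
#' @return Saturation fraction(s) in (0, 1).
#' @examples
#' sa_o2(110)           # ~0.983 at normoxia
#' sa_o2(500) - sa_o2(110)  # ~0.017: arterial Hb is nearly saturated already
#' @export
sa_o2 <- function(pao2) {
  if (any(!is.finite(pao2)) || any(pao2 <= 0))
    stop("pao2 must be positive and finite")
  1 / (23400 / (pao2^3 + 150 * pao2) + 1)
}

#' Total arterial blood oxygen content
#'
#' Sum of haemoglobin-bound and plasma-dissolved oxygen:
#' `CaO2 = phi * [Hb] * SaO2(PaO2) + epsilon * PaO2`, in ml(O2)/dl blood.
#' On hyperoxia nearly all of the additional oxygen travels dissolved in
#' plasma, since haemoglobin is close to saturation at normoxia.
#'
#' @inheritParams sa_o2
#' @param const A [gas_constants()] object.
#' @return Oxygen content(s), ml(O2) per dl of blood.
#' @examples
#' ca_o2(110)               # ~20.1 ml/dl
#' ca_o2(500) - ca_o2(110)  # ~1.55 ml/dl extra, mostly dissolved
#' @export
ca_o2 <- function(pao2, const = gas_constants()) {
  const$phi * const$hb * sa_o2(pao2) + const$epsilon * pao2
}

#' Venous oxygenation state implied by PaO2 and a fixed oxygen extraction
#'
#' The absolute oxygen extraction `OE = CaO2(baseline) * OEF` is assumed
#' independent of the inspired oxygen level, so the venous oxygen content is
#' `CvO2 = CaO2(PaO2) - OE`, and (neglecting dissolved oxygen on the venous
#' side, which is far from saturation) the venous haemoglobin saturation is
#' `Yv = CvO2 / (phi * [Hb])`.  The venous deoxyhaemoglobin fraction is
#' `Q = 1 - Yv`; at the baseline PaO2 this reduces to `Yv ~ 1 - OEF` up to
#' the small dissolved-oxygen term.
#'
#' @inheritParams ca_o2
#' @param oef Resting oxygen extraction fraction in (0, 1); numerically
#'   equal to the resting venous deoxyhaemoglobin fraction Q0.
#' @param baseline_pao2 Normoxic baseline PaO2 in mm Hg.
#' @return An object of class `oxygenation_state`: list with vector fields
#'   `pao2`, `sao2`, `cao2` (ml/dl), `yv`, `q` (fractions, `yv + q = 1`).
#' @examples
#' venous_state(110)$yv                      # ~0.600 for OEF = 0.4
#' venous_state(440)$yv - venous_state(110)$yv   # ~0.068
#' @export
venous_state <- function(pao2, oef = 0.4, baseline_pao2 = 110,
                         const = gas_constants()) {
  if (any(oef <= 0) || any(oef >= 1)) stop("oef must lie in (0, 1)")
  oe <- ca_o2(baseline_pao2, const) * oef
  cao2 <- ca_o2(pao2, const)
  yv <- (cao2 - oe) / (const$phi * const$hb)
  if (any(yv <= 0) || any(yv >= 1))
    stop("infeasible physiology: venous saturation outside (0, 1) ",
         "(yv = ", paste(signif(yv, 4), collapse = ", "), ")")
  structure(
    list(pao2 = pao2, sao2 = sa_o2(pao2), cao2 = cao2, yv = yv, q = 1 - yv),
    class = "oxygenation_state"
  )
}

#' @export
print.oxygenation_state <- function(x, ...) {
  df <- data.frame(pao2_mmHg = x$pao2, sao2 = round(x$sao2, 4),
                   cao2_ml_dl = round(x$cao2, 3),
                   yv = round(x$yv, 4), q = round(x$q, 4))
  cat("Oxygenation state (venous side from level-independent extraction)\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-block hyperoxia deoxyhaemoglobin contrast from an end-tidal trace
#'
#' For each gas block of the paradigm, PaO2 is taken as the mean end-tidal
#' PO2 over the block's steady-state window (by default the final 120 s,
#' clamped to the block length).  The absolute change in venous
#' deoxyhaemoglobin fraction relative to the pooled normoxic baseline,
#' `dQ_h = Q(block) - Q(baseline)`, is independent of the assumed OEF;
#' the relative change `q_h = dQ_h / Q0` scales inversely with the assumed
#' resting deoxyhaemoglobin fraction `q0`.  Normoxic blocks are assigned
#' `q_h = 0` by construction.
#'
#' @param trace An [endtidal_trace()].
#' @param paradigm A [make_paradigm()] object (or any paradigm with a
#'   `blocks` table).
#' @param q0 Assumed resting venous deoxyhaemoglobin fraction (= OEF).
#' @param window Steady-state window length per block, seconds.
#' @param const A [gas_constants()] object.
#' @return Data frame with one row per gas block: `block`, `label`, `pao2`,
#'   `yv`, `dq_h`, `q_h`; attributes `q0` and `baseline_pao2`.
#' @export
hyperoxia_contrast <- function(trace, paradigm, q0 = 0.4, window = 120,
                               const = gas_constants()) {
  stopifnot(inherits(trace, "endtidal_trace"))
  if (q0 <= 0 || q0 >= 1) stop("q0 must lie in (0, 1)")
  blocks <- paradigm$blocks
  block_po2 <- vapply(seq_len(nrow(blocks)), function(i) {
    w0 <- max(blocks$start[i], blocks$end[i] - window)
    sel <- trace$time_s >= w0 & trace$time_s < blocks$end[i]
    if (!any(sel))
      stop("no end-tidal samples in the steady-state window of block ", i)
    mean(trace$peto2_mmHg[sel])
  }, numeric(1))

  norm <- blocks$label == "normoxia"
  if (!any(norm)) stop("paradigm has no normoxic block to define a baseline")
  baseline_pao2 <- mean(block_po2[norm])

  yv_base <- venous_state(baseline_pao2, oef = q0,
                          baseline_pao2 = baseline_pao2, const = const)$yv
  yv_blk <- vapply(block_po2, function(p)
    venous_state(p, oef = q0, baseline_pao2 = baseline_pao2,
                 const = const)$yv, numeric(1))
  dq_h <- -(yv_blk - yv_base)       # Q = 1 - Yv
  dq_h[norm] <- 0                   # exact zero at baseline by construction
  out <- data.frame(block = blocks$block, label = blocks$label,
                    pao2 = block_po2, yv = yv_blk,
                    dq_h = dq_h, q_h = dq_h / q0)
  attr(out, "q0") <- q0
  attr(out, "baseline_pao2") <- baseline_pao2
  out
}

#' Flag motor trials contaminated by end-tidal CO2 excursions
#'
#' CO2 is vasoactive, so trials during which end-tidal PCO2 strayed from
#' the normocapnic reference by more than `threshold` (default 1 mm Hg) are
#' discarded from the calibration.  The reference is the mean end-tidal
#' PCO2 over baseline timepoints (normoxia, away from recent trials).
#'
#' @inheritParams hyperoxia_contrast
#' @param threshold Maximum tolerated |PCO2 - reference| within a trial,
#'   mm Hg.
#' @return Logical vector, one element per paradigm trial: `TRUE` = keep.
#'   A trial window containing no gas samples is discarded with a warning.
#'   Attribute `reference` holds the normocapnia value used.
#' @export
petco2_trial_qc <- function(trace, paradigm, threshold = 1) {
  stopifnot(inherits(trace, "endtidal_trace"))
  base <- baseline_mask(paradigm, trace$time_s)
  if (!any(base)) stop("no baseline timepoints available for a reference")
  ref <- mean(trace$petco2_mmHg[base])
  trials <- paradigm$trials
  keep <- vapply(seq_len(nrow(trials)), function(i) {
    t0 <- trials$on_start[i]
    t1 <- t0 + trials$on_s[i] + trials$off_s[i]
    sel <- trace$time_s >= t0 & trace$time_s < t1
    if (!any(sel)) {
      warning("trial ", trials$trial[i],
              " has no end-tidal samples; discarding")
      return(FALSE)
    }
    all(abs(trace$petco2_mmHg[sel] - ref) <= threshold)
  }, logical(1))
  names(keep) <- trials$trial
  attr(keep, "reference") <- ref
  keep
}
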