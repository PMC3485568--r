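#' Construct a paradigm from explicit block and trial tables
#'
#' A paradigm couples a gas schedule (ordered, non-overlapping blocks
#' labelled `"normoxia"` or `"hyperoxia"`) with a motor-trial schedule
#' (visually cued tapping: `on_s` seconds of stimulation followed by
#' `off_s` seconds of rest).  Trials whose stimulation or rest window is
#' compromised (e.g. by a gas transition) are marked unusable and excluded
#' from calibration, but they still happened: the simulator and the
#' baseline definition honour them.
#'
#' @param blocks Data frame with columns `label` ("normoxia"/"hyperoxia"),
#'   `start`, `end` (seconds).
#' @param trials Data frame with columns `on_start`, `on_s`, `off_s`
#'   (seconds) and optionally `usable` (logical, default all `TRUE`).
#' @param tr Repetition time of the accompanying acquisition, seconds.
#' @param variant Free-form tag (e.g. "A", "B").
#'
#' @return An object of class `paradigm`: list with `variant`, `tr`,
#'   `blocks` (adds `block` ids), `trials` (adds `trial` ids and the
#'   containing `block`), `duration`.
#' @export
paradigm <- function(blocks, trials, tr = 2.4, variant = "custom") {
  stopifnot(is.data.frame(blocks), is.data.frame(trials), tr > 0)
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  if (any(blocks$end <= blocks$start)) stop("blocks must have end > start")
  if (nrow(blocks) > 1 &&
      any(blocks$start[-1] < blocks$end[-nrow(blocks)]))
    stop("blocks must not overlap")
  if (!all(blocks$label %in% c("normoxia", "hyperoxia")))
    stop("block labels must be 'normoxia' or 'hyperoxia'")
  blocks$block <- seq_len(nrow(blocks))

  if (is.null(trials$usable)) trials$usable <- rep(TRUE, nrow(trials))
  if (nrow(trials)) {
    trials <- trials[order(trials$on_start), , drop = FALSE]
    trials$trial <- seq_len(nrow(trials))
    # the containing block is defined by the stimulation onset
    idx <- findInterval(trials$on_start, blocks$start)
    if (any(idx < 1) || any(trials$on_start >= blocks$end[idx]))
      stop("every trial onset must fall inside a gas block")
    trials$block <- blocks$block[idx]
    # a usable trial's stimulation window must sit inside one gas level
    bad <- trials$usable &
      (trials$on_start + trials$on_s > blocks$end[idx])
    if (any(bad))
      stop("usable trial(s) ", paste(trials$trial[bad], collapse = ", "),
           " have stimulation crossing a gas transition")
  } else {
    trials$trial <- integer(0); trials$block <- integer(0)
  }
  structure(
    list(variant = variant, tr = tr,
         blocks = blocks[, c("block", "label", "start", "end")],
         trials = trials[, c("trial", "block", "on_start", "on_s", "off_s",
                             "usable")],
         duration = max(blocks$end)),
    class = "paradigm"
  )
}

#' Standard dual-gas motor paradigms
#'
#' Variant "A" (15 min): two repeats of 3 min normoxia followed by 3 min
#' hyperoxia, closing with 3 min of recovery normoxia.  Each of the first
#' four gas blocks carries two 30 s ON / 30 s OFF motor trials placed in
#' its final two minutes, finishing just before the gas transition --
#' 8 trials, 4 per gas level, all usable.
#'
#' Variant "B" (14 min): 2 min normoxia, then two repeats of 2 min
#' hyperoxia plus 4 min normoxia, with evenly spaced motor trials (90 s
#' spacing, 30 s ON / 60 s OFF) superimposed from t = 90 s.  Alternate
#' trials fall at a respiratory transition and are unusable, leaving
#' 4 usable trials (2 per gas level).
#'
#' @param variant `"A"` or `"B"`.
#' @param tr Repetition time, seconds.
#' @return A [paradigm()] object.
#' @examples
#' p <- make_paradigm("A")
#' table(p$blocks$label)
#' sum(p$trials$usable)
#' @export
make_paradigm <- function(variant = c("A", "B"), tr = 2.4) {
  variant <- match.arg(variant)
  if (variant == "A") {
    blocks <- data.frame(
      label = c("normoxia", "hyperoxia", "normoxia", "hyperoxia", "normoxia"),
      start = c(0, 180, 360, 540, 720),
      end   = c(180, 360, 540, 720, 900)
    )
    on_start <- as.vector(outer(c(60, 120), blocks$start[1:4], "+"))
    trials <- data.frame(on_start = sort(on_start), on_s = 30, off_s = 30,
                         usable = TRUE)
  } else {
    blocks <- data.frame(
      label = c("normoxia", "hyperoxia", "normoxia", "hyperoxia", "normoxia"),
      start = c(0, 120, 240, 480, 600),
      end   = c(120, 240, 480, 600, 840)
    )
    on_start <- 90 + 90 * (0:7)
    trials <- data.frame(on_start = on_start, on_s = 30, off_s = 60,
                         usable = rep(c(FALSE, TRUE), 4))
  }
  paradigm(blocks, trials, tr = tr, variant = variant)
}

#' Motor-only paradigm for the separate ASL flow measurement
#'
#' The flow measurement repeats the motor task breathing air: 10 trials of
#' the variant-A timing (30 s ON / 30 s OFF, back to back after a 60 s
#' lead-in) or 8 trials of the variant-B timing (90 s spacing after a 90 s
#' lead-in).  A single normoxic block spans the run.
#'
#' @inheritParams make_paradigm
#' @param tr Image repetition time of the ASL acquisition, seconds (one
#'   tag/control pair spans `2 * tr`).
#' @return A [paradigm()] object with all trials usable.
#' @export
make_asl_paradigm <- function(variant = c("A", "B"), tr = 3) {
  variant <- match.arg(variant)
  if (variant == "A") {
    trials <- data.frame(on_start = 60 + 60 * (0:9), on_s = 30, off_s = 30)
  } else {
    trials <- data.frame(on_start = 90 + 90 * (0:7), on_s = 30, off_s = 60)
  }
  dur <- max(trials$on_start + trials$on_s + trials$off_s)
  blocks <- data.frame(label = "normoxia", start = 0, end = dur)
  paradigm(blocks, trials, tr = tr, variant = paste0("ASL-", variant))
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("Dual-gas motor paradigm '%s': %.0f s, TR = %.2f s\n",
              x$variant, x$duration, x$tr))
  cat(sprintf("  %d gas blocks (%d hyperoxia), %d trials (%d usable)\n",
              nrow(x$blocks), sum(x$blocks$label == "hyperoxia"),
              nrow(x$trials), sum(x$trials$usable)))
  invisible(x)
}
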