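#' ROI timecourse container
#'
#' @param times Sample times, seconds (strictly increasing).
#' @param values Signal values (arbitrary units, or percent change after
#'   [normalise_to_baseline()]).
#' @return Data frame of class `roi_timecourse` with columns `time_s`,
#'   `signal`.
#' @export
roi_timecourse <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(data.frame(time_s = times, signal = values),
            class = c("roi_timecourse", "data.frame"))
}

#' Baseline timepoints of a dual-gas paradigm
#'
#' A timepoint belongs to the baseline if it falls in a normoxic gas block
#' and is not during, or within `post_trial` seconds after, any motor
#' stimulation window.  The baseline anchors detrending, normalisation and
#' the normocapnia reference for trial QC.
#'
#' @param paradigm A [paradigm()] object.
#' @param times Sample times, seconds.
#' @param post_trial Haemodynamic recovery margin after stimulation ends,
#'   seconds.
#' @return Logical vector along `times`.
#' @export
baseline_mask <- function(paradigm, times, post_trial = 30) {
  blocks <- paradigm$blocks
  in_norm <- rep(FALSE, length(times))
  for (i in which(blocks$label == "normoxia"))
    in_norm <- in_norm | (times >= blocks$start[i] & times < blocks$end[i])
  near_trial <- rep(FALSE, length(times))
  tr_tab <- paradigm$trials
  for (i in seq_len(nrow(tr_tab))) {
    t0 <- tr_tab$on_start[i]
    t1 <- t0 + tr_tab$on_s[i] + post_trial
    near_trial <- near_trial | (times >= t0 & times < t1)
  }
  in_norm & !near_trial
}

#' Remove a linear drift fitted to baseline timepoints only
#'
#' Fits `signal ~ time` to the baseline samples and subtracts the fitted
#' line from the whole series, adding back the baseline-mean level so that
#' absolute signal units (and the subsequent normalisation) are preserved.
#' Fitting on the baseline only keeps genuine task and hyperoxia responses
#' out of the drift estimate; a plain high-pass filter would not respect
#' the long gas cycle lengths.
#'
#' @param tc A [roi_timecourse()].
#' @param baseline Logical vector marking baseline samples (from
#'   [baseline_mask()]).
#' @return A `roi_timecourse` with the trend removed.
#' @export
detrend_linear <- function(tc, baseline) {
  stopifnot(inherits(tc, "roi_timecourse"),
            length(baseline) == nrow(tc))
  t_b <- tc$time_s[baseline]
  if (length(unique(t_b)) < 2)
    stop("need at least two distinct baseline timepoints to detrend")
  y_b <- tc$signal[baseline]
  slope <- stats::cov(t_b, y_b) / stats::var(t_b)
  # subtract the fitted line, re-centre on the baseline mean level
  fitted <- mean(y_b) + slope * (tc$time_s - mean(t_b))
  roi_timecourse(tc$time_s, tc$signal - fitted + mean(y_b))
}

#' Express a timecourse as percent change from its normoxic baseline
#'
#' Divides by the mean over baseline samples and converts to percent
#' change, so baseline reads 0 and a hyperoxic plateau of +6.4% reads 6.4.
#'
#' @inheritParams detrend_linear
#' @return A `roi_timecourse` whose `signal` is percent change; attribute
#'   `baseline_mean` holds the divisor.
#' @export
normalise_to_baseline <- function(tc, baseline) {
  stopifnot(inherits(tc, "roi_timecourse"),
            length(baseline) == nrow(tc))
  if (!any(baseline)) stop("no baseline timepoints")
  bm <- mean(tc$signal[baseline])
  if (!is.finite(bm) || bm <= 0)
    stop("baseline mean must be positive to normalise")
  out <- roi_timecourse(tc$time_s, 100 * (tc$signal / bm - 1))
  attr(out, "baseline_mean") <- bm
  out
}

#' Per-trial rest and active signal levels versus the normoxic baseline
#'
#' For every usable (and QC-kept) trial, averages the percent-change
#' signal over the stimulation window and over the rest window that
#' follows it.  The first `on_skip` seconds of stimulation and
#' `rest_skip` seconds after stimulation are excluded so that
#' haemodynamic rise and decay do not contaminate the plateau means, and
#' the rest window is clamped to the trial's gas block so that rest is
#' always read at the trial's own gas level.
#'
#' @param tc A percent-change [roi_timecourse()] (after detrending and
#'   normalisation).
#' @param paradigm A [paradigm()] object.
#' @param qc_keep Optional logical vector from [petco2_trial_qc()]; trials
#'   flagged `FALSE` are excluded.
#' @param on_skip,rest_skip Onset margins, seconds.
#' @return Data frame with one row per contributing trial: `trial`,
#'   `block`, `gas`, `rest_pct`, `act_pct`, `n_on`, `n_rest`.
#' @export
trial_summaries <- function(tc, paradigm, qc_keep = NULL,
                            on_skip = 6, rest_skip = 6) {
  stopifnot(inherits(tc, "roi_timecourse"))
  trials <- paradigm$trials
  blocks <- paradigm$blocks
  use <- trials$usable
  if (!is.null(qc_keep)) {
    stopifnot(length(qc_keep) == nrow(trials))
    use <- use & qc_keep
  }
  if (!any(use)) stop("no usable trials remain after QC")
  rows <- lapply(which(use), function(i) {
    on0 <- trials$on_start[i]
    on1 <- on0 + trials$on_s[i]
    blk_end <- blocks$end[blocks$block == trials$block[i]]
    r0 <- on1 + rest_skip
    r1 <- min(on1 + trials$off_s[i], blk_end)
    on_sel <- tc$time_s >= on0 + on_skip & tc$time_s < on1
    r_sel <- tc$time_s >= r0 & tc$time_s < r1
    if (!any(on_sel) || !any(r_sel))
      stop("trial ", trials$trial[i],
           " has an empty stimulation or rest window at TR = ",
           paradigm$tr)
    data.frame(trial = trials$trial[i], block = trials$block[i],
               gas = blocks$label[blocks$block == trials$block[i]],
               rest_pct = mean(tc$signal[r_sel]),
               act_pct = mean(tc$signal[on_sel]),
               n_on = sum(on_sel), n_rest = sum(r_sel))
  })
  out <- do.call(rbind, rows)
  for (lab in unique(blocks$label[blocks$block %in% trials$block]))
    if (!any(out$gas == lab))
      stop("no usable trials at ", lab, ": calibration impossible")
  out
}

#' Relative CBF change from interleaved ASL tag/control series
#'
#' Tag and control images are acquired alternately, one image every
#' `tr_image` seconds, so each stream is sampled every `2 * tr_image`.
#' Both streams are linearly interpolated onto the single-image grid
#' (edges clamped to the nearest sample), subtracted pairwise into a
#' perfusion-weighted series, normalised by the mean over the last half of
#' every rest period, and averaged over the stimulation windows to give
#' the fractional flow change.
#'
#' @param tag,control Numeric vectors of equal length: the tag and control
#'   image series in acquisition order within each stream.
#' @param paradigm A [paradigm()] describing the motor task (typically
#'   from [make_asl_paradigm()]).
#' @param tr_image Time between consecutive images (tag to control),
#'   seconds.
#' @param tag_first `TRUE` if the first acquired image is a tag.
#' @param on_skip Stimulation onset margin, seconds.
#' @param edge_margin Margin kept clear of every window edge, seconds.
#'   The default `2 * tr_image` (one tag/control pair, the real temporal
#'   resolution) excludes samples whose interpolation anchors straddle a
#'   flow transition.
#' @return List of class `asl_result`: `rcbf` (fraction), `time_s`,
#'   `perfusion` (tag/control difference), `relative` (normalised series).
#' @export
asl_rcbf <- function(tag, control, paradigm, tr_image = 3,
                     tag_first = TRUE, on_skip = 6,
                     edge_margin = 2 * tr_image) {
  if (length(tag) != length(control))
    stop("tag and control series must have equal length")
  n <- length(tag)
  if (n < 2) stop("need at least two tag/control pairs")
  off_tag <- if (tag_first) 0 else tr_image
  off_ctl <- if (tag_first) tr_image else 0
  t_tag <- off_tag + 2 * tr_image * (0:(n - 1))
  t_ctl <- off_ctl + 2 * tr_image * (0:(n - 1))
  grid <- tr_image * (0:(2 * n - 1))
  tag_i <- stats::approx(t_tag, tag, xout = grid, rule = 2)$y
  ctl_i <- stats::approx(t_ctl, control, xout = grid, rule = 2)$y
  perf <- ctl_i - tag_i

  trials <- paradigm$trials[paradigm$trials$usable, , drop = FALSE]
  if (!nrow(trials)) stop("paradigm has no usable trials")
  on_sel <- rep(FALSE, length(grid))
  rest_sel <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(trials))) {
    on0 <- trials$on_start[i]; on1 <- on0 + trials$on_s[i]
    r1 <- on1 + trials$off_s[i] - edge_margin
    r0 <- on1 + trials$off_s[i] / 2          # last half of the rest period
    on_sel <- on_sel |
      (grid >= on0 + max(on_skip, edge_margin) & grid < on1 - edge_margin)
    rest_sel <- rest_sel | (grid >= r0 & grid < r1)
  }
  if (!any(on_sel) || !any(rest_sel))
    stop("no samples in stimulation or rest windows; check tr_image")
  ref <- mean(perf[rest_sel])
  if (!is.finite(ref) || ref == 0)
    stop("rest-period perfusion reference is zero; cannot normalise")
  rel <- perf / ref
  structure(
    list(rcbf = mean(rel[on_sel]) - 1, time_s = grid,
         perfusion = perf, relative = rel),
    class = "asl_result"
  )
}

#' @export
print.asl_result <- function(x, ...) {
  cat(sprintf("ASL perfusion result: rCBF = %.1f%% (%d timepoints)\n",
              100 * x$rcbf, length(x$time_s)))
  invisible(x)
}
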