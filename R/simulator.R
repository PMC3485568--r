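#' Configuration for the paradigm-locked BOLD forward simulator
#'
#' Ground truth is parameterised the way the estimator reports it: the
#' calibration parameters `m` and `m'` (percent signal per unit abscissa),
#' the task deoxyhaemoglobin change `q_act`, and the hyperoxia level
#' `q_h`.  Defaults reconstruct the group-mean operating point of a 7 T
#' motor experiment: M = 36%, M' = 48%, q_act = -0.39, and q_h = -0.17
#' (a venous saturation increase of 0.068 at an assumed Q0 of 0.4),
#' with temporal SNR 161 on the baseline signal.
#'
#' @param variant Paradigm variant, `"A"` or `"B"`.
#' @param tr Repetition time, seconds.
#' @param te Echo time, seconds.
#' @param m,m_prime Rest and active calibration parameters, percent.
#' @param q_act Relative deoxyhaemoglobin change on activation.
#' @param q_h Relative deoxyhaemoglobin change on hyperoxia (negative).
#' @param tsnr Temporal SNR: baseline mean divided by noise SD;
#'   `Inf` for noiseless.
#' @param baseline Baseline signal level, arbitrary units.
#' @param drift Linear drift, percent of baseline per minute.
#' @param onset_tau Exponential time constant of the BOLD response onset,
#'   seconds; 0 for ideal boxcars (the estimator averages plateaus, so
#'   onset shape mainly stresses the window margins).
#' @param signal_model `"linear"` maps relaxation changes to signal as
#'   `S = S0 (1 - TE dR2*)`, the same small-signal approximation the
#'   estimator inverts; `"exponential"` uses `S = S0 exp(-TE dR2*)`.
#' @param n_reps Monte Carlo replicate count.
#' @param seed Master seed; replicate sub-seeds are derived from it by a
#'   counter scheme, so replicates are order-independent.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(variant = "A", tr = 2.4, te = 0.025,
                              m = 36, m_prime = 48, q_act = -0.39,
                              q_h = -0.17, tsnr = 161, baseline = 1000,
                              drift = 0, onset_tau = 0,
                              signal_model = c("linear", "exponential"),
                              n_reps = 10000, seed = 1L) {
  signal_model <- match.arg(signal_model)
  stopifnot(tr > 0, te > 0, m > 0, m_prime > 0, q_act > -1, q_h <= 0,
            tsnr > 0, baseline > 0, onset_tau >= 0, n_reps >= 1)
  structure(
    list(variant = variant, tr = tr, te = te, m = m, m_prime = m_prime,
         q_act = q_act, q_h = q_h, tsnr = tsnr, baseline = baseline,
         drift = drift, onset_tau = onset_tau, signal_model = signal_model,
         n_reps = as.integer(n_reps), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# deterministic sub-seed for replicate `rep` (order-independent; kept
# within 32-bit integer range)
.sub_seed <- function(seed, rep) {
  as.integer((as.double(seed) * 48271 + rep * 16807) %% 2147483647)
}

# noise-free percent-change curve and per-timepoint state for a config
.bold_deterministic <- function(config, paradigm) {
  times <- seq(0, paradigm$duration - config$tr / 2, by = config$tr)
  qh_t <- rep(0, length(times))
  for (i in which(paradigm$blocks$label == "hyperoxia"))
    qh_t[times >= paradigm$blocks$start[i] &
           times < paradigm$blocks$end[i]] <- config$q_h
  act_t <- rep(0, length(times))   # activation weight in [0, 1]
  for (i in seq_len(nrow(paradigm$trials))) {
    on0 <- paradigm$trials$on_start[i]
    on1 <- on0 + paradigm$trials$on_s[i]
    sel <- times >= on0 & times < on1
    if (config$onset_tau > 0)
      act_t[sel] <- 1 - exp(-(times[sel] - on0) / config$onset_tau)
    else act_t[sel] <- 1
  }
  x <- 1 + qh_t
  slope_rest <- config$m / (100 * config$te)
  slope_act <- config$m_prime / (100 * config$te)
  dr2s_rest <- slope_rest * (x - 1)
  dr2s_act <- slope_act * (x + config$q_act) - slope_rest
  dr2s <- dr2s_rest + act_t * (dr2s_act - dr2s_rest)
  pct <- if (config$signal_model == "linear")
    -100 * config$te * dr2s
  else
    100 * (exp(-config$te * dr2s) - 1)
  sig <- config$baseline * (1 + pct / 100) +
    config$baseline * (config$drift / 100) * (times / 60)
  list(times = times, signal = sig)
}

#' Simulate a paradigm-locked ROI BOLD timecourse
#'
#' Builds the noiseless percent-change curve from the forward signal model
#' (rest and active relaxation rates at each gas state), maps it onto a
#' baseline signal level, adds linear drift and white Gaussian noise with
#' SD `baseline / tsnr` (magnitude noise in the high-SNR regime).  In the
#' noiseless limit the full preprocessing and calibration pipeline
#' recovers the ground-truth rvCBV and q_act exactly.
#'
#' @param config A [simulation_config()].
#' @param rep_seed Seed for this realisation (defaults to the config
#'   master seed). Same config and seed give bit-identical output.
#' @param paradigm Optional pre-built [paradigm()]; defaults to
#'   `make_paradigm(config$variant, config$tr)`.
#' @return A [roi_timecourse()].
#' @export
simulate_bold <- function(config, rep_seed = config$seed,
                          paradigm = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(paradigm))
    paradigm <- make_paradigm(config$variant, config$tr)
  det <- .bold_deterministic(config, paradigm)
  sig <- det$signal
  if (is.finite(config$tsnr)) {
    set.seed(rep_seed)
    sig <- sig + stats::rnorm(length(sig), 0,
                              config$baseline / config$tsnr)
  }
  roi_timecourse(det$times, sig)
}

#' Synthetic end-tidal trace for a dual-gas paradigm
#'
#' End-tidal PO2 approaches each block's target (baseline at normoxia,
#' `target_po2` at hyperoxia) exponentially with time constant
#' `transition_tau` from the value reached at the transition; `tau = 0`
#' gives ideal steps.  PCO2 stays at `baseline_pco2` except for optional
#' transient overshoots (boxcars), emulating the brief 1-2 mm Hg
#' excursions that can accompany a gas transition and that trial QC is
#' designed to catch.
#'
#' @param paradigm A [paradigm()].
#' @param baseline_po2,target_po2 Normoxic and hyperoxic end-tidal PO2
#'   targets, mm Hg.
#' @param baseline_pco2 Normocapnic end-tidal PCO2, mm Hg.
#' @param transition_tau Exponential time constant of gas transitions,
#'   seconds.
#' @param dt Sampling interval of the trace, seconds (one breath-ish).
#' @param co2_overshoot `NULL`, or a data frame with columns `start`,
#'   `duration` (s) and `amplitude` (mm Hg) describing PCO2 excursions.
#' @return An [endtidal_trace()].
#' @export
synth_endtidal <- function(paradigm, baseline_po2 = 110, target_po2 = 500,
                           baseline_pco2 = 40, transition_tau = 15,
                           dt = 3, co2_overshoot = NULL) {
  stopifnot(baseline_po2 > 0, target_po2 > 0, transition_tau >= 0, dt > 0)
  times <- seq(0, paradigm$duration - dt / 2, by = dt)
  blocks <- paradigm$blocks
  targets <- ifelse(blocks$label == "hyperoxia", target_po2, baseline_po2)
  po2 <- numeric(length(times))
  level_at_start <- baseline_po2
  for (i in seq_len(nrow(blocks))) {
    sel <- times >= blocks$start[i] & times < blocks$end[i]
    if (transition_tau > 0) {
      po2[sel] <- targets[i] + (level_at_start - targets[i]) *
        exp(-(times[sel] - blocks$start[i]) / transition_tau)
      level_at_start <- targets[i] + (level_at_start - targets[i]) *
        exp(-(blocks$end[i] - blocks$start[i]) / transition_tau)
    } else {
      po2[sel] <- targets[i]
      level_at_start <- targets[i]
    }
  }
  pco2 <- rep(baseline_pco2, length(times))
  if (!is.null(co2_overshoot)) {
    stopifnot(all(c("start", "duration", "amplitude") %in%
                    names(co2_overshoot)))
    for (i in seq_len(nrow(co2_overshoot))) {
      sel <- times >= co2_overshoot$start[i] &
        times < co2_overshoot$start[i] + co2_overshoot$duration[i]
      pco2[sel] <- pco2[sel] + co2_overshoot$amplitude[i]
    }
  }
  endtidal_trace(times, po2, pco2)
}

#' Synthetic interleaved ASL tag/control streams
#'
#' Control images sit at `m0`; tag images are lower by a perfusion-
#' weighted difference `dm` that scales with `1 + rcbf` during
#' stimulation.  Gaussian noise with SD `m0 / tsnr` is added to both
#' streams.
#'
#' @param paradigm A motor [paradigm()] (e.g. [make_asl_paradigm()]).
#' @param rcbf True fractional flow increase during stimulation.
#' @param tr_image Single-image repetition time, seconds.
#' @param m0 Control signal level.
#' @param dm Baseline perfusion-weighted difference (control - tag).
#' @param tsnr Temporal SNR of each stream; `Inf` for noiseless.
#' @param seed Seed used when noise is added.
#' @param tag_first `TRUE` if the first acquired image is a tag.
#' @return List with vectors `tag` and `control`.
#' @export
synth_asl <- function(paradigm, rcbf = 0.58, tr_image = 3, m0 = 1000,
                      dm = 20, tsnr = Inf, seed = 1L, tag_first = TRUE) {
  stopifnot(rcbf > -1, tr_image > 0, dm > 0)
  n_pairs <- floor(paradigm$duration / (2 * tr_image))
  off_tag <- if (tag_first) 0 else tr_image
  off_ctl <- if (tag_first) tr_image else 0
  t_tag <- off_tag + 2 * tr_image * (0:(n_pairs - 1))
  t_ctl <- off_ctl + 2 * tr_image * (0:(n_pairs - 1))
  flow <- function(t) {
    f <- rep(1, length(t))
    for (i in seq_len(nrow(paradigm$trials))) {
      on0 <- paradigm$trials$on_start[i]
      on1 <- on0 + paradigm$trials$on_s[i]
      f[t >= on0 & t < on1] <- 1 + rcbf
    }
    f
  }
  tag <- m0 - dm * flow(t_tag)
  control <- rep(m0, n_pairs)
  if (is.finite(tsnr)) {
    set.seed(seed)
    tag <- tag + stats::rnorm(n_pairs, 0, m0 / tsnr)
    control <- control + stats::rnorm(n_pairs, 0, m0 / tsnr)
  }
  list(tag = tag, control = control)
}

#' Monte Carlo precision of the calibration estimators
#'
#' Repeats simulate -> preprocess -> fit with independent replicate
#' sub-seeds and summarises the spread and bias of the estimates.  Each
#' replicate runs the same pipeline a measured dataset would: baseline
#' masking, linear detrending, normalisation, trial averaging, and the
#' two-condition regression.
#'
#' @param config A [simulation_config()].
#' @return Object of class `precision_report`: data frame `estimates`
#'   (per parameter: truth, mean, sd, bias over successful replicates),
#'   `n_reps`, `n_failed`, logical `unstable` (more than 10% failed
#'   fits), and the config.
#' @export
monte_carlo <- function(config) {
  stopifnot(inherits(config, "simulation_config"), config$n_reps >= 2)
  paradigm <- make_paradigm(config$variant, config$tr)
  base <- baseline_mask(paradigm, .bold_deterministic(config,
                                                      paradigm)$times)
  contrast <- data.frame(block = paradigm$blocks$block,
                         q_h = ifelse(paradigm$blocks$label == "hyperoxia",
                                      config$q_h, 0))
  one_rep <- function(rep) {
    tc <- simulate_bold(config, .sub_seed(config$seed, rep), paradigm)
    fit <- calibrate_timecourse(tc, paradigm, contrast, config$te,
                                baseline = base)
    c(m = fit$m, m_prime = fit$m_prime, rvcbv = fit$rvcbv,
      q_act = fit$q_act)
  }
  res <- matrix(NA_real_, config$n_reps, 4,
                dimnames = list(NULL, c("m", "m_prime", "rvcbv", "q_act")))
  for (rep in seq_len(config$n_reps)) {
    v <- tryCatch(one_rep(rep), error = function(e) NULL)
    if (!is.null(v)) res[rep, ] <- v
  }
  ok <- stats::complete.cases(res)
  n_failed <- sum(!ok)
  if (!any(ok)) stop("all Monte Carlo replicates failed to fit")
  truth <- c(m = config$m, m_prime = config$m_prime,
             rvcbv = config$m_prime / config$m - 1, q_act = config$q_act)
  est <- data.frame(
    parameter = colnames(res),
    truth = unname(truth),
    mean = colMeans(res[ok, , drop = FALSE]),
    sd = apply(res[ok, , drop = FALSE], 2, stats::sd),
    row.names = NULL
  )
  est$bias <- est$mean - est$truth
  est$se_mean <- est$sd / sqrt(sum(ok))
  structure(
    list(estimates = est, n_reps = config$n_reps, n_failed = n_failed,
         unstable = n_failed > 0.1 * config$n_reps, config = config),
    class = "precision_report"
  )
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo precision: %d replicates (%d failed)%s\n",
    x$n_reps, x$n_failed,
    if (x$unstable) " -- UNSTABLE (>10% failures)" else ""))
  est <- x$estimates
  est[, c("truth", "mean", "sd", "bias", "se_mean")] <-
    lapply(est[, c("truth", "mean", "sd", "bias", "se_mean")], signif, 4)
  print(est, row.names = FALSE)
  invisible(x)
}
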