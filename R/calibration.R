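#' Convert percent BOLD change to a transverse relaxation rate change
#'
#' Uses the small-signal gradient-echo approximation
#' `dR2* = -%BOLD / (100 * TE)`; [dr2s_to_percent_bold()] is its exact
#' inverse.
#'
#' @param pct_bold Percent signal change (vectorised).
#' @param te Echo time, seconds.
#' @return Relaxation rate change in s^-1.
#' @export
percent_bold_to_dr2s <- function(pct_bold, te) {
  if (!is.numeric(te) || te <= 0) stop("te must be positive")
  -pct_bold / (100 * te)
}

#' @rdname percent_bold_to_dr2s
#' @param dr2s Relaxation rate change, s^-1.
#' @export
dr2s_to_percent_bold <- function(dr2s, te) {
  if (!is.numeric(te) || te <= 0) stop("te must be positive")
  -dr2s * 100 * te
}

#' Parameters of the linear extravascular signal model
#'
#' The static-dephasing model for randomly oriented vessels gives
#' `R2* = k V (1 - Y) + R2,0*` with `k = (4/3) pi dchi [Hb_tot] B0`; the
#' exponent relating relaxation to deoxyhaemoglobin content is fixed at 1
#' (appropriate at high field).  `k` matters only for forward simulation:
#' every estimated quantity is a ratio or intercept difference in which it
#' cancels.
#'
#' @param v0 Resting venous blood volume fraction, in (0, 1).
#' @param dv_act Absolute venous blood volume change on activation
#'   (fraction; `v0 + dv_act` must stay in (0, 1)).
#' @param q0 Resting venous deoxyhaemoglobin fraction (= OEF).
#' @param q_act Relative deoxyhaemoglobin change on activation (negative
#'   for a flow-dominated response).
#' @param k Field/haemoglobin constant, s^-1 per unit (volume x dHb
#'   fraction).
#' @param r2_0 Relaxation rate of tissue with fully oxygenated blood,
#'   s^-1.
#' @param te Echo time, seconds.
#' @return Object of class `signal_model_params`.
#' @export
signal_model_params <- function(v0 = 0.03, dv_act = 0.0096, q0 = 0.4,
                                q_act = -0.39, k = 1200, r2_0 = 30,
                                te = 0.025) {
  stopifnot(v0 > 0, v0 < 1, v0 + dv_act > 0, v0 + dv_act < 1,
            q0 > 0, q0 < 1, q_act > -1, k > 0, r2_0 >= 0, te > 0)
  structure(list(v0 = v0, dv_act = dv_act, q0 = q0, q_act = q_act,
                 k = k, r2_0 = r2_0, te = te),
            class = "signal_model_params")
}

#' Forward transverse relaxation rate at a given hyperoxia level
#'
#' Rest: `R2* = k v0 q0 (1 + q_h) + R2,0*`.
#' Active: `R2* = k (v0 + dv_act) q0 (1 + q_h + q_act) + R2,0*`.
#' Plotted against the abscissa `(1 + q_h)`, the rest and active lines
#' have slopes `k v0 q0` and `k (v0 + dv_act) q0` (the calibration
#' parameters M and M' once scaled to percent signal), and their intercept
#' difference at abscissa zero is `k (v0 + dv_act) q0 q_act`.
#'
#' @param p A [signal_model_params()] object.
#' @param q_h Relative hyperoxia deoxyhaemoglobin change (<= 0;
#'   vectorised).
#' @param active Logical: task condition.
#' @return R2* in s^-1.
#' @export
forward_r2s <- function(p, q_h, active = FALSE) {
  stopifnot(inherits(p, "signal_model_params"))
  if (active)
    p$k * (p$v0 + p$dv_act) * p$q0 * (1 + q_h + p$q_act) + p$r2_0
  else
    p$k * p$v0 * p$q0 * (1 + q_h) + p$r2_0
}

# closed-form simple OLS used by fit_calibration; equivalent to lm() but
# cheap enough for Monte Carlo loops
.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stop("regression abscissa is degenerate")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  df <- n - 2
  if (df > 0) {
    s2 <- sum((y - intercept - slope * x)^2) / df
    se_slope <- sqrt(s2 / sxx)
    se_int <- sqrt(s2 * (1 / n + mx^2 / sxx))
    cov_is <- -s2 * mx / sxx
  } else {
    se_slope <- se_int <- cov_is <- NA_real_
  }
  list(slope = slope, intercept = intercept, se_slope = se_slope,
       se_intercept = se_int, cov_int_slope = cov_is, df = df)
}

#' Two-condition calibration fit: M, M', rvCBV and q_act
#'
#' Ordinary least squares of the rest and active relaxation-rate changes
#' against the abscissa `x = (1 + q_h)`.  The percent-signal calibration
#' parameters are `M = 100 TE * slope_rest` and `M' = 100 TE * slope_act`;
#' the slope ratio gives `rvCBV = M'/M - 1` and the intercept difference
#' at abscissa zero gives `q_act = (intercept_act - intercept_rest) /
#' slope_act`.  Fitting against `(1 + q_h)` rather than `q_h` matters: the
#' intercept-difference identity for q_act holds at abscissa zero, and
#' differencing intercepts taken at `q_h = 0` would add an `(M' - M)`
#' term.
#'
#' Standard errors come from the two regressions with first-order
#' propagation through the ratio and quotient (treating the rest and
#' active fits as independent); Monte Carlo simulation
#' ([monte_carlo()]) is the authoritative precision estimate.
#'
#' @param points Data frame of per-trial calibration points with columns
#'   `q_h`, `dr2s_rest`, `dr2s_act` (s^-1, relative to the normoxic-rest
#'   baseline), e.g. from [calibration_points()].
#' @param te Echo time, seconds.
#' @return Object of class `calibration_fit` with fields `m`, `m_prime`
#'   (percent), `slope_rest`, `slope_act`, `intercept_rest`,
#'   `intercept_act` (s^-1 against `(1 + q_h)`), `rvcbv`, `q_act`,
#'   standard errors `se_*`, `n_points`, `te`.
#' @examples
#' p <- signal_model_params()
#' qh <- c(0, 0, -0.17, -0.17)
#' pts <- data.frame(
#'   q_h = qh,
#'   dr2s_rest = forward_r2s(p, qh, FALSE) - forward_r2s(p, 0, FALSE),
#'   dr2s_act  = forward_r2s(p, qh, TRUE)  - forward_r2s(p, 0, FALSE))
#' fit <- fit_calibration(pts, te = p$te)
#' c(fit$rvcbv, fit$q_act)   # recovers dv_act/v0 and q_act exactly
#' @export
fit_calibration <- function(points, te) {
  if (!is.numeric(te) || te <= 0) stop("te must be positive")
  need <- c("q_h", "dr2s_rest", "dr2s_act")
  if (!all(need %in% names(points)))
    stop("points must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(points$q_h))) stop("q_h must be finite")
  if (length(unique(points$q_h)) < 2)
    stop("need at least two distinct q_h levels to fit the calibration")
  x <- 1 + points$q_h
  rest <- .ols(x, points$dr2s_rest)
  act <- .ols(x, points$dr2s_act)
  if (rest$slope <= 0)
    stop("non-physical fit: rest slope (M) is not positive")
  m <- 100 * te * rest$slope
  m_prime <- 100 * te * act$slope
  rvcbv <- act$slope / rest$slope - 1
  q_act <- (act$intercept - rest$intercept) / act$slope

  se_m <- 100 * te * rest$se_slope
  se_m_prime <- 100 * te * act$se_slope
  ratio <- act$slope / rest$slope
  se_rvcbv <- abs(ratio) *
    sqrt((act$se_slope / act$slope)^2 + (rest$se_slope / rest$slope)^2)
  # var(q_act) by the delta method; rest intercept independent of the
  # active fit, intercept/slope covariance within the active fit retained
  v_q <- (act$se_intercept^2 + rest$se_intercept^2) / act$slope^2 +
    q_act^2 * act$se_slope^2 / act$slope^2 -
    2 * q_act * act$cov_int_slope / act$slope^2
  se_q_act <- sqrt(pmax(v_q, 0))

  structure(
    list(m = m, m_prime = m_prime,
         slope_rest = rest$slope, slope_act = act$slope,
         intercept_rest = rest$intercept, intercept_act = act$intercept,
         rvcbv = rvcbv, q_act = q_act,
         se_m = se_m, se_m_prime = se_m_prime,
         se_rvcbv = se_rvcbv, se_q_act = se_q_act,
         n_points = nrow(points), te = te),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  fmt <- function(v, se, scale = 1)
    if (is.na(se)) sprintf("%.1f", scale * v)
    else sprintf("%.1f +/- %.1f", scale * v, scale * se)
  cat("Dual-gas calibration fit (", x$n_points, " trial points)\n", sep = "")
  cat("  M      = ", fmt(x$m, x$se_m), " %\n", sep = "")
  cat("  M'     = ", fmt(x$m_prime, x$se_m_prime), " %\n", sep = "")
  cat("  rvCBV  = ", fmt(x$rvcbv, x$se_rvcbv, 100), " %\n", sep = "")
  cat("  q_act  = ", fmt(x$q_act, x$se_q_act, 100), " %\n", sep = "")
  invisible(x)
}

#' Relative CMRO2 change from q_act and rCBF via Fick's principle
#'
#' Oxygen consumption equals flow times the arteriovenous content
#' difference, so for relative changes
#' `1 + rCMRO2 = (1 + q_act) (1 + rCBF)`.
#'
#' @param q_act Relative venous deoxyhaemoglobin change on activation
#'   (> -1; vectorised).
#' @param rcbf Relative CBF change on activation (> -1; vectorised).
#' @return Object of class `cmro2_result`: list with `rcbf`, `q_act`,
#'   `rcmro2` (fractions).
#' @examples
#' fick_rcmro2(-0.290, 0.580)$rcmro2   # 0.122
#' @export
fick_rcmro2 <- function(q_act, rcbf) {
  if (any(q_act <= -1) || any(rcbf <= -1))
    stop("q_act and rcbf must both exceed -1")
  structure(list(rcbf = rcbf, q_act = q_act,
                 rcmro2 = (1 + q_act) * (1 + rcbf) - 1),
            class = "cmro2_result")
}

#' @export
print.cmro2_result <- function(x, ...) {
  df <- data.frame(rcbf_pct = round(100 * x$rcbf, 1),
                   q_act_pct = round(100 * x$q_act, 1),
                   rcmro2_pct = round(100 * x$rcmro2, 1))
  cat("Fick rCMRO2\n"); print(df, row.names = FALSE)
  invisible(x)
}

#' Absolute venous saturation increase on activation
#'
#' `dY_act = -Q0 * q_act`: converts the relative deoxyhaemoglobin change
#' into an absolute venous saturation change.
#'
#' @param q_act Relative deoxyhaemoglobin change on activation.
#' @param q0 Resting deoxyhaemoglobin fraction (= OEF), in (0, 1).
#' @return Saturation fraction change.
#' @export
delta_y_act <- function(q_act, q0 = 0.4) {
  if (any(q0 <= 0) || any(q0 >= 1)) stop("q0 must lie in (0, 1)")
  -q0 * q_act
}

#' Rescale q_act to a different assumed resting deoxyhaemoglobin fraction
#'
#' The q_h abscissa scales as `c = q0_assumed / q0_measured`, and the
#' conventional conversion of a fitted q_act is the proportional rescale
#' `q_act * c`, applied without refitting; rvCBV is unaffected by the
#' choice of Q0 either way.  Note that refitting the regression with the
#' corrected abscissa gives exactly
#' `c * q_act + (c - 1) * (1 - slope_rest / slope_act)` -- still linear in
#' the Q0 error, but with an intercept-offset term of order
#' `(c - 1) * rvCBV / (1 + rvCBV)` that the proportional convention drops.
#' [run_calibration()] refits; this helper implements the conventional
#' table conversion.
#'
#' @param q_act Fitted relative deoxyhaemoglobin change.
#' @param q0_assumed Q0 used when the fit was performed.
#' @param q0_measured Q0 to rescale to (e.g. phase-derived).
#' @return Rescaled q_act.
#' @export
rescale_q_act <- function(q_act, q0_assumed, q0_measured) {
  if (any(q0_assumed <= 0) || any(q0_assumed >= 1) ||
      any(q0_measured <= 0) || any(q0_measured >= 1))
    stop("q0 values must lie in (0, 1)")
  q_act * q0_assumed / q0_measured
}

#' Assemble per-trial calibration points from trial summaries and gas blocks
#'
#' Joins [trial_summaries()] output with the per-block q_h from
#' [hyperoxia_contrast()] and converts percent signal levels to
#' relaxation-rate changes.
#'
#' @param summaries Output of [trial_summaries()].
#' @param contrast Output of [hyperoxia_contrast()], or a data frame with
#'   columns `block` and `q_h`.
#' @param te Echo time, seconds.
#' @return Data frame with columns `trial`, `block`, `condition`, `q_h`,
#'   `dr2s_rest`, `dr2s_act`.
#' @export
calibration_points <- function(summaries, contrast, te) {
  idx <- match(summaries$block, contrast$block)
  if (any(is.na(idx)))
    stop("trial summaries reference blocks missing from the gas contrast")
  data.frame(trial = summaries$trial, block = summaries$block,
             condition = summaries$gas, q_h = contrast$q_h[idx],
             dr2s_rest = percent_bold_to_dr2s(summaries$rest_pct, te),
             dr2s_act = percent_bold_to_dr2s(summaries$act_pct, te))
}
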