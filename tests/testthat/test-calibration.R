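test_that("percent BOLD and dR2* conversion is a sign-inverting bijection", {
  expect_equal(percent_bold_to_dr2s(0, 0.025), 0)
  expect_equal(percent_bold_to_dr2s(2.5, 0.025), -1)
  x <- c(-3, 0.1, 6.4)
  expect_equal(dr2s_to_percent_bold(percent_bold_to_dr2s(x, 0.03), 0.03), x)
  expect_error(percent_bold_to_dr2s(1, 0), "positive")
})

test_that("forward relaxation model obeys its slope and intercept identities", {
  p <- signal_model_params(v0 = 0.03, dv_act = 0.0096, q0 = 0.4,
                           q_act = -0.39, k = 1200, r2_0 = 30)
  p0 <- signal_model_params(v0 = 0.03, dv_act = 0, q0 = 0.4, q_act = 0,
                            k = 1200, r2_0 = 30)
  expect_equal(forward_r2s(p0, 0, TRUE), forward_r2s(p0, 0, FALSE))
  qh <- c(0, -0.1, -0.2)
  x <- 1 + qh
  slope_rest <- diff(forward_r2s(p, qh, FALSE)) / diff(x)
  slope_act <- diff(forward_r2s(p, qh, TRUE)) / diff(x)
  expect_equal(unique(round(slope_rest, 9)), p$k * p$v0 * p$q0)
  expect_equal(slope_act / slope_rest, rep(1 + p$dv_act / p$v0, 2))
  # intercept difference at abscissa zero is k (v0 + dv) q0 q_act
  int_rest <- forward_r2s(p, -1, FALSE)
  int_act <- forward_r2s(p, -1, TRUE)
  expect_equal(int_act - int_rest,
               p$k * (p$v0 + p$dv_act) * p$q0 * p$q_act)
})

test_that("calibration fit recovers noiseless forward-model parameters", {
  p <- signal_model_params(v0 = 0.03, dv_act = 0.32 * 0.03, q0 = 0.4,
                           q_act = -0.39)
  fit <- fit_calibration(forward_points(p), te = p$te)
  expect_equal(fit$rvcbv, 0.32, tolerance = 1e-12)
  expect_equal(fit$q_act, -0.39, tolerance = 1e-12)
  # M and M' in percent signal units
  expect_equal(fit$m, 100 * p$te * p$k * p$v0 * p$q0, tolerance = 1e-10)
  expect_equal(fit$m_prime / fit$m, 1.32, tolerance = 1e-12)
})

test_that("slope ratio turns M = 36%, M' = 48% into rvCBV = 1/3", {
  te <- 0.025
  qh <- c(0, 0, -0.17, -0.17)
  x <- 1 + qh
  pts <- data.frame(q_h = qh,
                    dr2s_rest = 36 / (100 * te) * (x - 1),
                    dr2s_act = 48 / (100 * te) * (x - 0.39) - 36 / (100 * te))
  fit <- fit_calibration(pts, te)
  expect_equal(fit$m, 36, tolerance = 1e-10)
  expect_equal(fit$m_prime, 48, tolerance = 1e-10)
  expect_equal(fit$rvcbv, 1 / 3, tolerance = 1e-12)
  # duplicating every point leaves the fit unchanged
  fit2 <- fit_calibration(rbind(pts, pts), te)
  expect_equal(fit2$rvcbv, fit$rvcbv)
  expect_equal(fit2$q_act, fit$q_act)
})

test_that("calibration fit rejects degenerate and non-physical input", {
  pts <- forward_points()
  expect_error(fit_calibration(pts[pts$q_h == 0, ], 0.025), "distinct q_h")
  flipped <- transform(pts, dr2s_rest = -dr2s_rest)
  expect_error(fit_calibration(flipped, 0.025), "non-physical")
})

test_that("closed-form OLS agrees with lm on noisy points", {
  set.seed(99)
  qh <- rep(c(0, -0.08, -0.17), each = 3)
  p <- signal_model_params()
  pts <- forward_points(p, q_h_levels = c(0, -0.08, -0.17), reps = 3)
  pts$dr2s_rest <- pts$dr2s_rest + rnorm(9, 0, 0.1)
  pts$dr2s_act <- pts$dr2s_act + rnorm(9, 0, 0.1)
  fit <- fit_calibration(pts, p$te)
  x <- 1 + pts$q_h
  lr <- lm(pts$dr2s_rest ~ x)
  la <- lm(pts$dr2s_act ~ x)
  expect_equal(fit$slope_rest, unname(coef(lr)[2]), tolerance = 1e-12)
  expect_equal(fit$intercept_act, unname(coef(la)[1]), tolerance = 1e-12)
  expect_equal(fit$se_m, 100 * p$te *
                 unname(sqrt(diag(vcov(lr)))[2]), tolerance = 1e-10)
  expect_equal(fit$rvcbv, unname(coef(la)[2] / coef(lr)[2]) - 1,
               tolerance = 1e-12)
})

test_that("Fick's principle reproduces worked subject arithmetic", {
  expect_equal(fick_rcmro2(0, 0)$rcmro2, 0)
  expect_equal(fick_rcmro2(-0.290, 0.580)$rcmro2, 0.1218, tolerance = 1e-10)
  # algebraic null: q_act = -rcbf/(1+rcbf) cancels the flow increase
  rcbf <- 0.7
  expect_equal(fick_rcmro2(-rcbf / (1 + rcbf), rcbf)$rcmro2, 0,
               tolerance = 1e-12)
  expect_error(fick_rcmro2(-1, 0.5), "exceed -1")
  expect_error(fick_rcmro2(-0.3, -1.2), "exceed -1")
})

test_that("venous saturation change on activation follows -Q0 q_act", {
  expect_equal(delta_y_act(0), 0)
  expect_equal(delta_y_act(-0.369, 0.4), 0.1476, tolerance = 1e-12)
  expect_equal(round(delta_y_act(-0.434, 0.4), 3), 0.174)
})

test_that("q_act responds linearly to an assumed-Q0 error; rvCBV does not", {
  expect_equal(rescale_q_act(-0.3, 0.4, 0.4), -0.3)
  expect_equal(round(rescale_q_act(-0.290, 0.4, 0.424), 3), -0.274)
  # oracle: rerun the fit with q_h scaled by c = q0_assumed/q0_measured.
  # The refit obeys q_act' = c q_act + (c - 1)(1 - slope_rest/slope_act)
  # exactly: linear in the Q0 error, proportional rescaling plus a known
  # intercept-offset term.
  p <- signal_model_params()
  pts <- forward_points(p)
  fit <- fit_calibration(pts, p$te)
  offset <- 1 - fit$slope_rest / fit$slope_act
  for (q0_meas in c(0.3, 0.47, 0.55)) {
    scale <- 0.4 / q0_meas
    fit2 <- fit_calibration(transform(pts, q_h = q_h * scale), p$te)
    expect_equal(fit2$q_act,
                 scale * fit$q_act + (scale - 1) * offset,
                 tolerance = 1e-10)
    # rvCBV does not move when the assumed Q0 changes
    expect_equal(fit2$rvcbv, fit$rvcbv, tolerance = 1e-12)
  }
})
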