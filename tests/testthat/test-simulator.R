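test_that("paradigm A has the documented gas and trial structure", {
  p <- make_paradigm("A")
  expect_equal(p$duration, 900)
  expect_equal(nrow(p$trials), 8)
  gas <- p$blocks$label[p$trials$block]
  expect_equal(sum(gas == "normoxia"), 4)
  expect_equal(sum(gas == "hyperoxia"), 4)
  # trials never straddle a gas transition
  blk_end <- p$blocks$end[p$trials$block]
  expect_true(all(p$trials$on_start + p$trials$on_s + p$trials$off_s
                  <= blk_end))
})

test_that("paradigm B flags exactly four usable trials, two per gas", {
  p <- make_paradigm("B")
  expect_equal(p$duration, 840)
  expect_equal(nrow(p$trials), 8)
  expect_equal(sum(p$trials$usable), 4)
  gas <- p$blocks$label[p$trials$block[p$trials$usable]]
  expect_equal(as.vector(sort(table(gas))), c(2L, 2L))
})

test_that("paradigm constructor rejects malformed schedules", {
  expect_error(paradigm(data.frame(label = "normoxia", start = 0, end = 0),
                        data.frame(on_start = numeric(0), on_s = numeric(0),
                                   off_s = numeric(0))), "end > start")
  expect_error(
    paradigm(data.frame(label = c("normoxia", "hyperoxia"),
                        start = c(0, 50), end = c(100, 150)),
             data.frame(on_start = numeric(0), on_s = numeric(0),
                        off_s = numeric(0))), "overlap")
  expect_error(
    paradigm(data.frame(label = "normoxia", start = 0, end = 100),
             data.frame(on_start = 90, on_s = 30, off_s = 30)),
    "crossing a gas transition")
  expect_error(make_paradigm("C"), "arg")
})

test_that("synthetic end-tidal traces approach their targets", {
  p <- make_paradigm("A")
  step <- synth_endtidal(p, transition_tau = 0)
  hyper <- p$blocks[p$blocks$label == "hyperoxia", ]
  sel <- step$time_s >= hyper$start[1] & step$time_s < hyper$end[1]
  expect_true(all(step$peto2_mmHg[sel] == 500))
  # steady-state window means within 1% of target for tau = 15 s
  smooth <- synth_endtidal(p, transition_tau = 15)
  hc <- hyperoxia_contrast(smooth, p, q0 = 0.4)
  expect_true(all(abs(hc$pao2[hc$label == "hyperoxia"] - 500) / 500 < 0.01))
  expect_true(all(abs(hc$pao2[hc$label == "normoxia"] - 110) / 110 < 0.01))
  # a CO2 overshoot at the first transition knocks out the overlapped trial
  osc <- synth_endtidal(p, transition_tau = 0,
                        co2_overshoot = data.frame(start = 180,
                                                   duration = 70,
                                                   amplitude = 2))
  keep <- petco2_trial_qc(osc, p)
  expect_identical(unname(which(!keep)), 3L)   # trial starting at 240 s
})

test_that("simulated BOLD is deterministic and carries the model plateaus", {
  cfg <- simulation_config(n_reps = 1, seed = 33)
  a <- simulate_bold(cfg, rep_seed = 123)
  b <- simulate_bold(cfg, rep_seed = 123)
  expect_identical(a$signal, b$signal)
  c <- simulate_bold(cfg, rep_seed = 124)
  expect_false(identical(a$signal, c$signal))
  # hyperoxia baseline shift equals -M q_h percent in the noiseless limit
  cfg0 <- simulation_config(tsnr = Inf, n_reps = 1)
  p <- make_paradigm("A")
  tc <- simulate_bold(cfg0)
  base <- baseline_mask(p, tc$time_s)
  pct <- normalise_to_baseline(detrend_linear(tc, base), base)
  hyper_rest <- rep(FALSE, nrow(pct))
  for (i in which(p$blocks$label == "hyperoxia"))
    hyper_rest <- hyper_rest |
      (pct$time_s >= p$blocks$start[i] & pct$time_s < p$blocks$start[i] + 54)
  expect_equal(mean(pct$signal[hyper_rest]), -36 * -0.17,
               tolerance = 1e-8)
})

test_that("noiseless pipeline recovery survives drift and onset shaping", {
  p <- make_paradigm("A")
  cfg <- simulation_config(tsnr = Inf, drift = 1.5, n_reps = 1)
  fit <- calibrate_timecourse(simulate_bold(cfg), p, fixed_contrast(p),
                              cfg$te)
  expect_equal(fit$rvcbv, config_truth(cfg)$rvcbv, tolerance = 1e-10)
  expect_equal(fit$q_act, cfg$q_act, tolerance = 1e-10)
  # a 2 s onset time constant is absorbed by the 6 s window margins
  cfg2 <- simulation_config(tsnr = Inf, onset_tau = 2, n_reps = 1)
  fit2 <- calibrate_timecourse(simulate_bold(cfg2), p, fixed_contrast(p),
                               cfg2$te)
  expect_lt(abs(fit2$rvcbv - config_truth(cfg2)$rvcbv), 0.02)
})

test_that("Monte Carlo reports are reproducible and consistent", {
  cfg <- simulation_config(n_reps = 40, seed = 7)
  r1 <- monte_carlo(cfg)
  r2 <- monte_carlo(cfg)
  expect_identical(r1$estimates, r2$estimates)
  expect_equal(r1$n_failed, 0)
  expect_false(r1$unstable)
  est <- r1$estimates
  expect_true(all(est$sd > 0))
  # means stay within a few standard errors of the truth
  expect_true(all(abs(est$bias) < 5 * est$se_mean + 1e-12))
})

test_that("estimator spread scales inversely with temporal SNR", {
  sds <- sapply(c(80, 320), function(tsnr) {
    cfg <- simulation_config(n_reps = 150, tsnr = tsnr, seed = 101)
    monte_carlo(cfg)$estimates$sd[3]   # rvcbv
  })
  slope <- log(sds[2] / sds[1]) / log(320 / 80)
  expect_lt(abs(slope + 1), 0.15)
})
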