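test_that("baseline mask keeps normoxia samples away from recent trials", {
  # no trials, one normoxic block: everything is baseline
  p0 <- paradigm(data.frame(label = "normoxia", start = 0, end = 120),
                 data.frame(on_start = numeric(0), on_s = numeric(0),
                            off_s = numeric(0)), tr = 2.4)
  times0 <- seq(0, 117.6, by = 2.4)
  expect_true(all(baseline_mask(p0, times0)))

  # paradigm A at TR = 2.4 s: hand enumeration leaves the first 60 s of
  # each task-bearing normoxic block (25 samples each) plus the whole
  # recovery block (75 samples)
  p <- make_paradigm("A")
  times <- seq(0, 897.6, by = 2.4)
  m <- baseline_mask(p, times)
  expect_equal(sum(m), 125)
  hyper <- p$blocks[p$blocks$label == "hyperoxia", ]
  in_hyper <- rep(FALSE, length(times))
  for (i in seq_len(nrow(hyper)))
    in_hyper <- in_hyper |
      (times >= hyper$start[i] & times < hyper$end[i])
  expect_false(any(m & in_hyper))
  # a trial ending at the paradigm end leaves no trailing baseline
  p_end <- paradigm(data.frame(label = "normoxia", start = 0, end = 120),
                    data.frame(on_start = 60, on_s = 30, off_s = 30),
                    tr = 2.4)
  m_end <- baseline_mask(p_end, times0)
  expect_false(any(m_end & times0 >= 60))
})

test_that("detrending removes baseline drift and preserves responses", {
  t <- seq(0, 299, by = 1)
  base <- rep(TRUE, length(t))
  ramp <- roi_timecourse(t, 100 + 0.05 * t)
  out <- detrend_linear(ramp, base)
  expect_equal(out$signal, rep(mean(ramp$signal), length(t)),
               tolerance = 1e-9)
  # response confined to non-baseline times is untouched
  resp_win <- t >= 120 & t < 150
  tc <- roi_timecourse(t, 100 + 0.05 * t + 5 * resp_win)
  out2 <- detrend_linear(tc, !resp_win)
  expect_equal(mean(out2$signal[resp_win]) - mean(out2$signal[!resp_win]),
               5, tolerance = 1e-9)
  # already-flat series is unchanged
  flat <- roi_timecourse(t, rep(7, length(t)))
  expect_equal(detrend_linear(flat, base)$signal, flat$signal)
  expect_error(detrend_linear(flat, c(TRUE, rep(FALSE, length(t) - 1))),
               "two distinct baseline")
})

test_that("normalisation reports percent change from the baseline mean", {
  t <- 0:99
  base <- t < 50
  v <- c(rep(200, 50), rep(200 * 1.064, 50))
  out <- normalise_to_baseline(roi_timecourse(t, v), base)
  expect_equal(out$signal[base], rep(0, 50))
  expect_equal(out$signal[!base], rep(6.4, 50), tolerance = 1e-9)
  # scale invariance
  out2 <- normalise_to_baseline(roi_timecourse(t, 3.7 * v), base)
  expect_equal(out2$signal, out$signal, tolerance = 1e-12)
  expect_error(normalise_to_baseline(roi_timecourse(t, v - 500), base),
               "positive")
  # detrend o normalise is idempotent on its own output
  out3 <- detrend_linear(out, base)
  expect_equal(out3$signal, out$signal, tolerance = 1e-9)
})

test_that("trial summaries read the forward-model plateaus exactly", {
  cfg <- simulation_config(tsnr = Inf, n_reps = 1)
  p <- make_paradigm("A")
  tc <- simulate_bold(cfg)
  base <- baseline_mask(p, tc$time_s)
  tc <- normalise_to_baseline(detrend_linear(tc, base), base)
  s <- trial_summaries(tc, p)
  expect_equal(nrow(s), 8)
  # plateau values implied by M = 36, M' = 48, q_h = -0.17, q_act = -0.39
  expect_equal(s$rest_pct[s$gas == "normoxia"], rep(0, 4),
               tolerance = 1e-10)
  expect_equal(s$rest_pct[s$gas == "hyperoxia"], rep(6.12, 4),
               tolerance = 1e-10)
  expect_equal(s$act_pct[s$gas == "normoxia"],
               rep(36 - 48 * (1 - 0.39), 4), tolerance = 1e-10)
  expect_equal(s$act_pct[s$gas == "hyperoxia"],
               rep(36 - 48 * (1 - 0.17 - 0.39), 4), tolerance = 1e-10)
})

test_that("trial summaries honour QC flags and demand both gas levels", {
  cfg <- simulation_config(tsnr = Inf, n_reps = 1)
  p <- make_paradigm("A")
  tc <- simulate_bold(cfg)
  base <- baseline_mask(p, tc$time_s)
  tc <- normalise_to_baseline(detrend_linear(tc, base), base)
  hyper_trials <- p$blocks$label[p$trials$block] == "hyperoxia"
  expect_error(trial_summaries(tc, p, qc_keep = !hyper_trials),
               "hyperoxia")
  keep3 <- !(p$trials$trial == 3)
  expect_equal(nrow(trial_summaries(tc, p, qc_keep = keep3)), 7)
})

test_that("paradigm B contributes exactly its four non-transition trials", {
  cfg <- simulation_config(variant = "B", tsnr = Inf, n_reps = 1)
  p <- make_paradigm("B")
  tc <- simulate_bold(cfg)
  base <- baseline_mask(p, tc$time_s)
  tc <- normalise_to_baseline(detrend_linear(tc, base), base)
  s <- trial_summaries(tc, p)
  expect_equal(nrow(s), 4)
  expect_equal(sort(table(s$gas)), sort(table(c(rep("normoxia", 2),
                                                rep("hyperoxia", 2)))))
  # and the full pipeline still recovers the truth from 4 trials
  fit <- calibrate_timecourse(simulate_bold(cfg), p, fixed_contrast(p),
                              cfg$te)
  expect_equal(fit$rvcbv, config_truth(cfg)$rvcbv, tolerance = 1e-8)
  expect_equal(fit$q_act, cfg$q_act, tolerance = 1e-8)
})

test_that("ASL subtraction recovers a programmed flow increase", {
  p <- make_asl_paradigm("A")
  streams <- synth_asl(p, rcbf = 0.58, tsnr = Inf)
  res <- asl_rcbf(streams$tag, streams$control, p)
  expect_equal(res$rcbf, 0.58, tolerance = 1e-10)
  # control = tag + constant: flat perfusion, no flow change
  flat <- asl_rcbf(streams$control - 20, streams$control, p)
  expect_equal(flat$rcbf, 0, tolerance = 1e-12)
  # common scaling of both streams cancels
  res2 <- asl_rcbf(3 * streams$tag, 3 * streams$control, p)
  expect_equal(res2$rcbf, res$rcbf, tolerance = 1e-12)
  expect_error(asl_rcbf(streams$tag[-1], streams$control, p),
               "equal length")
  # low-noise streams still land within 2% relative
  noisy <- synth_asl(p, rcbf = 0.58, tsnr = 5000, seed = 5)
  resn <- asl_rcbf(noisy$tag, noisy$control, p)
  expect_lt(abs(resn$rcbf - 0.58) / 0.58, 0.02)
})
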