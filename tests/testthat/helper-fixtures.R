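# shared in-code fixtures: everything is generated, nothing is stored

# per-block gas contrast with an exactly known q_h (bypasses the end-tidal
# trace when a test wants the abscissa fixed)
fixed_contrast <- function(paradigm, q_h = -0.17) {
  data.frame(block = paradigm$blocks$block,
             q_h = ifelse(paradigm$blocks$label == "hyperoxia", q_h, 0))
}

# noiseless per-trial calibration points straight from the forward model
forward_points <- function(p = signal_model_params(),
                           q_h_levels = c(0, -0.17), reps = 2) {
  qh <- rep(q_h_levels, each = reps)
  r0 <- forward_r2s(p, 0, active = FALSE)
  data.frame(q_h = qh,
             dr2s_rest = forward_r2s(p, qh, active = FALSE) - r0,
             dr2s_act = forward_r2s(p, qh, active = TRUE) - r0)
}

# ground truth implied by a simulation config
config_truth <- function(config) {
  list(rvcbv = config$m_prime / config$m - 1, q_act = config$q_act)
}
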