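# Compact simulation settings shared across tests: short sessions with the
# same generative structure as the defaults, sized so whole-cohort studies
# run quickly.

flat_bleach <- function(b0 = 1) {
  c(b0 = b0, c1 = 0.05, tau1 = 60, c2 = 0.05, tau2 = 600, c3 = 0.9)
}

fast_cfg <- function(...) {
  args <- list(...)
  defaults <- list(duration = 75, fs_raw = 100, n_events = 2,
                   event_gap = c(20, 26), t_start = 12,
                   tau_rise = 0.2, tau_decay = 1.5,
                   bleach_465 = flat_bleach(100), bleach_405 = flat_bleach(70))
  do.call(sim_config, utils::modifyList(defaults, args))
}

fast_preset <- function() {
  protocol_preset("fast", smooth_window = 0.5, target_fs = 50,
                  peri_pre = -5, peri_post = 10, baseline = c(-5, -2),
                  summary_windows = list(c(0, 5)))
}

# settings for amplitude-recovery studies: unit brightness, 1-s smoothing
recovery_preset <- function() {
  protocol_preset("recovery", smooth_window = 1, target_fs = 50,
                  peri_pre = -10, peri_post = 15, baseline = c(-10, -2),
                  summary_windows = list(c(0, 5)))
}

recovery_cfg <- function(amplitude, seed, noise_sd = 0.005) {
  sim_config(duration = 260, fs_raw = 200, n_events = 5,
             event_gap = c(35, 45), t_start = 15,
             amplitude = amplitude, tau_rise = 0.2, tau_decay = 1.5,
             bleach_465 = flat_bleach(1), bleach_405 = flat_bleach(1),
             artifact_sd = 0, noise_sd = noise_sd, seed = seed)
}
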