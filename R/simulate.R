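#' Double-exponential sensor impulse response
#'
#' `k(t) = exp(-t / tau_decay) - exp(-t / tau_rise)`, normalised to peak 1,
#' sampled at `fs` and truncated at `5 * tau_decay`. This is the standard
#' phenomenological kernel for fluorescent sensor transients: a fast rise
#' set by sensor binding and a slower decay set by unbinding/clearance.
#'
#' @param tau_rise,tau_decay Time constants in seconds, `tau_decay > tau_rise > 0`.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of kernel samples starting at `t = 0` (where the
#'   kernel is 0) with maximum exactly 1.
#' @export
transient_kernel <- function(tau_rise, tau_decay, fs) {
  check_number(tau_rise, "tau_rise", positive = TRUE)
  check_number(tau_decay, "tau_decay", positive = TRUE)
  check_number(fs, "fs", positive = TRUE)
  if (tau_decay <= tau_rise) {
    abort_param("`tau_decay` must exceed `tau_rise`.")
  }
  t <- seq(0, 5 * tau_decay, by = 1 / fs)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / max(k)
}

#' Event train with uniformly random gaps
#'
#' Event times are `t_start` plus cumulative sums of independent
#' `Uniform(gap_min, gap_max)` draws — the "random intervals" design used
#' to prevent anticipatory responses to periodic stimuli. The default gap
#' bounds of 60 and 180 s reproduce inter-pellet intervals of 1-3 minutes.
#'
#' @param n Number of events (>= 1).
#' @param gap_min,gap_max Gap bounds in seconds, `0 < gap_min <= gap_max`.
#' @param t_start Time origin in seconds; the first event falls at
#'   `t_start + gap_1`.
#' @param seed Optional integer seed; the train is deterministic given it.
#' @return A `photometry_events` table with labels `"event"`.
#' @export
make_event_train <- function(n, gap_min = 60, gap_max = 180, t_start = 0,
                             seed = NULL) {
  if (!is.numeric(n) || n < 1) abort_param("`n` must be >= 1.")
  if (!(gap_min > 0 && gap_max >= gap_min)) {
    abort_param("Need 0 < gap_min <= gap_max.")
  }
  draw <- function() t_start + cumsum(runif(n, gap_min, gap_max))
  times <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  event_table(times, "event")
}

#' Simulation configuration for a two-channel recording
#'
#' Defines the generative model of one animal's session: event-locked
#' multiplicative transients on the 465 nm channel, multi-exponential
#' photobleaching in both channels, a slow motion artifact multiplicatively
#' coupled into both channels, and additive Gaussian channel noise.
#'
#' Defaults represent a realistic session: 200 Hz acquisition (an integer
#' multiple of the 50 Hz analysis rate), five pellet events at 1-3 min
#' random intervals, transient peak dF/F of 0.05, a bleach profile losing
#' roughly 10% of fluorescence over the session, motion artifact SD of 2% and
#' channel noise of 0.5% of the channel brightness.
#'
#' @param duration Session length in seconds.
#' @param fs_raw Acquisition rate in Hz (>= 50).
#' @param n_events Number of stimulus events.
#' @param event_gap Length-2 numeric, uniform gap bounds in seconds.
#' @param t_start Seconds before the first gap begins (acclimation +
#'   cropped start).
#' @param amplitude Peak dF/F of each transient; the sign encodes direction
#'   (positive = release/excitation as for dopamine sensors, negative =
#'   inhibition as for AgRP activity on food detection). Recycled across
#'   events if scalar.
#' @param tau_rise,tau_decay Kernel time constants in seconds.
#' @param bleach_465,bleach_405 Named numeric `(b0, c1, tau1, c2, tau2, c3)`
#'   per channel: brightness `B(t) = b0 * (c1 exp(-t/tau1) + c2 exp(-t/tau2) + c3)`.
#' @param artifact_sd SD of the shared motion artifact (fraction of channel
#'   brightness); 0 disables.
#' @param artifact_coupling Coupling of the artifact into the reference
#'   channel (1 = identical coupling, the assumption under which isosbestic
#'   regression removes it).
#' @param noise_sd Additive noise SD per channel, length 1 or 2
#'   (signal, reference); `NULL` defaults to 0.5% of each channel's `b0`.
#' @param sensor_tag,animal_id,group_id Labels carried onto the recording.
#' @param seed Optional integer seed; the simulation is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 1000, fs_raw = 200, n_events = 5,
                       event_gap = c(60, 180), t_start = 40,
                       amplitude = 0.05, tau_rise = 0.5, tau_decay = 2,
                       bleach_465 = c(b0 = 100, c1 = 0.05, tau1 = 60,
                                      c2 = 0.05, tau2 = 600, c3 = 0.9),
                       bleach_405 = c(b0 = 70, c1 = 0.05, tau1 = 60,
                                      c2 = 0.05, tau2 = 600, c3 = 0.9),
                       artifact_sd = 0.02, artifact_coupling = 1,
                       noise_sd = NULL,
                       sensor_tag = "dLight", animal_id = "animal",
                       group_id = "group", seed = NULL) {
  check_number(duration, "duration", positive = TRUE)
  check_number(fs_raw, "fs_raw", positive = TRUE)
  if (fs_raw < 50) abort_param("`fs_raw` must be >= 50 Hz.")
  check_number(tau_rise, "tau_rise", positive = TRUE)
  check_number(tau_decay, "tau_decay", positive = TRUE)
  if (tau_decay <= tau_rise) abort_param("`tau_decay` must exceed `tau_rise`.")
  if (length(event_gap) != 2L || !(event_gap[1] > 0) ||
      event_gap[2] < event_gap[1]) {
    abort_param("`event_gap` must be (min, max) with 0 < min <= max.")
  }
  if (is.null(noise_sd)) {
    noise_sd <- 0.005 * c(bleach_465[["b0"]], bleach_405[["b0"]])
  }
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, 2L)
  if (any(noise_sd < 0) || artifact_sd < 0) {
    abort_param("`noise_sd` and `artifact_sd` must be >= 0.")
  }
  structure(list(duration = duration, fs_raw = fs_raw, n_events = n_events,
                 event_gap = as.numeric(event_gap), t_start = t_start,
                 amplitude = amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay, bleach_465 = bleach_465,
                 bleach_405 = bleach_405, artifact_sd = artifact_sd,
                 artifact_coupling = artifact_coupling, noise_sd = noise_sd,
                 sensor_tag = sensor_tag, animal_id = animal_id,
                 group_id = group_id, seed = seed),
            class = "sim_config")
}

bleach_curve <- function(t, p) {
  p[["b0"]] * (p[["c1"]] * exp(-t / p[["tau1"]]) +
               p[["c2"]] * exp(-t / p[["tau2"]]) + p[["c3"]])
}

#' Simulate one two-channel recording with ground truth
#'
#' Generative model (all series sampled at `fs_raw`):
#' \deqn{signal(t) = B_{465}(t) (1 + x(t) + M(t)) + \epsilon_{465}(t)}
#' \deqn{reference(t) = B_{405}(t) (1 + \alpha M(t)) + \epsilon_{405}(t)}
#' where `x(t)` is the sum of event-locked kernels scaled by the per-event
#' amplitudes, `M(t)` is the shared motion artifact (0.5-s moving-averaged
#' white noise, re-standardised to SD `artifact_sd`) and the epsilon terms
#' are white Gaussian channel noise. Transients appear only in the 465 nm
#' channel; bleach and motion appear in both — exactly the structure the
#' isosbestic correction assumes.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `recording` (a `photometry_recording`),
#'   `events` (a `photometry_events` table) and `truth` (event times,
#'   realised amplitudes, the artifact trace and the configuration).
#' @examples
#' sim <- simulate_recording(sim_config(duration = 200, n_events = 1, seed = 7))
#' sim$truth$event_times
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  run <- function() simulate_recording_impl(cfg)
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

simulate_recording_impl <- function(cfg) {
  fs <- cfg$fs_raw
  n <- round(cfg$duration * fs)
  t <- (seq_len(n) - 1L) / fs

  ev <- make_event_train(cfg$n_events, cfg$event_gap[1], cfg$event_gap[2],
                         t_start = cfg$t_start)
  keep <- ev$time_s < cfg$duration
  if (!all(keep)) {
    warn(sprintf("%d event(s) beyond the session duration trimmed.",
                 sum(!keep)), class = "photoflux_events_trimmed")
    ev <- event_table(ev$time_s[keep], ev$label[keep])
  }
  amps <- rep_len(cfg$amplitude, nrow(ev))

  x <- numeric(n)
  if (nrow(ev) > 0 && any(amps != 0)) {
    k <- transient_kernel(cfg$tau_rise, cfg$tau_decay, fs)
    for (i in seq_len(nrow(ev))) {
      i0 <- round(ev$time_s[i] * fs) + 1L
      len <- min(length(k), n - i0 + 1L)
      if (len > 0) x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
          amps[i] * k[seq_len(len)]
    }
  }

  artifact <- numeric(n)
  if (cfg$artifact_sd > 0) {
    m <- moving_average(rnorm(n), fs, 0.5)
    artifact <- m / sd(m) * cfg$artifact_sd
  }

  b465 <- bleach_curve(t, cfg$bleach_465)
  b405 <- bleach_curve(t, cfg$bleach_405)
  e465 <- if (cfg$noise_sd[1] > 0) rnorm(n, 0, cfg$noise_sd[1]) else numeric(n)
  e405 <- if (cfg$noise_sd[2] > 0) rnorm(n, 0, cfg$noise_sd[2]) else numeric(n)

  signal <- b465 * (1 + x + artifact) + e465
  reference <- b405 * (1 + cfg$artifact_coupling * artifact) + e405

  rec <- raw_recording(t, signal, reference, sensor_tag = cfg$sensor_tag,
                       animal_id = cfg$animal_id, group_id = cfg$group_id,
                       fs = fs)
  list(recording = rec, events = ev,
       truth = list(event_times = ev$time_s, amplitudes = amps,
                    artifact = artifact, transient = x, config = cfg))
}

#' Simulate a cohort of animals across groups
#'
#' Each animal gets an independent recording simulated from the template
#' configuration with its group's transient amplitude and a per-animal seed
#' equal to `seed + animal index`, so any single animal can be regenerated
#' from the master seed.
#'
#' @param n_per_group Integer vector of group sizes, one per group.
#' @param group_amplitudes Numeric vector of transient amplitudes, one per
#'   group; names become group labels (defaults `g1`, `g2`, ...). A blunted
#'   response is emulated by giving one group a smaller amplitude.
#' @param cfg Template [sim_config()].
#' @param seed Master integer seed.
#' @return Tibble with one row per animal: `animal_id`, `group_id`,
#'   `amplitude`, `seed`, and list-columns `recording`, `events`, `truth`.
#' @examples
#' coh <- simulate_cohort(c(2, 2), c(ctrl = 0.05, exposed = 0.025),
#'                        sim_config(duration = 300, n_events = 2), seed = 1)
#' coh$group_id
#' @export
simulate_cohort <- function(n_per_group, group_amplitudes,
                            cfg = sim_config(), seed = 1) {
  if (length(n_per_group) != length(group_amplitudes)) {
    abort_param("`n_per_group` and `group_amplitudes` must have equal length.")
  }
  if (length(n_per_group) < 1L) abort_param("Need at least one group.")
  groups <- names(group_amplitudes)
  if (is.null(groups)) groups <- paste0("g", seq_along(group_amplitudes))
  plan <- tibble(group_id = rep(groups, n_per_group),
                 amplitude = rep(as.numeric(group_amplitudes), n_per_group))
  plan$animal_id <- sprintf("%s_a%02d", plan$group_id,
                            stats::ave(seq_len(nrow(plan)), plan$group_id,
                                       FUN = seq_along))
  plan$seed <- seed + seq_len(nrow(plan))
  sims <- purrr::pmap(plan[, c("group_id", "amplitude", "animal_id", "seed")],
                      function(group_id, amplitude, animal_id, seed) {
    cfg_i <- cfg
    cfg_i$amplitude <- amplitude
    cfg_i$animal_id <- animal_id
    cfg_i$group_id <- group_id
    cfg_i$seed <- seed
    simulate_recording(cfg_i)
  })
  plan$recording <- purrr::map(sims, "recording")
  plan$events <- purrr::map(sims, "events")
  plan$truth <- purrr::map(sims, "truth")
  plan[, c("animal_id", "group_id", "amplitude", "seed",
           "recording", "events", "truth")]
}
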