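new_trial_matrix <- function(time, values, trials, preset, scale,
                             animal_id = NULL, group_id = NULL) {
  structure(list(time = time, values = values, trials = trials,
                 preset = preset, scale = scale,
                 animal_id = animal_id, group_id = group_id),
            class = "trial_matrix")
}

#' Extract peri-event trials from a dF/F trace
#'
#' For each event the window `[peri_pre, peri_post)` (relative seconds,
#' half-open so every trial has the same length) is cut from the trace.
#' Events are mapped to samples by nearest-sample rounding:
#' the first sample index is `round((t_event + peri_pre - t0) * fs)` and
#' `round((peri_post - peri_pre) * fs)` samples are taken. Events whose
#' window falls outside the recording are kept as rows but marked invalid
#' (with a warning), as are trials whose baseline contains masked dF/F
#' samples.
#'
#' @param dff A `photometry_dff` from [preprocess()].
#' @param events A `photometry_events` table.
#' @param preset The `photometry_protocol` used to preprocess `dff`; its
#'   `target_fs` must equal the trace rate.
#' @return A `trial_matrix`: list with `time` (shared relative time axis),
#'   `values` (trials x samples matrix, dF/F units), and `trials`, a tibble
#'   with one row per event (`trial`, `event_time`, `label`, `valid`,
#'   `baseline_mean`, `baseline_sd` — the latter filled by
#'   [zscore_trials()]).
#' @export
extract_trials <- function(dff, events, preset) {
  stopifnot(inherits(dff, "photometry_dff"),
            inherits(preset, "photometry_protocol"))
  fs <- attr(dff, "fs")
  if (abs(fs - preset$target_fs) > 1e-9) {
    abort_data(sprintf("Trace rate %.6g Hz != protocol target_fs %g Hz.",
                       fs, preset$target_fs))
  }
  if (nrow(events) == 0L) abort_data("Event table is empty: no trials to extract.")
  t0 <- attr(dff, "t0")
  n_axis <- round((preset$peri_post - preset$peri_pre) * fs)
  time_axis <- preset$peri_pre + (seq_len(n_axis) - 1L) / fs
  n_rec <- nrow(dff)
  bl_idx <- window_index(time_axis, preset$baseline, fs)

  vals <- matrix(NA_real_, nrow = nrow(events), ncol = n_axis)
  valid <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    start0 <- round((events$time_s[i] + preset$peri_pre - t0) * fs)  # 0-based
    if (start0 < 0 || start0 + n_axis > n_rec) {
      warn(sprintf("Event %d at t = %.6g s: peri-event window exceeds the recording; trial marked invalid.",
                   i, events$time_s[i]), class = "photoflux_trial_dropped")
      next
    }
    idx <- start0 + seq_len(n_axis)
    vals[i, ] <- dff$dff[idx]
    if (anyNA(vals[i, bl_idx]) || !all(dff$valid[idx[bl_idx]])) {
      warn(sprintf("Event %d at t = %.6g s: invalid dF/F samples in baseline; trial marked invalid.",
                   i, events$time_s[i]), class = "photoflux_trial_dropped")
      next
    }
    valid[i] <- TRUE
  }
  if (!any(valid)) abort_data("No extractable trials: all peri-event windows invalid.")
  trials <- tibble(trial = seq_len(nrow(events)), event_time = events$time_s,
                   label = events$label, valid = valid,
                   baseline_mean = NA_real_, baseline_sd = NA_real_)
  new_trial_matrix(time_axis, vals, trials, preset, scale = "dff",
                   animal_id = attr(dff, "animal_id"),
                   group_id = attr(dff, "group_id"))
}

# sample indices with start <= t < end on a trial time axis (half-open)
window_index <- function(time_axis, window, fs) {
  which(time_axis >= window[1L] - 1e-9 / fs & time_axis < window[2L] - 1e-9 / fs)
}

#' Z-score trials against their own pre-event baseline
#'
#' Each valid trial is standardised by the mean and sample SD (n - 1
#' denominator) of its own baseline window, so every trial is expressed in
#' baseline-SD units: `z = (x - mean_base) / sd_base`. Trials whose
#' baseline SD is below 1e-12 (constant baseline) are marked invalid.
#'
#' @param trials A `trial_matrix` from [extract_trials()] (dF/F scale).
#' @param preset The protocol carrying the baseline window.
#' @return The `trial_matrix` on the z scale; `trials$baseline_mean` and
#'   `trials$baseline_sd` record the per-trial normalisers.
#' @export
zscore_trials <- function(trials, preset = trials$preset) {
  stopifnot(inherits(trials, "trial_matrix"))
  if (trials$scale == "z") abort_param("Trials are already z-scored.")
  bl_idx <- window_index(trials$time, preset$baseline, preset$target_fs)
  if (length(bl_idx) < 2L) abort_param("Baseline window contains < 2 samples.")
  meta <- trials$trials
  vals <- trials$values
  for (i in which(meta$valid)) {
    base <- vals[i, bl_idx]
    mu <- mean(base)
    s <- sd(base)
    meta$baseline_mean[i] <- mu
    meta$baseline_sd[i] <- s
    if (!is.finite(s) || s < 1e-12) {
      meta$valid[i] <- FALSE
      warn(sprintf("Trial %d: baseline SD ~ 0; trial marked invalid.", i),
           class = "photoflux_trial_dropped")
      next
    }
    vals[i, ] <- (vals[i, ] - mu) / s
  }
  if (!any(meta$valid)) abort_data("All trials invalid after z-scoring.")
  out <- trials
  out$values <- vals
  out$trials <- meta
  out$scale <- "z"
  out
}

#' Average trials within an animal
#'
#' Pointwise mean over the valid trials of one animal; invalid trials are
#' excluded. Per-animal averaging precedes any group statistic, so each
#' animal contributes one value per summary window regardless of its trial
#' count.
#'
#' @param trials A `trial_matrix` (usually z-scored).
#' @param animal_id,group_id Labels; default to those carried by the trials.
#' @return An `animal_summary`: list with `time`, `mean_trace`,
#'   `n_valid_trials`, `scale`, the protocol, and labels.
#' @export
average_trials <- function(trials, animal_id = trials$animal_id,
                           group_id = trials$group_id) {
  stopifnot(inherits(trials, "trial_matrix"))
  keep <- trials$trials$valid
  if (!any(keep)) abort_data("No valid trials to average.")
  m <- trials$values[keep, , drop = FALSE]
  structure(list(time = trials$time, mean_trace = colMeans(m),
                 n_valid_trials = sum(keep), scale = trials$scale,
                 preset = trials$preset,
                 animal_id = animal_id %||% "animal",
                 group_id = group_id %||% "group"),
            class = "animal_summary")
}

#' Window mean of a per-animal mean trace
#'
#' Mean of the trace over samples with `start <= t < end`.
#'
#' @param summary An `animal_summary`.
#' @param window Length-2 numeric `(start, end)`, seconds relative to the
#'   event, inside the peri-event window.
#' @return A single number (z units for z-scored traces).
#' @export
window_mean <- function(summary, window) {
  stopifnot(inherits(summary, "animal_summary"))
  idx <- window_index(summary$time, window, summary$preset$target_fs)
  if (length(idx) == 0L) abort_param("Window contains no samples on the trial time axis.")
  mean(summary$mean_trace[idx])
}

#' Binned average of a per-animal mean trace
#'
#' Consecutive non-overlapping bins of `bin_width` seconds starting at
#' `peri_pre`; a trailing partial bin is dropped.
#'
#' @param summary An `animal_summary`.
#' @param bin_width Bin width in seconds (> 0); defaults to the protocol's.
#' @return Tibble with columns `bin_start`, `bin_end`, `mean`.
#' @export
bin_trace <- function(summary, bin_width = summary$preset$bin_width) {
  stopifnot(inherits(summary, "animal_summary"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    abort_param("`bin_width` must be a single number > 0.")
  }
  fs <- summary$preset$target_fs
  k <- round(bin_width * fs)
  if (k < 1L) abort_param("`bin_width * fs` rounds to zero samples.")
  m <- length(summary$mean_trace) %/% k
  if (m == 0L) abort_param("Trace shorter than one bin.")
  means <- colMeans(matrix(summary$mean_trace[seq_len(m * k)], nrow = k))
  starts <- summary$preset$peri_pre + (seq_len(m) - 1L) * bin_width
  tibble(bin_start = starts, bin_end = starts + bin_width, mean = means)
}

#' Area under the curve of a per-animal mean trace
#'
#' Trapezoidal integral of the mean trace over `start <= t <= end` (closed
#' window, so the integral is additive over adjacent windows split at a
#' sample point), in z-seconds for z-scored traces.
#'
#' @inheritParams window_mean
#' @return A single number.
#' @export
trace_auc <- function(summary, window) {
  stopifnot(inherits(summary, "animal_summary"))
  fs <- summary$preset$target_fs
  idx <- which(summary$time >= window[1L] - 1e-9 / fs &
                 summary$time <= window[2L] + 1e-9 / fs)
  if (length(idx) < 2L) abort_param("Window contains < 2 samples; AUC undefined.")
  t <- summary$time[idx]
  y <- summary$mean_trace[idx]
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Summarise one animal under a protocol
#'
#' Convenience wrapper: [extract_trials()], [zscore_trials()],
#' [average_trials()], then one row per protocol summary window with the
#' window mean and AUC.
#'
#' @param dff A `photometry_dff`.
#' @param events A `photometry_events` table.
#' @param preset A `photometry_protocol`.
#' @return Tibble with columns `animal_id`, `group_id`, `n_valid_trials`,
#'   `window`, `win_start`, `win_end`, `window_mean`, `auc`.
#' @export
summarize_animal <- function(dff, events, preset) {
  tm <- zscore_trials(extract_trials(dff, events, preset), preset)
  avg <- average_trials(tm)
  wins <- preset$summary_windows
  if (length(wins) == 0L) wins <- list(c(0, preset$peri_post))
  purrr::map_dfr(wins, function(w) {
    tibble(animal_id = avg$animal_id, group_id = avg$group_id,
           n_valid_trials = avg$n_valid_trials,
           window = sprintf("[%g,%g]", w[1], w[2]),
           win_start = w[1], win_end = w[2],
           window_mean = window_mean(avg, w), auc = trace_auc(avg, w))
  })
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf("<trial_matrix> %d trials (%d valid) x %d samples, %s scale, protocol %s\n",
              nrow(x$values), sum(x$trials$valid), ncol(x$values), x$scale,
              x$preset$name))
  invisible(x)
}

#' @export
print.animal_summary <- function(x, ...) {
  cat(sprintf("<animal_summary> %s/%s: %d valid trials, %d samples, %s scale\n",
              x$animal_id, x$group_id, x$n_valid_trials,
              length(x$mean_trace), x$scale))
  invisible(x)
}

#' Tidy peri-event objects into long tibbles
#'
#' @param x A `trial_matrix` or `animal_summary`.
#' @param ... Unused.
#' @return For a `trial_matrix`: one row per trial per sample (`trial`,
#'   `time`, `value`, `valid`, `label`). For an `animal_summary`: one row
#'   per sample of the mean trace.
#' @export
tidy.trial_matrix <- function(x, ...) {
  meta <- x$trials
  purrr::map_dfr(meta$trial, function(i) {
    tibble(trial = i, time = x$time, value = x$values[i, ],
           label = meta$label[i], valid = meta$valid[i])
  })
}

#' @rdname tidy.trial_matrix
#' @export
glance.trial_matrix <- function(x, ...) {
  tibble(n_trials = nrow(x$values), n_valid = sum(x$trials$valid),
         n_samples = ncol(x$values), scale = x$scale, preset = x$preset$name)
}

#' @rdname tidy.trial_matrix
#' @export
tidy.animal_summary <- function(x, ...) {
  tibble(animal_id = x$animal_id, group_id = x$group_id,
         time = x$time, mean_z = x$mean_trace)
}
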