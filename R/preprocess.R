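#' Discard the start of a recording
#'
#' The first seconds of a recording (laser power-up, autofluorescence
#' settling) are discarded before any other processing.
#'
#' @param rec A `photometry_recording`.
#' @param crop_s Seconds to remove from the start (default 10).
#' @return The cropped recording; `t0` advances by `crop_s` and the sample
#'   count drops by `round(crop_s * fs)`.
#' @export
crop_initial <- function(rec, crop_s = 10) {
  stopifnot(inherits(rec, "photometry_recording"))
  check_number(crop_s, "crop_s")
  if (crop_s < 0) abort_param("`crop_s` must be >= 0.")
  if (crop_s == 0) return(rec)
  fs <- recording_fs(rec)
  n <- nrow(rec)
  drop <- round(crop_s * fs)
  if (n - drop < 2L || (n - 1) / fs <= crop_s) {
    abort_data(sprintf("Recording (%.3g s) is not longer than crop_s = %.3g s.",
                       (n - 1) / fs, crop_s))
  }
  keep <- (drop + 1L):n
  rebuild_recording(rec, rec$time_s[keep], rec$signal_465[keep],
                    rec$reference_405[keep], fs = fs)
}

#' Centred moving-average smoothing
#'
#' Smooths a sample vector with a centred moving mean of
#' `w = round(window_s * fs)` samples. At the edges the window truncates to
#' the available samples (the mean is taken over the intersection), so
#' constant traces are preserved exactly and no padding value is invented.
#' For even `w` the window extends one sample further to the right.
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param window_s Window width in seconds; 0 returns the input unchanged.
#' @return Smoothed numeric vector, same length.
#' @examples
#' moving_average(c(0, 0, 1, 0, 0), fs = 1, window_s = 3)
#' @export
moving_average <- function(samples, fs, window_s) {
  check_number(fs, "fs", positive = TRUE)
  check_number(window_s, "window_s")
  if (window_s < 0) abort_param("`window_s` must be >= 0.")
  if (window_s == 0) return(samples)
  w <- round(window_s * fs)
  if (w < 1) abort_param("`window_s * fs` rounds to zero samples.")
  if (w == 1) return(samples)
  n <- length(samples)
  lo <- floor((w - 1) / 2)          # samples to the left of the centre
  hi <- w - 1L - lo                 # samples to the right
  cs <- cumsum(c(0, samples))
  i <- seq_len(n)
  left <- pmax(i - lo, 1L)
  right <- pmin(i + hi, n)
  (cs[right + 1L] - cs[left]) / (right - left + 1L)
}

#' Downsample by non-overlapping bin means
#'
#' Reduces the sampling rate by averaging blocks of `k = fs_in / fs_out`
#' consecutive samples; the ratio must be an integer (within 1e-9). A
#' trailing partial bin is dropped.
#'
#' @param samples Numeric vector at rate `fs_in`.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Numeric vector of length `floor(n / k)`.
#' @export
downsample_trace <- function(samples, fs_in, fs_out = 50) {
  check_number(fs_in, "fs_in", positive = TRUE)
  check_number(fs_out, "fs_out", positive = TRUE)
  if (fs_in < fs_out) abort_param("`fs_in` must be >= `fs_out`.")
  r <- fs_in / fs_out
  k <- round(r)
  if (abs(r - k) > 1e-9) {
    abort_param(sprintf(
      "fs_in/fs_out = %.9g is not an integer; resample to a rate dividing fs_in.",
      r))
  }
  if (k == 1L) return(samples)
  m <- length(samples) %/% k
  if (m == 0L) abort_data("Fewer samples than one downsampling bin.")
  colMeans(matrix(samples[seq_len(m * k)], nrow = k))
}

#' Least-squares alignment of the isosbestic reference
#'
#' Fits `signal ~ slope * reference + intercept` by ordinary least squares
#' over the full (post-crop) recording. The scaled reference
#' `slope * reference + intercept` then serves as the ligand-independent
#' baseline for the dF/F computation, removing bleaching and motion
#' components shared between the channels.
#'
#' @param signal,reference Equal-length numeric vectors (length >= 2).
#' @return Named numeric vector `c(slope =, intercept =)`.
#' @examples
#' fit_reference(2 * (1:10) + 1, 1:10)
#' @export
fit_reference <- function(signal, reference) {
  n <- length(signal)
  if (n < 2L || length(reference) != n) {
    abort_param("`signal` and `reference` must have equal length >= 2.")
  }
  if (var(reference) == 0) {
    abort_degenerate("Reference channel has zero variance; no correction possible.")
  }
  fit <- lm.fit(cbind(intercept = 1, slope = reference), signal)
  c(slope = unname(fit$coefficients["slope"]),
    intercept = unname(fit$coefficients["intercept"]))
}

#' Compute dF/F from an aligned reference
#'
#' `dff = (signal - scaled) / scaled` where
#' `scaled = slope * reference + intercept` from [fit_reference()]. Samples
#' where `|scaled|` falls below `eps` (near-zero denominator) are masked
#' invalid rather than silently dropped; the mask propagates into trial
#' extraction.
#'
#' @param signal,reference Equal-length numeric vectors.
#' @param fit Named vector from [fit_reference()] on the same pair.
#' @param eps Denominator guard; defaults to `1e-6 * median(|scaled|)`.
#' @param fs,t0 Sampling rate and start time recorded on the result.
#' @return A tibble of class `photometry_dff` with columns `time_s`, `dff`,
#'   `valid` and attributes `fs`, `t0`, `fit`.
#' @export
compute_dff <- function(signal, reference, fit, eps = NULL, fs = 1, t0 = 0) {
  n <- length(signal)
  if (length(reference) != n) abort_param("Channel lengths differ.")
  scaled <- fit[["slope"]] * reference + fit[["intercept"]]
  if (is.null(eps)) eps <- 1e-6 * median(abs(scaled))
  valid <- abs(scaled) >= eps & is.finite(scaled)
  if (!any(valid)) abort_data("All samples masked: scaled reference is ~0 everywhere.")
  dff <- rep(NA_real_, n)
  dff[valid] <- (signal[valid] - scaled[valid]) / scaled[valid]
  out <- tibble(time_s = t0 + (seq_len(n) - 1L) / fs, dff = dff, valid = valid)
  structure(out, class = c("photometry_dff", class(out)),
            fs = fs, t0 = t0, fit = fit)
}

#' Full preprocessing chain: crop, smooth, downsample, correct, dF/F
#'
#' Applies the stages in fixed order: discard the initial seconds, smooth
#' both channels with the protocol's moving average, downsample both
#' channels to the protocol rate, fit the isosbestic reference to the
#' signal by least squares over the whole processed recording, and compute
#' dF/F against the scaled reference.
#'
#' @param rec A `photometry_recording`.
#' @param preset A `photometry_protocol` (see [load_protocol()]).
#' @param crop_s Seconds discarded from the start (default 10).
#' @return A `photometry_dff` tibble (see [compute_dff()]); the OLS fit and
#'   processing parameters are carried in attributes (`fit`, `preset_name`,
#'   `animal_id`, `group_id`).
#' @examples
#' sim <- simulate_recording(sim_config(duration = 120, n_events = 1, seed = 1))
#' dff <- preprocess(sim$recording, load_protocol("dlight_food"))
#' @export
preprocess <- function(rec, preset, crop_s = 10) {
  stopifnot(inherits(rec, "photometry_recording"),
            inherits(preset, "photometry_protocol"))
  fs_in <- recording_fs(rec)
  if (fs_in < preset$target_fs) {
    abort_data(sprintf("Recording rate %.6g Hz is below the protocol's %g Hz.",
                       fs_in, preset$target_fs))
  }
  rec <- crop_initial(rec, crop_s)
  sig <- moving_average(rec$signal_465, fs_in, preset$smooth_window)
  ref <- moving_average(rec$reference_405, fs_in, preset$smooth_window)
  sig <- downsample_trace(sig, fs_in, preset$target_fs)
  ref <- downsample_trace(ref, fs_in, preset$target_fs)
  fit <- fit_reference(sig, ref)
  out <- compute_dff(sig, ref, fit, fs = preset$target_fs, t0 = recording_t0(rec))
  attr(out, "preset_name") <- preset$name
  attr(out, "animal_id") <- attr(rec, "animal_id")
  attr(out, "group_id") <- attr(rec, "group_id")
  out
}

#' @export
glance.photometry_dff <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble(n = nrow(x), n_valid = sum(x$valid), fs = attr(x, "fs"),
         t0 = attr(x, "t0"),
         slope = fit[["slope"]], intercept = fit[["intercept"]])
}
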