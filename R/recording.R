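#' Construct a two-channel photometry recording
#'
#' A recording is a tibble with columns `time_s`, `signal_465` (sensor
#' channel, arbitrary fluorescence units) and `reference_405` (isosbestic
#' reference), carrying the sampling rate and animal metadata as attributes.
#' The isosbestic reference is recorded at a wavelength where the sensor is
#' ligand-independent, so it captures bleaching and motion but not neural
#' signal; the preprocessing chain uses it to correct the 465 nm channel.
#'
#' @param time_s Numeric vector of sample times in seconds, uniformly spaced.
#' @param signal_465 Sensor-channel fluorescence samples.
#' @param reference_405 Isosbestic-channel fluorescence samples, same length.
#' @param sensor_tag Sensor label, e.g. `"dLight"` or `"GCaMP6s"`.
#' @param animal_id,group_id Identifier labels attached to downstream
#'   summaries.
#' @param fs Sampling rate in Hz. If `NULL` it is inferred from the median
#'   inter-sample interval; sampling must be uniform within 1% relative
#'   tolerance.
#'
#' @return A tibble of class `photometry_recording` with attributes `fs`,
#'   `t0`, `sensor_tag`, `animal_id`, `group_id`.
#' @examples
#' rec <- raw_recording(time_s = seq(0, 1, by = 0.01),
#'                      signal_465 = rnorm(101, 100),
#'                      reference_405 = rnorm(101, 70))
#' recording_fs(rec)
#' @export
raw_recording <- function(time_s, signal_465, reference_405,
                          sensor_tag = "other", animal_id = "animal",
                          group_id = "group", fs = NULL) {
  n <- length(time_s)
  if (n < 2L) abort_data("A recording needs at least 2 samples.")
  if (length(signal_465) != n || length(reference_405) != n) {
    abort_data("`time_s`, `signal_465` and `reference_405` must have equal length.")
  }
  if (anyNA(time_s) || any(!is.finite(time_s))) abort_data("Sample times must be finite.")
  if (any(!is.finite(signal_465)) || any(!is.finite(reference_405))) {
    abort_data("All fluorescence samples must be finite.")
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) abort_data("Sample times must be strictly increasing.")
  dt_med <- median(dt)
  if (max(abs(dt - dt_med)) > 0.01 * dt_med) {
    abort_data("Sampling is not uniform within 1% relative tolerance.")
  }
  if (is.null(fs)) fs <- 1 / dt_med
  check_number(fs, "fs", positive = TRUE)

  out <- tibble(time_s = as.numeric(time_s),
                signal_465 = as.numeric(signal_465),
                reference_405 = as.numeric(reference_405))
  structure(out,
            class = c("photometry_recording", class(out)),
            fs = fs, t0 = time_s[[1L]],
            sensor_tag = sensor_tag,
            animal_id = animal_id, group_id = group_id)
}

#' Recording accessors
#'
#' @param rec A `photometry_recording`.
#' @return `recording_fs()` the sampling rate in Hz; `recording_t0()` the
#'   time of the first sample in seconds.
#' @export
recording_fs <- function(rec) attr(rec, "fs")

#' @rdname recording_fs
#' @export
recording_t0 <- function(rec) attr(rec, "t0")

# rebuild a recording from modified channel vectors, preserving metadata
rebuild_recording <- function(rec, time_s, signal, reference, fs = NULL) {
  raw_recording(time_s, signal, reference,
                sensor_tag = attr(rec, "sensor_tag"),
                animal_id = attr(rec, "animal_id"),
                group_id = attr(rec, "group_id"),
                fs = fs)
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("<photometry_recording> %s | %s/%s | %d samples @ %.6g Hz, t0 = %.6g s\n",
              attr(x, "sensor_tag"), attr(x, "animal_id"), attr(x, "group_id"),
              nrow(x), attr(x, "fs"), attr(x, "t0")))
  NextMethod()
}

#' Construct an event table
#'
#' Stimulus timestamps (food-pellet approach, i.p. injection, ...) with text
#' labels. Times must be non-negative and, after sorting, strictly
#' increasing (duplicate timestamps are rejected).
#'
#' @param time_s Event times in seconds.
#' @param label Character labels, recycled if length 1.
#' @param recording_id Optional label linking the table to a recording.
#' @return A tibble of class `photometry_events` with columns `time_s`,
#'   `label`, sorted by time.
#' @export
event_table <- function(time_s = numeric(), label = character(),
                        recording_id = NULL) {
  if (length(label) == 1L && length(time_s) > 1L) {
    label <- rep(label, length(time_s))
  }
  if (length(time_s) != length(label) && length(time_s) > 0L) {
    abort_data("`time_s` and `label` must have equal length.")
  }
  if (anyNA(time_s) || any(!is.finite(time_s))) abort_data("Event times must be finite.")
  if (any(time_s < 0)) abort_data("Event times must be non-negative.")
  ord <- order(time_s)
  time_s <- as.numeric(time_s)[ord]
  if (anyDuplicated(time_s)) abort_data("Duplicate event timestamps.")
  out <- tibble(time_s = time_s, label = as.character(label)[ord])
  structure(out, class = c("photometry_events", class(out)),
            recording_id = recording_id)
}
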