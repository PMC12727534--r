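delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read and write photometry recordings
#'
#' Recordings are stored as delimited tables (CSV or TSV, autodetected by
#' extension) with mandatory header columns `time_s`, `signal_465`,
#' `reference_405`. Metadata (sensor tag, animal and group labels) lives in a
#' companion JSON file named `<stem>.json` next to the table; it is written
#' by [write_recording()] and read back when present.
#'
#' @param path Path to the delimited table.
#' @return [read_recording()] returns a validated [raw_recording()]; the
#'   sampling rate is inferred from the median inter-sample interval and
#'   checked uniform within 1% relative tolerance.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' rec <- raw_recording(seq(0, 1, 0.01), rnorm(101, 100), rnorm(101, 70))
#' write_recording(rec, p)
#' rec2 <- read_recording(p)
#' all.equal(rec$signal_465, rec2$signal_465)
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("File not found: %s", path))
  # base strtod parsing: correctly rounded, so written doubles round-trip
  tab <- utils::read.table(path, header = TRUE, sep = delim_for(path))
  need <- c("time_s", "signal_465", "reference_405")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    abort_format(sprintf("Recording table is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  meta <- list(sensor_tag = "other", animal_id = "animal", group_id = "group")
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    got <- jsonlite::read_json(sp, simplifyVector = TRUE)
    meta[names(got)[names(got) %in% names(meta)]] <-
      got[names(got) %in% names(meta)]
  }
  raw_recording(tab$time_s, tab$signal_465, tab$reference_405,
                sensor_tag = meta$sensor_tag, animal_id = meta$animal_id,
                group_id = meta$group_id)
}

#' @param rec A `photometry_recording`.
#' @rdname read_recording
#' @return [write_recording()] invisibly returns `path`; samples round-trip
#'   bit-exactly (full double precision is written).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "photometry_recording"))
  tab <- tibble(time_s = format(rec$time_s, digits = 17, trim = TRUE, scientific = FALSE),
                signal_465 = format(rec$signal_465, digits = 17, trim = TRUE),
                reference_405 = format(rec$reference_405, digits = 17, trim = TRUE))
  readr::write_delim(tab, path, delim = delim_for(path), progress = FALSE)
  jsonlite::write_json(
    list(sensor_tag = attr(rec, "sensor_tag"),
         animal_id = attr(rec, "animal_id"),
         group_id = attr(rec, "group_id"),
         fs = attr(rec, "fs"), t0 = attr(rec, "t0")),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write event tables
#'
#' Delimited tables (CSV/TSV by extension) with header columns `time_s`,
#' `label`. Rows are sorted ascending on read; an empty table is valid and
#' yields an empty [event_table()].
#'
#' @param path Path to the delimited table.
#' @param recording_id Optional label linking events to a recording.
#' @return A `photometry_events` tibble.
#' @export
read_events <- function(path, recording_id = NULL) {
  if (!file.exists(path)) abort_format(sprintf("File not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                           colClasses = NA, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("time_s", "label"), names(tab))
  if (length(missing_cols) > 0L) {
    abort_format(sprintf("Event table is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  event_table(tab$time_s, tab$label, recording_id = recording_id)
}

#' @param events A `photometry_events` table.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "photometry_events"))
  tab <- tibble(time_s = format(events$time_s, digits = 17, trim = TRUE,
                                scientific = FALSE),
                label = events$label)
  readr::write_delim(tab, path, delim = delim_for(path), progress = FALSE)
  invisible(path)
}
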