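#' Construct a peri-event analysis protocol
#'
#' A protocol bundles every tunable of the preprocessing and peri-event
#' stages: moving-average smoothing width, downsampling target rate, the
#' peri-event window around each stimulus, the pre-event baseline used for
#' z-scoring, the response windows summarised per animal, and an optional
#' bin width for binned trace averages. All times are seconds relative to
#' the event (negative = before).
#'
#' @param name Protocol label.
#' @param smooth_window Moving-average width in seconds; 0 disables smoothing.
#' @param target_fs Downsampling target rate in Hz.
#' @param peri_pre,peri_post Window bounds in seconds; `peri_pre < 0 < peri_post`.
#' @param baseline Length-2 numeric, baseline window `(start, end)`; must lie
#'   inside the peri-event window and end at or before the event (`end <= 0`)
#'   so stimulus administration cannot leak into the normalisation.
#' @param summary_windows List of length-2 numerics, each inside the
#'   peri-event window.
#' @param bin_width Bin width in seconds for binned averages; 0 disables.
#' @return A list of class `photometry_protocol`.
#' @seealso [load_protocol()] for the built-in presets.
#' @export
protocol_preset <- function(name, smooth_window, target_fs, peri_pre, peri_post,
                            baseline, summary_windows = list(), bin_width = 0) {
  check_number(smooth_window, "smooth_window")
  check_number(target_fs, "target_fs", positive = TRUE)
  check_number(peri_pre, "peri_pre")
  check_number(peri_post, "peri_post")
  check_number(bin_width, "bin_width")
  if (smooth_window < 0) abort_param("`smooth_window` must be >= 0.")
  if (bin_width < 0) abort_param("`bin_width` must be >= 0.")
  if (!(peri_pre < 0 && peri_post > 0)) {
    abort_param("Need `peri_pre` < 0 < `peri_post`.")
  }
  baseline <- as.numeric(baseline)
  if (length(baseline) != 2L || baseline[1L] >= baseline[2L]) {
    abort_param("`baseline` must be (start, end) with start < end.")
  }
  if (baseline[1L] < peri_pre || baseline[2L] > peri_post) {
    abort_param("`baseline` must lie within the peri-event window.")
  }
  if (baseline[2L] > 0) {
    abort_param("`baseline` must end at or before the event (end <= 0).")
  }
  summary_windows <- lapply(summary_windows, as.numeric)
  for (w in summary_windows) {
    if (length(w) != 2L || w[1L] >= w[2L]) {
      abort_param("Each summary window must be (start, end) with start < end.")
    }
    if (w[1L] < peri_pre || w[2L] > peri_post) {
      abort_param("Each summary window must lie within the peri-event window.")
    }
  }
  structure(list(name = name, smooth_window = smooth_window,
                 target_fs = target_fs, peri_pre = peri_pre,
                 peri_post = peri_post, baseline = baseline,
                 summary_windows = summary_windows, bin_width = bin_width),
            class = "photometry_protocol")
}

#' @export
print.photometry_protocol <- function(x, ...) {
  sw <- if (length(x$summary_windows) == 0) "none" else
    paste(vapply(x$summary_windows,
                 function(w) sprintf("[%g, %g]", w[1], w[2]), ""),
          collapse = ", ")
  cat(sprintf(paste0("<photometry_protocol> %s\n",
                     "  smooth %g s | %g Hz | peri [%g, %g] s\n",
                     "  baseline [%g, %g] s | summaries %s | bin %g s\n"),
              x$name, x$smooth_window, x$target_fs, x$peri_pre, x$peri_post,
              x$baseline[1], x$baseline[2], sw, x$bin_width))
  invisible(x)
}

builtin_protocols <- function() {
  list(
    # dopamine sensor, food-pellet approach: no smoothing, 5-s binned average
    dlight_food = protocol_preset(
      "dlight_food", smooth_window = 0, target_fs = 50,
      peri_pre = -30, peri_post = 60, baseline = c(-30, -20),
      summary_windows = list(c(0, 5), c(5, 10)), bin_width = 5),
    # AgRP GCaMP, food-pellet introduction
    agrp_food = protocol_preset(
      "agrp_food", smooth_window = 1, target_fs = 50,
      peri_pre = -60, peri_post = 180, baseline = c(-60, -20),
      summary_windows = list(c(15, 180))),
    # AgRP GCaMP, i.p. injection (ghrelin window / CCK baseline)
    agrp_injection = protocol_preset(
      "agrp_injection", smooth_window = 1, target_fs = 50,
      peri_pre = -120, peri_post = 180, baseline = c(-120, -60),
      summary_windows = list(c(15, 180))),
    # AgRP GCaMP, slow hormone responses (ghrelin, PYY, 5-HT, glucagon)
    agrp_hormone = protocol_preset(
      "agrp_hormone", smooth_window = 3, target_fs = 50,
      peri_pre = -300, peri_post = 1200, baseline = c(-300, -60),
      summary_windows = list(c(15, 180))))
}

#' Load a protocol preset by name or from a JSON config
#'
#' Four built-in presets cover the package's standard paradigms:
#'
#' * `dlight_food` — dopamine (dLight) responses to food-pellet approach:
#'   no smoothing, 50 Hz, peri-event window -30 to +60 s, baseline -30 to
#'   -20 s, summary windows 0-5 s and 5-10 s, 5-s bins.
#' * `agrp_food` — AgRP responses to food-pellet introduction: 1-s moving
#'   average, 50 Hz, window -60 to +180 s, baseline -60 to -20 s, summary
#'   +15 to +180 s.
#' * `agrp_injection` — AgRP responses around i.p. injection: 1-s moving
#'   average, window -120 to +180 s, baseline -120 to -60 s.
#' * `agrp_hormone` — slow AgRP hormone responses: 3-s moving average,
#'   window -300 to +1200 s, baseline -300 to -60 s, summary +15 to +180 s.
#'
#' Alternatively pass a path to a JSON file with fields matching
#' [protocol_preset()] arguments; invalid custom configs fail validation.
#'
#' @param name_or_path Preset name or path to a JSON config.
#' @return A `photometry_protocol`.
#' @examples
#' load_protocol("dlight_food")$baseline
#' @export
load_protocol <- function(name_or_path) {
  builtin <- builtin_protocols()
  if (name_or_path %in% names(builtin)) {
    return(builtin[[name_or_path]])
  }
  if (!file.exists(name_or_path)) {
    abort_config(sprintf(
      "Unknown protocol '%s'. Valid names: %s; or pass a path to a JSON config.",
      name_or_path, paste(names(builtin), collapse = ", ")))
  }
  cfg <- jsonlite::read_json(name_or_path, simplifyVector = TRUE)
  need <- c("name", "target_fs", "peri_pre", "peri_post", "baseline")
  missing_f <- setdiff(need, names(cfg))
  if (length(missing_f) > 0L) {
    abort_config(sprintf("Protocol config is missing field(s): %s",
                         paste(missing_f, collapse = ", ")))
  }
  sw <- cfg$summary_windows
  if (is.null(sw)) {
    sw <- list()
  } else if (is.matrix(sw)) {
    sw <- lapply(seq_len(nrow(sw)), function(i) sw[i, ])
  } else if (!is.list(sw)) {
    sw <- list(sw)
  }
  protocol_preset(cfg$name,
                  smooth_window = cfg$smooth_window %||% 0,
                  target_fs = cfg$target_fs,
                  peri_pre = cfg$peri_pre, peri_post = cfg$peri_post,
                  baseline = cfg$baseline, summary_windows = sw,
                  bin_width = cfg$bin_width %||% 0)
}

#' @rdname load_protocol
#' @param preset A `photometry_protocol`.
#' @param path Output JSON path.
#' @export
write_protocol <- function(preset, path) {
  stopifnot(inherits(preset, "photometry_protocol"))
  jsonlite::write_json(unclass(preset), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
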