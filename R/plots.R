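#' Plot methods for photometry objects
#'
#' `autoplot()` methods give quick ggplot2 views of each result type: the
#' two raw channels of a recording, a processed dF/F trace, a peri-event
#' trial heat map with the trial-average overlaid, and a per-animal mean
#' trace with its summary windows shaded.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @param downsample_to Approximate number of points drawn per channel for
#'   raw recordings (thinning is for display only).
#' @return A ggplot object.
#' @name photoflux-autoplot
NULL

#' @rdname photoflux-autoplot
#' @export
autoplot.photometry_recording <- function(object, ..., downsample_to = 5000) {
  step <- max(1L, floor(nrow(object) / downsample_to))
  idx <- seq(1L, nrow(object), by = step)
  d <- tibble(time_s = rep(object$time_s[idx], 2L),
              channel = rep(c("465 nm signal", "405 nm reference"),
                            each = length(idx)),
              f = c(object$signal_465[idx], object$reference_405[idx]))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$f,
                                  colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)", colour = NULL,
                  title = sprintf("%s / %s", attr(object, "animal_id"),
                                  attr(object, "group_id"))) +
    ggplot2::theme_minimal()
}

#' @rdname photoflux-autoplot
#' @export
autoplot.photometry_dff <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$valid),
                  ggplot2::aes(.data$time_s, .data$dff)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F)) +
    ggplot2::theme_minimal()
}

#' @rdname photoflux-autoplot
#' @export
autoplot.trial_matrix <- function(object, ...) {
  long <- tidy(object)
  valid_long <- dplyr::filter(long, .data$valid)
  avg <- valid_long |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ylab <- if (object$scale == "z") "z" else "dF/F"
  heat <- ggplot2::ggplot(valid_long,
                          ggplot2::aes(.data$time, factor(.data$trial),
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", name = ylab) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from event (s)", y = "trial") +
    ggplot2::theme_minimal()
  heat
}

#' @rdname photoflux-autoplot
#' @export
autoplot.animal_summary <- function(object, ...) {
  d <- tidy(object)
  shade <- purrr::map_dfr(object$preset$summary_windows, function(w) {
    tibble(xmin = w[1], xmax = w[2])
  })
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$mean_z)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50")
  if (nrow(shade) > 0) {
    p <- p + ggplot2::geom_rect(data = shade,
                                ggplot2::aes(xmin = .data$xmin,
                                             xmax = .data$xmax,
                                             ymin = -Inf, ymax = Inf),
                                inherit.aes = FALSE, alpha = 0.12,
                                fill = "#2c7fb8")
  }
  p + ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time from event (s)",
                  y = if (object$scale == "z") "z (baseline SD units)" else "dF/F",
                  title = sprintf("%s / %s (%d trials)", object$animal_id,
                                  object$group_id, object$n_valid_trials)) +
    ggplot2::theme_minimal()
}

#' Group summary plot of per-animal window values
#'
#' Dot plot of per-animal window means (or AUCs) by group and summary
#' window, with group mean and s.e.m. overlaid — the standard figure
#' accompanying peri-event group comparisons.
#'
#' @param analysis A `cohort_analysis` or its summaries tibble.
#' @param measure `"window_mean"` or `"auc"`.
#' @return A ggplot object.
#' @export
plot_group_windows <- function(analysis, measure = c("window_mean", "auc")) {
  measure <- match.arg(measure)
  d <- if (inherits(analysis, "cohort_analysis")) analysis$summaries else analysis
  stats_d <- d |>
    dplyr::group_by(.data$window, .data$group_id) |>
    dplyr::summarise(m = mean(.data[[measure]]),
                     sem = sd(.data[[measure]]) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$group_id, .data[[measure]],
                                  colour = .data$group_id)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7, size = 1.6) +
    ggplot2::geom_pointrange(data = stats_d,
                             ggplot2::aes(y = .data$m,
                                          ymin = .data$m - .data$sem,
                                          ymax = .data$m + .data$sem),
                             colour = "black", linewidth = 0.4) +
    ggplot2::facet_wrap(~window, scales = "free_y") +
    ggplot2::labs(x = NULL, y = measure, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
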