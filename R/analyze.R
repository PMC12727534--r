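#' Analyse a cohort of recordings under one protocol
#'
#' Runs the full chain — [preprocess()], [extract_trials()],
#' [zscore_trials()], [average_trials()], window summaries — for every
#' animal and collects per-animal results. Animals whose trials are all
#' invalid are excluded from the summaries and listed in the exclusion log
#' rather than silently dropped.
#'
#' @param cohort Tibble with columns `animal_id`, `group_id` and
#'   list-columns `recording`, `events` (as from [simulate_cohort()]), or
#'   built by hand from [read_recording()]/[read_events()].
#' @param preset A `photometry_protocol`.
#' @param crop_s Seconds discarded at the start of each recording.
#' @return A `cohort_analysis`: list with `summaries` (one row per animal
#'   per summary window, see [summarize_animal()]), `exclusions` (tibble
#'   `animal_id`, `reason`), `dropped_trials` (count of invalid trials per
#'   animal) and the preset.
#' @export
analyze_cohort <- function(cohort, preset, crop_s = 10) {
  stopifnot(is.data.frame(cohort), inherits(preset, "photometry_protocol"))
  need <- c("animal_id", "group_id", "recording", "events")
  if (!all(need %in% names(cohort))) {
    abort_param(sprintf("`cohort` must have columns: %s.",
                        paste(need, collapse = ", ")))
  }
  summaries <- list()
  exclusions <- list()
  dropped <- list()
  for (i in seq_len(nrow(cohort))) {
    aid <- cohort$animal_id[[i]]
    gid <- cohort$group_id[[i]]
    n_dropped <- 0L
    res <- tryCatch(
      withCallingHandlers({
        dff <- preprocess(cohort$recording[[i]], preset, crop_s = crop_s)
        attr(dff, "animal_id") <- aid
        attr(dff, "group_id") <- gid
        summarize_animal(dff, cohort$events[[i]], preset)
      },
      photoflux_trial_dropped = function(w) {
        n_dropped <<- n_dropped + 1L
        rlang::cnd_muffle(w)
      }),
      error = function(e) e)
    dropped[[i]] <- tibble(animal_id = aid, n_dropped_trials = n_dropped)
    if (inherits(res, "error")) {
      exclusions[[length(exclusions) + 1L]] <-
        tibble(animal_id = aid, reason = conditionMessage(res))
    } else {
      summaries[[length(summaries) + 1L]] <- res
    }
  }
  if (length(summaries) == 0L) abort_data("Every animal was excluded.")
  structure(list(summaries = dplyr::bind_rows(summaries),
                 exclusions = if (length(exclusions) == 0L) {
                   tibble(animal_id = character(), reason = character())
                 } else {
                   dplyr::bind_rows(exclusions)
                 },
                 dropped_trials = dplyr::bind_rows(dropped),
                 preset = preset),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> protocol %s: %d animals, %d excluded\n",
              x$preset$name, length(unique(x$summaries$animal_id)),
              nrow(x$exclusions)))
  invisible(x)
}

#' @rdname analyze_cohort
#' @param x A `cohort_analysis`.
#' @param ... Unused.
#' @export
tidy.cohort_analysis <- function(x, ...) x$summaries

#' @rdname analyze_cohort
#' @export
glance.cohort_analysis <- function(x, ...) {
  tibble(preset = x$preset$name,
         n_animals = length(unique(x$summaries$animal_id)),
         n_excluded = nrow(x$exclusions),
         n_dropped_trials = sum(x$dropped_trials$n_dropped_trials))
}

#' Group statistics over cohort summary windows
#'
#' For each summary window, compares the per-animal values (window mean or
#' AUC) between the two groups with the chosen test.
#'
#' @param analysis A `cohort_analysis` or its `summaries` tibble.
#' @param measure `"window_mean"` or `"auc"`.
#' @param method Test passed to [compare_groups()].
#' @return Tibble with one row per window: the window bounds, measure and
#'   the tidy comparison columns.
#' @export
group_stats <- function(analysis, measure = c("window_mean", "auc"),
                        method = "student") {
  measure <- match.arg(measure)
  summaries <- if (inherits(analysis, "cohort_analysis")) {
    analysis$summaries
  } else {
    analysis
  }
  summaries |>
    dplyr::group_by(.data$window, .data$win_start, .data$win_end) |>
    dplyr::group_modify(function(d, key) {
      compare_groups(d, .data[[measure]], .data$group_id, method = method)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(measure = measure, .before = 1L)
}
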