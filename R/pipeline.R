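pkg_version <- function() as.character(utils::packageVersion("photoflux"))

write_manifest <- function(path, stage, seed, config, files, counts = list()) {
  jsonlite::write_json(
    list(stage = stage, software = paste0("photoflux ", pkg_version()),
         seed = seed, config_hash = rlang::hash(config),
         files = sort(basename(files)), counts = counts),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

cohort_config_from_json <- function(config_path) {
  if (!file.exists(config_path)) {
    abort_config(sprintf("Config file not found: %s", config_path))
  }
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  for (f in c("n_per_group", "group_amplitudes")) {
    if (is.null(cfg[[f]])) {
      abort_config(sprintf("Config field missing: $.%s", f))
    }
  }
  sim_args <- cfg[setdiff(names(cfg), c("n_per_group", "group_amplitudes"))]
  known <- names(formals(sim_config))
  bad <- setdiff(names(sim_args), known)
  if (length(bad) > 0L) {
    abort_config(sprintf("Unknown config field(s): %s",
                         paste0("$.", bad, collapse = ", ")))
  }
  for (f in c("bleach_465", "bleach_405")) {
    if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
  }
  list(n_per_group = unlist(cfg$n_per_group),
       group_amplitudes = unlist(cfg$group_amplitudes),
       template = do.call(sim_config, sim_args))
}

#' Pipeline commands: simulate, analyze, report
#'
#' The three orchestration entry points behind the shell interface in
#' `system.file("scripts", "photoflux.R", package = "photoflux")`. Each
#' writes its outputs plus a JSON manifest (config hash, seed, file list,
#' record counts) so a run can be audited and repeated.
#'
#' @param config_path JSON cohort config: `n_per_group` (integer array),
#'   `group_amplitudes` (group label to transient amplitude), and any
#'   [sim_config()] field.
#' @param out_dir Output directory, created if missing.
#' @param seed Master integer seed.
#' @return `cmd_simulate()` invisibly returns the manifest path after
#'   writing, per animal, `<animal>_recording.csv` (+ metadata sidecar),
#'   `<animal>_events.csv` and `<animal>_truth.json`.
#' @export
cmd_simulate <- function(config_path, out_dir, seed = 1) {
  cc <- cohort_config_from_json(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(cc$n_per_group, cc$group_amplitudes,
                            cfg = cc$template, seed = seed)
  files <- character()
  for (i in seq_len(nrow(cohort))) {
    aid <- cohort$animal_id[[i]]
    rp <- file.path(out_dir, paste0(aid, "_recording.csv"))
    ep <- file.path(out_dir, paste0(aid, "_events.csv"))
    tp <- file.path(out_dir, paste0(aid, "_truth.json"))
    write_recording(cohort$recording[[i]], rp)
    write_events(cohort$events[[i]], ep)
    truth <- cohort$truth[[i]]
    jsonlite::write_json(
      list(animal_id = aid, group_id = cohort$group_id[[i]],
           seed = cohort$seed[[i]], event_times = truth$event_times,
           amplitudes = truth$amplitudes,
           config = unclass(truth$config)),
      tp, auto_unbox = TRUE, digits = NA)
    files <- c(files, rp, sidecar_path(rp), ep, tp)
  }
  write_manifest(file.path(out_dir, "manifest.json"), "simulate", seed,
                 jsonlite::read_json(config_path), files,
                 counts = list(n_animals = nrow(cohort)))
}

pair_by_stem <- function(recordings, events) {
  stem <- function(x, suffix) sub(suffix, "", tools::file_path_sans_ext(basename(x)))
  rs <- stem(recordings, "_recording$")
  es <- stem(events, "_events$")
  if (!setequal(rs, es) || anyDuplicated(rs) || anyDuplicated(es)) {
    abort_data("Recording and event files do not pair one-to-one by stem.")
  }
  tibble(stem = sort(rs),
         recording = recordings[match(sort(rs), rs)],
         events = events[match(sort(rs), es)])
}

#' @param recordings,events Character vectors of file paths or glob
#'   patterns; files pair by shared stem (`<animal>_recording.csv` with
#'   `<animal>_events.csv`).
#' @param preset Preset name or JSON path, resolved by [load_protocol()].
#' @param crop_s Seconds discarded at recording start.
#' @param stat_method Group test for the summary windows
#'   (see [compare_groups()]).
#' @return `cmd_analyze()` invisibly returns the manifest path after
#'   writing `animal_summaries.csv`, `group_stats.csv`, `exclusions.csv`
#'   and `manifest.json`.
#' @rdname cmd_simulate
#' @export
cmd_analyze <- function(recordings, events, preset, out_dir, crop_s = 10,
                        stat_method = "student") {
  rec_files <- Sys.glob(recordings)
  ev_files <- Sys.glob(events)
  if (length(rec_files) == 0L) abort_data("No recording files matched.")
  pairs <- pair_by_stem(rec_files, ev_files)
  preset <- load_protocol(preset)
  cohort <- purrr::pmap_dfr(pairs, function(stem, recording, events) {
    rec <- read_recording(recording)
    tibble(animal_id = attr(rec, "animal_id"),
           group_id = attr(rec, "group_id"),
           recording = list(rec), events = list(read_events(events)))
  })
  analysis <- analyze_cohort(cohort, preset, crop_s = crop_s)
  stats_tbl <- if (length(unique(analysis$summaries$group_id)) == 2L) {
    dplyr::bind_rows(group_stats(analysis, "window_mean", stat_method),
                     group_stats(analysis, "auc", stat_method))
  } else {
    tibble()
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(analysis$summaries, file.path(out_dir, "animal_summaries.csv"))
  readr::write_csv(stats_tbl, file.path(out_dir, "group_stats.csv"))
  readr::write_csv(analysis$exclusions, file.path(out_dir, "exclusions.csv"))
  files <- file.path(out_dir, c("animal_summaries.csv", "group_stats.csv",
                                "exclusions.csv"))
  write_manifest(file.path(out_dir, "manifest.json"), "analyze", NA,
                 list(preset = unclass(preset), crop_s = crop_s,
                      inputs = sort(basename(c(rec_files, ev_files)))),
                 files,
                 counts = list(
                   n_animals = length(unique(analysis$summaries$animal_id)),
                   n_excluded = nrow(analysis$exclusions),
                   n_dropped_trials = sum(analysis$dropped_trials$n_dropped_trials)))
}

#' @param in_dir Directory written by `cmd_analyze()`.
#' @return `cmd_report()` returns the report text (a character vector of
#'   markdown lines) invisibly after writing `report.md` into `in_dir`.
#' @rdname cmd_simulate
#' @export
cmd_report <- function(in_dir) {
  sp <- file.path(in_dir, "animal_summaries.csv")
  if (!file.exists(sp)) {
    abort_data(sprintf("No analysis outputs found in %s.", in_dir))
  }
  summaries <- readr::read_csv(sp, show_col_types = FALSE)
  stats_path <- file.path(in_dir, "group_stats.csv")
  stats_tbl <- if (file.exists(stats_path) && file.size(stats_path) > 1) {
    tryCatch(readr::read_csv(stats_path, show_col_types = FALSE),
             error = function(e) tibble())
  } else {
    tibble()
  }
  excl <- readr::read_csv(file.path(in_dir, "exclusions.csv"),
                          show_col_types = FALSE)

  lines <- c("# Photometry cohort report", "")
  grp <- summaries |>
    dplyr::group_by(.data$group_id, .data$window) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$animal_id),
                     mean = mean(.data$window_mean),
                     sem = sd(.data$window_mean) / sqrt(dplyr::n()),
                     .groups = "drop")
  lines <- c(lines, "## Per-group window means (z, mean +/- s.e.m.)", "")
  for (i in seq_len(nrow(grp))) {
    lines <- c(lines, sprintf("- %s, window %s: n = %d, %.3f +/- %.3f",
                              grp$group_id[i], grp$window[i], grp$n[i],
                              grp$mean[i], grp$sem[i]))
  }
  lines <- c(lines, "", "## Group comparisons", "")
  if (nrow(stats_tbl) == 0L) {
    lines <- c(lines, "no comparisons")
  } else {
    for (i in seq_len(nrow(stats_tbl))) {
      lines <- c(lines, sprintf(
        "- %s of %s in window %s: statistic = %.4g, p = %.4g",
        stats_tbl$method[i], stats_tbl$measure[i], stats_tbl$window[i],
        stats_tbl$statistic[i], stats_tbl$p.value[i]))
    }
  }
  lines <- c(lines, "", "## Exclusions", "")
  if (nrow(excl) == 0L) {
    lines <- c(lines, "none")
  } else {
    lines <- c(lines, sprintf("- %s: %s", excl$animal_id, excl$reason))
  }
  writeLines(lines, file.path(in_dir, "report.md"))
  invisible(lines)
}
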