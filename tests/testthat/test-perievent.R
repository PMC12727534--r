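# dF/F trace with known content for direct trial checks
synthetic_dff <- function(n = 15000, fs = 50, t0 = 0, values = NULL) {
  if (is.null(values)) values <- numeric(n)
  structure(tibble::tibble(time_s = t0 + (seq_len(n) - 1) / fs,
                           dff = values, valid = rep(TRUE, n)),
            class = c("photometry_dff", class(tibble::tibble())),
            fs = fs, t0 = t0, fit = c(slope = 1, intercept = 0))
}

test_that("extract_trials cuts half-open windows of fixed length", {
  preset <- load_protocol("dlight_food")
  dff <- synthetic_dff(n = 50 * 300)  # 300 s at 50 Hz
  ev <- event_table(c(100, 150), "pellet")
  tm <- extract_trials(dff, ev, preset)
  expect_equal(ncol(tm$values), 4500)          # 90 s x 50 Hz
  expect_equal(nrow(tm$values), 2)
  expect_equal(tm$time[1], -30)
  expect_lt(max(tm$time), 60)                   # half-open: +60 excluded
  # index of t = 0 equals round(-peri_pre * fs) (0-based alignment)
  expect_equal(which.min(abs(tm$time)) - 1L, round(30 * 50))
})

test_that("events whose window leaves the recording are invalid, counted, warned", {
  preset <- load_protocol("dlight_food")
  dff <- synthetic_dff(n = 50 * 200)
  ev <- event_table(c(5, 100, 195), "pellet")  # first and last out of range
  expect_warning(expect_warning(tm <- extract_trials(dff, ev, preset),
                                class = "photoflux_trial_dropped"),
                 class = "photoflux_trial_dropped")
  expect_equal(tm$trials$valid, c(FALSE, TRUE, FALSE))
  expect_equal(sum(tm$trials$valid) + sum(!tm$trials$valid), nrow(ev))
  ev_bad <- event_table(2, "pellet")
  expect_error(suppressWarnings(extract_trials(dff, ev_bad, preset)),
               class = "photoflux_data_error")
})

test_that("z-scoring normalises each trial by its own baseline", {
  preset <- fast_preset()
  fs <- 50
  dff <- synthetic_dff(n = 50 * 60, values = rnorm(3000, 0.02, 0.004))
  ev <- event_table(c(20, 40), "e")
  tm <- extract_trials(dff, ev, preset)
  z <- zscore_trials(tm)
  bl <- which(z$time >= -5 & z$time < -2)
  for (i in 1:2) {
    expect_lt(abs(mean(z$values[i, bl])), 1e-9)
    expect_lt(abs(sd(z$values[i, bl]) - 1), 1e-9)
  }
  # a known offset maps to (x - mu) / sd
  x <- tm$values[1, ]
  mu <- mean(x[bl])
  s <- sd(x[bl])
  expect_equal(z$values[1, ], (x - mu) / s)
})

test_that("constant trials are invalidated by z-scoring", {
  preset <- fast_preset()
  dff <- synthetic_dff(n = 3000, values = rep(0.5, 3000))
  ev <- event_table(c(20, 40), "e")
  tm <- extract_trials(dff, ev, preset)
  expect_error(suppressWarnings(zscore_trials(tm)),
               class = "photoflux_data_error")
})

test_that("average_trials pools only valid trials", {
  preset <- fast_preset()
  dff <- synthetic_dff(n = 3000, values = rnorm(3000, 0, 0.01))
  ev <- event_table(c(20, 40), "e")
  tm <- zscore_trials(extract_trials(dff, ev, preset))
  avg <- average_trials(tm)
  expect_equal(avg$mean_trace, colMeans(tm$values))
  expect_equal(avg$n_valid_trials, 2)
  # invalidate trial 2: mean must equal trial 1 alone
  tm2 <- tm
  tm2$trials$valid[2] <- FALSE
  avg1 <- average_trials(tm2)
  expect_equal(avg1$mean_trace, tm$values[1, ])
  expect_equal(avg1$n_valid_trials, 1)
  # antisymmetric pair averages to zero
  tm3 <- tm
  tm3$values[2, ] <- -tm3$values[1, ]
  expect_equal(average_trials(tm3)$mean_trace, numeric(ncol(tm$values)),
               tolerance = 1e-12)
})

test_that("window_mean, bins and AUC agree with their definitions", {
  preset <- fast_preset()
  fs <- 50
  avg <- structure(list(time = -5 + (0:749) / fs,
                        mean_trace = rep(2, 750), n_valid_trials = 1,
                        scale = "z", preset = preset,
                        animal_id = "a", group_id = "g"),
                   class = "animal_summary")
  expect_equal(window_mean(avg, c(0, 5)), 2)
  expect_equal(trace_auc(avg, c(0, 5)), 2 * 5)  # rectangle over closed window
  b <- bin_trace(avg, 5)
  expect_equal(nrow(b), 3)
  expect_true(all(b$mean == 2))
  # ramp 0 -> 1 over the window has mean ~ 0.5
  ramp <- avg
  ramp$mean_trace <- seq(0, 1, length.out = 750)
  expect_equal(window_mean(ramp, c(-5, 10)), 0.5, tolerance = 1e-3)
  # linearity and antisymmetry of AUC
  sc <- avg
  sc$mean_trace <- 3 * avg$mean_trace
  expect_equal(trace_auc(sc, c(0, 5)), 3 * trace_auc(avg, c(0, 5)))
  neg <- avg
  neg$mean_trace <- -avg$mean_trace
  expect_equal(trace_auc(neg, c(0, 5)), -trace_auc(avg, c(0, 5)))
  expect_error(window_mean(avg, c(20, 30)), class = "photoflux_param_error")
  expect_error(bin_trace(avg, 0), class = "photoflux_param_error")
})

test_that("AUC is additive over adjacent windows split at a sample point", {
  preset <- fast_preset()
  set.seed(8)
  avg <- structure(list(time = -5 + (0:749) / 50,
                        mean_trace = rnorm(750), n_valid_trials = 1,
                        scale = "z", preset = preset,
                        animal_id = "a", group_id = "g"),
                   class = "animal_summary")
  expect_equal(trace_auc(avg, c(0, 8)),
               trace_auc(avg, c(0, 4)) + trace_auc(avg, c(4, 8)),
               tolerance = 1e-10)
})

test_that("bin means over 5-s bins equal window means on the same intervals", {
  sim <- simulate_recording(fast_cfg(seed = 13))
  preset <- fast_preset()
  dff <- preprocess(sim$recording, preset)
  avg <- average_trials(zscore_trials(extract_trials(dff, sim$events, preset)))
  b <- bin_trace(avg, 5)
  for (i in seq_len(nrow(b))) {
    expect_equal(b$mean[i], window_mean(avg, c(b$bin_start[i], b$bin_end[i])))
  }
})

test_that("tidy/glance expose trials and summaries as tibbles", {
  sim <- simulate_recording(fast_cfg(seed = 2))
  preset <- fast_preset()
  dff <- preprocess(sim$recording, preset)
  tm <- zscore_trials(extract_trials(dff, sim$events, preset))
  long <- tidy(tm)
  expect_equal(nrow(long), nrow(tm$values) * ncol(tm$values))
  expect_named(long, c("trial", "time", "value", "label", "valid"))
  g <- glance(tm)
  expect_equal(g$n_trials, nrow(tm$values))
  expect_equal(g$scale, "z")
  summ <- summarize_animal(dff, sim$events, preset)
  expect_true(all(c("window_mean", "auc", "n_valid_trials") %in% names(summ)))
})
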