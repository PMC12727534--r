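test_that("read_recording infers fs from timestamps and validates columns", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,signal_465,reference_405",
               "0,1,1", "0.01,2,1", "0.02,3,1"), p)
  rec <- read_recording(p)
  expect_equal(recording_fs(rec), 100)
  expect_equal(rec$signal_465, c(1, 2, 3))

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,signal_465", "0,1", "0.01,2"), p2)
  expect_error(read_recording(p2), "reference_405",
               class = "photoflux_format_error")
})

test_that("non-monotonic or non-uniform timestamps are data errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,signal_465,reference_405",
               "0,1,1", "0.02,2,1", "0.01,3,1"), p)
  expect_error(read_recording(p), class = "photoflux_data_error")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,signal_465,reference_405",
               "0,1,1", "0.01,2,1", "0.05,3,1"), p2)
  expect_error(read_recording(p2), "uniform", class = "photoflux_data_error")
})

test_that("recording round-trip is bit-exact and keeps metadata, csv and tsv", {
  for (ext in c(".csv", ".tsv")) {
    p <- withr::local_tempfile(fileext = ext)
    set.seed(42)
    rec <- raw_recording(seq(0, 2, by = 0.02), rnorm(101, 100), rnorm(101, 70),
                         sensor_tag = "dLight", animal_id = "m01",
                         group_id = "ctrl")
    write_recording(rec, p)
    back <- read_recording(p)
    expect_identical(back$signal_465, rec$signal_465)
    expect_identical(back$reference_405, rec$reference_405)
    expect_identical(back$time_s, rec$time_s)
    expect_identical(attr(back, "animal_id"), "m01")
    expect_identical(attr(back, "sensor_tag"), "dLight")
  }
})

test_that("event tables sort, reject duplicates/negative times, allow empty", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,label", "190.0,pellet", "65.2,pellet"), p)
  ev <- read_events(p)
  expect_equal(ev$time_s, c(65.2, 190.0))
  expect_equal(nrow(ev), 2L)

  expect_error(event_table(c(5, 5), c("a", "b")),
               class = "photoflux_data_error")
  expect_error(event_table(-1, "a"), class = "photoflux_data_error")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_s,label", p2)
  expect_equal(nrow(read_events(p2)), 0L)
})

test_that("event round-trip reproduces times exactly", {
  p <- withr::local_tempfile(fileext = ".tsv")
  ev <- event_table(c(65.2, 190.0, 300.77), "pellet")
  write_events(ev, p)
  back <- read_events(p)
  expect_identical(back$time_s, ev$time_s)
  expect_identical(back$label, ev$label)
})

test_that("built-in protocols carry the documented parameters and validate", {
  dl <- load_protocol("dlight_food")
  expect_equal(dl$baseline, c(-30, -20))
  expect_equal(c(dl$peri_pre, dl$peri_post), c(-30, 60))
  expect_equal(dl$smooth_window, 0)
  expect_equal(dl$summary_windows, list(c(0, 5), c(5, 10)))
  expect_equal(dl$bin_width, 5)

  af <- load_protocol("agrp_food")
  expect_equal(af$smooth_window, 1)
  expect_equal(c(af$peri_pre, af$peri_post), c(-60, 180))
  expect_equal(af$baseline, c(-60, -20))
  expect_equal(af$summary_windows, list(c(15, 180)))

  ai <- load_protocol("agrp_injection")
  expect_equal(c(ai$peri_pre, ai$peri_post), c(-120, 180))
  expect_equal(ai$baseline, c(-120, -60))

  ah <- load_protocol("agrp_hormone")
  expect_equal(ah$smooth_window, 3)
  expect_equal(c(ah$peri_pre, ah$peri_post), c(-300, 1200))
  expect_equal(ah$baseline, c(-300, -60))

  # every built-in respects the protocol invariants by construction:
  # rebuilding from its own fields must succeed
  for (nm in c("dlight_food", "agrp_food", "agrp_injection", "agrp_hormone")) {
    pp <- load_protocol(nm)
    expect_s3_class(do.call(protocol_preset, unclass(pp)), "photometry_protocol")
    expect_true(pp$target_fs == 50)
    expect_lte(pp$baseline[2], 0)
  }
})

test_that("unknown preset names list the valid ones; bad configs fail", {
  expect_error(load_protocol("nope"), "dlight_food",
               class = "photoflux_config_error")
  expect_error(protocol_preset("x", 0, 50, -30, 60, baseline = c(-30, 5)),
               class = "photoflux_param_error")
  expect_error(protocol_preset("x", 0, 50, -30, 60, baseline = c(-40, -20)),
               class = "photoflux_param_error")
  expect_error(protocol_preset("x", 0, 50, -30, 60, baseline = c(-30, -20),
                               summary_windows = list(c(50, 70))),
               class = "photoflux_param_error")
})

test_that("protocols round-trip through JSON", {
  p <- withr::local_tempfile(fileext = ".json")
  orig <- load_protocol("agrp_food")
  write_protocol(orig, p)
  back <- load_protocol(p)
  expect_equal(unclass(back), unclass(orig))
})
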