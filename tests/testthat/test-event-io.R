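test_that("long-format TextGrid point tier reads back directly", {
  p <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(make_long_textgrid(c(0.10, 0.40, 0.69)), p)
  rec <- read_textgrid(p, "steps", individual_id = "h1", gait = "walk")
  expect_equal(rec$onsets, c(0.10, 0.40, 0.69), tolerance = 1e-9)
  expect_identical(rec$gait, "walk")
})

test_that("short- and long-format TextGrids with same content agree", {
  times <- c(0.12, 0.31, 0.55, 0.80)
  p1 <- withr::local_tempfile(fileext = ".TextGrid")
  p2 <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(make_long_textgrid(times), p1)
  writeLines(make_short_textgrid(times), p2)
  r1 <- read_textgrid(p1, "steps", "h", "trot")
  r2 <- read_textgrid(p2, "steps", "h", "trot")
  expect_equal(r1$onsets, r2$onsets, tolerance = 1e-9)
})

test_that("TextGrid write/read round-trip is lossless to 1e-6 s", {
  rec <- simulate_recording(gait_spec("trot", 0.36, 0.05, 10), 1, seed = 2,
                            individual_id = "h2")
  p <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(rec, p)
  back <- read_textgrid(p, "trot", individual_id = "h2")
  expect_equal(back$onsets, rec$onsets, tolerance = 1e-6)
})

test_that("UTF-16 TextGrids are decoded via byte-order mark", {
  lines <- make_long_textgrid(c(0.2, 0.5, 0.9))
  raw16 <- iconv(paste0(paste(lines, collapse = "\n"), "\n"),
                 from = "UTF-8", to = "UTF-16LE", toRaw = TRUE)[[1]]
  p <- withr::local_tempfile(fileext = ".TextGrid")
  con <- file(p, "wb")
  writeBin(as.raw(c(0xFF, 0xFE)), con)
  writeBin(raw16, con)
  close(con)
  rec <- read_textgrid(p, "steps", "h", "walk")
  expect_equal(rec$onsets, c(0.2, 0.5, 0.9), tolerance = 1e-9)
})

test_that("missing tier and duplicate points are handled", {
  p <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(make_long_textgrid(c(0.1, 0.4)), p)
  expect_error(read_textgrid(p, "nope", "h", "walk"),
               class = "gaitrhythm_tier_not_found")

  writeLines(make_long_textgrid(c(0.1, 0.1, 0.4, 0.7)), p)
  expect_warning(rec <- read_textgrid(p, "steps", "h", "walk"), "duplicate")
  expect_equal(rec$onsets, c(0.1, 0.4, 0.7), tolerance = 1e-9)
})

test_that("CSV writer emits one row per onset and round-trips", {
  recs <- fixture_clean_recordings()
  p <- withr::local_tempfile(fileext = ".csv")
  n <- write_timeseries_csv(recs, p)
  expect_identical(n, sum(vapply(recs, function(r) length(r$onsets), 0L)))
  back <- read_timeseries_csv(p)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$onsets, recs[[i]]$onsets, tolerance = 1e-9)
    expect_identical(back[[i]]$individual_id, recs[[i]]$individual_id)
    expect_identical(back[[i]]$gait, recs[[i]]$gait)
  }
})

test_that("CSV reader groups interleaved rows and validates input", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,gait,onset_s",
               "a,walk,0.0", "b,walk,0.1", "a,walk,0.4", "b,walk,0.5",
               "a,trot,0.0", "a,trot,0.3"), p)
  recs <- read_timeseries_csv(p)
  expect_length(recs, 3)
  expect_equal(recs[[1]]$onsets, c(0.0, 0.4))
  expect_equal(recs[[2]]$onsets, c(0.1, 0.5))
  expect_identical(recs[[3]]$gait, "trot")

  writeLines(c("individual_id,gait,onset_s", "a,walk,0.0", "a,walk,oops",
               "a,walk,0.4"), p)
  expect_error(read_timeseries_csv(p), "line\\(s\\): 2",
               class = "gaitrhythm_format")

  writeLines(c("individual_id,gait,onset_s", "a,walk,-1", "a,walk,0.4"), p)
  expect_error(read_timeseries_csv(p), class = "gaitrhythm_format")

  writeLines("individual_id,gait,onset_s", p)
  expect_error(read_timeseries_csv(p), class = "gaitrhythm_format")
})
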