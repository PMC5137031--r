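test_that("fixation exports parse, group and sort correctly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("ParticipantName", "MediaName", "GazeEventType",
          "RecordingTimestamp", "GazeEventDuration", "FixationPointX",
          "FixationPointY", "RecordingQuality", sep = "\t"),
    "P01\tS1\tFixation\t400\t90\t100\t100\t85",
    "P01\tS1\tFixation\t0\t80\t120\t110\t85",
    "P01\tS1\tSaccade\t100\t40\t\t\t85"), f)
  ev <- read_fixation_export(f)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$start_ms, c(0, 100, 400))  # time-sorted
  expect_equal(ev$event_type, c("Fixation", "Saccade", "Fixation"))
  expect_equal(unique(ev$recording_quality), 0.85)
  expect_true(is.na(ev$x[2]))  # empty coordinates allowed on saccades

  # 2 participants x 2 stimuli -> 4 recordings
  writeLines(c(
    readLines(f)[1],
    "P01\tS1\tFixation\t0\t80\t1\t1\t90",
    "P01\tS2\tFixation\t0\t80\t1\t1\t90",
    "P02\tS1\tFixation\t0\t80\t1\t1\t90",
    "P02\tS2\tFixation\t0\t80\t1\t1\t90"), f)
  ev <- read_fixation_export(f)
  expect_equal(nrow(unique(ev[, c("participant_id", "stimulus_id")])), 4)

  # header-only file is empty, not an error
  writeLines(readLines(f)[1], f)
  expect_equal(nrow(read_fixation_export(f)), 0)
})

test_that("parse errors name the offending column and line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ParticipantName\tMediaName\tGazeEventType", "P01\tS1\tFixation"), f)
  expect_error(read_fixation_export(f), "RecordingTimestamp")

  writeLines(c(
    paste("ParticipantName", "MediaName", "GazeEventType",
          "RecordingTimestamp", "GazeEventDuration", "FixationPointX",
          "FixationPointY", "RecordingQuality", sep = "\t"),
    "P01\tS1\tFixation\t0\t80\t1\t1\t90",
    "P01\tS1\tFixation\t100\tabc\t1\t1\t90"), f)
  err <- tryCatch(read_fixation_export(f), error = conditionMessage)
  expect_match(err, "GazeEventDuration")
  expect_match(err, "line 3")
})

test_that("quality filtering is per participant, boundary-inclusive and idempotent", {
  ev <- bind_events(
    make_event("P01", "S1", "Fixation", 0, 100, 50, 100, quality = 0.70),
    make_event("P01", "S2", "Fixation", 0, 100, 50, 100, quality = 0.70),
    make_event("P02", "S1", "Fixation", 0, 100, 50, 100, quality = 0.69),
    make_event("P02", "S2", "Fixation", 0, 100, 50, 100, quality = 0.69),
    make_event("P03", "S1", "Fixation", 0, 100, 50, 100, quality = 0))
  out <- filter_recordings(ev)
  # exactly the boundary participant survives; all of a failing
  # participant's recordings drop together
  expect_setequal(unique(out$participant_id), "P01")
  expect_equal(nrow(out), 2)
  expect_identical(filter_recordings(out), out)
})

test_that("the 43-participant cohort with 12 low-quality members filters to 31", {
  cfg <- synthetic_config(
    stimuli = data.frame(stimulus_id = "S1", layout_id = "A",
                         n_correct = 16L, n_incorrect = 15L),
    n_participants = 31L, n_low_quality = 12L, seed = 11)
  cohort <- generate_cohort(cfg)
  expect_equal(length(unique(cohort$events$participant_id)), 43)
  kept <- filter_recordings(cohort$events)
  expect_equal(length(unique(kept$participant_id)), 31)
})

test_that("scan-path construction applies the event filters", {
  lay <- ecg_layout("A")
  r <- lay$regions
  in_aoi <- function(lab) {
    i <- match(lab, r$label)
    c(x = (r$x_min[i] + r$x_max[i]) / 2, y = (r$y_min[i] + r$y_max[i]) / 2)
  }
  g <- in_aoi("G"); h <- in_aoi("H")  # V1 and V2
  ev <- bind_events(
    make_event("P01", "S1", "Fixation", 0, 80, g["x"], g["y"]),
    make_event("P01", "S1", "Saccade", 80, 40, g["x"], g["y"]),
    make_event("P01", "S1", "Fixation", 120, 90, h["x"], h["y"]))
  p <- build_scanpaths(ev, lay)
  expect_equal(p$aoi_label, c("G", "H"))

  # 59 ms dropped, 60 ms kept (minimum fixation duration boundary)
  ev <- bind_events(
    make_event("P01", "S1", "Fixation", 0, 59, g["x"], g["y"]),
    make_event("P01", "S1", "Fixation", 100, 60, g["x"], g["y"]))
  expect_equal(build_scanpaths(ev, lay)$duration_ms, 60)

  # fixation in no AOI is bridged over: neighbours become adjacent
  gap <- c(x = 35, y = 35)  # outside every rectangle
  ev <- bind_events(
    make_event("P01", "S1", "Fixation", 0, 100, g["x"], g["y"]),
    make_event("P01", "S1", "Fixation", 200, 100, gap["x"], gap["y"]),
    make_event("P01", "S1", "Fixation", 400, 100, h["x"], h["y"]))
  expect_equal(build_scanpaths(ev, lay)$aoi_label, c("G", "H"))

  # annotation AOIs drop under lead_only but are kept otherwise
  ann <- in_aoi("N")
  ev <- bind_events(
    make_event("P01", "S1", "Fixation", 0, 100, ann["x"], ann["y"]),
    make_event("P01", "S1", "Fixation", 200, 100, g["x"], g["y"]))
  expect_equal(build_scanpaths(ev, lay)$aoi_label, "G")
  expect_equal(build_scanpaths(ev, lay, lead_only = FALSE)$aoi_label,
               c("N", "G"))

  # AOI membership is half-open: a point on a shared grid edge belongs to
  # exactly one AOI, and a point at x_max is outside
  edge <- make_event("P01", "S1", "Fixation", 0, 100, r$x_max[match("A", r$label)],
                     (r$y_min[1] + r$y_max[1]) / 2)
  p <- build_scanpaths(bind_events(edge), lay)
  expect_true(nrow(p) <= 1)
  if (nrow(p) == 1) expect_false(p$aoi_label == "A")
})

test_that("collapse_repeats merges runs and sums their durations", {
  lay <- ecg_layout("A")
  i <- match("G", lay$regions$label)
  x <- (lay$regions$x_min[i] + lay$regions$x_max[i]) / 2
  y <- (lay$regions$y_min[i] + lay$regions$y_max[i]) / 2
  ev <- bind_events(
    make_event("P01", "S1", "Fixation", 0, 100, x, y),
    make_event("P01", "S1", "Fixation", 200, 150, x, y))
  merged <- build_scanpaths(ev, lay, collapse_repeats = TRUE)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$duration_ms, 250)
  expect_equal(nrow(build_scanpaths(ev, lay)), 2)
})

test_that("write-then-read round-trips every event field", {
  cohort <- generate_cohort(single_stimulus_config(delta = 0, seed = 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_export(cohort$events, f)
  back <- read_fixation_export(f)
  expect_equal(back$participant_id, cohort$events$participant_id)
  expect_equal(back$event_type, cohort$events$event_type)
  expect_equal(back$start_ms, cohort$events$start_ms)
  expect_equal(back$duration_ms, cohort$events$duration_ms)
  expect_equal(back$x, cohort$events$x)
  expect_equal(back$y, cohort$events$y)
  expect_equal(back$recording_quality, cohort$events$recording_quality,
               tolerance = 1e-12)
})
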