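#' Column dialect for fixation-event exports
#'
#' Fixation exports are UTF-8 tab-separated files with one classified gaze
#' event per row. The default dialect matches a Tobii-Studio-style export;
#' any source can be read by remapping the column names.
#'
#' @param participant,stimulus,event_type,start,duration,x,y,quality Column
#'   names in the export file for, respectively, the participant identifier,
#'   stimulus identifier, gaze event type (`Fixation`, `Saccade` or
#'   `Unclassified`), event onset (ms), event duration (ms), fixation point
#'   coordinates (px), and per-participant recording quality (0--100 %,
#'   repeated on every row).
#' @return A named list of column names.
#' @export
tobii_dialect <- function(participant = "ParticipantName",
                          stimulus = "MediaName",
                          event_type = "GazeEventType",
                          start = "RecordingTimestamp",
                          duration = "GazeEventDuration",
                          x = "FixationPointX",
                          y = "FixationPointY",
                          quality = "RecordingQuality") {
  list(participant = participant, stimulus = stimulus,
       event_type = event_type, start = start, duration = duration,
       x = x, y = y, quality = quality)
}

.event_types <- c("Fixation", "Saccade", "Unclassified")

#' Read a fixation-event export
#'
#' Parses a tab-separated export of classified gaze events into a tidy event
#' table with one row per event and canonical column names. All event types
#' are retained; filtering (quality, fixation-only, minimum duration, AOI
#' membership) happens downstream in [filter_recordings()] and
#' [build_scanpaths()]. Events are sorted by onset within each
#' (participant, stimulus) recording. Recording quality is rescaled from the
#' file's percentage to a fraction in `[0, 1]`.
#'
#' @param path Path to the TSV export (header row required). An empty file
#'   (header only) yields a zero-row table.
#' @param dialect Column mapping, see [tobii_dialect()].
#' @return A `data.frame` of class `gaze_events` with columns
#'   `participant_id`, `stimulus_id`, `event_type`, `start_ms`,
#'   `duration_ms`, `x`, `y`, `recording_quality`.
#' @export
read_fixation_export <- function(path, dialect = tobii_dialect()) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(unlist(dialect), names(raw))
  if (length(missing_cols) > 0L) {
    stop("fixation export is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num <- function(field) {
    v <- trimws(raw[[dialect[[field]]]])
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & v != "")
    if (length(bad) > 0L) {
      stop("non-numeric value in column '", dialect[[field]], "' at line ",
           bad[1] + 1L, ": '", v[bad[1]], "'")  # +1 for the header row
    }
    out
  }
  ev <- data.frame(
    participant_id = raw[[dialect$participant]],
    stimulus_id = raw[[dialect$stimulus]],
    event_type = raw[[dialect$event_type]],
    start_ms = num("start"),
    duration_ms = num("duration"),
    x = num("x"),
    y = num("y"),
    recording_quality = num("quality") / 100
  )
  unknown <- setdiff(unique(ev$event_type), .event_types)
  if (length(unknown) > 0L) {
    stop("unknown gaze event type(s): ", paste(unknown, collapse = ", "))
  }
  ev <- ev[order(ev$participant_id, ev$stimulus_id, ev$start_ms), ]
  rownames(ev) <- NULL
  class(ev) <- c("gaze_events", "data.frame")
  ev
}

#' Write gaze events in the fixation-export dialect
#'
#' Emits the exact TSV dialect consumed by [read_fixation_export()], so that
#' write-then-read round-trips reproduce every event field. Recording
#' quality is written back on the 0--100 scale.
#'
#' @param events A `gaze_events` data frame (see [read_fixation_export()]).
#' @param path Output file path.
#' @param dialect Column mapping, see [tobii_dialect()].
#' @export
write_fixation_export <- function(events, path, dialect = tobii_dialect()) {
  out <- data.frame(
    events$participant_id, events$stimulus_id, events$event_type,
    events$start_ms, events$duration_ms, events$x, events$y,
    events$recording_quality * 100,
    check.names = FALSE
  )
  names(out) <- unlist(dialect[c("participant", "stimulus", "event_type",
                                 "start", "duration", "x", "y", "quality")])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Exclude participants with poor recording quality
#'
#' Drops every event of any participant whose recording quality is below the
#' threshold; a participant exactly at the threshold is retained ("below" is
#' excluded). Exclusion is per participant: all of a failing participant's
#' recordings drop together. The operation is idempotent.
#'
#' @param events A `gaze_events` data frame.
#' @param quality_threshold Minimum acceptable recording quality as a
#'   fraction; the default 0.70 is the eye-tracker manufacturer's
#'   recommended floor.
#' @return The filtered `gaze_events` data frame.
#' @export
filter_recordings <- function(events, quality_threshold = 0.70) {
  stopifnot(quality_threshold >= 0, quality_threshold <= 1)
  if (nrow(events) == 0L) return(events)
  q <- tapply(events$recording_quality, events$participant_id, max)
  keep_ids <- names(q)[q >= quality_threshold]
  out <- events[events$participant_id %in% keep_ids, ]
  rownames(out) <- NULL
  class(out) <- class(events)
  out
}

#' Build AOI scan paths from gaze events
#'
#' Reduces classified gaze events to per-participant, per-stimulus scan
#' paths over the layout's AOIs, applying the study filters: only events of
#' type `Fixation`, of duration at least `min_fixation_ms`, whose centre
#' point falls inside an AOI rectangle, are retained. Rectangles are
#' half-open (`x_min <= x < x_max`, `y_min <= y < y_max`), so a point on a
#' shared edge belongs to exactly one AOI. With `lead_only = TRUE` (the
#' default) fixations on annotation AOIs are also dropped. Filtered-out
#' events are bridged over: the surviving neighbours become adjacent in the
#' path. Consecutive fixations within the same AOI are kept as separate
#' steps (producing self-transitions) unless `collapse_repeats = TRUE`, in
#' which case runs merge into one step whose duration is the run total.
#'
#' @param events A `gaze_events` data frame; may span several participants
#'   and stimuli, but all events must belong to stimuli of `layout`'s type.
#' @param layout An [aoi_layout()] object.
#' @param min_fixation_ms Minimum fixation duration in ms (default 60, the
#'   classifier's default threshold; fixations this short occur in reading).
#' @param lead_only Keep only lead/rhythm AOIs (drop annotations).
#' @param collapse_repeats Merge runs of same-AOI fixations into one step.
#' @return A `data.frame` of class `scanpaths` with columns
#'   `participant_id`, `stimulus_id`, `start_ms`, `aoi_label`,
#'   `duration_ms`, ordered by participant, stimulus and onset. A
#'   participant with no surviving fixations simply has no rows.
#' @export
build_scanpaths <- function(events, layout, min_fixation_ms = 60,
                            lead_only = TRUE, collapse_repeats = FALSE) {
  stopifnot(inherits(layout, "aoi_layout"), min_fixation_ms >= 0)
  r <- layout$regions
  if (lead_only) r <- r[r$is_lead, ]
  keep <- events$event_type == "Fixation" &
    !is.na(events$duration_ms) & events$duration_ms >= min_fixation_ms &
    !is.na(events$x) & !is.na(events$y)
  ev <- events[keep, , drop = FALSE]
  label <- rep(NA_character_, nrow(ev))
  for (i in seq_len(nrow(r))) {
    inside <- ev$x >= r$x_min[i] & ev$x < r$x_max[i] &
      ev$y >= r$y_min[i] & ev$y < r$y_max[i]
    label[inside] <- r$label[i]
  }
  ev$aoi_label <- label
  ev <- ev[!is.na(label), c("participant_id", "stimulus_id", "start_ms",
                            "aoi_label", "duration_ms")]
  ev <- ev[order(ev$participant_id, ev$stimulus_id, ev$start_ms), ]
  rownames(ev) <- NULL
  if (collapse_repeats && nrow(ev) > 1L) {
    n <- nrow(ev)
    new_run <- c(TRUE,
                 ev$participant_id[-1] != ev$participant_id[-n] |
                 ev$stimulus_id[-1] != ev$stimulus_id[-n] |
                 ev$aoi_label[-1] != ev$aoi_label[-n])
    run <- cumsum(new_run)
    dur <- as.vector(tapply(ev$duration_ms, run, sum))
    ev <- ev[new_run, ]
    ev$duration_ms <- dur
    rownames(ev) <- NULL
  }
  class(ev) <- c("scanpaths", "data.frame")
  ev
}
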