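# Small programmatic fixtures shared across test files.

# A scan-path data frame from a label sequence.
make_path <- function(labels, pid = "P01", stim = "S1", duration = 100) {
  n <- length(labels)
  structure(
    data.frame(participant_id = rep(pid, n), stimulus_id = rep(stim, n),
               start_ms = seq_len(n) * 500, aoi_label = labels,
               duration_ms = rep_len(duration, n)),
    class = c("scanpaths", "data.frame"))
}

bind_paths <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("scanpaths", "data.frame")
  out
}

# A gaze-events row builder.
make_event <- function(pid, stim, type, start, dur, x, y, quality = 0.9) {
  data.frame(participant_id = pid, stimulus_id = stim, event_type = type,
             start_ms = start, duration_ms = dur, x = x, y = y,
             recording_quality = quality)
}

bind_events <- function(...) {
  out <- do.call(rbind, list(...))
  out <- out[order(out$participant_id, out$stimulus_id, out$start_ms), ]
  rownames(out) <- NULL
  class(out) <- c("gaze_events", "data.frame")
  out
}

# An interpretation-labels frame giving n_correct of the ids "correct" and
# the rest alternating partially_correct/incorrect.
make_labels <- function(ids, n_correct, stim = "S1") {
  lab <- rep(c("partially_correct", "incorrect"), length.out = length(ids))
  lab[seq_len(n_correct)] <- "correct"
  data.frame(participant_id = ids, stimulus_id = stim, label = lab)
}

# Single-stimulus synthetic config for calibration/power runs: 31
# participants split 16/15 on one layout-B stimulus (15 states).
single_stimulus_config <- function(delta, seed, n_correct = 16L,
                                   n_participants = 31L, ...) {
  synthetic_config(
    stimuli = data.frame(stimulus_id = "S1", layout_id = "B",
                         n_correct = n_correct,
                         n_incorrect = n_participants - n_correct),
    n_participants = n_participants, delta = delta, seed = seed, ...)
}

# Analyse one generated single-stimulus cohort end to end; returns the
# permutation result.
analyse_single <- function(cohort, n_perm, seed, ...) {
  layout <- ecg_layout("B")
  paths <- build_scanpaths(cohort$events, layout)
  assignment <- split_groups(cohort$labels, "S1",
                             cohort = sort(unique(cohort$events$participant_id)))
  permutation_test(paths, assignment, lead_states(layout), n_perm = n_perm,
                   seed = seed, ...)
}
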