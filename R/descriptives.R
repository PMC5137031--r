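#' Per-lead fixation descriptives by interpretation group
#'
#' Summarises fixation behaviour per AOI and group for one stimulus: the
#' mean (over group participants) total dwell time in the AOI, the mean
#' number of fixations on it, and the mean duration of a single fixation.
#' Participants who never fixated an AOI contribute zeros to the group
#' means rather than being dropped, so means do not depend on visit
#' prevalence. Note the distinction between the two duration metrics:
#' `mean_total_dwell_s` is per participant (and can reach several seconds
#' on a heavily revisited rhythm strip), while `mean_single_fixation_s` is
#' per fixation (typically a few hundred milliseconds) — group total dwell
#' divided by group fixation count, 0 when the count is 0.
#'
#' @param paths A `scanpaths` data frame for one stimulus.
#' @param assignment A [split_groups()] assignment for the same stimulus.
#' @param layout The stimulus's [aoi_layout()]; every lead AOI appears in
#'   the output even if never fixated.
#' @return Data frame with one row per (group, lead AOI): `stimulus_id`,
#'   `group`, `aoi_label`, `aoi_name`, `mean_total_dwell_s`,
#'   `mean_fixation_count`, `mean_single_fixation_s`, `n_participants`.
#' @export
aoi_fixation_summary <- function(paths, assignment, layout) {
  stopifnot(inherits(assignment, "group_assignment"),
            inherits(layout, "aoi_layout"))
  assigned <- c(assignment$correct_ids, assignment$incorrect_ids)
  stray <- setdiff(unique(paths$participant_id), assigned)
  if (length(stray) > 0L) {
    stop("participant(s) in scan paths but not in the group assignment: ",
         paste(stray, collapse = ", "))
  }
  leads <- layout$regions[layout$regions$is_lead, c("label", "name")]
  groups <- list(correct = assignment$correct_ids,
                 incorrect = assignment$incorrect_ids)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    ids <- groups[[g]]
    n_g <- length(ids)
    sub <- paths[paths$participant_id %in% ids, , drop = FALSE]
    per <- lapply(leads$label, function(lab) {
      rows <- sub[sub$aoi_label == lab, , drop = FALSE]
      total_count <- nrow(rows)
      total_dwell <- sum(rows$duration_ms) / 1000
      data.frame(
        group = g, aoi_label = lab,
        mean_total_dwell_s = if (n_g > 0) total_dwell / n_g else 0,
        mean_fixation_count = if (n_g > 0) total_count / n_g else 0,
        mean_single_fixation_s =
          if (total_count > 0) total_dwell / total_count else 0,
        n_participants = n_g
      )
    })
    do.call(rbind, per)
  }))
  out <- cbind(stimulus_id = assignment$stimulus_id, out)
  out$aoi_name <- leads$name[match(out$aoi_label, leads$label)]
  out[, c("stimulus_id", "group", "aoi_label", "aoi_name",
          "mean_total_dwell_s", "mean_fixation_count",
          "mean_single_fixation_s", "n_participants")]
}
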