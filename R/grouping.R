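#' Collapse three-way interpretation labels to correct/incorrect
#'
#' Interpretation adjudications arrive as one of three codes: `correct`,
#' `partially_correct` or `incorrect`. For analysis, partially correct
#' answers are amalgamated into the incorrect group, leaving a clean binary
#' split: an answer either names the condition precisely or it does not.
#'
#' @param raw_label Character vector of raw codes.
#' @return Character vector of `"correct"` / `"incorrect"`.
#' @export
binarize_label <- function(raw_label) {
  raw_label <- as.character(raw_label)
  bad <- setdiff(unique(raw_label), c("correct", "partially_correct", "incorrect"))
  if (length(bad) > 0L) {
    stop("unknown interpretation label(s): ", paste(bad, collapse = ", "),
         " (expected correct, partially_correct or incorrect)")
  }
  ifelse(raw_label == "correct", "correct", "incorrect")
}

#' Read a per-stimulus interpretation labels file
#'
#' @param path CSV with columns `participant_id`, `stimulus_id`, `label`
#'   (one of `correct`, `partially_correct`, `incorrect`).
#' @return Data frame with those three columns.
#' @export
read_interpretation_labels <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  needed <- c("participant_id", "stimulus_id", "label")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0L) {
    stop("labels file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  invisible(binarize_label(d$label))  # validates the codes
  d[, needed]
}

#' Split the cohort into correct and incorrect groups for one stimulus
#'
#' @param records Data frame of interpretation records (`participant_id`,
#'   `stimulus_id`, `label`); labels may be three-way, they are binarized
#'   internally.
#' @param stimulus_id The stimulus to split on.
#' @param cohort Optional character vector of participant ids that must all
#'   be labelled for this stimulus; ids present here but missing from
#'   `records` raise an error listing them.
#' @return An object of class `group_assignment`: a list with
#'   `stimulus_id`, `correct_ids`, `incorrect_ids`. The two sets are
#'   disjoint; a stimulus is only testable downstream when both are
#'   non-empty.
#' @export
split_groups <- function(records, stimulus_id, cohort = NULL) {
  rec <- records[records$stimulus_id == stimulus_id, , drop = FALSE]
  if (anyDuplicated(rec$participant_id)) {
    dups <- unique(rec$participant_id[duplicated(rec$participant_id)])
    stop("duplicate interpretation records for stimulus ", stimulus_id,
         ": ", paste(dups, collapse = ", "))
  }
  if (!is.null(cohort)) {
    absent <- setdiff(cohort, rec$participant_id)
    if (length(absent) > 0L) {
      stop("participants without an interpretation record for stimulus ",
           stimulus_id, ": ", paste(absent, collapse = ", "))
    }
    rec <- rec[rec$participant_id %in% cohort, , drop = FALSE]
  }
  lab <- binarize_label(rec$label)
  structure(
    list(stimulus_id = stimulus_id,
         correct_ids = sort(rec$participant_id[lab == "correct"]),
         incorrect_ids = sort(rec$participant_id[lab == "incorrect"])),
    class = "group_assignment"
  )
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Group assignment for stimulus '", x$stimulus_id, "': ",
      length(x$correct_ids), " correct / ",
      length(x$incorrect_ids), " incorrect\n", sep = "")
  invisible(x)
}
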