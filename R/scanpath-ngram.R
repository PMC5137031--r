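#' Encode a scan path as a string of AOI letters
#'
#' Scan paths are represented as strings whose characters are the
#' single-letter AOI labels, visited in order. Optionally, runs of repeated
#' letters collapse to one (an idempotent operation); by default repeats
#' are kept, matching the convention used for transition counting.
#'
#' @param labels Character vector of single-letter AOI labels in visit
#'   order (e.g. the `aoi_label` column of one path).
#' @param collapse_repeats Collapse runs of identical letters to one.
#' @return A single string; an empty path encodes to `""`.
#' @export
encode_scanpath <- function(labels, collapse_repeats = FALSE) {
  labels <- as.character(labels)
  if (length(labels) == 0L) return("")
  if (collapse_repeats) labels <- rle(labels)$values
  paste(labels, collapse = "")
}

#' Encode every path of a scan-path table
#'
#' @param paths A `scanpaths` data frame (see [build_scanpaths()]).
#' @param collapse_repeats See [encode_scanpath()].
#' @return Data frame `participant_id`, `stimulus_id`, `string`.
#' @export
encode_scanpaths <- function(paths, collapse_repeats = FALSE) {
  if (nrow(paths) == 0L) {
    return(data.frame(participant_id = character(0),
                      stimulus_id = character(0), string = character(0)))
  }
  key <- interaction(paths$participant_id, paths$stimulus_id, drop = TRUE)
  pieces <- split(paths, key)
  out <- do.call(rbind, lapply(pieces, function(p) {
    data.frame(participant_id = p$participant_id[1],
               stimulus_id = p$stimulus_id[1],
               string = encode_scanpath(p$aoi_label, collapse_repeats))
  }))
  rownames(out) <- NULL
  out[order(out$participant_id, out$stimulus_id), , drop = FALSE]
}

#' Sliding-window n-gram counts over scan-path strings
#'
#' Counts every contiguous substring of each size in `n_range`, with
#' overlapping windows, pooled across the supplied strings. Windows never
#' span two strings (two participants' paths never concatenate), so the
#' total count at size `n` is `sum(max(nchar(s) - n + 1, 0))`.
#'
#' @param strings Character vector of encoded scan paths for one stimulus.
#' @param n_range Integer interval `c(lower, upper)` of gram sizes; the
#'   lower bound must be at least 2 (a 1-gram carries no sequence
#'   information).
#' @return Data frame `n`, `gram`, `count`, one row per observed n-gram,
#'   ordered by `n` then decreasing `count`.
#' @export
ngram_frequencies <- function(strings, n_range = c(2L, 8L)) {
  n_range <- as.integer(n_range)
  if (length(n_range) != 2L || n_range[1] < 2L) {
    stop("n_range must be c(lower, upper) with lower >= 2")
  }
  if (n_range[2] < n_range[1]) stop("n_range upper bound below lower bound")
  out <- list()
  for (n in seq(n_range[1], n_range[2])) {
    grams <- unlist(lapply(strings, function(s) {
      len <- nchar(s)
      if (len < n) return(character(0))
      substring(s, 1:(len - n + 1L), n:len)
    }))
    if (length(grams) == 0L) next
    tab <- table(grams)
    out[[length(out) + 1L]] <- data.frame(
      n = n, gram = names(tab), count = as.integer(tab))
  }
  if (length(out) == 0L) {
    return(data.frame(n = integer(0), gram = character(0), count = integer(0)))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$n, -out$count, out$gram), ]
  rownames(out) <- NULL
  out
}

#' Profile the repeated-sequence structure of an n-gram table
#'
#' For each gram size, records the count of the single most frequent gram;
#' reports the modal size (the `n` whose best gram is most frequent, ties
#' broken toward smaller `n`) and the largest size at which any gram occurs
#' at least twice. A modal size of 2 across stimuli is the empirical
#' justification for modelling gaze shifts as a first-order Markov process:
#' the dominant repeated unit is the single transition.
#'
#' @param table A data frame from [ngram_frequencies()].
#' @return List with `per_n_max_frequency` (named integer vector),
#'   `modal_n`, and `max_repeated_length` (1 if no gram repeats).
#' @export
ngram_profile <- function(table) {
  if (nrow(table) == 0L) stop("empty n-gram table")
  best <- tapply(table$count, table$n, max)
  ns <- as.integer(names(best))
  modal_n <- ns[which.max(best)]   # which.max takes the first => smallest n
  repeated <- ns[best >= 2L]
  list(
    per_n_max_frequency = stats::setNames(as.integer(best), names(best)),
    modal_n = modal_n,
    max_repeated_length = if (length(repeated) > 0L) max(repeated) else 1L
  )
}
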