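#' Study design reference table
#'
#' The eleven ECG stimuli of the reference study design, with their layout
#' type (A: one rhythm strip, lead II; B: three rhythm strips V1, II, V5),
#' the published correct/incorrect group sizes for the 31-participant
#' analysed cohort, and the key leads that the ECG literature associates
#' with each condition (`"None"` where diagnosis does not depend on
#' specific leads; `"Rhythm strip"` where the rhythm strip(s) are the key
#' region). This table drives the default synthetic study and annotates
#' reports; it is reference metadata, not measured data.
#'
#' @return Data frame with columns `stimulus_id`, `layout_id`, `n_correct`,
#'   `n_incorrect`, `key_leads`.
#' @export
study_design <- function() {
  data.frame(
    stimulus_id = c(
      "Anterolateral STEMI", "Atrial Flutter", "Hyperkalaemia",
      "LBBB", "Normal Sinus Rhythm", "Sinus Tachycardia",
      "Supraventricular Tachycardia", "torsades de pointes",
      "Ventricular paced rhythm", "Ventricular Tachycardia",
      "Wolff-Parkinson-White syndrome"),
    layout_id = c("A", "A", "A", "B", "B", "B", "B", "A", "B", "B", "A"),
    n_correct = c(16L, 25L, 2L, 23L, 23L, 12L, 10L, 5L, 9L, 26L, 12L),
    n_incorrect = c(15L, 6L, 29L, 8L, 8L, 19L, 21L, 26L, 22L, 5L, 19L),
    key_leads = c(
      "I, aVL, V1-V6", "Rhythm strip", "None", "V1, V6", "None",
      "Rhythm strip", "Rhythm strip", "None", "None", "None", "V1-V3")
  )
}

# Expand a key-leads annotation into AOI letter labels of a layout.
# "None" -> character(0); "Rhythm strip" -> every rhythm-strip AOI;
# otherwise a comma-separated list of lead names, ranges like "V1-V6"
# allowed.
key_lead_labels <- function(key_leads, layout) {
  r <- layout$regions[layout$regions$is_lead, ]
  if (is.na(key_leads) || key_leads == "None") return(character(0))
  if (key_leads == "Rhythm strip") {
    return(r$label[grepl("^rhythm", r$name)])
  }
  parts <- trimws(strsplit(key_leads, ",")[[1]])
  names_out <- unlist(lapply(parts, function(p) {
    if (grepl("^V[1-6]-V[1-6]$", p)) {
      lo <- as.integer(substr(p, 2, 2))
      hi <- as.integer(substr(p, 5, 5))
      paste0("V", lo:hi)
    } else p
  }))
  lab <- r$label[match(names_out, r$name)]
  if (anyNA(lab)) {
    stop("key lead name(s) not in layout: ",
         paste(names_out[is.na(lab)], collapse = ", "))
  }
  lab
}
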