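#' AOI layouts for 12-lead ECG stimuli
#'
#' An AOI (area of interest) layout is a set of labelled, non-overlapping
#' rectangles over one ECG stimulus image. Lead and rhythm-strip AOIs
#' (`is_lead = TRUE`) define the state space of the transition analysis;
#' annotation AOIs are carried along for completeness but excluded when scan
#' paths are built with `lead_only = TRUE`.
#'
#' Two layout families are supported, mirroring the two stimulus formats of
#' the study design: type A stimuli show the 12 standard leads plus a single
#' rhythm strip (lead II), giving 13 lead AOIs lettered `A`--`M`; type B
#' stimuli show three rhythm strips (V1, II, V5), giving 15 lead AOIs
#' lettered `A`--`O`, with annotation AOIs taking the following letters.
#'
#' @param layout_id `"A"` or `"B"`.
#' @param regions A data frame with columns `label`, `name`, `x_min`,
#'   `y_min`, `x_max`, `y_max`, `is_lead`, one row per AOI, in state order.
#' @param stimulus_size Numeric length-2 vector `(width, height)` in pixels.
#' @param key_leads Optional character vector of AOI labels regarded as the
#'   key leads for the displayed condition (reference metadata only).
#'
#' @return An object of class `aoi_layout`: a list with elements
#'   `layout_id`, `regions`, `stimulus_size` and `key_leads`.
#' @seealso [load_aoi_layout()], [ecg_layout()], [lead_states()]
#' @export
aoi_layout <- function(layout_id, regions, stimulus_size, key_leads = NULL) {
  layout_id <- match.arg(as.character(layout_id), c("A", "B"))
  stopifnot(is.data.frame(regions), length(stimulus_size) == 2)
  needed <- c("label", "name", "x_min", "y_min", "x_max", "y_max", "is_lead")
  missing_cols <- setdiff(needed, names(regions))
  if (length(missing_cols) > 0L) {
    stop("layout regions lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  regions <- regions[, needed]
  regions$label <- as.character(regions$label)
  regions$name <- as.character(regions$name)
  regions$is_lead <- as.logical(regions$is_lead)
  x <- structure(
    list(
      layout_id = layout_id,
      regions = regions,
      stimulus_size = as.numeric(stimulus_size),
      key_leads = if (is.null(key_leads)) character(0) else as.character(key_leads)
    ),
    class = "aoi_layout"
  )
  validate_aoi_layout(x)
  x
}

# Expected number of lead/rhythm AOIs per layout family:
# A = 12 leads + rhythm II; B = 12 leads + rhythm V1, II, V5.
.lead_counts <- c(A = 13L, B = 15L)

validate_aoi_layout <- function(x) {
  r <- x$regions
  if (anyDuplicated(r$label)) {
    dups <- unique(r$label[duplicated(r$label)])
    stop("duplicate AOI label(s) in layout: ", paste(dups, collapse = ", "))
  }
  bad <- r$x_min >= r$x_max | r$y_min >= r$y_max
  if (any(bad)) {
    stop("degenerate rectangle(s) for AOI(s): ",
         paste(r$label[bad], collapse = ", "))
  }
  n <- nrow(r)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        overlap_x <- r$x_min[i] < r$x_max[j] && r$x_min[j] < r$x_max[i]
        overlap_y <- r$y_min[i] < r$y_max[j] && r$y_min[j] < r$y_max[i]
        if (overlap_x && overlap_y) {
          stop("overlapping AOI rectangles: ", r$label[i], " and ", r$label[j])
        }
      }
    }
  }
  n_lead <- sum(r$is_lead)
  expected <- .lead_counts[[x$layout_id]]
  if (n_lead != expected) {
    stop("layout ", x$layout_id, " must contain ", expected,
         " lead AOIs, found ", n_lead)
  }
  lead_labels <- r$label[r$is_lead]
  if (!identical(lead_labels, LETTERS[seq_len(n_lead)])) {
    stop("lead AOI labels must be consecutive letters A.. in region order")
  }
  extra <- x$key_leads[!x$key_leads %in% r$label]
  if (length(extra) > 0L) {
    stop("key_leads not present in layout: ", paste(extra, collapse = ", "))
  }
  invisible(x)
}

#' Read an AOI layout from a JSON definition
#'
#' The JSON format is
#' `{"layout_id": "A", "stimulus_size": [w, h], "regions":`
#' `[{"label", "name", "rect": [x_min, y_min, x_max, y_max], "is_lead"}, ...],`
#' `"key_leads": [...]}`. Region order is preserved and fixes the state
#' ordering of all downstream transition matrices.
#'
#' @param path Path to (or literal text of) a layout JSON definition.
#' @return An [aoi_layout()] object.
#' @export
load_aoi_layout <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(j$layout_id) || is.null(j$regions)) {
    stop("layout JSON must contain 'layout_id' and 'regions'")
  }
  regions <- do.call(rbind, lapply(j$regions, function(reg) {
    if (length(reg$rect) != 4L) {
      stop("region ", reg$label %||% "?", ": 'rect' must have 4 numbers")
    }
    data.frame(
      label = reg$label, name = reg$name,
      x_min = reg$rect[[1]], y_min = reg$rect[[2]],
      x_max = reg$rect[[3]], y_max = reg$rect[[4]],
      is_lead = isTRUE(reg$is_lead)
    )
  }))
  aoi_layout(j$layout_id, regions, unlist(j$stimulus_size),
             key_leads = unlist(j$key_leads))
}

#' Write an AOI layout to JSON
#'
#' Inverse of [load_aoi_layout()].
#'
#' @param layout An [aoi_layout()] object.
#' @param path Output file path.
#' @export
write_aoi_layout <- function(layout, path) {
  stopifnot(inherits(layout, "aoi_layout"))
  r <- layout$regions
  j <- list(
    layout_id = layout$layout_id,
    stimulus_size = layout$stimulus_size,
    regions = lapply(seq_len(nrow(r)), function(i) {
      list(label = r$label[i], name = r$name[i],
           rect = c(r$x_min[i], r$y_min[i], r$x_max[i], r$y_max[i]),
           is_lead = r$is_lead[i])
    }),
    key_leads = layout$key_leads
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Packaged ECG AOI layouts
#'
#' Loads one of the two AOI layouts shipped with the package. The lead
#' inventory matches the study design (13 lead AOIs for type A, 15 for type
#' B); the pixel geometry is a synthetic, regular 4-by-3 lead grid with
#' rhythm strips beneath and an annotation banner above, since no published
#' coordinates exist for the original stimuli. AOI-level analyses never use
#' within-AOI position, so only the labelling and non-overlap matter.
#'
#' @param layout_id `"A"` or `"B"`.
#' @return An [aoi_layout()] object.
#' @examples
#' lay <- ecg_layout("A")
#' lead_states(lay)
#' @export
ecg_layout <- function(layout_id = c("A", "B")) {
  layout_id <- match.arg(layout_id)
  path <- system.file("extdata", paste0("layout_", layout_id, ".json"),
                      package = "ecgaze", mustWork = TRUE)
  load_aoi_layout(path)
}

#' Lead-AOI state labels of a layout
#'
#' @param layout An [aoi_layout()] object.
#' @return Character vector of lead/rhythm AOI labels in state order; this
#'   ordering is shared by all transition matrices built from the layout.
#' @export
lead_states <- function(layout) {
  stopifnot(inherits(layout, "aoi_layout"))
  layout$regions$label[layout$regions$is_lead]
}

#' @export
print.aoi_layout <- function(x, ...) {
  cat("ECG AOI layout", x$layout_id, "-", nrow(x$regions), "AOIs (",
      sum(x$regions$is_lead), "lead/rhythm ),",
      paste(x$stimulus_size, collapse = "x"), "px\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
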