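#' Settings for a full study analysis
#'
#' @param n_perm Permutations per stimulus (default 10000).
#' @param seed Master seed; each stimulus uses `seed + its design-row
#'   index`, so per-stimulus results are independent of which other
#'   stimuli are analysed.
#' @param alpha_prior Additive smoothing pseudo-count.
#' @param mode Chain-distance reduction mode, see [chain_js_distance()].
#' @param p_convention See [permutation_test()].
#' @param min_fixation_ms Minimum fixation duration filter.
#' @param quality_threshold Recording-quality exclusion threshold.
#' @param alpha Significance level for [classify_result()].
#' @param collapse_repeats Collapse same-AOI fixation runs before analysis.
#' @param ngram_max Upper n-gram size profiled.
#' @return A named list of settings.
#' @export
study_settings <- function(n_perm = 10000L, seed = 1L, alpha_prior = 1.0,
                           mode = "flatten_uniform",
                           p_convention = "smoothed",
                           min_fixation_ms = 60, quality_threshold = 0.70,
                           alpha = 0.05, collapse_repeats = FALSE,
                           ngram_max = 8L) {
  list(n_perm = as.integer(n_perm), seed = as.integer(seed),
       alpha_prior = alpha_prior, mode = mode, p_convention = p_convention,
       min_fixation_ms = min_fixation_ms,
       quality_threshold = quality_threshold, alpha = alpha,
       collapse_repeats = collapse_repeats, ngram_max = as.integer(ngram_max))
}

#' Run the full scan-path comparison study
#'
#' Orchestrates the whole pipeline for every stimulus of the design:
#' quality filtering, scan-path construction against the stimulus's
#' layout, group splitting, per-lead fixation descriptives, n-gram
#' profiling, pooled transition counting, chain estimation, the
#' Jensen-Shannon distance between the correct and incorrect groups'
#' chains, the permutation test, and the three-way classification.
#' Deterministic for a fixed seed. A stimulus where one group is empty is
#' reported as untestable and the run continues.
#'
#' @param events A `gaze_events` data frame or path to a fixation export.
#' @param labels Interpretation labels data frame (`participant_id`,
#'   `stimulus_id`, `label`) or path to the labels CSV.
#' @param design Data frame `stimulus_id`, `layout_id` (optionally
#'   `key_leads`) naming the layout of every analysed stimulus; defaults
#'   to [study_design()].
#' @param layouts Named list of [aoi_layout()] objects keyed by layout id;
#'   defaults to the packaged layouts.
#' @param settings See [study_settings()].
#' @param verbose Log stage boundaries and counts to the console.
#' @return A `study_report` object: list with `rows` (one data frame row
#'   per stimulus: distance, p-value, classification, group sizes, key
#'   leads), `settings`, `descriptives`, `ngram_profiles`, `null_summaries`
#'   and per-group `transition_counts`.
#' @export
run_study_analysis <- function(events, labels, design = study_design(),
                               layouts = list(A = ecg_layout("A"),
                                              B = ecg_layout("B")),
                               settings = study_settings(),
                               verbose = FALSE) {
  if (is.character(events)) events <- read_fixation_export(events)
  if (is.character(labels)) labels <- read_interpretation_labels(labels)
  say <- function(...) if (verbose) message(sprintf(...))

  n_before <- length(unique(events$participant_id))
  events <- filter_recordings(events, settings$quality_threshold)
  cohort <- sort(unique(events$participant_id))
  say("quality filter: %d of %d participants retained", length(cohort),
      n_before)

  stim_ids <- intersect(design$stimulus_id, unique(events$stimulus_id))
  rows <- list(); descr <- list(); profiles <- list()
  null_summaries <- list(); tmats <- list()

  for (stim in stim_ids) {
    idx <- match(stim, design$stimulus_id)
    layout <- layouts[[design$layout_id[idx]]]
    if (is.null(layout)) stop("no layout for stimulus '", stim, "'")
    states <- lead_states(layout)
    paths <- build_scanpaths(
      events[events$stimulus_id == stim, , drop = FALSE], layout,
      min_fixation_ms = settings$min_fixation_ms,
      collapse_repeats = settings$collapse_repeats)
    assignment <- split_groups(labels, stim, cohort = cohort)
    n1 <- length(assignment$correct_ids)
    n2 <- length(assignment$incorrect_ids)
    say("stimulus '%s': %d fixations retained, split %d/%d", stim,
        nrow(paths), n1, n2)

    key <- if ("key_leads" %in% names(design)) design$key_leads[idx]
           else NA_character_

    descr[[stim]] <- aoi_fixation_summary(paths, assignment, layout)
    strings <- encode_scanpaths(paths)$string
    freqs <- ngram_frequencies(
      strings, c(2L, max(2L, min(settings$ngram_max,
                                 max(nchar(strings), 2L)))))
    profiles[[stim]] <- if (nrow(freqs) > 0) ngram_profile(freqs) else NULL

    if (n1 == 0L || n2 == 0L) {
      rows[[stim]] <- data.frame(
        stimulus_id = stim, layout_id = layout$layout_id,
        js_distance = NA_real_, p_value = NA_real_,
        classification = "untestable", n_correct = n1, n_incorrect = n2,
        key_leads = key)
      next
    }

    cA <- count_transitions(
      paths[paths$participant_id %in% assignment$correct_ids, ], states)
    cB <- count_transitions(
      paths[paths$participant_id %in% assignment$incorrect_ids, ], states)
    tmats[[stim]] <- list(correct = cA, incorrect = cB)
    say("  transitions: %d correct-group, %d incorrect-group", sum(cA), sum(cB))

    res <- permutation_test(
      paths, assignment, states, n_perm = settings$n_perm,
      seed = settings$seed + idx, alpha_prior = settings$alpha_prior,
      mode = settings$mode, p_convention = settings$p_convention)
    null_summaries[[stim]] <- c(
      min = min(res$null_sample), max = max(res$null_sample),
      mean = mean(res$null_sample),
      stats::quantile(res$null_sample, c(0.05, 0.25, 0.5, 0.75, 0.95)))
    rows[[stim]] <- data.frame(
      stimulus_id = stim, layout_id = layout$layout_id,
      js_distance = res$observed$value, p_value = res$p_value,
      classification = classify_result(res, settings$alpha),
      n_correct = n1, n_incorrect = n2, key_leads = key)
  }

  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  structure(
    list(rows = rows, settings = settings,
         descriptives = do.call(rbind, c(descr, list(make.row.names = FALSE))),
         ngram_profiles = profiles, null_summaries = null_summaries,
         transition_counts = tmats),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", nrow(x$rows), "stimuli,",
      sum(x$rows$classification == "distance_larger"),
      "with a significantly larger between-group distance\n")
  print(x$rows[, c("stimulus_id", "js_distance", "p_value",
                   "classification", "n_correct", "n_incorrect")],
        digits = 5)
  invisible(x)
}

#' Write a study report to disk
#'
#' JSON carries the full report (rows, settings, null-distribution
#' summaries, n-gram profiles); CSV carries the per-stimulus result rows.
#' Per-group transition matrices and descriptives are written alongside
#' when a directory is given.
#'
#' @param report A [run_study_analysis()] report.
#' @param path Output file (`.json` or `.csv`) or an existing directory,
#'   in which case `report.json`, `report.csv`, `descriptives.csv` and
#'   `transitions_<stimulus>_<group>.csv` are written inside it.
#' @param format `"json"` or `"csv"`; ignored when `path` is a directory.
#' @return The path(s) written, invisibly.
#' @export
write_study_report <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "study_report"))
  format <- match.arg(format)
  if (dir.exists(path)) {
    written <- c(
      write_study_report(report, file.path(path, "report.json"), "json"),
      write_study_report(report, file.path(path, "report.csv"), "csv"))
    utils::write.csv(report$descriptives,
                     file.path(path, "descriptives.csv"), row.names = FALSE)
    for (stim in names(report$transition_counts)) {
      for (g in names(report$transition_counts[[stim]])) {
        f <- file.path(path, paste0("transitions_", gsub("\\W+", "_", stim),
                                    "_", g, ".csv"))
        write_transition_matrix(report$transition_counts[[stim]][[g]], f)
      }
    }
    return(invisible(written))
  }
  if (format == "csv") {
    utils::write.csv(report$rows, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(rows = report$rows, settings = report$settings,
           null_summaries = report$null_summaries,
           ngram_profiles = report$ngram_profiles),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Simulate a study and write it in the ingestion formats
#'
#' Generates a synthetic cohort and writes the fixation export TSV, the
#' labels CSV, both layout JSON files, the design table, and the
#' generating truth, so the files can be analysed exactly as a real
#' export would be (including from the command line).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return The cohort list from [generate_cohort()], invisibly.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  write_fixation_export(cohort$events, file.path(out_dir, "fixations.tsv"))
  utils::write.csv(cohort$labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  utils::write.csv(config$stimuli, file.path(out_dir, "design.csv"),
                   row.names = FALSE)
  write_aoi_layout(ecg_layout("A"), file.path(out_dir, "layout_A.json"))
  write_aoi_layout(ecg_layout("B"), file.path(out_dir, "layout_B.json"))
  jsonlite::write_json(
    list(group_kernels = cohort$truth$group_kernels,
         correct_ids = cohort$truth$correct_ids,
         quality = as.list(cohort$truth$quality),
         config = list(n_participants = config$n_participants,
                       delta = config$delta, kappa = config$kappa,
                       seed = config$seed)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}
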