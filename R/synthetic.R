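#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated eye-tracking study:
#' group-level lead-to-lead transition kernels whose separation is
#' controlled by `delta`, participant-level kernel heterogeneity controlled
#' by `kappa`, negative-binomial scan-path lengths, log-normal per-fixation
#' dwell times (longer for the incorrect group, as observed in practice),
#' and the per-stimulus correct/incorrect split.
#'
#' The defaults emulate the reference study conditions: a 31-participant
#' cohort viewing the eleven stimuli of [study_design()] with the published
#' group sizes. Path lengths of mean 80 fixations per stimulus reflect
#' unhurried inspection of a 13--15-AOI ECG (a handful of fixations per
#' lead); dwell parameters give mean single-fixation durations of roughly
#' 300 ms (correct) and 410 ms (incorrect), typical reading/inspection
#' fixations; `kappa = 50` yields mild idiosyncratic deviation of each
#' participant's kernel from their group's.
#'
#' @param stimuli Data frame `stimulus_id`, `layout_id`, `n_correct`,
#'   `n_incorrect` (and optionally `key_leads`); defaults to
#'   [study_design()].
#' @param n_participants Cohort size after quality exclusion; every
#'   stimulus's group sizes must sum to it.
#' @param delta Kernel separation in `[0, Inf)`: the incorrect group's
#'   kernel is the row-wise mixture
#'   `K_incorrect = K_correct / (1 + delta) + delta * D / (1 + delta)`
#'   with `D` an independent random kernel. `delta = 0` is the exact null.
#' @param kappa Dirichlet concentration for participant-level kernels
#'   (rows drawn from `Dirichlet(kappa * group row)`); larger is more
#'   homogeneous.
#' @param path_length Named vector `c(mean, dispersion)` of the
#'   negative-binomial scan-path length law (minimum length 2 enforced).
#' @param dwell List with elements `correct` and `incorrect`, each a named
#'   vector `c(meanlog, sdlog)` of the log-normal dwell law in ms; draws
#'   are floored at the 60 ms minimum fixation duration.
#' @param n_low_quality Number of additional participants generated with
#'   recording quality below 0.70, to exercise the quality filter; they
#'   receive gaze data and labels but are excluded by [filter_recordings()].
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(stimuli = study_design(),
                             n_participants = 31L,
                             delta = 0.5,
                             kappa = 50,
                             path_length = c(mean = 80, dispersion = 10),
                             dwell = list(
                               correct = c(meanlog = log(280), sdlog = 0.4),
                               incorrect = c(meanlog = log(380), sdlog = 0.4)),
                             n_low_quality = 0L,
                             seed = 1L) {
  stopifnot(is.data.frame(stimuli), delta >= 0, kappa > 0,
            path_length[["mean"]] > 2, path_length[["dispersion"]] > 0,
            n_low_quality >= 0)
  bad <- stimuli$n_correct + stimuli$n_incorrect != n_participants
  if (any(bad)) {
    stop("group sizes must sum to n_participants for every stimulus; ",
         "offending stimuli: ",
         paste(stimuli$stimulus_id[bad], collapse = ", "))
  }
  structure(
    list(stimuli = stimuli, n_participants = as.integer(n_participants),
         delta = delta, kappa = kappa, path_length = path_length,
         dwell = dwell, n_low_quality = as.integer(n_low_quality),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Dirichlet sampler: n draws over the simplex with concentration vector a.
rdirichlet <- function(n, a) {
  x <- matrix(stats::rgamma(n * length(a), shape = a), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Draw a pair of group transition kernels
#'
#' The correct group's kernel `K_correct` is drawn row-wise from a
#' Dirichlet over the `k` states, with extra concentration on a designated
#' key-lead block (emulating cross-referencing of the condition's key
#' leads). The incorrect group's kernel is the row-wise mixture
#' `(1 / (1 + delta)) * K_correct + (delta / (1 + delta)) * D`, with `D` an
#' independent draw, so `delta = 0` gives identical kernels and
#' `delta -> Inf` gives an unrelated kernel.
#'
#' @param k Number of states (at least 2).
#' @param delta Kernel separation, `>= 0`.
#' @param seed Optional integer seed (caller's RNG state restored).
#' @param key_states Integer or character indices of the key-lead block;
#'   empty for a symmetric kernel.
#' @param key_weight Concentration multiplier on key-block columns
#'   (default 3).
#' @return List with row-stochastic matrices `K_correct`, `K_incorrect`.
#' @export
make_group_kernels <- function(k, delta, seed = NULL, key_states = integer(0),
                               key_weight = 3) {
  if (k < 2) stop("k must be at least 2")
  stopifnot(delta >= 0)
  .with_seed(seed, {
    a <- rep(1, k)
    if (length(key_states) > 0L) a[key_states] <- key_weight
    K_correct <- rdirichlet(k, a)
    D <- rdirichlet(k, rep(1, k))
    w <- delta / (1 + delta)
    K_incorrect <- (1 - w) * K_correct + w * D
    list(K_correct = K_correct, K_incorrect = K_incorrect)
  })
}

#' Generate a synthetic eye-tracking cohort
#'
#' Simulates a full study data set in the ingestion formats of the
#' analysis pipeline: a gaze-event table (fixations interleaved with
#' saccade filler events, which carry no analytic weight but exercise the
#' event-type filter), an interpretation-label table, and the generating
#' truth (group and participant kernels, group membership) for parameter
#' recovery tests.
#'
#' Per participant and stimulus: a personal kernel is drawn row-wise from
#' `Dirichlet(kappa * group kernel row)`; the path length from the
#' negative-binomial law (floored at 2); the AOI sequence from the personal
#' kernel with a uniform initial state over lead AOIs; dwell times from the
#' group's log-normal law floored at the 60 ms minimum fixation duration;
#' and fixation coordinates uniformly inside the target AOI's rectangle.
#'
#' @param config A [synthetic_config()].
#' @return List with `events` (a `gaze_events` data frame), `labels`
#'   (`participant_id`, `stimulus_id`, `label`), and `truth` (per-stimulus
#'   group kernels, per-participant kernels, correct-group membership,
#'   participant recording qualities).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(config) {
  n_good <- config$n_participants
  n_all <- n_good + config$n_low_quality
  ids <- sprintf("P%02d", seq_len(n_all))
  good_ids <- ids[seq_len(n_good)]
  quality <- c(stats::runif(n_good, 0.75, 0.99),
               stats::runif(config$n_low_quality, 0.30, 0.6999))
  names(quality) <- ids

  layouts <- list(A = ecg_layout("A"), B = ecg_layout("B"))
  events <- list()
  labels <- list()
  truth <- list(group_kernels = list(), participant_kernels = list(),
                correct_ids = list(), quality = quality)

  for (s in seq_len(nrow(config$stimuli))) {
    stim <- config$stimuli$stimulus_id[s]
    layout <- layouts[[config$stimuli$layout_id[s]]]
    states <- lead_states(layout)
    k <- length(states)
    key <- if ("key_leads" %in% names(config$stimuli)) {
      match(key_lead_labels(config$stimuli$key_leads[s], layout), states)
    } else integer(0)
    kern <- make_group_kernels(k, config$delta, key_states = key)
    truth$group_kernels[[stim]] <- kern

    correct_ids <- sample(good_ids, config$stimuli$n_correct[s])
    truth$correct_ids[[stim]] <- sort(correct_ids)
    # low-quality participants get labels too (they are excluded upstream
    # of the analysis, not absent from the raw files)
    raw_label <- ifelse(ids %in% correct_ids, "correct",
                        sample(c("partially_correct", "incorrect"),
                               n_all, replace = TRUE))
    labels[[length(labels) + 1L]] <- data.frame(
      participant_id = ids, stimulus_id = stim, label = raw_label)

    pk <- list()
    for (pid in ids) {
      group <- if (pid %in% correct_ids) "correct" else "incorrect"
      K <- if (group == "correct") kern$K_correct else kern$K_incorrect
      P <- t(vapply(seq_len(k),
                    function(i) rdirichlet(1, config$kappa * K[i, ])[1, ],
                    numeric(k)))
      pk[[pid]] <- P
      len <- max(2L, stats::rnbinom(1, size = config$path_length[["dispersion"]],
                                    mu = config$path_length[["mean"]]))
      path <- integer(len)
      path[1] <- sample.int(k, 1)
      for (t in seq_len(len - 1L)) {
        path[t + 1L] <- sample.int(k, 1, prob = P[path[t], ])
      }
      dw <- config$dwell[[group]]
      dur <- pmax(60, round(stats::rlnorm(len, dw[["meanlog"]], dw[["sdlog"]])))
      r <- layout$regions[match(states[path], layout$regions$label), ]
      # 0.2 px inner margin so rounding to 1 decimal cannot cross the
      # half-open right/bottom edge
      x <- stats::runif(len, r$x_min, r$x_max - 0.2)
      y <- stats::runif(len, r$y_min, r$y_max - 0.2)
      sacc <- round(stats::runif(len - 1L, 20, 60))
      start <- cumsum(c(0, dur[-len] + sacc))
      fix <- data.frame(
        participant_id = pid, stimulus_id = stim, event_type = "Fixation",
        start_ms = start, duration_ms = dur, x = round(x, 1), y = round(y, 1),
        recording_quality = quality[[pid]])
      if (len > 1L) {
        sc <- data.frame(
          participant_id = pid, stimulus_id = stim, event_type = "Saccade",
          start_ms = start[-len] + dur[-len], duration_ms = sacc,
          x = round((x[-len] + x[-1]) / 2, 1),
          y = round((y[-len] + y[-1]) / 2, 1),
          recording_quality = quality[[pid]])
        fix <- rbind(fix, sc)
      }
      events[[length(events) + 1L]] <- fix
    }
    truth$participant_kernels[[stim]] <- pk
  }

  ev <- do.call(rbind, events)
  ev <- ev[order(ev$participant_id, ev$stimulus_id, ev$start_ms), ]
  rownames(ev) <- NULL
  class(ev) <- c("gaze_events", "data.frame")
  lab <- do.call(rbind, labels)
  rownames(lab) <- NULL
  list(events = ev, labels = lab, truth = truth)
}
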