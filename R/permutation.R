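#' Permutation test of the chain distance between interpretation groups
#'
#' Tests whether the Jensen-Shannon distance between the correct and
#' incorrect groups' pooled transition chains is larger (or smaller) than
#' expected between randomly composed groups of the same sizes. Each
#' permutation draws, uniformly at random and without replacement, a
#' pseudo-correct group of the same size as the true correct group from the
#' full cohort, recomputes both pooled count matrices and the chain
#' distance. When the number of distinct splits `choose(n, n_correct)` does
#' not exceed `n_perm`, all splits are enumerated instead and the p-value
#' is exact.
#'
#' Two p-value conventions are available. The default `smoothed` estimator
#' `(#\{null >= observed\} + 1) / (n_perm + 1)` is never zero and counts
#' ties conservatively toward rejection; under enumeration it becomes the
#' exact `#\{null >= observed\} / n_splits` (the observed split is one of
#' the enumerated splits, so this is still positive). The `paper`
#' convention is the plain fraction of null values strictly greater than
#' the observed distance.
#'
#' Participants are processed in sorted-id order, so relabelling or
#' reordering them leaves the seeded null sample unchanged. Assigned
#' participants with no surviving fixations contribute an all-zero count
#' matrix (they are cohort members whose fixations were filtered out).
#'
#' @param paths A `scanpaths` data frame for one stimulus.
#' @param assignment A [split_groups()] assignment for that stimulus; both
#'   groups must be non-empty.
#' @param states Ordered state labels, e.g. [lead_states()].
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Integer seed making the whole null sample reproducible; the
#'   caller's RNG state is restored afterwards.
#' @param alpha_prior Additive smoothing pseudo-count, see [estimate_chain()].
#' @param mode Chain-distance reduction mode, see [chain_js_distance()].
#' @param p_convention `"smoothed"` (default) or `"paper"`, see Details.
#' @param exhaustive `"auto"` (enumerate when feasible, the default),
#'   `"never"`, or `"always"` (error if more than 5e6 splits).
#' @return A `permutation_result` object: list with `stimulus_id`,
#'   `observed` (a `chain_distance`), `null_sample`, `p_value`, `n_perm`
#'   (effective number of null values), `seed`, `p_convention`,
#'   `group_sizes`, `exhaustive`.
#' @export
permutation_test <- function(paths, assignment, states, n_perm = 10000,
                             seed = NULL, alpha_prior = 1.0,
                             mode = c("flatten_uniform", "joint_bigram",
                                      "stationary_weighted"),
                             p_convention = c("smoothed", "paper"),
                             exhaustive = c("auto", "never", "always")) {
  mode <- match.arg(mode)
  p_convention <- match.arg(p_convention)
  exhaustive <- match.arg(exhaustive)
  stopifnot(inherits(assignment, "group_assignment"))
  if (n_perm < 1) stop("n_perm must be at least 1")
  n1 <- length(assignment$correct_ids)
  n2 <- length(assignment$incorrect_ids)
  if (n1 == 0L || n2 == 0L) {
    stop("untestable stimulus '", assignment$stimulus_id,
         "': one group is empty (", n1, " correct / ", n2, " incorrect)")
  }
  ids <- sort(c(assignment$correct_ids, assignment$incorrect_ids))
  n <- length(ids)
  k <- length(states)

  # one k x k count matrix per participant, in sorted-id order
  arr <- array(0, dim = c(k, k, n))
  for (i in seq_len(n)) {
    sub <- paths[paths$participant_id == ids[i], , drop = FALSE]
    arr[, , i] <- count_transitions(sub, states)
  }
  total <- rowSums(arr, dims = 2)
  idx_correct <- which(ids %in% assignment$correct_ids)
  c1 <- rowSums(arr[, , idx_correct, drop = FALSE], dims = 2)
  observed <- chain_js_distance(c1, total - c1, alpha = alpha_prior,
                                mode = mode)

  n_splits <- choose(n, n1)
  use_exhaustive <- switch(exhaustive,
    auto = n_splits <= n_perm,
    never = FALSE,
    always = TRUE)
  if (use_exhaustive && n_splits > 5e6) {
    stop("exhaustive enumeration infeasible: ", n_splits, " splits")
  }

  if (use_exhaustive) {
    combos <- utils::combn(n, min(n1, n2))
    null_sample <- apply(combos, 2, function(idx) {
      cs <- rowSums(arr[, , idx, drop = FALSE], dims = 2)
      # combn is over the smaller group; the statistic is symmetric in the
      # two groups, so either orientation gives the same distance
      .chain_js_stat(cs, total - cs, alpha_prior, mode)
    })
    n_eff <- length(null_sample)
    p <- switch(p_convention,
      smoothed = sum(null_sample >= observed$value - 1e-15) / n_eff,
      paper = sum(null_sample > observed$value + 1e-15) / n_eff)
  } else {
    null_sample <- .with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(n, n1)
        cs <- rowSums(arr[, , idx, drop = FALSE], dims = 2)
        .chain_js_stat(cs, total - cs, alpha_prior, mode)
      }, numeric(1))
    })
    n_eff <- n_perm
    p <- switch(p_convention,
      smoothed = (sum(null_sample >= observed$value - 1e-15) + 1) / (n_perm + 1),
      paper = sum(null_sample > observed$value + 1e-15) / n_perm)
  }

  structure(
    list(stimulus_id = assignment$stimulus_id, observed = observed,
         null_sample = null_sample, p_value = p, n_perm = n_eff,
         seed = seed, p_convention = p_convention,
         group_sizes = c(n_correct = n1, n_incorrect = n2),
         exhaustive = use_exhaustive),
    class = "permutation_result"
  )
}

# Evaluate expr under a temporary RNG seed, restoring the caller's state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  expr
}

#' Classify a permutation result
#'
#' Three-way outcome at significance level `alpha`: the observed distance
#' is significantly *larger* than random-split distances (`p <= alpha`),
#' significantly *smaller* (`p >= 1 - alpha`, i.e. almost all random splits
#' beat the true split — the two groups transition more alike than chance),
#' or not distinguishable from chance.
#'
#' @param result A [permutation_test()] result.
#' @param alpha Significance level in `(0, 0.5)`; default 0.05.
#' @return One of `"distance_larger"`, `"no_difference"`,
#'   `"distance_smaller"`.
#' @export
classify_result <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "permutation_result"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 0.5) {
    stop("alpha must lie strictly between 0 and 0.5")
  }
  p <- result$p_value
  if (p <= alpha) "distance_larger"
  else if (p >= 1 - alpha) "distance_smaller"
  else "no_difference"
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test, stimulus '%s' (%d vs %d):\n  JS distance %.7f, p = %.4g (%s, %d %s)\n",
    x$stimulus_id, x$group_sizes[1], x$group_sizes[2], x$observed$value,
    x$p_value, x$p_convention, x$n_perm,
    if (x$exhaustive) "exhaustive splits" else "random permutations"))
  invisible(x)
}
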