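#' Pooled AOI transition counts
#'
#' Counts gaze transitions between lead AOIs, pooled ("aggregated
#' frequency") over all scan paths supplied — typically all participants of
#' one interpretation group on one stimulus. Each consecutive pair of steps
#' within one participant's path on one stimulus increments one cell; pairs
#' never span two paths, and self-transitions (consecutive fixations in the
#' same AOI) are counted.
#'
#' @param paths A `scanpaths` data frame (see [build_scanpaths()]).
#' @param states Character vector of state labels in fixed order, e.g.
#'   [lead_states()] of the layout.
#' @return A `k x k` integer matrix with `dimnames` `states`; cell `(i, j)`
#'   is the number of observed shifts from state `i` to state `j`. The
#'   grand total equals `sum(max(path length - 1, 0))`.
#' @export
count_transitions <- function(paths, states) {
  stopifnot(length(states) >= 2, !anyDuplicated(states))
  unknown <- setdiff(unique(paths$aoi_label), states)
  if (length(unknown) > 0L) {
    stop("scan-path label(s) not in the state set: ",
         paste(unknown, collapse = ", "))
  }
  k <- length(states)
  m <- matrix(0L, k, k, dimnames = list(states, states))
  n <- nrow(paths)
  if (n < 2L) return(m)
  i <- seq_len(n - 1L)
  same <- paths$participant_id[i] == paths$participant_id[i + 1L] &
    paths$stimulus_id[i] == paths$stimulus_id[i + 1L]
  if (!any(same)) return(m)
  from <- factor(paths$aoi_label[i][same], levels = states)
  to <- factor(paths$aoi_label[i + 1L][same], levels = states)
  tab <- table(from, to)
  m[] <- as.integer(tab)
  m
}

#' Estimate a smoothed first-order Markov chain
#'
#' Converts a transition count matrix into a row-stochastic transition
#' probability matrix by maximum likelihood with an additive (Bayesian)
#' prior: a pseudo-count `alpha` is added to every cell before normalising,
#' `P[i, j] = (C[i, j] + alpha) / (sum_j C[i, j] + k * alpha)`. The prior
#' guarantees strictly positive probabilities, so rows with no observed
#' transitions become uniform instead of dividing by zero, and downstream
#' divergences are always finite.
#'
#' @param counts Non-negative count matrix (square).
#' @param alpha Positive pseudo-count per cell; the default 1 is the
#'   Laplace (uniform Dirichlet) prior.
#' @return A `markov_chain` object: the row-stochastic matrix with
#'   attribute `alpha`.
#' @export
estimate_chain <- function(counts, alpha = 1.0) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a single positive number (the additive prior ",
         "exists to prevent division by zero)")
  }
  k <- nrow(counts)
  P <- (counts + alpha) / (rowSums(counts) + k * alpha)
  structure(P, alpha = alpha, class = c("markov_chain", class(P)))
}

#' Kullback-Leibler divergence in bits
#'
#' `KL(p || q) = sum_i p_i log2(p_i / q_i)`, with the convention
#' `0 * log(0 / q) = 0`.
#'
#' @param p,q Probability vectors of equal length; `q` must be strictly
#'   positive wherever `p` is (guaranteed after additive smoothing).
#' @return Non-negative divergence in bits.
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (abs(sum(p) - 1) > 1e-9) stop("p must sum to 1")
  pos <- p > 0
  if (any(q[pos] == 0)) {
    stop("q has zero mass where p is positive; KL is infinite")
  }
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' Jensen-Shannon distance in base 2
#'
#' The square root of the Jensen-Shannon divergence,
#' `sqrt((KL(p, m) + KL(q, m)) / 2)` with `m = (p + q) / 2` and logs base 2.
#' A true metric on distributions, bounded in `[0, 1]`: 0 iff `p = q`, 1 for
#' distributions with disjoint support.
#'
#' @param p,q Probability vectors of equal length, each summing to 1
#'   (tolerance `1e-9`).
#' @return The distance, a number in `[0, 1]`.
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("p and q must each sum to 1")
  }
  m <- (p + q) / 2
  d2 <- (kl_divergence(p, m) + kl_divergence(q, m)) / 2
  sqrt(max(d2, 0))
}

#' Jensen-Shannon distance between two estimated Markov chains
#'
#' Estimates a smoothed chain from each group's pooled transition counts
#' and reduces the pair of `k x k` row-stochastic matrices to a single
#' distance. Because a Markov chain is a family of `k` conditional
#' distributions rather than one distribution, the reduction is ambiguous;
#' three modes are provided:
#'
#' * `flatten_uniform` (default): each chain's matrix is flattened to a
#'   length-`k^2` vector and divided by `k` so it sums to 1, then
#'   [js_distance()] is applied. Equivalent to weighting every row
#'   (current-state conditional) uniformly; the most literal reading of a
#'   distance "between the two Markov chains".
#' * `joint_bigram`: the smoothed counts `C + alpha` are normalised by
#'   their grand total per group, and the distance is taken between those
#'   empirical bigram distributions — rows are weighted by how often each
#'   state was occupied.
#' * `stationary_weighted`: rows of each chain are weighted by the average
#'   of the two chains' stationary distributions, comparing the implied
#'   long-run joint distributions over transitions.
#'
#' All modes return a value in `[0, 1]` that is 0 iff the compared
#' distributions coincide.
#'
#' @param countsA,countsB Count matrices over the same ordered state set
#'   (identical `dimnames`).
#' @param alpha Additive smoothing pseudo-count, see [estimate_chain()].
#' @param mode Reduction mode, see Details.
#' @return A `chain_distance` object: list with `value`, `mode`, `alpha`.
#' @export
chain_js_distance <- function(countsA, countsB, alpha = 1.0,
                              mode = c("flatten_uniform", "joint_bigram",
                                       "stationary_weighted")) {
  mode <- match.arg(mode)
  countsA <- as.matrix(countsA)
  countsB <- as.matrix(countsB)
  if (!identical(dim(countsA), dim(countsB)) ||
      !identical(dimnames(countsA), dimnames(countsB))) {
    stop("countsA and countsB must share the same ordered state set")
  }
  value <- .chain_js_stat(countsA, countsB, alpha, mode)
  structure(list(value = value, mode = mode, alpha = alpha),
            class = "chain_distance")
}

# Fast unvalidated statistic, shared with the permutation loop. All inputs
# are k x k non-negative count matrices; alpha > 0 keeps every cell positive
# so no 0*log(0) handling is needed.
.chain_js_stat <- function(cA, cB, alpha, mode) {
  k <- nrow(cA)
  if (mode == "joint_bigram") {
    p <- (cA + alpha) / (sum(cA) + k * k * alpha)
    q <- (cB + alpha) / (sum(cB) + k * k * alpha)
  } else {
    PA <- (cA + alpha) / (rowSums(cA) + k * alpha)
    PB <- (cB + alpha) / (rowSums(cB) + k * alpha)
    if (mode == "flatten_uniform") {
      p <- PA / k
      q <- PB / k
    } else { # stationary_weighted
      w <- (.stationary_dist(PA) + .stationary_dist(PB)) / 2
      p <- PA * w   # row i scaled by w[i]; sums to sum(w) = 1
      q <- PB * w
    }
  }
  m <- (p + q) / 2
  d2 <- (sum(p * log2(p / m)) + sum(q * log2(q / m))) / 2
  sqrt(max(d2, 0))
}

# Stationary distribution of a strictly positive row-stochastic matrix
# (unique by Perron-Frobenius): leading left eigenvector, renormalised.
.stationary_dist <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v <- abs(v)
  v / sum(v)
}

#' @export
print.chain_distance <- function(x, ...) {
  cat(sprintf("Jensen-Shannon chain distance: %.7f (mode %s, alpha %g)\n",
              x$value, x$mode, x$alpha))
  invisible(x)
}

#' Write a transition count matrix as CSV
#'
#' State labels form the header row and first column, mirroring the usual
#' presentation of AOI transition matrices.
#'
#' @param counts Square matrix with state `dimnames`.
#' @param path Output file path.
#' @export
write_transition_matrix <- function(counts, path) {
  utils::write.csv(as.data.frame(as.matrix(counts)), path, row.names = TRUE)
  invisible(path)
}
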