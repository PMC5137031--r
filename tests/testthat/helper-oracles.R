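# Independent, deliberately naive (loop-based) evaluations of the
# information-theoretic definitions, used as oracles against the package's
# vectorised implementations.

oracle_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i]) / log(2)
  }
  s
}

oracle_js <- function(p, q) {
  m <- (p + q) / 2
  sqrt((oracle_kl(p, m) + oracle_kl(q, m)) / 2)
}

# Stationary distribution by power iteration (independent of the eigen
# route used in the package).
oracle_stationary <- function(P, tol = 1e-14, max_iter = 100000) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(max_iter)) {
    v2 <- as.numeric(v %*% P)
    if (max(abs(v2 - v)) < tol) return(v2 / sum(v2))
    v <- v2
  }
  v / sum(v)
}

# Direct evaluation of the chain distance from the definitions, one cell
# at a time.
oracle_chain_js <- function(cA, cB, alpha, mode) {
  k <- nrow(cA)
  smooth_rows <- function(C) {
    P <- matrix(0, k, k)
    for (i in 1:k) {
      denom <- sum(C[i, ]) + k * alpha
      for (j in 1:k) P[i, j] <- (C[i, j] + alpha) / denom
    }
    P
  }
  if (mode == "joint_bigram") {
    p <- as.vector(cA + alpha) / sum(cA + alpha)
    q <- as.vector(cB + alpha) / sum(cB + alpha)
  } else if (mode == "flatten_uniform") {
    p <- as.vector(smooth_rows(cA)) / k
    q <- as.vector(smooth_rows(cB)) / k
  } else {
    PA <- smooth_rows(cA)
    PB <- smooth_rows(cB)
    w <- (oracle_stationary(PA) + oracle_stationary(PB)) / 2
    p <- as.vector(diag(w) %*% PA)
    q <- as.vector(diag(w) %*% PB)
  }
  oracle_js(p, q)
}

random_distribution <- function(k) {
  x <- stats::rgamma(k, shape = 1)
  x / sum(x)
}

random_count_matrix <- function(k, max_count = 30) {
  matrix(sample.int(max_count + 1L, k * k, replace = TRUE) - 1L, k, k)
}
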