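# Modularity maximization. The Louvain local-moving/aggregation core lives
# in src/louvain.cpp and operates on a dense modularity matrix, which lets
# the same engine serve single-layer weighted networks and the temporal
# multilayer case (see community-dynamics.R).

# Negative-weight truncation: modular analyses take only positive edge
# weights into account.
trunc_neg <- function(w) {
  w <- as.matrix(w)
  w[w < 0] <- 0
  diag(w) <- 0
  w
}

# Single-layer modularity matrix B with configuration null and resolution
# gamma, scaled by 1/(2m) so Q(partition) = sum of B within communities.
modularity_matrix <- function(w, gamma = 1) {
  w <- trunc_neg(w)
  k <- rowSums(w)
  m2 <- sum(k)
  if (m2 <= 0) stop("all-zero weight matrix")
  (w - gamma * outer(k, k) / m2) / m2
}

#' Modularity Q of a given partition
#'
#' Scores a partition against the configuration null:
#' `Q = (1/2m) sum_ij (A_ij - gamma k_i k_j / 2m) delta(c_i, c_j)`, with
#' negative weights truncated to zero.
#'
#' @param fc weight matrix (`fc_matrix` or plain symmetric matrix).
#' @param membership integer/character vector of community labels per node.
#' @param gamma resolution parameter (default 1).
#' @return Q value.
#' @export
modularity_q <- function(fc, membership, gamma = 1) {
  b <- modularity_matrix(as.matrix(fc), gamma)
  m <- canonical_labels(membership)
  sum(b[outer(m, m, "==")])
}

#' Louvain community detection on a weighted FC matrix
#'
#' One seeded run of greedy Louvain modularity maximization with
#' configuration null and resolution `gamma`; negative weights are truncated
#' to zero. Node visiting order is randomized per run, so restarts with
#' different seeds explore different local maxima.
#'
#' @param fc weight matrix (`fc_matrix` or plain symmetric matrix).
#' @param gamma resolution parameter.
#' @param seed integer seed.
#' @return list with `partition` (named integer vector, labels 1..k) and `q`.
#' @export
louvain_q <- function(fc, gamma = 1, seed = 1) {
  w <- as.matrix(fc)
  b <- modularity_matrix(w, gamma)
  set.seed(as_seed(seed))
  res <- cpp_louvain(b)
  ids <- rownames(w) %||% sprintf("n%03d", seq_len(nrow(w)))
  list(partition = setNames(as.integer(res$membership), ids), q = res$q)
}

#' Maximal-Q partition over seeded Louvain restarts
#'
#' Runs [louvain_q()] `repetitions` times with child seeds derived from
#' `seed` and returns the partition attaining the highest Q (first one on
#' ties).
#'
#' @inheritParams louvain_q
#' @param repetitions number of restarts (the reference analysis uses 100).
#' @return list with `partition`, `q`, and `q_all` (Q of every restart).
#' @export
max_modularity <- function(fc, gamma = 1, repetitions = 100, seed = 1) {
  stopifnot(repetitions >= 1)
  seeds <- child_seeds(seed, repetitions)
  best <- NULL
  q_all <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    res <- louvain_q(fc, gamma, seed = seeds[r])
    q_all[r] <- res$q
    if (is.null(best) || res$q > best$q) best <- res
  }
  list(partition = best$partition, q = best$q, q_all = q_all)
}
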