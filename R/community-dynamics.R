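# Temporal multilayer community detection and allegiance analysis.

# Supra-modularity matrix for ordinal (temporally adjacent) interlayer
# coupling omega: block-diagonal per-layer modularity terms
# (A_s - gamma k_s k_s' / 2m_s) plus omega on the identity off-diagonal
# blocks linking copies of each node in adjacent windows, all scaled by
# 1/(2 mu) with 2 mu = sum_s 2m_s + 2 omega N (w - 1).
supra_modularity_matrix <- function(layers, gamma = 1, omega = 1) {
  w <- length(layers)
  n <- nrow(layers[[1]])
  twom <- vapply(layers, sum, numeric(1))
  if (any(twom <= 0)) stop("all-zero layer")
  mu2 <- sum(twom) + 2 * omega * n * (w - 1)
  b <- matrix(0, n * w, n * w)
  for (s in seq_len(w)) {
    idx <- (s - 1) * n + seq_len(n)
    a <- layers[[s]]
    k <- rowSums(a)
    b[idx, idx] <- a - gamma * outer(k, k) / twom[s]
    if (s < w) {
      jdx <- s * n + seq_len(n)
      b[cbind(idx, jdx)] <- omega
      b[cbind(jdx, idx)] <- omega
    }
  }
  b / mu2
}

# Seeds shared between the multilayer omega = 0 dispatch and per-window
# louvain_q, laid out repetition-major: seed for (rep r, window s) is
# element (r - 1) * w + s.
per_layer_seeds <- function(seed, repetitions, w) {
  matrix(child_seeds(seed, repetitions * w), nrow = repetitions,
         ncol = w, byrow = TRUE)
}

#' Multilayer community detection across sliding windows
#'
#' Runs `repetitions` seeded restarts of generalized Louvain on the temporal
#' multilayer modularity with ordinal interlayer coupling `omega` between
#' temporally adjacent copies of each node. Negative window weights are
#' truncated to zero (only positive edge weights are taken into account).
#' `omega = 0` is the degenerate per-window mode: each layer is clustered
#' independently with [louvain_q()] under seeds from `per_layer_seeds()`,
#' so the reduction to single-layer Louvain is exact.
#'
#' @param windows a `windowed_fc`.
#' @param gamma resolution parameter.
#' @param omega interlayer coupling (>= 0).
#' @param repetitions number of seeded restarts retained in the ensemble.
#' @param seed integer seed.
#' @return A `partition_ensemble`: list with `partitions` (list of length
#'   `repetitions`, each an N x w integer matrix of community labels),
#'   `r`, `w`, `node_ids`, `gamma`, `omega`, `q` (multilayer modularity per
#'   repetition; NA in the omega = 0 mode where per-layer Q applies instead).
#' @export
multilayer_communities <- function(windows, gamma = 1, omega = 1,
                                   repetitions = 100, seed = 1) {
  stopifnot(inherits(windows, "windowed_fc"), omega >= 0, repetitions >= 1)
  w <- length(windows$windows)
  layers <- lapply(windows$windows, trunc_neg)
  n <- nrow(layers[[1]])
  ids <- rownames(windows$windows[[1]]) %||% sprintf("n%03d", seq_len(n))
  parts <- vector("list", repetitions)
  q <- rep(NA_real_, repetitions)
  if (omega == 0) {
    seeds <- per_layer_seeds(seed, repetitions, w)
    for (r in seq_len(repetitions)) {
      m <- matrix(NA_integer_, n, w, dimnames = list(ids, NULL))
      for (s in seq_len(w))
        m[, s] <- louvain_q(layers[[s]], gamma, seed = seeds[r, s])$partition
      parts[[r]] <- m
    }
  } else {
    b <- supra_modularity_matrix(layers, gamma, omega)
    seeds <- child_seeds(seed, repetitions)
    for (r in seq_len(repetitions)) {
      set.seed(seeds[r])
      res <- cpp_louvain(b)
      parts[[r]] <- matrix(as.integer(res$membership), n, w,
                           dimnames = list(ids, NULL))
      q[r] <- res$q
    }
  }
  structure(list(partitions = parts, r = repetitions, w = w, node_ids = ids,
                 gamma = gamma, omega = omega, q = q, seed = as_seed(seed)),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat("Partition ensemble:", x$r, "repetitions x", x$w, "windows,",
      length(x$node_ids), "nodes (gamma =", x$gamma, ", omega =", x$omega,
      ")\n")
  invisible(x)
}

#' Allegiance matrix of a partition ensemble
#'
#' `P_ij` is the fraction of the r-by-w (repetition, window) layers in
#' which nodes i and j are assigned to the same community; the diagonal is
#' set to 1. Entries are exact rationals with denominator r*w.
#'
#' @param ensemble a `partition_ensemble`.
#' @return An `allegiance_matrix`: N x N matrix with entries in `[0, 1]` with attributes
#'   `r` and `w`.
#' @export
allegiance <- function(ensemble) {
  stopifnot(inherits(ensemble, "partition_ensemble"))
  n <- length(ensemble$node_ids)
  acc <- matrix(0, n, n)
  for (p in ensemble$partitions)
    for (s in seq_len(ensemble$w)) {
      m <- p[, s]
      acc <- acc + (outer(m, m, "==") * 1)
    }
  p <- acc / (ensemble$r * ensemble$w)
  diag(p) <- 1
  dimnames(p) <- list(ensemble$node_ids, ensemble$node_ids)
  structure(p, class = c("allegiance_matrix", "matrix"),
            r = ensemble$r, w = ensemble$w)
}

#' Similarity between two allegiance matrices
#'
#' Pearson correlation over the strictly-upper-triangle vectors.
#'
#' @param a,b `allegiance_matrix` objects over the same node set.
#' @return Pearson correlation coefficient.
#' @export
allegiance_similarity <- function(a, b) fc_similarity(a, b)

#' Consensus partition from an ensemble of partitions
#'
#' Builds the agreement matrix (node-pair co-assignment fraction) of the
#' input partitions, zeroes entries below `tau`, and re-clusters it with
#' seeded Louvain restarts; iterates until all restarts agree (up to label
#' permutation) or `max_iter` is reached.
#'
#' @param partitions a `partition_ensemble`, a list of membership vectors,
#'   or a matrix with one partition per column.
#' @param tau agreement threshold in [0, 1).
#' @param max_iter maximum re-clustering iterations.
#' @param restarts Louvain restarts per iteration.
#' @param seed integer seed.
#' @return list with `partition` (named integer vector), `converged`
#'   (logical), `n_iter`.
#' @export
consensus_partition <- function(partitions, tau = 0.5, max_iter = 20,
                                restarts = 100, seed = 1) {
  stopifnot(tau >= 0, tau < 1)
  plist <- as_partition_list(partitions)
  if (length(plist) < 1) stop("no partitions supplied")
  ids <- names(plist[[1]]) %||% sprintf("n%03d", seq_along(plist[[1]]))
  seeds <- child_seeds(seed, max_iter)
  current <- plist
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    canon <- lapply(current, canonical_labels)
    if (length(unique(canon)) == 1) { converged <- TRUE; break }
    if (iter > max_iter) break
    agree <- agreement_matrix(current)
    agree[agree < tau] <- 0
    diag(agree) <- 0
    if (sum(agree) == 0)
      stop("agreement matrix empty after thresholding at tau = ", tau)
    rs <- child_seeds(seeds[iter], restarts)
    current <- lapply(rs, function(s) louvain_q(agree, seed = s)$partition)
  }
  if (!converged)
    warning("consensus clustering did not converge after ", max_iter,
            " iterations; returning the modal partition")
  part <- canonical_labels(current[[1]])
  list(partition = setNames(as.integer(part), ids), converged = converged,
       n_iter = iter)
}

as_partition_list <- function(partitions) {
  if (inherits(partitions, "partition_ensemble")) {
    out <- list()
    for (p in partitions$partitions)
      for (s in seq_len(ncol(p))) out[[length(out) + 1]] <- p[, s]
    out
  } else if (is.matrix(partitions)) {
    lapply(seq_len(ncol(partitions)), function(j) partitions[, j])
  } else if (is.list(partitions)) {
    partitions
  } else {
    list(partitions)
  }
}

agreement_matrix <- function(plist) {
  n <- length(plist[[1]])
  acc <- matrix(0, n, n)
  for (m in plist) acc <- acc + (outer(m, m, "==") * 1)
  acc / length(plist)
}
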