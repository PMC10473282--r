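# Fixtures and independent oracles used across the suite. Everything here is
# deliberately brute-force and separate from the package's own algorithms.

# Wrap an adjacency matrix as the package's binary-graph container.
bg <- function(adj) {
  adj <- as.matrix(adj)
  storage.mode(adj) <- "integer"
  structure(list(adjacency = adj, density = sum(adj) / (nrow(adj) *
                                                          (nrow(adj) - 1)),
                 n_edges = sum(adj) / 2, source_state = NULL),
            class = "binary_graph")
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; bg(a)
}

path_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  bg(a)
}

star_graph <- function(n_leaves) {
  a <- matrix(0L, n_leaves + 1, n_leaves + 1)
  a[1, -1] <- a[-1, 1] <- 1L
  bg(a)
}

random_connected_graph <- function(n, p = 0.35) {
  repeat {
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
    a <- a + t(a)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    if (igraph::is_connected(g)) return(bg(a))
  }
}

# --- shortest-path oracles (Floyd-Warshall + exhaustive path enumeration) ---

fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

brute_efficiency <- function(adj) {
  d <- fw_distances(adj)
  inv <- 1 / d[upper.tri(d)]
  mean(inv)
}

# All shortest paths between s and t by depth-first search on the distance
# matrix; returns a list of node-index vectors (including endpoints).
all_shortest_paths_brute <- function(adj, d, s, t) {
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- acc
      return(invisible())
    }
    for (u in which(adj[v, ] == 1))
      if (d[v, t] == d[u, t] + 1) walk(u, c(acc, u))
  }
  walk(s, s)
  paths
}

brute_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    paths <- all_shortest_paths_brute(adj, d, s, t)
    counts <- numeric(n)
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      counts[inner] <- counts[inner] + 1
    }
    btw <- btw + counts / length(paths)
  }
  btw
}

brute_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) { ci[i] <- 0; next }
    links <- sum(adj[nb, nb]) / 2
    ci[i] <- 2 * links / (k * (k - 1))
  }
  mean(ci)
}

# --- exhaustive partition enumeration (restricted growth strings) ----------

all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1))
      grow(c(prefix, lab), max(maxlab, lab))
  }
  grow(integer(0), 0L)
  out
}

# Exhaustive maximum of Newman-Girvan modularity at resolution gamma.
brute_max_q <- function(w, gamma = 1) {
  w <- as.matrix(w); w[w < 0] <- 0; diag(w) <- 0
  k <- rowSums(w); m2 <- sum(k)
  b <- (w - gamma * outer(k, k) / m2) / m2
  best <- -Inf
  for (p in all_partitions(nrow(w))) {
    q <- sum(b[outer(p, p, "==")])
    if (q > best) best <- q
  }
  best
}

# Small weighted FC-like fixture with planted two-block structure.
planted_fc <- function(n = 8, w_in = 1, w_out = 0.1) {
  stopifnot(n %% 2 == 0)
  mem <- rep(1:2, each = n / 2)
  w <- ifelse(outer(mem, mem, "=="), w_in, w_out)
  diag(w) <- 0
  w
}

ari <- function(a, b) netreconfig:::adjusted_rand(a, b)

expect_deterministic <- function(expr1, expr2) {
  expect_identical(expr1, expr2)
}
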