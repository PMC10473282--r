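#' Threshold an FC matrix into a connected binary graph
#'
#' Keeps the strongest positive Fisher-z edges up to a target edge density,
#' on top of a maximum-weight spanning tree backbone (minimum spanning tree
#' of distance `max(weight) - weight`) that guarantees connectedness. Only
#' positive weights compete for the ranked edges; ties are broken by
#' lexicographic (lower node id, lower node id) order.
#'
#' @param fc an `fc_matrix` (or symmetric weight matrix, zero diagonal).
#' @param density target fraction of the N(N-1)/2 node pairs kept as edges.
#' @return A `binary_graph`: list with `adjacency` (0/1 symmetric matrix),
#'   `density` (requested), `n_edges`, `source_state`.
#' @export
binarize <- function(fc, density = 0.2) {
  w <- as.matrix(fc)
  n <- nrow(w)
  diag(w) <- 0
  n_pairs <- n * (n - 1) / 2
  target <- round(density * n_pairs)
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  floor_density <- (n - 1) / n_pairs
  if (target < n - 1)
    stop("density below the MST floor of ", signif(floor_density, 4),
         " (", n - 1, " edges)")

  # MST backbone on distance = max weight - weight (strongest edges first);
  # shifted by +1 so no finite distance is 0 (igraph drops zero entries)
  d <- max(w) - w + 1
  diag(d) <- 0
  g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g_full, weights = igraph::E(g_full)$weight)
  adj <- matrix(0L, n, n, dimnames = dimnames(w))
  me <- igraph::as_edgelist(mst, names = FALSE)
  adj[me] <- 1L
  adj[me[, c(2, 1)]] <- 1L

  # rank remaining positive edges: weight desc, then (i, j) lexicographic
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[ut]
  ord <- order(-wt, ut[, 1], ut[, 2])
  n_edges <- sum(adj) / 2
  for (e in ord) {
    if (n_edges >= target) break
    i <- ut[e, 1]; j <- ut[e, 2]
    if (wt[e] <= 0) break
    if (adj[i, j] == 0L) {
      adj[i, j] <- adj[j, i] <- 1L
      n_edges <- n_edges + 1
    }
  }
  if (n_edges < target)
    warning("only ", n_edges, " edges available (", target,
            " requested): positive-weight supply exhausted")
  structure(list(adjacency = adj, density = density, n_edges = n_edges,
                 source_state = attr(fc, "state_label")),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("Binary graph:", nrow(x$adjacency), "nodes,", x$n_edges,
      "edges (density", signif(2 * x$n_edges /
        (nrow(x$adjacency) * (nrow(x$adjacency) - 1)), 3), ")\n")
  invisible(x)
}

as_igraph <- function(g) {
  if (inherits(g, "binary_graph"))
    igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  else if (igraph::is_igraph(g)) g
  else igraph::graph_from_adjacency_matrix(as.matrix(g) != 0, mode = "undirected")
}

#' Global topology metrics of a binary graph
#'
#' `clustering_coefficient` is the mean Watts-Strogatz nodal clustering
#' (nodes of degree < 2 count as 0); `global_efficiency` is the mean inverse
#' shortest-path length over node pairs; `mean_betweenness` is the mean
#' unnormalized shortest-path betweenness over nodes.
#'
#' @param g a `binary_graph` (or igraph).
#' @return A single numeric value.
#' @export
clustering_coefficient <- function(g) {
  ig <- as_igraph(g)
  mean(igraph::transitivity(ig, type = "local", isolates = "zero"))
}

#' @rdname clustering_coefficient
#' @export
global_efficiency <- function(g) {
  ig <- as_igraph(g)
  igraph::global_efficiency(ig)
}

#' @rdname clustering_coefficient
#' @export
mean_betweenness <- function(g) {
  ig <- as_igraph(g)
  mean(igraph::betweenness(ig, normalized = FALSE))
}

# Characteristic path length (mean shortest-path length over reachable pairs).
char_path_length <- function(g) {
  igraph::mean_distance(as_igraph(g))
}

#' Small-worldness sigma against degree-preserving null networks
#'
#' `sigma = (C / <C_null>) / (L / <L_null>)` where C is the mean clustering
#' coefficient, L the characteristic path length, and nulls are generated by
#' degree-preserving double-edge swaps (10 x |E| swaps each), retried until
#' connected.
#'
#' @param g a `binary_graph`.
#' @param n_null number of null networks (>= 10).
#' @param seed integer seed.
#' @param max_retry maximum rewiring attempts per connected null.
#' @return sigma value with attributes `c_ratio` and `l_ratio`.
#' @export
small_worldness <- function(g, n_null = 100, seed = 1, max_retry = 50) {
  stopifnot(n_null >= 10)
  ig <- as_igraph(g)
  if (!igraph::is_connected(ig)) stop("graph must be connected")
  set.seed(as_seed(seed))
  n_swap <- 10 * igraph::ecount(ig)
  c_obs <- clustering_coefficient(g)
  l_obs <- igraph::mean_distance(ig)
  c_null <- l_null <- numeric(n_null)
  for (k in seq_len(n_null)) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      r <- igraph::rewire(ig, igraph::keeping_degseq(niter = n_swap))
      if (igraph::is_connected(r)) { ok <- TRUE; break }
    }
    if (!ok) stop("failed to generate a connected degree-preserving null")
    c_null[k] <- mean(igraph::transitivity(r, type = "local", isolates = "zero"))
    l_null[k] <- igraph::mean_distance(r)
  }
  sigma <- (c_obs / mean(c_null)) / (l_obs / mean(l_null))
  attr(sigma, "c_ratio") <- c_obs / mean(c_null)
  attr(sigma, "l_ratio") <- l_obs / mean(l_null)
  sigma
}
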