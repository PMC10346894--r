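# Five topological metrics on binary undirected graphs: global and local
# efficiency, betweenness centrality, clustering coefficient, and average
# shortest path length. Conventions for disconnected graphs are explicit:
# 1/inf = 0 in efficiencies, and the average path length is taken over
# finite-distance pairs only.

as_adj_matrix <- function(adjacency) {
  a <- if (inherits(adjacency, "adjacency")) adjacency$adj else adjacency
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must have a zero diagonal")
  if (!all(a %in% c(0, 1))) stop("adjacency must be binary")
  storage.mode(a) <- "double"
  a
}

#' All-pairs hop-count shortest paths
#'
#' Synchronous breadth-first search from every node simultaneously.
#' Unreachable pairs get `Inf`; the diagonal is 0.
#'
#' @param adjacency Binary symmetric matrix (or `adjacency` object).
#' @return N x N numeric distance matrix.
#' @export
shortest_paths <- function(adjacency) {
  a <- as_adj_matrix(adjacency)
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reached <- diag(n) > 0
  frontier <- reached
  step <- 0L
  while (any(frontier)) {
    step <- step + 1L
    nxt <- (frontier %*% a > 0) & !reached
    if (!any(nxt)) break
    d[nxt] <- step
    reached <- reached | nxt
    frontier <- nxt
  }
  d
}

#' Global efficiency
#'
#' Mean inverse shortest path length over all ordered pairs,
#' `E_glob = 1/(N(N-1)) * sum_{i != j} 1/d_ij`, with `1/Inf = 0`.
#'
#' @param adjacency Binary symmetric matrix (or `adjacency` object).
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adjacency) {
  a <- as_adj_matrix(adjacency)
  n <- nrow(a)
  if (n < 2L) stop("global efficiency needs at least 2 nodes")
  d <- shortest_paths(a)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by
#' each node's neighbors (the node itself excluded); nodes with fewer
#' than 2 neighbors contribute 0.
#'
#' @param adjacency Binary symmetric matrix (or `adjacency` object).
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(adjacency) {
  a <- as_adj_matrix(adjacency)
  n <- nrow(a)
  if (n < 1L) stop("empty adjacency")
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(a[nb, nb, drop = FALSE])
  }, numeric(1L))
  mean(vals)
}

#' Betweenness centrality
#'
#' Brandes' exact accumulation over breadth-first shortest-path DAGs:
#' `BC(j) = sum_{i < k, i,k != j} sigma_ik(j) / sigma_ik` over pairs with
#' at least one path, optionally normalized by `(N-1)(N-2)/2`.
#'
#' @param adjacency Binary symmetric matrix (or `adjacency` object).
#' @param normalized Divide by the number of possible pairs (default).
#' @return List with `bc` (per-node vector) and `mean`.
#' @export
betweenness <- function(adjacency, normalized = TRUE) {
  a <- as_adj_matrix(adjacency)
  n <- nrow(a)
  bc <- numeric(n)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] > 0))
  for (s in seq_len(n)) {
    # single-source BFS with path counting
    dist <- rep(-1L, n); dist[s] <- 0L
    sigma <- numeric(n); sigma[s] <- 1
    order_visited <- integer(0L)
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    delta <- numeric(n)
    for (v in rev(order_visited)) {
      for (w in nbrs[[v]]) {
        if (dist[w] == dist[v] + 1L) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  bc <- bc / 2  # undirected: each unordered pair counted twice
  if (normalized && n > 2L) bc <- bc / ((n - 1) * (n - 2) / 2)
  names(bc) <- rownames(a)
  list(bc = bc, mean = mean(bc))
}

#' Clustering coefficient
#'
#' Per node: `2 T_i / (k_i (k_i - 1))` where `T_i` is the number of
#' triangles through node i and `k_i` its degree; nodes of degree < 2
#' contribute 0. The network value is the unweighted mean over nodes.
#'
#' @param adjacency Binary symmetric matrix (or `adjacency` object).
#' @return List with `cc` (per-node vector) and `mean`.
#' @export
clustering_coefficient <- function(adjacency) {
  a <- as_adj_matrix(adjacency)
  n <- nrow(a)
  deg <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  cc <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  names(cc) <- rownames(a)
  list(cc = cc, mean = mean(cc))
}

#' Average shortest path length
#'
#' Mean hop-count distance over all unordered pairs with finite distance;
#' errors if no pair is connected. Whether the graph was fully connected
#' is reported alongside.
#'
#' @param adjacency Binary symmetric matrix (or `adjacency` object).
#' @return List with `l_avg` and `connected` (logical).
#' @export
avg_path_length <- function(adjacency) {
  a <- as_adj_matrix(adjacency)
  d <- shortest_paths(a)
  vals <- d[upper.tri(d)]
  fin <- is.finite(vals)
  if (!any(fin)) stop("graph has no connected pair of nodes")
  list(l_avg = mean(vals[fin]), connected = all(fin))
}

#' Bundle the five graph metrics
#'
#' @param adjacency Binary symmetric matrix (or `adjacency` object).
#' @param bc_normalized Normalize betweenness (default TRUE).
#' @return An object of class `metrics_record`: list with `e_glob`,
#'   `e_loc`, `bc_mean`, `cc`, `l_avg`, `connected`.
#' @export
metrics_record <- function(adjacency, bc_normalized = TRUE) {
  a <- as_adj_matrix(adjacency)
  apl <- avg_path_length(a)
  structure(list(e_glob = global_efficiency(a),
                 e_loc = local_efficiency(a),
                 bc_mean = betweenness(a, normalized = bc_normalized)$mean,
                 cc = clustering_coefficient(a)$mean,
                 l_avg = apl$l_avg,
                 connected = apl$connected),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf(paste0("<metrics_record> E_glob=%.5f E_loc=%.5f BC=%.5f ",
                     "CC=%.5f l_avg=%.5f%s\n"),
              x$e_glob, x$e_loc, x$bc_mean, x$cc, x$l_avg,
              if (x$connected) "" else " (disconnected)"))
  invisible(x)
}
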