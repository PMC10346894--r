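# Independent brute-force oracle for the five graph metrics, based on
# exhaustive enumeration of simple paths. For each node count n, every
# simple path (sequence of distinct vertices) between every unordered
# pair is tabulated once: the set of edges it uses (bitmask), its length,
# and its interior vertices (bitmask). A graph is a bitmask over edges;
# a path exists in the graph iff its edge mask is a subset of the
# graph's. All metrics follow by direct minimisation/counting. This
# shares no code with the package implementation.

.oracle_env <- new.env(parent = emptyenv())

.perms <- function(v) {
  n <- length(v)
  if (n == 0L) return(matrix(integer(0), 1L, 0L))
  if (n == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], .perms(v[-i]), deparse.level = 0)
  }))
}

oracle_edge_ids <- function(n) {
  eid <- matrix(0L, n, n)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      k <- k + 1L
      eid[i, j] <- eid[j, i] <- k
    }
  }
  eid
}

oracle_path_table <- function(n) {
  key <- as.character(n)
  if (!is.null(.oracle_env[[key]])) return(.oracle_env[[key]])
  eid <- oracle_edge_ids(n)
  pi <- integer(0); pj <- integer(0); len <- integer(0)
  emask <- integer(0); vmask <- integer(0)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, n)) {
      others <- setdiff(seq_len(n), c(i, j))
      for (k in 0:length(others)) {
        subsets <- if (k == 0L) {
          list(integer(0))
        } else if (length(others) == 1L) {
          list(others)
        } else {
          asplit(utils::combn(others, k), 2L)
        }
        for (sub in subsets) {
          pm <- .perms(as.integer(sub))
          for (r in seq_len(nrow(pm))) {
            seqv <- c(i, pm[r, ], j)
            ids <- eid[cbind(seqv[-length(seqv)], seqv[-1L])]
            pi <- c(pi, i); pj <- c(pj, j)
            len <- c(len, length(ids))
            emask <- c(emask, sum(bitwShiftL(1L, ids - 1L)))
            vmask <- c(vmask, sum(bitwShiftL(1L, pm[r, ] - 1L)))
          }
        }
      }
    }
  }
  pair <- eid[cbind(pi, pj)]
  tab <- list(n = n, eid = eid, pi = pi, pj = pj, pair = pair,
              len = len, emask = as.integer(emask),
              vmask = as.integer(vmask),
              bypair = split(seq_along(pair), pair),
              npairs = (n * (n - 1L)) %/% 2L)
  .oracle_env[[key]] <- tab
  tab
}

oracle_graph_mask <- function(a) {
  n <- nrow(a)
  eid <- oracle_edge_ids(n)
  gm <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, n)) {
      if (a[i, j] > 0) gm <- bitwOr(gm, bitwShiftL(1L, eid[i, j] - 1L))
    }
  }
  gm
}

# pairwise distances by enumeration: d(pair) = shortest valid path length
oracle_distances <- function(a) {
  n <- nrow(a)
  if (n < 2L) return(numeric(0))
  tab <- oracle_path_table(n)
  gm <- oracle_graph_mask(a)
  valid <- bitwAnd(tab$emask, gm) == tab$emask
  d <- rep(Inf, tab$npairs)
  for (p in seq_len(tab$npairs)) {
    rows <- tab$bypair[[as.character(p)]]
    v <- rows[valid[rows]]
    if (length(v)) d[p] <- min(tab$len[v])
  }
  d
}

oracle_global_efficiency <- function(a) {
  d <- oracle_distances(a)
  mean(1 / d)       # each unordered pair represents its two ordered pairs
}

oracle_avg_path_length <- function(a) {
  d <- oracle_distances(a)
  fin <- is.finite(d)
  if (!any(fin)) stop("no connected pair")
  mean(d[fin])
}

oracle_betweenness_mean <- function(a, normalized = TRUE) {
  n <- nrow(a)
  tab <- oracle_path_table(n)
  gm <- oracle_graph_mask(a)
  valid <- bitwAnd(tab$emask, gm) == tab$emask
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  bc <- numeric(n)
  for (p in seq_len(tab$npairs)) {
    rows <- tab$bypair[[as.character(p)]]
    v <- rows[valid[rows]]
    if (!length(v)) next
    dmin <- min(tab$len[v])
    sp <- v[tab$len[v] == dmin]
    sig <- length(sp)
    for (t in sp) {
      vm <- tab$vmask[t]
      if (vm == 0L) next
      inside <- bitwAnd(vm, bits) > 0L
      bc[inside] <- bc[inside] + 1 / sig
    }
  }
  if (normalized && n > 2L) bc <- bc / ((n - 1) * (n - 2) / 2)
  mean(bc)
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  tab <- oracle_path_table(n)
  gm <- oracle_graph_mask(a)
  valid <- bitwAnd(tab$emask, gm) == tab$emask
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    m <- length(nb)
    if (m < 2L) next
    allowed <- sum(bitwShiftL(1L, nb - 1L))
    forbidden <- bitwAnd(bitwNot(as.integer(allowed)),
                         sum(bitwShiftL(1L, seq_len(n) - 1L)))
    acc <- 0
    for (ai in seq_len(m - 1L)) {
      for (bi in seq(ai + 1L, m)) {
        p <- tab$eid[nb[ai], nb[bi]]
        rows <- tab$bypair[[as.character(p)]]
        v <- rows[valid[rows] & bitwAnd(tab$vmask[rows], forbidden) == 0L]
        if (length(v)) acc <- acc + 1 / min(tab$len[v])
      }
    }
    vals[i] <- 2 * acc / (m * (m - 1))
  }
  mean(vals)
}

oracle_clustering_mean <- function(a) {
  n <- nrow(a)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    tri <- 0L
    for (ai in seq_len(k - 1L)) {
      for (bi in seq(ai + 1L, k)) {
        if (a[nb[ai], nb[bi]] > 0) tri <- tri + 1L
      }
    }
    cc[i] <- 2 * tri / (k * (k - 1))
  }
  mean(cc)
}

oracle_all_metrics <- function(a) {
  list(e_glob = oracle_global_efficiency(a),
       e_loc = oracle_local_efficiency(a),
       bc_mean = oracle_betweenness_mean(a),
       cc = oracle_clustering_mean(a),
       l_avg = tryCatch(oracle_avg_path_length(a), error = function(e) NA))
}

# adjacency matrix from an edge bitmask (n nodes)
graph_from_mask <- function(mask, n) {
  eid <- oracle_edge_ids(n)
  a <- matrix(0, n, n)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, n)) {
      if (bitwAnd(mask, bitwShiftL(1L, eid[i, j] - 1L)) > 0L) {
        a[i, j] <- a[j, i] <- 1
      }
    }
  }
  a
}

random_graph <- function(n, p = 0.5) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.numeric(stats::runif(length(up)) < p)
  a + t(a)
}
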