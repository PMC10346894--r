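# ROI time-series extraction, Fisher-z correlation matrices, group
# edge-wise one-sample t-tests with Benjamini-Hochberg FDR control, and
# binarization into adjacency matrices.

#' Extract ROI time series
#'
#' Node signal = unweighted arithmetic mean over the node's voxels at each
#' time point, then each row standardized to zero mean and unit variance.
#'
#' @param image An [fmri_image()].
#' @param atlas A [roi_atlas()] on the same grid.
#' @return An object of class `roi_timeseries`: list with `ts` (N x T
#'   matrix), `node_names`, `tr_s`.
#' @export
extract_roi_timeseries <- function(image, atlas) {
  stopifnot(inherits(image, "fmri_image"), inherits(atlas, "roi_atlas"))
  gi <- dim(image$data)[1:3]
  if (!identical(gi, dim(atlas$labels))) {
    stop(sprintf("grid mismatch: image %s vs atlas %s",
                 paste(gi, collapse = "x"),
                 paste(dim(atlas$labels), collapse = "x")))
  }
  n <- length(atlas$node_names)
  t_len <- dim(image$data)[4L]
  lab <- as.vector(atlas$labels)
  keep <- lab > 0L
  counts <- tabulate(lab[keep], nbins = n)
  empty <- which(counts == 0L)
  if (length(empty)) {
    stop("atlas labels with zero voxels: ", paste(empty, collapse = ", "))
  }
  mat <- matrix(image$data, ncol = t_len)[keep, , drop = FALSE]
  sums <- rowsum(mat, group = lab[keep], reorder = TRUE)
  means <- sums / counts
  ts <- tryCatch(standardize_rows(means), error = function(e) {
    stop("zero-variance node time series for label(s): ",
         sub(".*: ", "", conditionMessage(e)))
  })
  dimnames(ts) <- list(atlas$node_names, NULL)
  structure(list(ts = ts, node_names = atlas$node_names, tr_s = image$tr_s),
            class = "roi_timeseries")
}

#' Pearson correlation matrix of node time series
#'
#' @param ts An N x T numeric matrix or a `roi_timeseries`.
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  m <- if (inherits(ts, "roi_timeseries")) ts$ts else ts
  if (ncol(m) < 3L) stop("need at least 3 time points")
  v <- apply(m, 1L, stats::var)
  if (any(v < .Machine$double.eps)) {
    stop("zero-variance rows: ",
         paste(which(v < .Machine$double.eps), collapse = ", "))
  }
  r <- stats::cor(t(m))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Fisher z-transformation
#'
#' `z = arctanh(r)`, with `|r|` clipped at `1 - 1e-7` beforehand so that
#' degenerate (noise-free) inputs stay finite.
#'
#' @param r Correlations in `[-1, 1]` (vector or matrix).
#' @return Same shape, transformed.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Subject connectivity matrix
#'
#' Fisher-z transformed Pearson correlations with the diagonal stored as
#' 0 (self-connectivity is undefined).
#'
#' @param ts N x T matrix or `roi_timeseries`.
#' @return N x N symmetric Fisher-z matrix, zero diagonal.
#' @export
connectivity_matrix <- function(ts) {
  z <- fisher_z(correlation_matrix(ts))
  diag(z) <- 0
  z
}

# unordered edge index helpers -------------------------------------------

edge_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Group edge-wise inference
#'
#' For each unordered node pair, a two-sided one-sample t-test of the
#' subjects' Fisher-z values against zero (df = n_subjects - 1), followed
#' by Benjamini-Hochberg adjustment over the full edge family of
#' N(N-1)/2 tests. Edges with zero across-subject variance get p floored
#' at 1e-30 when the mean is nonzero and p = 1 otherwise.
#'
#' @param z_matrices List of per-subject N x N Fisher-z matrices.
#' @param node_names Optional node names (defaults to `V1..VN`).
#' @return An object of class `group_edge_stats`: a data frame with
#'   columns `node_a`, `node_b`, `mean_z`, `t`, `p`, `q`, `sign`, plus
#'   attributes `n_nodes`, `n_subjects`, `node_names`.
#' @export
group_edge_test <- function(z_matrices, node_names = NULL) {
  ns <- length(z_matrices)
  if (ns < 2L) stop("need at least 2 subjects")
  n <- nrow(z_matrices[[1L]])
  if (is.null(node_names)) node_names <- paste0("V", seq_len(n))
  pairs <- edge_pairs(n)
  m <- nrow(pairs)
  zmat <- vapply(z_matrices, function(z) z[pairs], numeric(m))  # m x ns
  if (!is.matrix(zmat)) zmat <- matrix(zmat, nrow = m)
  mu <- rowMeans(zmat)
  sd <- sqrt(rowSums((zmat - mu)^2) / (ns - 1L))
  tval <- numeric(m)
  pval <- numeric(m)
  ok <- sd > 0
  tval[ok] <- mu[ok] / (sd[ok] / sqrt(ns))
  pval[ok] <- 2 * stats::pt(-abs(tval[ok]), df = ns - 1L)
  if (any(!ok)) {
    degen <- !ok
    tval[degen] <- ifelse(mu[degen] == 0, 0, sign(mu[degen]) * Inf)
    pval[degen] <- ifelse(mu[degen] == 0, 1, 1e-30)
    message(sum(degen), " edge(s) had zero across-subject variance")
  }
  qval <- stats::p.adjust(pval, method = "BH")
  out <- data.frame(node_a = node_names[pairs[, 1L]],
                    node_b = node_names[pairs[, 2L]],
                    mean_z = mu, t = tval, p = pval, q = qval,
                    sign = sign(mu), stringsAsFactors = FALSE)
  attr(out, "n_nodes") <- n
  attr(out, "n_subjects") <- ns
  attr(out, "node_names") <- node_names
  class(out) <- c("group_edge_stats", class(out))
  out
}

#' Benjamini-Hochberg step-up rejection mask
#'
#' Rejects all hypotheses with rank up to `max{i : p_(i) <= i q / m}`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate.
#' @return Logical vector, `TRUE` where rejected.
#' @export
fdr_threshold <- function(p_values, q = 0.05) {
  m <- length(p_values)
  if (m == 0L) return(logical(0L))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  ord <- order(p_values)
  ps <- p_values[ord]
  below <- which(ps <= seq_len(m) * q / m)
  mask <- logical(m)
  if (length(below)) mask[ord[seq_len(max(below))]] <- TRUE
  mask
}

#' Binarize group edge statistics into an adjacency matrix
#'
#' An edge is present iff its BH-adjusted q-value falls below `q`
#' (two-sided: significant negative edges count unless
#' `positive_only = TRUE`).
#'
#' @param stats A `group_edge_stats` object.
#' @param q FDR threshold (default 0.05).
#' @param positive_only Drop significant edges with negative mean z.
#' @return List of class `adjacency`: `adj` (binary N x N symmetric,
#'   zero diagonal), `sign` (signed N x N: -1/0/+1), `node_names`.
#' @export
binarize <- function(stats, q = 0.05, positive_only = FALSE) {
  stopifnot(inherits(stats, "group_edge_stats"))
  n <- attr(stats, "n_nodes")
  keep <- stats$q <= q
  if (positive_only) keep <- keep & stats$sign > 0
  pairs <- edge_pairs(n)
  adj <- matrix(0L, n, n)
  sgn <- matrix(0L, n, n)
  sel <- pairs[keep, , drop = FALSE]
  adj[sel] <- 1L
  sgn[sel] <- as.integer(stats$sign[keep])
  adj <- adj + t(adj)
  sgn <- sgn + t(sgn)
  nn <- attr(stats, "node_names")
  dimnames(adj) <- dimnames(sgn) <- list(nn, nn)
  structure(list(adj = adj, sign = sgn, node_names = nn),
            class = "adjacency")
}

#' Write connectivity outputs as TSV
#'
#' @param stats A `group_edge_stats` object.
#' @param adjacency An `adjacency` object (optional).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_connectivity <- function(stats, adjacency = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(stats), file.path(dir, "edge_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(adjacency)) {
    utils::write.table(adjacency$adj, file.path(dir, "adjacency.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(dir)
}
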