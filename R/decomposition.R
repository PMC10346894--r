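# Group-level PCA and spatial ICA with per-component kurtosis/skewness
# summaries and cross-kernel comparison matrices.

#' Stack subjects into a group data matrix
#'
#' Per subject, every voxel time series is standardized to zero mean and
#' unit variance; voxels that are constant in any subject are dropped
#' (recorded in the mask). Subjects are then concatenated along time:
#' rows = subjects x time, columns = retained voxels.
#'
#' @param images List of [fmri_image()] objects on a common grid.
#' @param mask Optional logical 3D array restricting the voxel set.
#' @return An object of class `group_data`: list with `x` (matrix),
#'   `voxel_index` (linear indices of retained voxels), `grid`,
#'   `n_subjects`, `n_volumes`.
#' @export
stack_group_data <- function(images, mask = NULL) {
  if (!length(images)) stop("need at least one subject")
  grids <- lapply(images, function(im) dim(im$data)[1:3])
  if (length(unique(vapply(grids, paste, "", collapse = "x"))) != 1L) {
    stop("subjects are on inconsistent grids")
  }
  g <- grids[[1L]]
  nv <- prod(g)
  keep <- if (is.null(mask)) rep(TRUE, nv) else as.vector(mask)
  if (length(keep) != nv) stop("mask does not match the grid")
  mats <- vector("list", length(images))
  for (s in seq_along(images)) {
    t_len <- dim(images[[s]]$data)[4L]
    m <- matrix(images[[s]]$data, nrow = nv)   # voxel x time
    mu <- rowMeans(m)
    sd <- sqrt(rowSums((m - mu)^2) / (t_len - 1L))
    keep <- keep & sd > .Machine$double.eps
    mats[[s]] <- m
  }
  if (!any(keep)) stop("no voxel is non-constant in every subject")
  for (s in seq_along(mats)) {
    m <- mats[[s]][keep, , drop = FALSE]
    mu <- rowMeans(m)
    sd <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
    mats[[s]] <- t((m - mu) / sd)              # time x voxel
  }
  x <- do.call(rbind, mats)
  structure(list(x = x, voxel_index = which(keep), grid = g,
                 n_subjects = length(images),
                 n_volumes = vapply(mats, nrow, 0L)),
            class = "group_data")
}

.as_group_matrix <- function(x) {
  if (inherits(x, "group_data")) x$x else as.matrix(x)
}

# fixed sign convention: flip each map so its largest-|value| entry is
# positive (ties broken by the first occurrence)
.fix_signs <- function(maps, courses) {
  for (k in seq_len(nrow(maps))) {
    j <- which.max(abs(maps[k, ]))
    if (maps[k, j] < 0) {
      maps[k, ] <- -maps[k, ]
      courses[, k] <- -courses[, k]
    }
  }
  list(maps = maps, courses = courses)
}

#' Group PCA
#'
#' Top-`n` singular directions of the (already column-standardized) group
#' matrix: spatial maps are the orthonormal right singular vectors,
#' time courses the left singular vectors scaled by the singular values.
#' Computed from the eigendecomposition of the smaller Gram matrix, so it
#' is exact and deterministic.
#'
#' @param x A `group_data` object or numeric matrix (rows = time,
#'   columns = voxels).
#' @param n Number of components (default 40).
#' @return An object of class `component_set` with `maps`
#'   (n x voxels, orthonormal rows), `courses` (rows x n),
#'   `explained_variance` (ratios, non-increasing), `method = "pca"`.
#' @export
pca_components <- function(x, n = 40L) {
  xm <- .as_group_matrix(x)
  n <- as.integer(n)
  if (n < 1L || n > min(dim(xm))) {
    stop("`n` must lie in 1..min(dim(x)) = ", min(dim(xm)))
  }
  xm <- sweep(xm, 2L, colMeans(xm))
  if (nrow(xm) <= ncol(xm)) {
    gram <- tcrossprod(xm)                      # rows x rows
    eg <- eigen(gram, symmetric = TRUE)
    d2 <- pmax(eg$values, 0)
    u <- eg$vectors[, seq_len(n), drop = FALSE]
    d <- sqrt(d2[seq_len(n)])
    maps <- crossprod(u, xm) / ifelse(d > 0, d, 1)   # n x voxels
    courses <- u * rep(d, each = nrow(u))
    total <- sum(d2)
  } else {
    gram <- crossprod(xm)
    eg <- eigen(gram, symmetric = TRUE)
    d2 <- pmax(eg$values, 0)
    v <- eg$vectors[, seq_len(n), drop = FALSE]
    d <- sqrt(d2[seq_len(n)])
    maps <- t(v)
    courses <- xm %*% v
    total <- sum(d2)
  }
  fixed <- .fix_signs(maps, courses)
  structure(list(maps = fixed$maps, courses = fixed$courses,
                 explained_variance = d2[seq_len(n)] / total,
                 singular_values = d, method = "pca",
                 voxel_index = if (inherits(x, "group_data")) x$voxel_index,
                 grid = if (inherits(x, "group_data")) x$grid),
            class = "component_set")
}

#' Group spatial ICA
#'
#' FastICA with the log-cosh negentropy contrast and symmetric
#' decorrelation: the data are whitened to `n` dimensions via PCA, then a
#' fixed-point iteration rotates the whitened basis until successive
#' unmixing matrices differ by less than `tol` (or `max_iter` is hit, in
#' which case the result is flagged non-converged with a warning).
#' Estimated sources are the spatial maps; deterministic given `seed`.
#'
#' @param x A `group_data` object or numeric matrix (rows = time,
#'   columns = voxels).
#' @param n Number of components (default 40).
#' @param seed Integer seed for the random orthonormal initialization.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return A `component_set` with `maps` (n x voxels, unit-variance
#'   sources), `courses` (estimated mixing), `method = "ica"`,
#'   `converged`, `n_iter`.
#' @export
ica_components <- function(x, n = 40L, seed = 1L, max_iter = 500L,
                           tol = 1e-4) {
  xm <- .as_group_matrix(x)
  n <- as.integer(n)
  if (n < 1L || n > min(dim(xm))) {
    stop("`n` must lie in 1..min(dim(x)) = ", min(dim(xm)))
  }
  xm <- xm - rowMeans(xm)   # center each channel over samples (voxels)
  nv <- ncol(xm)
  # whiten to n dims: z = D^{-1/2} U' X, rows of z white over voxels
  gram <- tcrossprod(xm) / nv
  eg <- eigen(gram, symmetric = TRUE)
  d2 <- eg$values[seq_len(n)]
  if (any(d2 < 1e-12)) stop("degenerate whitening: data rank below `n`")
  u <- eg$vectors[, seq_len(n), drop = FALSE]
  whiten <- t(u) / sqrt(d2)                     # n x rows
  z <- whiten %*% xm                            # n x voxels
  set.seed(as.integer(seed))
  w <- matrix(stats::rnorm(n * n), n, n)
  w <- .sym_decorrelate(w)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    wz <- w %*% z                               # n x voxels
    g <- tanh(wz)
    gp <- 1 - g^2
    w_new <- (g %*% t(z)) / nv - rowMeans(gp) * w
    w_new <- .sym_decorrelate(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("FastICA did not converge in ", max_iter, " iterations")
  }
  s <- w %*% z                                  # sources = spatial maps
  # log-cosh negentropy proxy per component, J = (E[log cosh s] - E0)^2
  # with E0 = E[log cosh X] for X ~ N(0,1)
  e0 <- 0.3745672
  contrast <- (rowMeans(log(cosh(s))) - e0)^2
  low_contrast <- all(contrast < 1e-4)
  if (low_contrast) {
    warning("all components have near-Gaussian contrast; ",
            "ICA is unidentifiable on this data")
  }
  # mixing (time courses): X' ~ A s  =>  A = X s' (s s')^{-1} = X s'/nv
  a <- xm %*% t(s) / nv
  fixed <- .fix_signs(s, a)
  structure(list(maps = fixed$maps, courses = fixed$courses,
                 explained_variance = NULL, method = "ica",
                 converged = converged, n_iter = it,
                 contrast = contrast, low_contrast = low_contrast,
                 voxel_index = if (inherits(x, "group_data")) x$voxel_index,
                 grid = if (inherits(x, "group_data")) x$grid),
            class = "component_set")
}

# symmetric decorrelation: W <- (W W')^{-1/2} W
.sym_decorrelate <- function(w) {
  s <- eigen(tcrossprod(w), symmetric = TRUE)
  s$vectors %*% (t(s$vectors) / sqrt(s$values)) %*% w
}

# population-moment skewness and excess kurtosis
sample_skewness <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 < .Machine$double.eps) stop("zero-variance input")
  mean(x^3) / m2^1.5
}

sample_kurtosis <- function(x, excess = TRUE) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 < .Machine$double.eps) stop("zero-variance input")
  k <- mean(x^4) / m2^2
  if (excess) k - 3 else k
}

#' Component shape statistics
#'
#' Per spatial map, the sample skewness `m3 / m2^(3/2)` and kurtosis
#' `m4 / m2^2` (excess form subtracts 3, so a Gaussian scores 0), using
#' population moment definitions; plus min/mean/max summaries with the
#' across-component SD.
#'
#' @param component_set A `component_set` (or a plain matrix of maps,
#'   component x voxel).
#' @param excess_kurtosis Use excess kurtosis (default TRUE).
#' @return An object of class `shape_stats`: list with `kurtosis`,
#'   `skewness` (per-component vectors), `summary` (data frame with rows
#'   kurtosis/skewness and columns min/mean/max/sd), `method`.
#' @export
shape_stats <- function(component_set, excess_kurtosis = TRUE) {
  maps <- if (inherits(component_set, "component_set")) {
    component_set$maps
  } else {
    as.matrix(component_set)
  }
  if (!nrow(maps)) stop("no component maps")
  kur <- apply(maps, 1L, sample_kurtosis, excess = excess_kurtosis)
  ske <- apply(maps, 1L, sample_skewness)
  summ <- data.frame(
    statistic = c("kurtosis", "skewness"),
    min = c(min(kur), min(ske)),
    mean = c(mean(kur), mean(ske)),
    max = c(max(kur), max(ske)),
    sd = c(stats::sd(kur), stats::sd(ske)))
  structure(list(kurtosis = kur, skewness = ske, summary = summ,
                 method = if (inherits(component_set, "component_set")) {
                   component_set$method
                 } else {
                   NA_character_
                 }),
            class = "shape_stats")
}

#' Cross-kernel comparison of component statistics
#'
#' For every pair of FWHM levels, a two-sided Welch two-sample t-test on
#' the per-component values of the chosen statistic; returns a symmetric
#' p-value matrix with unit diagonal.
#'
#' @param stats_by_fwhm Named list of `shape_stats` (names = kernel
#'   labels), or a named list of numeric vectors.
#' @param statistic `"kurtosis"` or `"skewness"` (ignored when plain
#'   vectors are supplied).
#' @return K x K symmetric matrix of p-values, unit diagonal, dimnames
#'   from the list names.
#' @export
compare_across_kernels <- function(stats_by_fwhm,
                                   statistic = c("kurtosis", "skewness")) {
  statistic <- match.arg(statistic)
  k <- length(stats_by_fwhm)
  if (k < 2L) stop("need at least 2 kernel levels")
  vals <- lapply(stats_by_fwhm, function(s) {
    v <- if (inherits(s, "shape_stats")) s[[statistic]] else as.numeric(s)
    if (length(v) < 2L) stop("need at least 2 components per level")
    v
  })
  p <- matrix(1, k, k)
  labs <- names(stats_by_fwhm)
  if (is.null(labs)) labs <- as.character(seq_len(k))
  dimnames(p) <- list(labs, labs)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      p[i, j] <- p[j, i] <- welch_p(vals[[i]], vals[[j]])
    }
  }
  p
}

# two-sided Welch t-test p-value (direct formula; identical sample sets
# give t = 0, p = 1)
welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 < .Machine$double.eps) return(1)
  tval <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tval), df = df)
}

#' Write component maps as a 4D NIfTI image
#'
#' Components become the 4th axis; voxels outside the retained mask are 0.
#'
#' @param component_set A `component_set` produced from a `group_data`
#'   input (so the voxel index and grid are known).
#' @param path Output `.nii`/`.nii.gz` path.
#' @param voxel_size_mm Voxel size for the header.
#' @return `path`, invisibly.
#' @export
write_component_maps <- function(component_set, path, voxel_size_mm = 3) {
  if (is.null(component_set$grid)) {
    stop("component set carries no grid information")
  }
  g <- component_set$grid
  n <- nrow(component_set$maps)
  arr <- array(0, dim = c(g, n))
  flat <- matrix(0, prod(g), n)
  flat[component_set$voxel_index, ] <- t(component_set$maps)
  arr[] <- flat
  write_nifti(arr, path, voxel_size_mm = voxel_size_mm)
}
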