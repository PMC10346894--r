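# Shared fixtures and independent numeric oracles used across test files.

# brute-force dense 3D Gaussian smoothing with joint boundary
# renormalization: weights of the full 3D product kernel that fall inside
# the volume, divided by their sum
dense_smooth_oracle <- function(vol, kernel) {
  d <- dim(vol)
  r <- kernel$truncation_radius_vox
  w <- kernel$weights
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    wsum <- 0
    for (a in seq(-r[1], r[1])) {
      ii <- i + a
      if (ii < 1L || ii > d[1]) next
      wa <- w[[1]][a + r[1] + 1L]
      for (b in seq(-r[2], r[2])) {
        jj <- j + b
        if (jj < 1L || jj > d[2]) next
        wb <- w[[2]][b + r[2] + 1L]
        for (cc in seq(-r[3], r[3])) {
          kk <- k + cc
          if (kk < 1L || kk > d[3]) next
          wt <- wa * wb * w[[3]][cc + r[3] + 1L]
          acc <- acc + wt * vol[ii, jj, kk]
          wsum <- wsum + wt
        }
      }
    }
    out[i, j, k] <- acc / wsum
  }
  out
}

# small cohort configuration used by several test files
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(12L, 12L, 12L), n_subjects = 4L, n_nodes = 4L,
         n_blocks = 2L, n_volumes = 40L, seed = 11L),
    list(...))
  do.call(sim_config, args)
}

# textbook moment oracle for skewness / excess kurtosis
moments_oracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# Laplacian (double-exponential) sampler for ICA recovery tests
rlaplace <- function(n) {
  u <- stats::runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u))
}

# permutation-matched absolute correlations between recovered and true
# sources (greedy assignment on the absolute correlation matrix)
match_sources <- function(est, truth) {
  k <- nrow(truth)
  cm <- abs(stats::cor(t(est), t(truth)))
  out <- numeric(k)
  for (i in seq_len(k)) {
    best <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    out[best[2L]] <- cm[best[1L], best[2L]]
    cm[best[1L], ] <- -1
    cm[, best[2L]] <- -1
  }
  out
}
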