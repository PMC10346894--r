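test_that("extract_roi_timeseries aggregates and validates", {
  cfg <- tiny_config(noise_sd = 0, subject_tau = 0)
  co <- render_cohort(cfg)
  img <- co$subjects[[1]]$image
  ts <- extract_roi_timeseries(img, co$atlas)
  # noise-free: extracted = latent node signals (already standardized)
  expect_equal(ts$ts, co$subjects[[1]]$ground_truth$node_timeseries,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(ts$node_names, co$atlas$node_names)

  # single-voxel ROI returns that voxel's (standardized) series
  lab <- array(0L, dim = c(4, 4, 4))
  lab[2, 2, 2] <- 1L
  at1 <- roi_atlas(lab, "only")
  set.seed(2)
  arr <- array(rnorm(4^3 * 10), dim = c(4, 4, 4, 10))
  im <- fmri_image(arr)
  t1 <- extract_roi_timeseries(im, at1)
  expect_equal(t1$ts[1, ], as.vector(scale(arr[2, 2, 2, ])),
               tolerance = 1e-12)

  # a 2-voxel ROI holding s and -s cancels to zero variance -> error
  lab2 <- array(0L, dim = c(4, 4, 4))
  lab2[1, 1, 1] <- 1L
  lab2[2, 1, 1] <- 1L
  arr2 <- array(0, dim = c(4, 4, 4, 10))
  s <- rnorm(10)
  arr2[1, 1, 1, ] <- s
  arr2[2, 1, 1, ] <- -s
  expect_error(extract_roi_timeseries(fmri_image(arr2), roi_atlas(lab2, "x")),
               "zero-variance")

  # grid mismatch
  expect_error(extract_roi_timeseries(im, co$atlas), "grid mismatch")
})

test_that("correlation_matrix matches direct covariance computation", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 5)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- correlation_matrix(rbind(x, y))
  expect_equal(r[1, 2], r_oracle, tolerance = 1e-12)
  expect_equal(r[1, 2], 0.9827076, tolerance = 1e-6)
  expect_equal(diag(r), rep(1, 2), ignore_attr = TRUE)

  expect_equal(correlation_matrix(rbind(x, -x))[1, 2], -1)
  expect_error(correlation_matrix(rbind(x, rep(1, 4))), "zero-variance")
  expect_error(correlation_matrix(matrix(1:4, 2, 2)), "3 time points")
})

test_that("fisher_z is arctanh with clipping", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3), tolerance = 1e-15)
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.5), "<= 1")
  # round trip with tanh on (-5, 5)
  zz <- seq(-5, 5, by = 0.25)
  expect_equal(fisher_z(tanh(zz)), zz, tolerance = 1e-10)
})

test_that("group_edge_test reproduces the one-sample t by hand", {
  mk <- function(v) {
    m <- matrix(0, 2, 2)
    m[1, 2] <- m[2, 1] <- v
    m
  }
  st <- group_edge_test(lapply(c(0.5, 0.6, 0.7), mk))
  t_oracle <- 0.6 / (sd(c(0.5, 0.6, 0.7)) / sqrt(3))
  expect_equal(st$t, t_oracle, tolerance = 1e-12)
  expect_equal(st$t, 10.39230, tolerance = 1e-5)
  expect_equal(st$p, 2 * pt(-t_oracle, df = 2), tolerance = 1e-12)
  # cross-check against stats::t.test
  tt <- t.test(c(0.5, 0.6, 0.7))
  expect_equal(st$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(st$p, tt$p.value, tolerance = 1e-12)

  # all-zero edge: t = 0, p = 1 (degenerate variance path)
  expect_message(st0 <- group_edge_test(lapply(c(0, 0, 0), mk)),
                 "zero across-subject variance")
  expect_equal(st0$t[1], 0)
  expect_equal(st0$p[1], 1)

  # constant nonzero edge: p floored
  expect_message(stc <- group_edge_test(lapply(c(0.4, 0.4, 0.4), mk)),
                 "zero across-subject variance")
  expect_equal(stc$p[1], 1e-30)

  expect_error(group_edge_test(list(mk(0.1))), "2 subjects")
})

test_that("group_edge_test agrees with t.test across many random edges", {
  set.seed(77)
  n <- 6
  zs <- lapply(1:8, function(i) {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- rnorm(n * (n - 1) / 2, mean = 0.2, sd = 0.3)
    m + t(m)
  })
  st <- group_edge_test(zs)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), ]
  for (e in sample(nrow(pairs), 5)) {
    vals <- vapply(zs, function(z) z[pairs[e, 1], pairs[e, 2]], 0)
    tt <- t.test(vals)
    expect_equal(st$t[e], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(st$p[e], tt$p.value, tolerance = 1e-10)
  }
})

test_that("fdr_threshold implements the BH step-up rule", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  expect_identical(fdr_threshold(p, 0.05), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(fdr_threshold(rep(1, 4), 0.05), rep(FALSE, 4))
  expect_identical(fdr_threshold(rep(0, 4), 0.05), rep(TRUE, 4))
  expect_identical(fdr_threshold(numeric(0)), logical(0))
  expect_error(fdr_threshold(c(0.5, 1.2)), "\\[0, 1\\]")

  # agreement with the p.adjust route on random inputs
  set.seed(5)
  for (i in 1:20) {
    pv <- runif(50)^2
    expect_identical(fdr_threshold(pv, 0.05),
                     p.adjust(pv, "BH") <= 0.05)
  }
})

test_that("binarize yields symmetric binary adjacency with recorded signs", {
  cfg <- tiny_config(n_subjects = 6, rho_within = 0.7, rho_between = 0)
  sim <- simulate_group_timeseries(cfg)
  zs <- lapply(sim$timeseries, connectivity_matrix)
  st <- group_edge_test(zs)
  adj <- binarize(st, q = 0.05)
  a <- adj$adj
  expect_true(all(a %in% 0:1))
  expect_identical(a, t(a))
  expect_identical(diag(a), setNames(rep(0L, 4), rownames(a)))
  # mask -> matrix round trip consistent with the stats rows
  expect_equal(sum(a) / 2, sum(st$q <= 0.05))

  # no rejection -> zero matrix
  st_null <- st
  st_null$q <- rep(1, nrow(st_null))
  expect_true(all(binarize(st_null)$adj == 0))

  # positive_only drops negative significant edges
  adj_pos <- binarize(st, positive_only = TRUE)
  expect_true(all(adj_pos$sign[adj_pos$adj == 1] > 0))
})

test_that("a fully significant 32-node family gives the complete 496-edge graph", {
  cfg <- sim_config(n_subjects = 8, n_volumes = 60, rho_within = 0.6,
                    rho_between = 0.5, subject_tau = 0.02, noise_sd = 0.5,
                    seed = 12)
  sim <- simulate_group_timeseries(cfg)
  st <- group_edge_test(lapply(sim$timeseries, connectivity_matrix))
  expect_equal(nrow(st), 496)              # N(N-1)/2 for N = 32
  adj <- binarize(st, q = 0.05)
  expect_equal(sum(adj$adj) / 2, 496)
  expect_equal(metrics_record(adj)$e_glob, 1)
})

test_that("FDR is controlled under the global null (quick check)", {
  set.seed(303)
  fdp <- replicate(40, {
    zs <- lapply(1:8, function(i) {
      connectivity_matrix(matrix(rnorm(8 * 50), 8))
    })
    st <- group_edge_test(zs)
    r <- sum(st$q <= 0.05)
    if (r == 0) 0 else r / max(r, 1)  # all discoveries are false here
  })
  se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 3 * se + 0.02)
})

test_that("planted edges are detected with high sensitivity (quick check)", {
  cfg <- sim_config(n_subjects = 20, n_volumes = 100, seed = 71)
  sim <- simulate_group_timeseries(cfg)
  st <- group_edge_test(lapply(sim$timeseries, connectivity_matrix))
  blocks <- attr(sim$sigma_true, "block")
  pairs <- which(upper.tri(sim$sigma_true), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), ]
  within <- blocks[pairs[, 1]] == blocks[pairs[, 2]]
  expect_gte(mean(st$q[within] <= 0.05), 0.9)
})
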