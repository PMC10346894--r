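test_that("planted_sigma builds the stated block structure", {
  expect_equal(planted_sigma(5, 5, 0, 0), diag(5), ignore_attr = TRUE)

  s <- planted_sigma(4, 2, 0.6, 0.1)
  expect_equal(s[1, 2], 0.6)
  expect_equal(s[3, 4], 0.6)
  expect_equal(s[1, 3], 0.1)
  expect_equal(s[2, 4], 0.1)
  expect_equal(diag(s), rep(1, 4))
  expect_equal(attr(s, "block"), rep(1:2, each = 2))

  # default 32/8 matrix is positive definite by the eigen oracle
  s32 <- planted_sigma(32, 8, 0.6, 0.1)
  expect_gt(min(eigen(s32, symmetric = TRUE, only.values = TRUE)$values), 0)

  # an impossible combination errors and reports the eigenvalue
  expect_error(planted_sigma(8, 2, -0.5, 0), "positive definite")
})

test_that("sample_node_timeseries has the planted correlation structure", {
  s <- planted_sigma(4, 2, 0.6, 0.1)
  x <- sample_node_timeseries(s, 1e5, seed = 42)
  expect_equal(rowMeans(x), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(x, 1, sd), rep(1, 4), tolerance = 1e-12)
  r <- cor(t(x))
  expect_lt(max(abs(r - s)), 0.02)     # Monte-Carlo bound ~3/sqrt(T)

  id <- diag(4)
  xi <- sample_node_timeseries(id, 1e5, seed = 43)
  ri <- cor(t(xi))
  expect_lt(max(abs(ri[upper.tri(ri)])), 0.02)

  x2 <- sample_node_timeseries(id, 2, seed = 1)
  expect_equal(dim(x2), c(4L, 2L))
  expect_equal(apply(x2, 1, sd), rep(1, 4), tolerance = 1e-12)

  expect_error(sample_node_timeseries(matrix(c(1, 2, 2, 1), 2, 2), 10),
               "positive definite")
})

test_that("make_task_regressor follows the block design", {
  # all-baseline design
  reg0 <- make_task_regressor(task_design(baseline_s = 60, n_trials = 0),
                              tr_s = 3, n_volumes = 20)
  expect_equal(reg0, rep(0, 20))

  # default 24-trial design over 288 s at TR = 3 -> 96 samples
  reg <- make_task_regressor(task_design(), tr_s = 3, n_volumes = 96)
  expect_length(reg, 96)
  expect_equal(max(reg), 1)
  expect_true(all(reg > -0.25 & reg <= 1))

  # single stimulus at t = 0: haemodynamic peak lands 6-9 s after onset
  reg1 <- make_task_regressor(task_design(baseline_s = 0, n_trials = 1),
                              tr_s = 3, n_volumes = 20)
  peak_t <- (which.max(reg1) - 1) * 3
  expect_true(peak_t >= 6 && peak_t <= 9)

  expect_error(make_task_regressor(task_design(), tr_s = 3, n_volumes = 50),
               "does not fit")
})

test_that("make_parcellation places disjoint spherical ROIs", {
  # discrete ball of radius 2 has 33 voxels
  cfg1 <- sim_config(grid_shape = c(8, 8, 8), n_nodes = 1, n_blocks = 1,
                     seed = 5)
  at1 <- make_parcellation(cfg1)
  expect_equal(sum(at1$labels == 1), 33)

  cfg <- sim_config(seed = 9)
  at <- make_parcellation(cfg)
  counts <- tabulate(at$labels[at$labels > 0], 32)
  expect_equal(counts, rep(33L, 32))            # disjoint by construction
  expect_identical(at$node_names, major_network_nodes())

  at_again <- make_parcellation(cfg)
  expect_identical(at$labels, at_again$labels)  # deterministic given seed

  expect_error(
    make_parcellation(sim_config(grid_shape = c(10, 10, 10), n_nodes = 32,
                                 seed = 1)),
    "grid too small")
})

test_that("subject_sigma perturbs on the Fisher-z scale and stays PD", {
  s <- planted_sigma(6, 3, 0.6, 0.1)
  expect_identical(subject_sigma(s, 0, seed = 1), s)
  p <- subject_sigma(s, 0.1, seed = 2)
  expect_equal(diag(p), rep(1, 6))
  expect_equal(p, t(p))
  expect_false(identical(p, unclass(s)))
  expect_gt(min(eigen(p, symmetric = TRUE, only.values = TRUE)$values), 0)
  # heavy perturbation still yields a valid correlation matrix
  h <- subject_sigma(planted_sigma(10, 2, 0.9, 0.5), 1.5, seed = 3)
  expect_gt(min(eigen(h, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_lte(max(abs(h)), 1 + 1e-12)
})

test_that("render_subject embeds latent signals per the noise contract", {
  cfg <- tiny_config(noise_sd = 0, subject_tau = 0)
  at <- make_parcellation(cfg)
  s <- planted_sigma(4, 2, 0.6, 0.1)
  sub <- render_subject(cfg, at, s, latent_seed = 21, noise_seed = 22)
  # noise-free: every ROI voxel equals its node's latent series
  for (k in 1:4) {
    vox <- which(at$labels == k, arr.ind = FALSE)
    mat <- matrix(sub$image$data, ncol = cfg$n_volumes)[vox, , drop = FALSE]
    expect_equal(mat, matrix(rep(sub$node_timeseries[k, ], each = length(vox)),
                             nrow = length(vox)), tolerance = 1e-12)
  }
  # background is exactly zero when noise_sd = 0
  bg <- which(at$labels == 0)
  expect_true(all(matrix(sub$image$data, ncol = cfg$n_volumes)[bg, ] == 0))

  # same latent seed + different noise seeds: same latents, different data
  cfgn <- tiny_config(noise_sd = 1, subject_tau = 0)
  a <- render_subject(cfgn, at, s, latent_seed = 21, noise_seed = 31)
  b <- render_subject(cfgn, at, s, latent_seed = 21, noise_seed = 32)
  expect_identical(a$node_timeseries, b$node_timeseries)
  expect_false(identical(a$image$data, b$image$data))
})

test_that("render_cohort is reproducible and correctly shaped", {
  cfg <- tiny_config(n_subjects = 2)
  co1 <- render_cohort(cfg)
  co2 <- render_cohort(cfg)
  expect_length(co1$subjects, 2)
  expect_equal(dim(co1$subjects[[1]]$image$data), c(12L, 12L, 12L, 40L))
  expect_identical(co1$subjects[[1]]$image$data, co2$subjects[[1]]$image$data)
  expect_identical(co1$atlas$labels, co2$atlas$labels)

  # different seeds give different data
  co3 <- render_cohort(tiny_config(n_subjects = 2, seed = 99))
  expect_false(identical(co1$subjects[[1]]$image$data,
                         co3$subjects[[1]]$image$data))
})

test_that("extraction recovers the subject correlation matrix at large T", {
  cfg <- sim_config(grid_shape = c(12, 12, 12), n_subjects = 1, n_nodes = 4,
                    n_blocks = 2, n_volumes = 1e4, noise_sd = 0,
                    subject_tau = 0.1, seed = 31)
  co <- render_cohort(cfg)
  ts <- extract_roi_timeseries(co$subjects[[1]]$image, co$atlas)
  r <- correlation_matrix(ts)
  expect_lt(max(abs(r - co$subjects[[1]]$ground_truth$sigma)), 0.03)
})

test_that("cohorts write to disk and read back exactly", {
  cfg <- tiny_config(n_subjects = 2)
  co <- render_cohort(cfg)
  dir <- tempfile()
  write_cohort(co, cfg, dir)
  expect_true(file.exists(file.path(dir, "atlas.nii.gz")))
  back <- read_nifti(file.path(dir, "sub-01.nii.gz"))
  expect_identical(back$data, co$subjects[[1]]$image$data)
  expect_equal(back$voxel_size_mm, rep(3, 3))
  atlas_back <- read_nifti(file.path(dir, "atlas.nii.gz"))
  expect_identical(atlas_back$data, array(as.double(co$atlas$labels),
                                          dim = dim(co$atlas$labels)))
  cfg_back <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg_back$n_subjects, 2)
  unlink(dir, recursive = TRUE)
})

test_that("simulate_group_timeseries mirrors the rendered cohort's nodes", {
  cfg <- tiny_config(n_subjects = 3)
  fast <- simulate_group_timeseries(cfg)
  expect_length(fast$timeseries, 3)
  expect_equal(dim(fast$timeseries[[1]]), c(4L, 40L))
  expect_equal(apply(fast$timeseries[[1]], 1, sd), rep(1, 4),
               tolerance = 1e-12)
  # noiseless fast path equals the latent node series of the renderer
  cfg0 <- tiny_config(n_subjects = 2, noise_sd = 0)
  fast0 <- simulate_group_timeseries(cfg0)
  co0 <- render_cohort(cfg0)
  expect_equal(fast0$timeseries[[1]],
               co0$subjects[[1]]$ground_truth$node_timeseries,
               tolerance = 1e-12)
})
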