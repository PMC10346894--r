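# Synthetic multi-subject BOLD cohorts with a planted block correlation
# structure. The generator emulates the acquisition geometry of the study
# design it stands in for: TR = 3 s, 3 mm isotropic voxels, a 300 s resting
# run (100 volumes), an optional block-design encoding run, ~20 subjects,
# 32 spherical ROIs grouped into 8 network blocks.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults encode
#' the emulated acquisition: 24^3 grid of 3 mm voxels, TR = 3 s, 100
#' volumes (300 s rest), 20 subjects, 32 nodes in 8 network blocks with
#' within-block correlation 0.6 and between-block correlation 0.1.
#'
#' @param grid_shape Integer length-3 voxel grid.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Number of time points.
#' @param n_subjects Cohort size.
#' @param n_nodes Number of ROIs.
#' @param n_blocks Number of network blocks (nodes split evenly).
#' @param rho_within,rho_between Planted node correlations inside/between
#'   blocks; the implied matrix must be positive definite.
#' @param subject_tau Between-subject perturbation SD applied to the
#'   Fisher-z transform of the off-diagonal entries.
#' @param noise_sd Voxel-level Gaussian noise SD relative to the unit-SD
#'   latent signal.
#' @param roi_radius_vox ROI radius in voxels (discrete ball).
#' @param task Optional [task_design()] descriptor; `NULL` for rest.
#' @param task_amp Amplitude of the task-regressor modulation added to
#'   node signals when `task` is set.
#' @param seed Integer master RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(24L, 24L, 24L), voxel_size_mm = 3,
                       tr_s = 3, n_volumes = 100L, n_subjects = 20L,
                       n_nodes = 32L, n_blocks = 8L,
                       rho_within = 0.6, rho_between = 0.1,
                       subject_tau = 0.1, noise_sd = 1,
                       roi_radius_vox = 2L, task = NULL, task_amp = 1,
                       seed = 1L) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  stopifnot(all(grid_shape >= 1L), voxel_size_mm > 0, tr_s > 0,
            n_volumes >= 2L, n_subjects >= 1L, n_nodes >= 1L,
            n_blocks >= 1L, n_blocks <= n_nodes,
            abs(rho_within) < 1, abs(rho_between) < 1,
            subject_tau >= 0, noise_sd >= 0, roi_radius_vox >= 0)
  if (!is.null(task) && !inherits(task, "task_design")) {
    stop("`task` must be NULL or a task_design object")
  }
  # fail early if the planted correlation matrix cannot exist
  planted_sigma(n_nodes, n_blocks, rho_within, rho_between)
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 tr_s = tr_s, n_volumes = as.integer(n_volumes),
                 n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes),
                 n_blocks = as.integer(n_blocks),
                 rho_within = rho_within, rho_between = rho_between,
                 subject_tau = subject_tau, noise_sd = noise_sd,
                 roi_radius_vox = as.integer(roi_radius_vox),
                 task = task, task_amp = task_amp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Block-design task descriptor
#'
#' Describes the emulated encoding run: a leading baseline, then
#' `n_trials` stimuli of `stim_s` seconds separated by `gap_s`-second
#' gaps (defaults: 30 s baseline, 24 trials of 6 s + 1 s, i.e. a 288 s
#' encoding block when sampled over 96 volumes at TR = 3 s).
#'
#' @param baseline_s Leading baseline duration (s).
#' @param stim_s Stimulus duration (s).
#' @param gap_s Inter-stimulus gap (s).
#' @param n_trials Number of stimuli.
#' @param run_s Total encoding-run duration in seconds (the trials plus
#'   trailing rest; default 288 s, i.e. 96 volumes at TR = 3 s).
#' @return An object of class `task_design`.
#' @export
task_design <- function(baseline_s = 30, stim_s = 6, gap_s = 1,
                        n_trials = 24L, run_s = 288) {
  stopifnot(baseline_s >= 0, stim_s > 0, gap_s >= 0, n_trials >= 0,
            run_s > 0)
  design_s <- baseline_s + n_trials * (stim_s + gap_s) -
    if (n_trials > 0) gap_s else 0
  if (design_s > run_s + 1e-9) {
    stop(sprintf("task design (%.1f s) does not fit the run (%.1f s)",
                 design_s, run_s))
  }
  structure(list(baseline_s = baseline_s, stim_s = stim_s, gap_s = gap_s,
                 n_trials = as.integer(n_trials), run_s = run_s),
            class = "task_design")
}

#' Planted block correlation matrix
#'
#' Builds the ground-truth node correlation matrix: unit diagonal,
#' `rho_within` inside each of `n_blocks` evenly-split blocks and
#' `rho_between` elsewhere. Positive definiteness is checked.
#'
#' @param n_nodes Number of nodes.
#' @param n_blocks Number of blocks (even split; remainders go to the
#'   leading blocks).
#' @param rho_within,rho_between Correlation values.
#' @return An `n_nodes` x `n_nodes` correlation matrix with a
#'   `block` attribute giving each node's block index.
#' @export
planted_sigma <- function(n_nodes = 32L, n_blocks = 8L,
                          rho_within = 0.6, rho_between = 0.1) {
  stopifnot(n_nodes >= 1L, n_blocks >= 1L, n_blocks <= n_nodes,
            abs(rho_within) < 1, abs(rho_between) < 1)
  sizes <- rep(n_nodes %/% n_blocks, n_blocks)
  extra <- n_nodes %% n_blocks
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block <- rep(seq_len(n_blocks), times = sizes)
  same <- outer(block, block, "==")
  sigma <- ifelse(same, rho_within, rho_between)
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf(paste0("planted correlation matrix is not positive ",
                        "definite (min eigenvalue %.3e); reduce |rho| or ",
                        "change the block structure"), min(ev)))
  }
  attr(sigma, "block") <- block
  sigma
}

#' Sample latent node time series
#'
#' Draws an N x T Gaussian matrix whose population correlation equals
#' `sigma` (via the Cholesky square root applied to iid standard normal
#' innovations), then standardizes each row to zero mean and unit
#' variance.
#'
#' @param sigma Positive-definite correlation matrix.
#' @param n_volumes Number of time points T (>= 2).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return N x T numeric matrix with standardized rows.
#' @export
sample_node_timeseries <- function(sigma, n_volumes, seed = NULL) {
  stopifnot(n_volumes >= 2L)
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("`sigma` must be positive definite"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(sigma)
  z <- matrix(stats::rnorm(n * n_volumes), nrow = n)
  x <- crossprod(ch, z)           # t(ch) %*% z has covariance sigma
  standardize_rows(x)
}

# zero-mean, unit-variance rows (denominator: sample SD, n-1)
standardize_rows <- function(x) {
  x <- x - rowMeans(x)
  s <- sqrt(rowSums(x^2) / (ncol(x) - 1L))
  bad <- s < .Machine$double.eps
  if (any(bad)) {
    stop("zero-variance rows cannot be standardized: ",
         paste(which(bad), collapse = ", "))
  }
  x / s
}

#' Haemodynamic task regressor
#'
#' Builds the stimulus boxcar of a [task_design()] on a fine time grid,
#' convolves it with a canonical double-gamma haemodynamic response
#' (response peak 6 s, undershoot peak 16 s, undershoot ratio 1/6,
#' amplitude-normalized so the HRF peaks at 1), and samples the result at
#' the repetition time.
#'
#' @param task A [task_design()].
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Number of volumes T in the run.
#' @param dt Internal convolution grid step in seconds.
#' @return Numeric vector of length `n_volumes`, normalized to unit peak
#'   (the HRF undershoot leaves small negative dips, so values lie in
#'   approximately `[-0.2, 1]`; an all-baseline design gives all zeros).
#' @export
make_task_regressor <- function(task, tr_s, n_volumes, dt = 0.1) {
  stopifnot(inherits(task, "task_design"), tr_s > 0, n_volumes >= 1L)
  run_s <- n_volumes * tr_s
  design_s <- task$baseline_s +
    task$n_trials * (task$stim_s + task$gap_s)
  if (task$n_trials > 0L) design_s <- design_s - task$gap_s  # no trailing gap
  if (design_s > run_s + 1e-9) {
    stop(sprintf("task design (%.1f s) does not fit the run (%.1f s)",
                 design_s, run_s))
  }
  tt <- seq(0, run_s, by = dt)
  box <- numeric(length(tt))
  if (task$n_trials > 0L) {
    onsets <- task$baseline_s +
      (seq_len(task$n_trials) - 1L) * (task$stim_s + task$gap_s)
    for (on in onsets) box[tt >= on & tt < on + task$stim_s] <- 1
  }
  hrf <- hrf_double_gamma(seq(0, 32, by = dt))
  resp <- stats::convolve(box, rev(hrf), type = "open")[seq_along(tt)] * dt
  idx <- round(seq(0, n_volumes - 1L) * tr_s / dt) + 1L
  out <- resp[idx]
  # unit-peak normalization; the HRF undershoot leaves small negative dips
  if (max(out) > 0) out <- out / max(out)
  out
}

# canonical double-gamma HRF: gamma pdf peaks at (shape-1)/rate; shape 6 and
# 16, rate 1 give peaks at 5 s and 15 s, the usual SPM-style parameters for
# a 6 s response peak / 16 s undershoot counted from onset. Peak scaled to 1.
hrf_double_gamma <- function(t, peak_shape = 6, under_shape = 16,
                             rate = 1, under_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_shape, rate = rate) -
    under_ratio * stats::dgamma(t, shape = under_shape, rate = rate)
  h / max(h)
}

#' Generate a spherical ROI parcellation
#'
#' Places `n_nodes` disjoint discrete balls of radius `roi_radius_vox`
#' voxels on the grid by seeded rejection sampling with minimum
#' center-to-center distance `2*radius + 1`, guaranteeing voxel
#' disjointness. Node names follow [major_network_nodes()] when
#' `n_nodes == 32`, otherwise `node01`, `node02`, ...
#'
#' @param config A [sim_config()].
#' @return A [roi_atlas()].
#' @export
make_parcellation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  r <- config$roi_radius_vox
  g <- config$grid_shape
  n <- config$n_nodes
  if (any(g < 2L * r + 1L)) {
    stop("grid too small: each axis must span at least 2*radius+1 = ",
         2L * r + 1L, " voxels")
  }
  set.seed(derive_seed(config$seed, 101L))
  lo <- rep(r + 1L, 3L)
  hi <- g - r
  min_d2 <- (2L * r + 1L)^2
  centers <- matrix(0L, nrow = 0L, ncol = 3L)
  tries <- 0L
  max_tries <- 20000L * n
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(paste0("grid too small: placed only %d of %d ROIs of ",
                          "radius %d with center spacing >= %d after %d ",
                          "draws"), nrow(centers), n, r,
                   2L * r + 1L, max_tries))
    }
    cand <- c(sample.int(hi[1] - lo[1] + 1L, 1L) + lo[1] - 1L,
              sample.int(hi[2] - lo[2] + 1L, 1L) + lo[2] - 1L,
              sample.int(hi[3] - lo[3] + 1L, 1L) + lo[3] - 1L)
    if (nrow(centers) > 0L) {
      d2 <- rowSums((centers - matrix(cand, nrow(centers), 3L,
                                      byrow = TRUE))^2)
      if (any(d2 < min_d2)) next
    }
    centers <- rbind(centers, cand)
  }
  off <- ball_offsets(r)
  labels <- array(0L, dim = g)
  for (k in seq_len(n)) {
    vox <- off + matrix(centers[k, ], nrow(off), 3L, byrow = TRUE)
    labels[vox] <- k
  }
  names <- if (n == 32L) major_network_nodes() else sprintf("node%02d", seq_len(n))
  atlas <- roi_atlas(labels, names, config$voxel_size_mm)
  atlas$centers <- centers
  atlas
}

# integer offsets of the discrete ball {v : ||v||^2 <= r^2}
ball_offsets <- function(r) {
  s <- seq(-r, r)
  grid <- as.matrix(expand.grid(dx = s, dy = s, dz = s))
  grid[rowSums(grid^2) <= r^2, , drop = FALSE]
}

#' Per-subject correlation matrix
#'
#' Perturbs the Fisher-z transform of the off-diagonal entries of
#' `sigma_true` with iid `N(0, tau^2)` noise, back-transforms, and — if
#' the perturbed matrix is no longer positive definite — projects it to
#' the nearest correlation matrix by eigenvalue clipping at 1e-6 followed
#' by re-normalization to unit diagonal.
#'
#' @param sigma_true Ground-truth correlation matrix.
#' @param tau Perturbation SD on the Fisher-z scale.
#' @param seed Optional integer seed.
#' @return A correlation matrix of the same dimension.
#' @export
subject_sigma <- function(sigma_true, tau, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(sigma_true)
  if (tau == 0 || n < 2L) return(sigma_true)
  z <- atanh(pmin(pmax(sigma_true, -1 + 1e-7), 1 - 1e-7))
  eps <- matrix(0, n, n)
  eps[upper.tri(eps)] <- stats::rnorm(n * (n - 1L) / 2L, sd = tau)
  eps <- eps + t(eps)
  s <- tanh(z + eps)
  diag(s) <- 1
  ev <- eigen(s, symmetric = TRUE)
  if (min(ev$values) <= 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    s <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(s))
    s <- s / tcrossprod(d)
    diag(s) <- 1
  }
  s
}

#' Render one synthetic subject
#'
#' Embeds latent node signals into a 4D volume: every voxel of node k
#' carries node k's latent series (plus `task_amp` times the task
#' regressor when a task is configured), every voxel adds iid Gaussian
#' noise of SD `noise_sd`; background voxels are pure noise.
#'
#' @param config A [sim_config()].
#' @param atlas [roi_atlas()] from [make_parcellation()].
#' @param sigma Subject-level node correlation matrix.
#' @param latent_seed,noise_seed Integer seeds for the latent signal draw
#'   and the voxel noise draw, kept separate so that cohorts can share
#'   latent signals while differing in noise.
#' @return List with `image` ([fmri_image()]) and `node_timeseries`
#'   (N x T matrix of the embedded latent signals).
#' @export
render_subject <- function(config, atlas, sigma, latent_seed, noise_seed) {
  ts <- sample_node_timeseries(sigma, config$n_volumes, seed = latent_seed)
  if (!is.null(config[["task"]])) {
    reg <- make_task_regressor(config[["task"]], config$tr_s, config$n_volumes)
    ts <- ts + config$task_amp * matrix(reg, nrow(ts), length(reg),
                                        byrow = TRUE)
  }
  g <- config$grid_shape
  t_len <- config$n_volumes
  lab <- as.vector(atlas$labels)
  set.seed(as.integer(noise_seed))
  if (config$noise_sd > 0) {
    dat <- matrix(stats::rnorm(prod(g) * t_len, sd = config$noise_sd),
                  nrow = prod(g))
  } else {
    dat <- matrix(0, nrow = prod(g), ncol = t_len)
  }
  inroi <- lab > 0L
  dat[inroi, ] <- dat[inroi, , drop = FALSE] + ts[lab[inroi], , drop = FALSE]
  img <- fmri_image(array(dat, dim = c(g, t_len)),
                    voxel_size_mm = config$voxel_size_mm, tr_s = config$tr_s)
  list(image = img, node_timeseries = ts)
}

#' Render a full synthetic cohort
#'
#' Generates the atlas and, for each subject, a perturbed correlation
#' matrix ([subject_sigma()]) and a rendered 4D image
#' ([render_subject()]); everything is reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `atlas`, `sigma_true` (with `block` attribute), and
#'   `subjects` — a list of per-subject lists `(image, ground_truth)`
#'   where `ground_truth` holds `sigma` and `node_timeseries`.
#' @export
render_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  atlas <- make_parcellation(config)
  sigma_true <- planted_sigma(config$n_nodes, config$n_blocks,
                              config$rho_within, config$rho_between)
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sig_s <- subject_sigma(sigma_true, config$subject_tau,
                           seed = derive_seed(config$seed, 3L * s))
    sub <- render_subject(config, atlas, sig_s,
                          latent_seed = derive_seed(config$seed, 3L * s + 1L),
                          noise_seed = derive_seed(config$seed, 3L * s + 2L))
    subjects[[s]] <- list(image = sub$image,
                          ground_truth = list(
                            sigma = sig_s,
                            node_timeseries = sub$node_timeseries))
  }
  list(atlas = atlas, sigma_true = sigma_true, subjects = subjects)
}

#' Node-level cohort generator (fast path)
#'
#' Generates, for each subject, the N x T node time series that the voxel
#' renderer would embed, with additive node-level noise of SD
#' `noise_sd / sqrt(v)` where `v` is the voxel count of one ROI — the
#' noise level that ROI-mean extraction over `v` voxels would leave.
#' Used for simulation studies (FDR calibration, sensitivity) where
#' rendering full volumes adds cost but no information.
#'
#' @param config A [sim_config()].
#' @return List with `sigma_true` and `timeseries` (list of N x T
#'   matrices, one per subject, rows standardized).
#' @export
simulate_group_timeseries <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sigma_true <- planted_sigma(config$n_nodes, config$n_blocks,
                              config$rho_within, config$rho_between)
  v <- nrow(ball_offsets(config$roi_radius_vox))
  eff_sd <- config$noise_sd / sqrt(v)
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sig_s <- subject_sigma(sigma_true, config$subject_tau,
                           seed = derive_seed(config$seed, 3L * s))
    ts <- sample_node_timeseries(sig_s, config$n_volumes,
                                 seed = derive_seed(config$seed, 3L * s + 1L))
    if (eff_sd > 0) {
      set.seed(derive_seed(config$seed, 3L * s + 2L))
      ts <- ts + matrix(stats::rnorm(length(ts), sd = eff_sd), nrow(ts))
      ts <- standardize_rows(ts)
    }
    out[[s]] <- ts
  }
  list(sigma_true = sigma_true, timeseries = out)
}

#' Write a cohort to disk
#'
#' Writes each subject's 4D image and the atlas as NIfTI-1 (.nii.gz), the
#' ground-truth correlation matrix and node names as TSV, and the
#' configuration as JSON.
#'
#' @param cohort Result of [render_cohort()].
#' @param config The [sim_config()] used.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(cohort$atlas$labels, file.path(dir, "atlas.nii.gz"),
              voxel_size_mm = config$voxel_size_mm)
  for (s in seq_along(cohort$subjects)) {
    img <- cohort$subjects[[s]]$image
    write_nifti(img$data, file.path(dir, sprintf("sub-%02d.nii.gz", s)),
                voxel_size_mm = img$voxel_size_mm, tr_s = img$tr_s)
  }
  sig <- as.data.frame(cohort$sigma_true)
  names(sig) <- cohort$atlas$node_names
  utils::write.table(cbind(node = cohort$atlas$node_names, sig),
                     file.path(dir, "sigma_true.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- config
  cfg$task <- if (is.null(cfg$task)) NULL else unclass(cfg$task)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
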