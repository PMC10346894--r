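# Orchestrated FWHM sweep: for each kernel size and each state (rest,
# task), smoothing -> ROI connectivity -> graph metrics -> PCA/ICA shape
# statistics. Smoothing always precedes connectivity and decomposition.

#' Sweep configuration
#'
#' @param fwhm_list FWHM values in mm (non-negative, unique; sorted).
#' @param states Subset of `c("rest", "task")`.
#' @param q FDR threshold for edge selection.
#' @param n_components Number of PCA/ICA components.
#' @param decompose Run the PCA/ICA stage (TRUE) or skip it.
#' @param positive_only Keep only positive significant edges.
#' @param seed Master seed for all stage randomness.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(fwhm_list = c(0, 2, 4, 6, 8, 10),
                         states = c("rest", "task"), q = 0.05,
                         n_components = 40L, decompose = TRUE,
                         positive_only = FALSE, seed = 1L) {
  if (any(fwhm_list < 0)) stop("FWHM values must be non-negative")
  if (anyDuplicated(fwhm_list)) stop("FWHM values must be unique")
  states <- match.arg(states, c("rest", "task"), several.ok = TRUE)
  structure(list(fwhm_list = sort(fwhm_list), states = states, q = q,
                 n_components = as.integer(n_components),
                 decompose = isTRUE(decompose),
                 positive_only = isTRUE(positive_only),
                 seed = as.integer(seed)),
            class = "sweep_config")
}

# task-run variant of a rest sim_config: 96 volumes (288 s at TR 3) with
# the default block design, unless the config already carries a task
.task_variant <- function(sim) {
  if (!is.null(sim[["task"]])) return(sim)
  td <- task_design()
  nvol <- max(2L, as.integer(ceiling(td$run_s / sim$tr_s)))
  cfg <- unclass(sim)
  cfg$task <- td
  cfg$n_volumes <- nvol
  structure(cfg, class = "sim_config")
}

#' Run the full FWHM sweep
#'
#' For every state, a synthetic cohort is rendered (rest: the config as
#' given without task; task: the block-design variant, 96 volumes at
#' TR = 3 s by default). For every FWHM, each subject's image is smoothed,
#' ROI time series extracted, the group edge test and binarization run,
#' graph metrics computed, and (optionally) group PCA and ICA shape
#' statistics collected.
#'
#' @param config A [sweep_config()].
#' @param data_source A [sim_config()] (synthetic cohort), or a list with
#'   elements `subjects` (list of [fmri_image()]) and `atlas`
#'   ([roi_atlas()]) for pre-loaded data, in which case the same images
#'   are used for every requested state.
#' @return An object of class `sweep_result`: nested list
#'   `results[[state]][[fwhm label]]` with fields `edge_stats`,
#'   `adjacency`, `metrics`, `n_edges`, `pca_stats`, `ica_stats`; plus
#'   `config` and `seed`.
#' @export
run_sweep <- function(config, data_source) {
  stopifnot(inherits(config, "sweep_config"))
  results <- list()
  for (state in config$states) {
    if (inherits(data_source, "sim_config")) {
      sim <- data_source
      sim$seed <- derive_seed(config$seed,
                              1000L + match(state, c("rest", "task")))
      if (state == "rest") sim["task"] <- list(NULL) else sim <- .task_variant(sim)
      cohort <- render_cohort(sim)
      images <- lapply(cohort$subjects, `[[`, "image")
      atlas <- cohort$atlas
    } else {
      images <- data_source$subjects
      atlas <- data_source$atlas
      if (is.null(images) || is.null(atlas)) {
        stop("data_source must be a sim_config or list(subjects=, atlas=)")
      }
    }
    state_res <- list()
    for (fwhm in config$fwhm_list) {
      lab <- format_fwhm(fwhm)
      smoothed <- lapply(images, smooth_fmri, fwhm_mm = fwhm)
      zs <- lapply(smoothed, function(im) {
        connectivity_matrix(extract_roi_timeseries(im, atlas))
      })
      stats <- group_edge_test(zs, node_names = atlas$node_names)
      adj <- binarize(stats, q = config$q,
                      positive_only = config$positive_only)
      # an edgeless graph is a legitimate sweep outcome (e.g. null
      # cohorts): record zero metrics with an undefined path length
      # rather than aborting the sweep
      met <- if (sum(adj$adj) == 0) {
        structure(list(e_glob = 0, e_loc = 0, bc_mean = 0, cc = 0,
                       l_avg = NA_real_, connected = FALSE),
                  class = "metrics_record")
      } else {
        metrics_record(adj)
      }
      rec <- list(edge_stats = stats, adjacency = adj,
                  metrics = met,
                  n_edges = sum(adj$adj) / 2L)
      if (config$decompose) {
        gd <- stack_group_data(smoothed)
        rec$pca_stats <- shape_stats(
          pca_components(gd, n = config$n_components))
        rec$ica_stats <- shape_stats(
          ica_components(gd, n = config$n_components,
                         seed = derive_seed(config$seed, 7L)))
      }
      state_res[[lab]] <- rec
    }
    results[[state]] <- state_res
  }
  structure(list(results = results, config = config, seed = config$seed),
            class = "sweep_result")
}

format_fwhm <- function(fwhm) sprintf("%gmm", fwhm)

#' Metric table across the sweep
#'
#' One row per kernel plus an `Average` row of column means; columns are
#' the five metrics for each state, formatted to 5 decimals when printed.
#'
#' @param result A `sweep_result` with the graph-metric stage complete.
#' @return Data frame with a `kernel` column and
#'   `<state>_<metric>` columns.
#' @export
metrics_table <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  states <- names(result$results)
  kernels <- names(result$results[[1L]])
  metric_names <- c("e_glob", "e_loc", "bc_mean", "cc", "l_avg")
  out <- data.frame(kernel = kernels, stringsAsFactors = FALSE)
  for (st in states) {
    if (!identical(names(result$results[[st]]), kernels)) {
      stop("incomplete sweep: states cover different kernel sets")
    }
    for (mn in metric_names) {
      out[[paste(st, mn, sep = "_")]] <-
        vapply(result$results[[st]],
               function(r) r$metrics[[mn]], numeric(1L))
    }
  }
  avg <- out[1L, , drop = FALSE]
  avg$kernel <- "Average"
  for (cn in names(out)[-1L]) avg[[cn]] <- mean(out[[cn]])
  rbind(out, avg)
}

#' Per-kernel edge report
#'
#' Significant-edge counts and signed edge lists per (state, kernel),
#' with a count trend summary across the sweep.
#'
#' @param result A `sweep_result`.
#' @return List with `counts` (data frame state x kernel x n_edges) and
#'   `edges` (named list of per-cell edge-list data frames).
#' @export
edge_report <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  counts <- data.frame()
  edges <- list()
  for (st in names(result$results)) {
    for (kl in names(result$results[[st]])) {
      rec <- result$results[[st]][[kl]]
      counts <- rbind(counts, data.frame(state = st, kernel = kl,
                                         n_edges = rec$n_edges))
      sig <- rec$edge_stats[rec$edge_stats$q <= result$config$q, ,
                            drop = FALSE]
      edges[[paste(st, kl, sep = ":")]] <-
        sig[, c("node_a", "node_b", "t", "sign")]
    }
  }
  list(counts = counts, edges = edges)
}

#' Write sweep outputs as TSV
#'
#' Writes the metric table, edge counts, per-cell edge lists and shape
#' summaries, plus a JSON manifest with the configuration and seed.
#'
#' @param result A `sweep_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(metrics_table(result),
                     file.path(dir, "metrics_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  rep <- edge_report(result)
  utils::write.table(rep$counts, file.path(dir, "edge_counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(rep$edges)) {
    utils::write.table(rep$edges[[nm]],
                       file.path(dir, paste0("edges_",
                                             gsub(":", "_", nm), ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  shp <- list()
  for (st in names(result$results)) {
    for (kl in names(result$results[[st]])) {
      rec <- result$results[[st]][[kl]]
      for (meth in c("pca_stats", "ica_stats")) {
        if (!is.null(rec[[meth]])) {
          s <- rec[[meth]]$summary
          s$state <- st; s$kernel <- kl
          s$method <- sub("_stats", "", meth)
          shp[[length(shp) + 1L]] <- s
        }
      }
    }
  }
  if (length(shp)) {
    utils::write.table(do.call(rbind, shp),
                       file.path(dir, "shape_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest <- list(config = unclass(result$config), seed = result$seed,
                   r_version = as.character(getRversion()),
                   package_version = "0.1.0")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
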