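# Core S3 containers: 4D BOLD images and ROI label atlases.

#' 4D fMRI image container
#'
#' Light S3 wrapper around a 4D numeric array (x, y, z, time) carrying the
#' voxel geometry and the repetition time.
#'
#' @param data 4D numeric array.
#' @param voxel_size_mm Voxel edge lengths in mm (scalar or length 3).
#' @param tr_s Repetition time in seconds.
#' @return An object of class `fmri_image`.
#' @export
fmri_image <- function(data, voxel_size_mm = 3, tr_s = 3) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4D array (x, y, z, t)")
  voxel_size_mm <- rep_len(as.double(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (tr_s <= 0) stop("`tr_s` must be positive")
  structure(list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s),
            class = "fmri_image")
}

#' @export
print.fmri_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fmri_image> %dx%dx%d voxels x %d volumes, %.3g mm, TR = %.3g s\n",
              d[1], d[2], d[3], d[4], x$voxel_size_mm[1], x$tr_s))
  invisible(x)
}

#' @export
dim.fmri_image <- function(x) dim(x$data)

#' ROI atlas container
#'
#' An integer label volume (0 = background, 1..N = nodes) with an ordered
#' vector of node names.
#'
#' @param labels 3D integer array of labels.
#' @param node_names Character vector of length `max(labels)`.
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @return An object of class `roi_atlas`.
#' @export
roi_atlas <- function(labels, node_names, voxel_size_mm = 3) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  n <- max(labels)
  if (n < 1L) stop("atlas contains no labels")
  if (length(node_names) != n) {
    stop("`node_names` must have length ", n, " (one per label)")
  }
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(seq_len(n), present)
  if (length(missing)) {
    stop("atlas labels with zero voxels: ", paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, node_names = as.character(node_names),
                 voxel_size_mm = rep_len(as.double(voxel_size_mm), 3L)),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<roi_atlas> %d nodes on a %dx%dx%d grid\n",
              length(x$node_names), d[1], d[2], d[3]))
  invisible(x)
}

#' Canonical 32-node major-network parcellation labels
#'
#' Node names for the default 32-region parcellation: high-level cognitive
#' areas of the eight major cortical/cerebellar networks (default mode,
#' somatomotor, visual, salience, dorsal attention, frontoparietal, limbic,
#' cerebellar), four sub-regions each.
#'
#' @return Character vector of length 32.
#' @export
major_network_nodes <- function() {
  c("DMN.MPFC", "DMN.LP.l", "DMN.LP.r", "DMN.PCC",
    "SMN.Lateral.l", "SMN.Lateral.r", "SMN.Superior",
    "VN.Medial", "VN.Occipital", "VN.Lateral.l", "VN.Lateral.r",
    "SN.ACC", "SN.AInsula.l", "SN.AInsula.r", "SN.RPFC.l", "SN.RPFC.r",
    "SN.SMG.l", "SN.SMG.r",
    "DAN.FEF.l", "DAN.FEF.r", "DAN.IPS.l", "DAN.IPS.r",
    "FPN.LPFC.l", "FPN.LPFC.r", "FPN.PPC.l", "FPN.PPC.r",
    "LN.IFG.l", "LN.IFG.r", "LN.pSTG.l", "LN.pSTG.r",
    "C.Anterior", "C.Posterior")
}

# internal: derive a child RNG seed (< 2^31) from a master seed
derive_seed <- function(master, offset) {
  m <- as.double(master) %% 2147483647
  as.integer((m * 48271 + as.double(offset) * 1009 + 1) %% 2147483647)
}
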