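# Gaussian spatial smoothing parameterized by FWHM, as a separable
# convolution on the voxel lattice. Boundary policy: taps falling outside
# the volume are dropped and the remaining taps renormalized to sum 1 —
# the discrete weighted average x_i = sum_k w_i(k) x_k / sum_k w_i(k).

#' Convert FWHM to Gaussian standard deviation
#'
#' `sigma = FWHM / (2 sqrt(2 ln 2))`.
#'
#' @param fwhm_mm Full-width-half-maximum in mm (>= 0).
#' @return Standard deviation in mm.
#' @export
fwhm_to_sigma <- function(fwhm_mm) {
  if (any(fwhm_mm < 0)) stop("`fwhm_mm` must be non-negative")
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

#' Build a separable Gaussian smoothing kernel
#'
#' Discretizes an isotropic Gaussian of the given FWHM on the voxel
#' lattice: per axis, taps at integer offsets `|k| <= ceil(3 sigma_vox)`
#' with weight proportional to `exp(-k^2 / (2 sigma_vox^2))`, normalized
#' to sum 1. `fwhm_mm = 0` yields the identity kernel (single unit tap).
#'
#' @param fwhm_mm Full-width-half-maximum in mm.
#' @param voxel_size_mm Voxel edge length per axis (scalar or length 3).
#' @return An object of class `smoothing_kernel` with fields `fwhm_mm`,
#'   `sigma_mm`, `sigma_vox`, `weights` (list of per-axis tap vectors) and
#'   `truncation_radius_vox`.
#' @export
build_kernel <- function(fwhm_mm, voxel_size_mm = 3) {
  if (length(fwhm_mm) != 1L || fwhm_mm < 0) {
    stop("`fwhm_mm` must be a single non-negative number")
  }
  voxel_size_mm <- rep_len(as.double(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  sigma_mm <- fwhm_to_sigma(fwhm_mm)
  sigma_vox <- sigma_mm / voxel_size_mm
  weights <- vector("list", 3L)
  radius <- integer(3L)
  for (a in 1:3) {
    if (sigma_vox[a] == 0) {
      weights[[a]] <- 1
      radius[a] <- 0L
    } else {
      r <- as.integer(ceiling(3 * sigma_vox[a]))
      k <- seq(-r, r)
      w <- exp(-k^2 / (2 * sigma_vox[a]^2))
      weights[[a]] <- w / sum(w)
      radius[a] <- r
    }
  }
  structure(list(fwhm_mm = fwhm_mm, sigma_mm = sigma_mm,
                 sigma_vox = sigma_vox, weights = weights,
                 truncation_radius_vox = radius),
            class = "smoothing_kernel")
}

# 1D smoothing matrix for an axis of length n: banded Gaussian taps with
# out-of-volume taps dropped and rows renormalized ("renorm"), zero-padded
# ("zero"), or reflected at the edge ("reflect").
axis_smoothing_matrix <- function(n, w, boundary = "renorm") {
  r <- (length(w) - 1L) %/% 2L
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq(-r, r)) {
      j <- i + k
      wt <- w[k + r + 1L]
      if (j >= 1L && j <= n) {
        m[i, j] <- m[i, j] + wt
      } else if (boundary == "reflect") {
        jr <- if (j < 1L) 2L - j else 2L * n - j
        jr <- min(max(jr, 1L), n)
        m[i, jr] <- m[i, jr] + wt
      }
      # "zero": outside taps contribute nothing
    }
    if (boundary == "renorm") m[i, ] <- m[i, ] / sum(m[i, ])
  }
  m
}

#' Smooth a single 3D volume
#'
#' Applies the separable Gaussian kernel along each axis in turn. With the
#' default boundary policy, weights extending past the volume edge are
#' dropped and the remaining weights renormalized to sum 1, so constants
#' are preserved exactly everywhere.
#'
#' @param volume 3D numeric array.
#' @param kernel A [build_kernel()] result.
#' @param boundary One of `"renorm"` (default), `"zero"`, `"reflect"`.
#' @return Smoothed 3D array of the same shape.
#' @export
smooth_volume <- function(volume, kernel, boundary = c("renorm", "zero",
                                                       "reflect")) {
  boundary <- match.arg(boundary)
  if (length(dim(volume)) != 3L) stop("`volume` must be a 3D array")
  if (!inherits(kernel, "smoothing_kernel")) {
    stop("`kernel` must be a smoothing_kernel")
  }
  if (kernel$fwhm_mm == 0) return(volume)
  d <- dim(volume)
  out <- volume
  for (a in 1:3) {
    if (length(kernel$weights[[a]]) == 1L) next
    m <- axis_smoothing_matrix(d[a], kernel$weights[[a]], boundary)
    perm <- c(a, setdiff(1:3, a))
    x <- aperm(out, perm)
    dp <- dim(x)
    x <- m %*% matrix(x, nrow = dp[1L])
    dim(x) <- dp
    out <- aperm(x, order(perm))
  }
  out
}

#' Smooth a 4D fMRI image
#'
#' Builds the kernel from the image's voxel size and applies
#' [smooth_volume()] to every time point independently; metadata is
#' preserved. `fwhm_mm = 0` returns the input data unchanged (the
#' no-smoothing reference).
#'
#' @param image An [fmri_image()].
#' @param fwhm_mm Full-width-half-maximum in mm.
#' @param boundary Boundary policy, see [smooth_volume()].
#' @return A smoothed [fmri_image()].
#' @export
smooth_fmri <- function(image, fwhm_mm, boundary = "renorm") {
  if (!inherits(image, "fmri_image")) stop("`image` must be an fmri_image")
  if (is.null(image$voxel_size_mm) || any(!is.finite(image$voxel_size_mm))) {
    stop("image has no voxel-size metadata")
  }
  if (fwhm_mm == 0) return(image)
  kernel <- build_kernel(fwhm_mm, image$voxel_size_mm)
  d <- dim(image$data)
  # one banded multiply per axis over all volumes at once
  out <- image$data
  for (a in 1:3) {
    if (length(kernel$weights[[a]]) == 1L) next
    m <- axis_smoothing_matrix(d[a], kernel$weights[[a]], boundary)
    perm <- c(a, setdiff(1:4, a))
    x <- aperm(out, perm)
    dp <- dim(x)
    x <- m %*% matrix(x, nrow = dp[1L])
    dim(x) <- dp
    out <- aperm(x, order(perm))
  }
  fmri_image(out, voxel_size_mm = image$voxel_size_mm, tr_s = image$tr_s)
}
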