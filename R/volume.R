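#' SPECT volume container
#'
#' A `spect_volume` is a 3D scalar count grid with isotropic-or-not voxel
#' spacing in mm. Axis convention (fixed throughout the package):
#' axis 1 = x, right-to-left (+x = left, "sin"); axis 2 = y,
#' posterior-to-anterior (+y = anterior); axis 3 = z, inferior-to-superior
#' (+z = superior). The sagittal plane is the y-z plane. World coordinates in
#' mm place the centre of voxel (1,1,1) at the origin.
#'
#' @param data numeric 3D array of voxel intensities (counts).
#' @param spacing numeric length-3, voxel spacing in mm per axis.
#' @return An object of class `spect_volume`.
#' @export
spect_volume <- function(data, spacing = c(2, 2, 2)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be positive and finite")
  }
  structure(list(data = data, spacing = spacing), class = "spect_volume")
}

#' @export
print.spect_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("SPECT volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], total counts %.6g\n",
              min(x$data), max(x$data), sum(x$data)))
  invisible(x)
}

#' @export
dim.spect_volume <- function(x) dim(x$data)

#' Centre of the volume in world mm coordinates
#' @param volume a [spect_volume].
#' @return numeric length-3 mm coordinate of the grid centre.
#' @export
volume_center <- function(volume) {
  (dim(volume$data) - 1) / 2 * volume$spacing
}

## world mm -> continuous 1-based voxel coordinate
mm_to_voxel <- function(volume, pts) {
  sweep(pts, 2L, volume$spacing, "/") + 1
}

voxel_to_mm <- function(volume, idx) {
  sweep(idx - 1, 2L, volume$spacing, "*")
}

#' Trilinear interpolation of a volume at arbitrary mm points
#'
#' Points outside the grid sample as 0 (background).
#'
#' @param volume a [spect_volume].
#' @param pts n x 3 matrix of mm coordinates.
#' @return numeric vector of n interpolated intensities.
#' @export
sample_trilinear <- function(volume, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  d <- dim(volume$data)
  g <- mm_to_voxel(volume, pts)
  i0 <- floor(g)
  f <- g - i0
  ok <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
    i0[, 1] <= d[1] - 1 & i0[, 2] <= d[2] - 1 & i0[, 3] <= d[3] - 1
  # points exactly on the upper face still interpolate
  hi <- g[, 1] == d[1] | g[, 2] == d[2] | g[, 3] == d[3]
  if (any(hi)) {
    at_hi <- which(hi & i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
                     g[, 1] <= d[1] & g[, 2] <= d[2] & g[, 3] <= d[3])
    i0[at_hi, ] <- pmin(i0[at_hi, , drop = FALSE],
                        matrix(d - 1L, length(at_hi), 3L, byrow = TRUE))
    f[at_hi, ] <- g[at_hi, , drop = FALSE] - i0[at_hi, , drop = FALSE]
    ok[at_hi] <- TRUE
  }
  out <- numeric(nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  fx <- f[ok, 1]; fy <- f[ok, 2]; fz <- f[ok, 3]
  d1 <- d[1]; d12 <- d[1] * d[2]
  base <- i0[, 1] + (i0[, 2] - 1) * d1 + (i0[, 3] - 1) * d12
  v <- volume$data
  c000 <- v[base];            c100 <- v[base + 1]
  c010 <- v[base + d1];       c110 <- v[base + d1 + 1]
  c001 <- v[base + d12];      c101 <- v[base + d12 + 1]
  c011 <- v[base + d1 + d12]; c111 <- v[base + d1 + d12 + 1]
  out[ok] <-
    c000 * (1 - fx) * (1 - fy) * (1 - fz) + c100 * fx * (1 - fy) * (1 - fz) +
    c010 * (1 - fx) * fy       * (1 - fz) + c110 * fx * fy       * (1 - fz) +
    c001 * (1 - fx) * (1 - fy) * fz       + c101 * fx * (1 - fy) * fz +
    c011 * (1 - fx) * fy       * fz       + c111 * fx * fy       * fz
  out
}

## separable Gaussian convolution along one array axis; kernel renormalized at
## the borders so a constant field stays constant.
convolve_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  n <- dim(arr)[axis]
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  # dense band matrix n x n
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - r); hi <- min(n, j + r)
    kk <- k[(lo - j + r + 1L):(hi - j + r + 1L)]
    K[j, lo:hi] <- kk / sum(kk)
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- K %*% matrix(a, nrow = n)
  a <- array(m, dim = dp)
  aperm(a, order(perm))
}

#' Gaussian blur of a volume (point-spread-function model)
#'
#' @param volume a [spect_volume].
#' @param fwhm_mm full width at half maximum of the isotropic Gaussian PSF.
#' @return blurred [spect_volume].
#' @export
blur_volume <- function(volume, fwhm_mm) {
  if (fwhm_mm <= 0) return(volume)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- volume$data
  for (ax in 1:3) out <- convolve_axis(out, sigma_mm / volume$spacing[ax], ax)
  spect_volume(out, volume$spacing)
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers around RNifti preserving voxel spacing.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [spect_volume]; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spect_volume(array(as.numeric(img), dim = dim(img)),
               RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param volume a [spect_volume] to write.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
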