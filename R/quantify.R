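#' Project maximal cortical counts onto surface sample points
#'
#' For each mesh sample point, intensities are sampled by trilinear
#' interpolation along the inward normal from the surface down to a depth of
#' `depth_fraction` of the brain length (anterior-posterior extent of the
#' fitted surface; 9% is about 15 mm for a normal-length brain), in steps of
#' at most `step_mm`. The maximum sample is the point's cortical value; on
#' ties the sample nearest the surface wins. Rays leaving the volume are
#' clipped (samples outside read 0) with a warning.
#'
#' @param volume a [spect_volume] (raw or normalized counts).
#' @param mesh a [surface_mesh].
#' @param depth_fraction depth as a fraction of brain length. Default 0.09.
#' @param step_mm maximum sampling step. Default 1.
#' @return numeric vector of per-point values, with attributes
#'   `brain_length_mm` and `depth_mm`.
#' @export
surface_projection <- function(volume, mesh, depth_fraction = 0.09,
                               step_mm = 1) {
  pts <- mesh$points
  brain_length <- diff(range(pts[, 2]))
  depth <- depth_fraction * brain_length
  ns <- max(2L, ceiling(depth / step_mm) + 1L)
  offs <- seq(0, depth, length.out = ns)
  n <- nrow(pts)
  allpts <- pts[rep(seq_len(n), each = ns), ] +
    mesh$inward_normals[rep(seq_len(n), each = ns), ] * rep(offs, times = n)
  fov <- (dim(volume$data) - 1) * volume$spacing
  if (any(allpts < 0) || any(sweep(allpts, 2L, fov) > 0)) {
    warning("surface projection rays exit the volume; samples clipped to 0")
  }
  vals <- matrix(sample_trilinear(volume, allpts), nrow = ns)
  out <- vals[cbind(max.col(t(vals), ties.method = "first"), seq_len(n))]
  attr(out, "brain_length_mm") <- brain_length
  attr(out, "depth_mm") <- depth
  out
}

is_cerebellar <- function(lobe) {
  lobe %in% c("cerebellum_dx", "cerebellum_sin")
}

#' Compute a count-normalization reference value
#'
#' Three reference statistics are supported: `cerebellum_mean` (mean of the
#' cortical surface-projection samples over cerebellar points),
#' `cerebellum_max` (mean of the hottest cerebellar voxel and its 26
#' neighbours) and `cortex_mean` (mean over all non-cerebellar surface
#' samples). The returned scale maps the reference to 100%.
#'
#' @param volume the raw-count [spect_volume].
#' @param mesh a [surface_mesh].
#' @param method one of `"cerebellum_mean"`, `"cerebellum_max"`,
#'   `"cortex_mean"`.
#' @param point_values optional precomputed [surface_projection()] values
#'   (computed if missing).
#' @param depth_fraction,step_mm passed to [surface_projection()] when
#'   needed.
#' @return object of class `normalization_result`: `method`,
#'   `reference_raw`, `scale` (= 100 / reference_raw).
#' @export
compute_reference_value <- function(volume, mesh,
                                    method = c("cerebellum_mean",
                                               "cerebellum_max",
                                               "cortex_mean"),
                                    point_values = NULL,
                                    depth_fraction = 0.09, step_mm = 1) {
  method <- match.arg(method)
  cer <- is_cerebellar(mesh$lobe)
  if (!any(cer)) stop("atlas error: no cerebellar surface points")
  if (is.null(point_values) && method != "cerebellum_max") {
    point_values <- surface_projection(volume, mesh, depth_fraction, step_mm)
  }
  ref <- switch(method,
    cerebellum_mean = mean(point_values[cer]),
    cortex_mean = mean(point_values[!cer]),
    cerebellum_max = cerebellum_max_reference(volume, mesh, depth_fraction,
                                              step_mm)
  )
  if (!is.finite(ref) || ref <= 0) {
    stop("data error: non-positive reference value (", method, ")")
  }
  structure(list(method = method, reference_raw = ref, scale = 100 / ref),
            class = "normalization_result")
}

## hottest voxel among those visited by the cerebellar sampling rays; among
## equally hot voxels the one with the largest 27-voxel neighbourhood mean
## wins (then the lowest linear index) -- reference = that neighbourhood mean
cerebellum_max_reference <- function(volume, mesh, depth_fraction, step_mm) {
  cer <- which(is_cerebellar(mesh$lobe))
  pts <- mesh$points[cer, , drop = FALSE]
  nrm <- mesh$inward_normals[cer, , drop = FALSE]
  brain_length <- diff(range(mesh$points[, 2]))
  depth <- depth_fraction * brain_length
  ns <- max(2L, ceiling(depth / step_mm) + 1L)
  offs <- seq(0, depth, length.out = ns)
  n <- nrow(pts)
  allpts <- pts[rep(seq_len(n), each = ns), ] +
    nrm[rep(seq_len(n), each = ns), ] * rep(offs, times = n)
  idx <- round(sweep(allpts, 2L, volume$spacing, "/")) + 1
  d <- dim(volume$data)
  ok <- idx[, 1] >= 1 & idx[, 2] >= 1 & idx[, 3] >= 1 &
    idx[, 1] <= d[1] & idx[, 2] <= d[2] & idx[, 3] <= d[3]
  idx <- idx[ok, , drop = FALSE]
  lin <- unique(idx[, 1] + (idx[, 2] - 1) * d[1] + (idx[, 3] - 1) * d[1] * d[2])
  vals <- volume$data[lin]
  vmax <- max(vals)
  cand <- lin[vals >= vmax - 1e-12]
  best_mean <- -Inf
  for (v in sort(cand)) {
    k <- (v - 1) %/% (d[1] * d[2]) + 1
    rem <- (v - 1) %% (d[1] * d[2])
    j <- rem %/% d[1] + 1
    i <- rem %% d[1] + 1
    ii <- max(1, i - 1):min(d[1], i + 1)
    jj <- max(1, j - 1):min(d[2], j + 1)
    kk <- max(1, k - 1):min(d[3], k + 1)
    m <- mean(volume$data[ii, jj, kk])
    if (m > best_mean + 1e-12) best_mean <- m
  }
  best_mean
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("Normalization (%s): reference = %.4g counts -> 100%%\n",
              x$method, x$reference_raw))
  invisible(x)
}

#' Normalize a volume to a reference value
#'
#' Multiplies every voxel by `100 / reference_raw`, so the reference
#' statistic of the normalized volume equals 100.
#'
#' @param volume a [spect_volume].
#' @param ref a `normalization_result` from [compute_reference_value()].
#' @return normalized [spect_volume].
#' @export
normalize_volume <- function(volume, ref) {
  if (ref$reference_raw <= 0) stop("data error: non-positive reference")
  spect_volume(volume$data * ref$scale, volume$spacing)
}

#' Regional mean cortical values
#'
#' Arithmetic mean of the sample-point values per lobe label, plus the
#' derived total-cerebellum mean (over the union of left and right
#' cerebellar points).
#'
#' @param point_values per-point values aligned with `mesh`.
#' @param mesh a [surface_mesh].
#' @return named numeric vector: `cerebellum` (total) followed by the 12
#'   atomic regions.
#' @export
regional_means <- function(point_values, mesh) {
  if (length(point_values) != nrow(mesh$points)) {
    stop("point values and mesh are not aligned")
  }
  counts <- table(mesh$lobe)
  if (any(counts == 0)) {
    stop("atlas error: region(s) with zero sample points: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  by_region <- tapply(point_values, mesh$lobe, mean)
  out <- c(cerebellum = mean(point_values[is_cerebellar(mesh$lobe)]),
           by_region[REGIONS])
  names(out) <- c("cerebellum", REGIONS)
  out
}

#' Left-right asymmetry index
#'
#' `100 * (CBF_sin - CBF_dx) / ((CBF_sin + CBF_dx) / 2)`: the left-right
#' difference of paired regional means as a percentage of their mean.
#' Antisymmetric under side swap.
#'
#' @param cbf_sin,cbf_dx mean cortical value of the left (sin) and right
#'   (dx) side of a region; both must be positive.
#' @return asymmetry in percent.
#' @export
asymmetry_index <- function(cbf_sin, cbf_dx) {
  if (any(cbf_sin <= 0) || any(cbf_dx <= 0)) {
    stop("data error: regional means must be positive")
  }
  100 * (cbf_sin - cbf_dx) / ((cbf_sin + cbf_dx) / 2)
}

#' Cortical index
#'
#' Percentage of brain-volume voxels at or above `threshold_pct` of the
#' reference value — high-intensity (cortical) tissue versus low-intensity
#' space such as the ventricles. Expects a normalized volume (reference =
#' 100).
#'
#' @param volume_normalized normalized [spect_volume].
#' @param brain_mask logical array, same dimensions, delimiting the brain.
#' @param threshold_pct high-intensity threshold (default 45, i.e. 45% of
#'   the reference).
#' @return percent in [0, 100].
#' @export
cortical_index <- function(volume_normalized, brain_mask, threshold_pct = 45) {
  if (!any(brain_mask)) stop("segmentation error: empty brain mask")
  100 * mean(volume_normalized$data[brain_mask] >= threshold_pct)
}

#' Fraction of low surface values (delineation quality metric)
#'
#' Percentage of sample points strictly below `threshold_pct` of the
#' reference — surface points reading implausibly low counts indicate a
#' possible false delineation of the brain.
#'
#' @param point_values normalized per-point values (reference = 100).
#' @param threshold_pct threshold percent. Default 45.
#' @return percent of points below threshold.
#' @export
low_value_fraction <- function(point_values, threshold_pct = 45) {
  100 * mean(point_values < threshold_pct)
}

#' Voxel mask enclosed by a fitted landmark surface
#'
#' Rasterizes the interior of a ring-structured landmark surface on the
#' grid of `volume` (used as the brain mask for the cortical index).
#'
#' @param landmarks a [landmark_set] in volume mm coordinates.
#' @param volume a [spect_volume] defining grid and spacing.
#' @return logical array of `dim(volume)`.
#' @export
surface_mask <- function(landmarks, volume) {
  tb <- radius_tables(ring_radius_grid(landmarks))
  d <- dim(volume$data); sp <- volume$spacing
  mask <- array(FALSE, d)
  yy <- rep((seq_len(d[2]) - 1) * sp[2], times = d[3])
  zz <- rep((seq_len(d[3]) - 1) * sp[3], each = d[2])
  for (ix in seq_len(d[1])) {
    s <- slice_inside(tb, (ix - 1) * sp[1], yy, zz)
    if (!is.null(s)) mask[ix, , ] <- s$inside
  }
  mask
}

#' Full regional quantification of a SPECT volume
#'
#' Runs the quantification steps on a delineated volume: builds the 3010-
#' point sample mesh, projects maximal cortical counts, computes all three
#' normalization references, and reports per-region means, left-right
#' asymmetry indices, the cortical index and the low-value quality fraction
#' under each normalization.
#'
#' @param volume the raw-count, oriented [spect_volume].
#' @param landmarks fitted [landmark_set] (e.g. from [fit_active_shape()]).
#' @param atlas a `lobe_atlas` on the landmark correspondence ids.
#' @param target_points sample-point count. Default 3010.
#' @param depth_fraction projection depth fraction. Default 0.09.
#' @param threshold_pct cortical-index / low-value threshold. Default 45.
#' @return object of class `rcbf_report`: `regions` (13 x 3 matrix of means,
#'   one column per normalization), `asymmetry` (paired regions x 3),
#'   `cortical_index`, `low_value_fraction`, `references`,
#'   `point_values_raw`, `lobe` (per-point labels), `brain_length_mm`.
#' @export
quantify_scan <- function(volume, landmarks, atlas, target_points = 3010L,
                          depth_fraction = 0.09, threshold_pct = 45) {
  mesh <- build_surface_mesh(landmarks, atlas, target_points)
  raw <- surface_projection(volume, mesh, depth_fraction)
  methods <- c("cerebellum_mean", "cerebellum_max", "cortex_mean")
  refs <- lapply(methods, function(m) {
    compute_reference_value(volume, mesh, m, point_values = raw,
                            depth_fraction = depth_fraction)
  })
  names(refs) <- methods
  mask <- surface_mask(landmarks, volume)
  regions <- sapply(refs, function(r) regional_means(raw * r$scale, mesh))
  asym <- sapply(refs, function(r) {
    v <- regional_means(raw * r$scale, mesh)
    vapply(PAIRED_REGIONS, function(pair) {
      asymmetry_index(v[pair[2]], v[pair[1]])   # pair = c(dx, sin)
    }, 0)
  })
  ci <- vapply(refs, function(r) {
    cortical_index(normalize_volume(volume, r), mask, threshold_pct)
  }, 0)
  lvf <- vapply(refs, function(r) {
    low_value_fraction(raw * r$scale, threshold_pct)
  }, 0)
  structure(list(regions = regions, asymmetry = asym,
                 cortical_index = ci, low_value_fraction = lvf,
                 references = vapply(refs, `[[`, 0, "reference_raw"),
                 point_values_raw = as.numeric(raw),
                 lobe = mesh$lobe,
                 brain_length_mm = attr(raw, "brain_length_mm"),
                 depth_mm = attr(raw, "depth_mm"),
                 threshold_pct = threshold_pct,
                 n_points = nrow(mesh$points)),
            class = "rcbf_report")
}

#' @export
print.rcbf_report <- function(x, digits = 1, ...) {
  cat(sprintf("rCBF quantification: %d sample points, brain length %.1f mm (projection depth %.1f mm)\n",
              x$n_points, x$brain_length_mm, x$depth_mm))
  cat("\nRegional means (% of reference):\n")
  print(round(x$regions, digits))
  cat("\nAsymmetry indices (sin vs dx, %):\n")
  print(round(x$asymmetry, digits + 1))
  cat(sprintf("\nCortical index (%%>= %g%%):\n", x$threshold_pct))
  print(round(x$cortical_index, digits))
  cat(sprintf("Low-value fraction (%%< %g%%):\n", x$threshold_pct))
  print(round(x$low_value_fraction, digits + 1))
  invisible(x)
}
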