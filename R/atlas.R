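swap_side <- function(labels) {
  out <- as.character(labels)
  sin_ <- grepl("_sin$", out)
  dx_ <- grepl("_dx$", out)
  out[sin_] <- sub("_sin$", "_dx", out[sin_])
  out[dx_] <- sub("_dx$", "_sin", out[dx_])
  out
}

#' Assign landmarks to brain lobes using single-lobe phantoms
#'
#' Each landmark receives the region whose single-lobe phantom shows the
#' highest intensity at the landmark position (ties break toward the lower
#' region index; a landmark reading zero in every phantom is an error). The
#' left-hemisphere labelling is then mirrored to the right hemisphere across
#' the mid-sagittal plane, giving a symmetrical atlas; median regions
#' (frontal med, occipital) straddle the midline and are left unpaired.
#'
#' @param landmarks a [landmark_set] (or a [shape_model], whose mean shape
#'   is used) in the same coordinate frame as the phantoms.
#' @param lobe_phantoms named list of [spect_volume]s, names from
#'   [brain_regions()], e.g. from [generate_lobe_phantom()].
#' @param mirror mirror left labels onto the right hemisphere (default
#'   `TRUE`).
#' @param override optional named character vector: names = landmark
#'   indices, values = region labels, applied after mirroring (machine-
#'   readable replacement for manual atlas adjustment).
#' @return object of class `lobe_atlas` with `labels` (factor per landmark)
#'   and the mirror correspondence map.
#' @export
assign_lobes <- function(landmarks, lobe_phantoms, mirror = TRUE,
                         override = NULL) {
  if (inherits(landmarks, "shape_model")) landmarks <- landmarks$mean_shape
  L <- nrow(landmarks)
  regs <- names(lobe_phantoms)
  if (is.null(regs) || !all(regs %in% REGIONS)) {
    stop("lobe_phantoms must be named with brain_regions() labels")
  }
  # probe at the landmark and slightly inward along its normal: surface
  # points on a hard shell edge can interpolate to 0 exactly at the boundary
  nrm <- vertex_normals(landmarks)
  offs <- c(0, 2, 4, 6)
  V <- matrix(0, L, length(REGIONS))
  for (r in regs) {
    vmax <- numeric(L)
    for (o in offs) {
      vmax <- pmax(vmax, sample_trilinear(lobe_phantoms[[r]],
                                          unclass(landmarks) - o * nrm))
    }
    V[, match(r, REGIONS)] <- vmax
  }
  none <- rowSums(V) <= 0
  if (any(none)) {
    stop("unassigned-landmark error: zero intensity in all phantoms at indices ",
         paste(utils::head(which(none), 20), collapse = ", "))
  }
  lab <- REGIONS[apply(V, 1L, which.max)]   # first max = lowest region index
  map <- mirror_correspondence(landmarks)
  if (mirror) {
    cx <- mean(unclass(landmarks)[, 1])
    right <- which(unclass(landmarks)[, 1] < cx)   # dx side (+x = sin)
    lab[right] <- swap_side(lab[map[right]])
  }
  if (!is.null(override)) {
    idx <- as.integer(names(override))
    if (anyNA(idx) || any(idx < 1 | idx > L) ||
        !all(override %in% REGIONS)) {
      stop("invalid atlas override")
    }
    lab[idx] <- override
  }
  structure(list(labels = factor(lab, levels = REGIONS),
                 mirror_map = map, n_landmarks = L),
            class = "lobe_atlas")
}

#' @export
print.lobe_atlas <- function(x, ...) {
  cat(sprintf("Lobe atlas: %d landmarks\n", x$n_landmarks))
  print(table(x$labels))
  invisible(x)
}

#' Build a normal-value database from quantified reports
#'
#' Per-sample-point and per-region sample means and standard deviations
#' (n-1 denominator) of the normalized cortical values of a group of normal
#' subjects, computed separately for each of the three normalization
#' references, plus the cortical-index mean/SD.
#'
#' @param reports list of `rcbf_report` objects (>= 2) with identical mesh
#'   configuration.
#' @return object of class `normal_db`.
#' @export
build_normal_database <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 subjects")
  n_pts <- vapply(reports, `[[`, 0L, "n_points")
  if (length(unique(n_pts)) != 1L) {
    stop("configuration error: inconsistent sample-point counts")
  }
  methods <- colnames(reports[[1]]$regions)
  point_norm <- lapply(methods, function(m) {
    vapply(reports, function(r) {
      r$point_values_raw * 100 / r$references[[m]]
    }, numeric(n_pts[1]))
  })
  names(point_norm) <- methods
  point_mean <- sapply(point_norm, rowMeans)
  point_sd <- sapply(point_norm, function(M) apply(M, 1L, stats::sd))
  region_vals <- lapply(methods, function(m) {
    vapply(reports, function(r) r$regions[, m], reports[[1]]$regions[, 1])
  })
  names(region_vals) <- methods
  region_mean <- sapply(region_vals, rowMeans)
  region_sd <- sapply(region_vals, function(M) apply(M, 1L, stats::sd))
  ci <- vapply(reports, `[[`, numeric(length(methods)), "cortical_index")
  structure(list(point_mean = point_mean, point_sd = point_sd,
                 region_mean = region_mean, region_sd = region_sd,
                 cortical_index_mean = rowMeans(ci),
                 cortical_index_sd = apply(ci, 1L, stats::sd),
                 n_subjects = length(reports),
                 n_points = n_pts[1],
                 methods = methods,
                 lobe = reports[[1]]$lobe),
            class = "normal_db")
}

#' @export
print.normal_db <- function(x, ...) {
  cat(sprintf("Normal-value database: %d subjects, %d sample points\n",
              x$n_subjects, x$n_points))
  cat("\nRegional means +/- SD (cerebellum_mean normalization):\n")
  m <- x$region_mean[, 1]; s <- x$region_sd[, 1]
  for (r in rownames(x$region_mean)) {
    cat(sprintf("  %-18s %6.1f +/- %.1f\n", r, m[r], s[r]))
  }
  cat(sprintf("\nCortical index: %.1f +/- %.1f\n",
              x$cortical_index_mean[1], x$cortical_index_sd[1]))
  invisible(x)
}

#' Z-scores of a patient report against the normal database
#'
#' `z = (value - mean) / SD` per sample point and per region, for each
#' normalization, plus the cortical-index z. Points with SD = 0 are
#' returned as `NA` and flagged.
#'
#' @param report an `rcbf_report`.
#' @param db a `normal_db` with matching configuration.
#' @return object of class `rcbf_zscores`: `point_z`, `region_z`,
#'   `cortical_index_z`, `undefined` (logical matrix of SD = 0 points).
#' @export
zscore_patient <- function(report, db) {
  if (report$n_points != db$n_points) {
    stop("configuration error: sample-point counts differ")
  }
  point_z <- sapply(db$methods, function(m) {
    v <- report$point_values_raw * 100 / report$references[[m]]
    z <- (v - db$point_mean[, m]) / db$point_sd[, m]
    z[db$point_sd[, m] == 0] <- NA_real_
    z
  })
  region_z <- sapply(db$methods, function(m) {
    z <- (report$regions[, m] - db$region_mean[, m]) / db$region_sd[, m]
    z[db$region_sd[, m] == 0] <- NA_real_
    z
  })
  ci_z <- (report$cortical_index - db$cortical_index_mean) /
    ifelse(db$cortical_index_sd == 0, NA_real_, db$cortical_index_sd)
  structure(list(point_z = point_z, region_z = region_z,
                 cortical_index_z = ci_z,
                 undefined = db$point_sd == 0,
                 lobe = db$lobe),
            class = "rcbf_zscores")
}

#' @export
print.rcbf_zscores <- function(x, ...) {
  cat("Regional z-scores:\n")
  print(round(x$region_z, 2))
  cat("Cortical index z:", paste(sprintf("%.2f", x$cortical_index_z),
                                 collapse = ", "), "\n")
  invisible(x)
}
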