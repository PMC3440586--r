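#' Interpolate a dense surface sample mesh from fitted landmarks
#'
#' Subdivides the landmark triangulation barycentrically (vertices, then
#' face centroids, then edge midpoints, each in a fixed canonical order) and
#' keeps exactly `target_points` sample points — 3010 by default, from the
#' 546 fitted landmarks. Each sample point carries an inward unit normal and
#' the lobe label of its nearest source landmark.
#'
#' @param landmarks fitted [landmark_set] in volume mm coordinates.
#' @param atlas a `lobe_atlas` (or factor of [brain_regions()] levels, one
#'   per landmark) defined on the landmark correspondence ids.
#' @param target_points number of sample points. Default 3010.
#' @return object of class `surface_mesh`: `points` (N x 3), `inward_normals`,
#'   `lobe`, `source_landmark`.
#' @export
build_surface_mesh <- function(landmarks, atlas, target_points = 3010L) {
  L <- nrow(landmarks)
  lab <- as_region_factor(atlas, L)
  P <- unclass(landmarks)
  faces <- landmark_triangulation(landmarks)
  vn <- vertex_normals(landmarks, faces)     # outward
  # candidate order: vertices, face centroids, edge midpoints
  cent <- (P[faces[, 1], ] + P[faces[, 2], ] + P[faces[, 3], ]) / 3
  cent_n <- vn[faces[, 1], ] + vn[faces[, 2], ] + vn[faces[, 3], ]
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  mid <- (P[edges[, 1], ] + P[edges[, 2], ]) / 2
  mid_n <- vn[edges[, 1], ] + vn[edges[, 2], ]
  n_total <- L + nrow(cent) + nrow(mid)
  if (target_points > n_total) {
    stop("geometry error: subdivision yields only ", n_total,
         " candidate points (< ", target_points, ")")
  }
  pts <- rbind(P, cent, mid)[seq_len(target_points), , drop = FALSE]
  nrm <- rbind(vn, cent_n, mid_n)[seq_len(target_points), , drop = FALSE]
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
  # provenance: nearest defining source landmark
  parents <- c(seq_len(L),
               apply_nearest(faces, P, cent),
               apply_nearest(edges, P, mid))[seq_len(target_points)]
  structure(list(points = pts, inward_normals = -nrm,
                 lobe = lab[parents], source_landmark = parents,
                 n_landmarks = L),
            class = "surface_mesh")
}

## for each row of `groups` (vertex index tuples) pick the member nearest to
## the corresponding row of `at`; ties -> lowest landmark index
apply_nearest <- function(groups, P, at) {
  n <- nrow(groups)
  out <- integer(n)
  d2 <- matrix(Inf, n, ncol(groups))
  for (c in seq_len(ncol(groups))) {
    d2[, c] <- rowSums((P[groups[, c], , drop = FALSE] - at)^2)
  }
  pick <- apply(d2, 1L, which.min)
  idx <- groups[cbind(seq_len(n), pick)]
  # resolve exact ties toward the lowest index
  for (i in seq_len(n)) {
    tied <- groups[i, d2[i, ] <= d2[i, pick[i]] + 1e-12]
    idx[i] <- min(tied)
  }
  idx
}

as_region_factor <- function(atlas, L) {
  lab <- if (inherits(atlas, "lobe_atlas")) atlas$labels else atlas
  lab <- factor(as.character(lab), levels = REGIONS)
  if (length(lab) != L) {
    stop("atlas labels length ", length(lab), " does not match landmark count ", L)
  }
  if (anyNA(lab)) stop("atlas contains labels outside brain_regions()")
  lab
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d sample points from %d landmarks\n",
              nrow(x$points), x$n_landmarks))
  print(table(x$lobe))
  invisible(x)
}
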