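#' Ordered landmark set on the brain surface
#'
#' An L x 3 matrix of mm coordinates whose row order defines point
#' correspondence across subjects (permuting rows is a different shape).
#' Landmarks are organized as closed rings in sagittal planes: `n_rings`
#' rings of `n_per` points each, ring-major order. The default configuration
#' is 26 rings x 21 points = 546 landmarks.
#'
#' @param points L x 3 numeric matrix (mm).
#' @param n_rings,n_per ring layout; `n_rings * n_per` must equal `nrow(points)`.
#' @return object of class `landmark_set` (a matrix with layout attributes).
#' @export
landmark_set <- function(points, n_rings = 26L, n_per = 21L) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("landmarks must be an L x 3 matrix")
  if (any(!is.finite(points))) stop("landmark coordinates must be finite")
  if (nrow(points) != n_rings * n_per) {
    stop("landmark count ", nrow(points), " does not match ring layout ",
         n_rings, " x ", n_per, call. = FALSE)
  }
  structure(points, n_rings = as.integer(n_rings), n_per = as.integer(n_per),
            class = c("landmark_set", "matrix", "array"))
}

ring_layout <- function(landmarks) {
  list(n_rings = attr(landmarks, "n_rings"), n_per = attr(landmarks, "n_per"))
}

## keep layout attributes through subset-free matrix ops
restore_landmarks <- function(points, template) {
  landmark_set(points, attr(template, "n_rings"), attr(template, "n_per"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set: %d points (%d sagittal rings x %d)\n",
              nrow(x), attr(x, "n_rings"), attr(x, "n_per")))
  invisible(x)
}

#' Triangulation of the ring-structured landmark surface
#'
#' Triangles connect consecutive sagittal rings; the two lateral end rings
#' are left open (small caps at the extreme slices are not triangulated).
#'
#' @param landmarks a [landmark_set] (only its layout is used).
#' @return integer F x 3 matrix of vertex indices with consistent winding.
#' @export
landmark_triangulation <- function(landmarks) {
  m <- attr(landmarks, "n_per"); R <- attr(landmarks, "n_rings")
  idx <- function(j, k) (j - 1L) * m + ((k - 1L) %% m) + 1L
  faces <- matrix(0L, 2L * m * (R - 1L), 3L)
  row <- 1L
  for (j in seq_len(R - 1L)) {
    k <- seq_len(m)
    a <- idx(j, k); b <- idx(j, k + 1L); cc <- idx(j + 1L, k); d <- idx(j + 1L, k + 1L)
    faces[row:(row + m - 1L), ] <- cbind(a, b, cc)
    faces[(row + m):(row + 2L * m - 1L), ] <- cbind(b, d, cc)
    row <- row + 2L * m
  }
  faces
}

## area-weighted vertex normals, oriented outward (away from the centroid).
## The lateral end rings are closed with extrapolated virtual pole vertices
## (dropped afterwards) so cap vertices get unbiased normals.
vertex_normals <- function(landmarks, faces = landmark_triangulation(landmarks)) {
  P <- unclass(landmarks)
  m <- attr(landmarks, "n_per"); R <- attr(landmarks, "n_rings")
  if (!is.null(m) && !is.null(R) && R >= 3L) {
    u <- cos(pi * (c(1, 2) - 0.5) / R)
    alpha <- (1 - u[1]) / (u[1] - u[2])
    ring_mean <- function(j) colMeans(P[((j - 1) * m + 1):(j * m), , drop = FALSE])
    pole1 <- ring_mean(1) + alpha * (ring_mean(1) - ring_mean(2))
    poleR <- ring_mean(R) + alpha * (ring_mean(R) - ring_mean(R - 1))
    L <- nrow(P)
    P <- rbind(P, pole1, poleR)
    k <- seq_len(m)
    kn <- c(k[-1], k[1])
    fan1 <- cbind(L + 1L, kn, k)
    fanR <- cbind(L + 2L, (R - 1L) * m + k, (R - 1L) * m + kn)
    faces <- rbind(faces, fan1, fanR)
  }
  e1 <- P[faces[, 2], ] - P[faces[, 1], ]
  e2 <- P[faces[, 3], ] - P[faces[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fn <- fn / pmax(sqrt(rowSums(fn^2)), 1e-12)
  # angle-weighted accumulation (robust to anisotropic triangle sizes)
  corner_angle <- function(a, b, c) {
    u <- P[b, ] - P[a, ]; v <- P[c, ] - P[a, ]
    cosv <- rowSums(u * v) /
      pmax(sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)), 1e-12)
    acos(pmin(pmax(cosv, -1), 1))
  }
  ang <- cbind(corner_angle(faces[, 1], faces[, 2], faces[, 3]),
               corner_angle(faces[, 2], faces[, 3], faces[, 1]),
               corner_angle(faces[, 3], faces[, 1], faces[, 2]))
  N <- matrix(0, nrow(P), 3L)
  for (c in 1:3) {
    for (ax in 1:3) {
      N[, ax] <- N[, ax] + tabulate2(faces[, c], ang[, c] * fn[, ax], nrow(P))
    }
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N <- N / len
  # global outward orientation
  ctr <- colMeans(P)
  outward <- rowSums(N * sweep(P, 2L, ctr))
  if (mean(sign(outward)) < 0) N <- -N
  # any residual inward-pointing vertex (degenerate local geometry): flip
  flip <- rowSums(N * sweep(P, 2L, ctr)) < 0
  N[flip, ] <- -N[flip, , drop = FALSE]
  N[seq_len(nrow(landmarks)), , drop = FALSE]
}

## sum `values` into bins given by `index` (fast accumulate)
tabulate2 <- function(index, values, nbins) {
  out <- numeric(nbins)
  s <- rowsum(values, index)  # rows ordered by sorted unique index
  out[as.integer(rownames(s))] <- s
  out
}

#' Left-right mirror correspondence of a landmark set
#'
#' Reflects points across the mid-sagittal plane (x = centroid x) and maps
#' each landmark to the nearest reflected landmark, establishing the
#' cross-hemisphere correspondence used for atlas mirroring.
#'
#' @param landmarks a [landmark_set].
#' @return integer vector `map` with `map[i]` = index of the mirror partner.
#' @export
mirror_correspondence <- function(landmarks) {
  P <- unclass(landmarks)
  cx <- mean(P[, 1])
  Q <- P
  Q[, 1] <- 2 * cx - Q[, 1]
  # nearest neighbour, small L so brute force is fine
  map <- integer(nrow(P))
  for (i in seq_len(nrow(P))) {
    d2 <- (P[, 1] - Q[i, 1])^2 + (P[, 2] - Q[i, 2])^2 + (P[, 3] - Q[i, 3])^2
    map[i] <- which.min(d2)
  }
  map
}
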