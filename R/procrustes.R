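## Procrustes machinery for landmark shapes.
## All shapes are L x 3 matrices with corresponding rows.

centroid_size <- function(P) {
  Pc <- sweep(P, 2L, colMeans(P))
  sqrt(sum(Pc^2))
}

## Weighted similarity Procrustes: find s, R, t minimizing
## sum_i w_i || s * R %*% x_i + t - y_i ||^2  (R proper rotation).
## Returns list(s, R, t) with points transformed as  s * X %*% t(R) + t.
procrustes_pair <- function(X, Y, w = NULL, scale = TRUE) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  W <- w / sum(w)
  xb <- colSums(X * W); yb <- colSums(Y * W)
  Xc <- sweep(X, 2L, xb); Yc <- sweep(Y, 2L, yb)
  M <- t(Xc) %*% (Yc * W)          # sum_i w_i x_i y_i^T  (3x3)
  sv <- svd(M)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, dsign))
  R <- sv$v %*% D %*% t(sv$u)
  denom <- sum(W * rowSums(Xc^2))
  if (denom <= .Machine$double.eps) stop("degenerate shape: zero spread")
  s <- if (scale) sum(sv$d * c(1, 1, dsign)) / denom else 1
  t_vec <- yb - s * as.numeric(R %*% xb)
  list(s = s, R = R, t = t_vec)
}

apply_similarity <- function(P, sim) {
  sweep(sim$s * P %*% t(sim$R), 2L, sim$t, "+")
}

invert_similarity <- function(sim) {
  Rinv <- t(sim$R)
  list(s = 1 / sim$s, R = Rinv, t = -as.numeric(Rinv %*% sim$t) / sim$s)
}

check_shape_rank <- function(P) {
  Pc <- sweep(P, 2L, colMeans(P))
  if (sum(svd(Pc)$d > 1e-9 * max(1, max(abs(Pc)))) < 2L) {
    stop("degenerate shape: landmarks are collinear (rank < 2)")
  }
}

#' Generalized Procrustes alignment of corresponding landmark sets
#'
#' Aligns two or more landmark configurations to a common coordinate frame by
#' similarity transformation (translation + rotation, and isotropic scale
#' removal when `scale = TRUE`). Each shape is centred at the origin and
#' scaled to unit centroid size, then iteratively rotated to the evolving
#' mean shape until the configurations stop moving. The final frame is
#' anchored to the orientation of the first shape for reproducibility.
#'
#' Set `scale = FALSE` to retain size as a shape feature (overall brain size
#' then becomes a mode of the shape model).
#'
#' @param shapes list of [landmark_set] objects (>= 2) with identical layout.
#' @param scale remove isotropic scale during alignment? Default `TRUE`.
#' @param tol convergence: maximum point displacement between sweeps, in the
#'   aligned (unit-size) frame. Default `1e-6`.
#' @param max_iter maximum alignment sweeps.
#' @return list with `aligned` (list of aligned [landmark_set]s), `mean`
#'   (mean shape matrix) and `frame` (alignment frame record: scale
#'   convention, mean centroid size in mm, iterations, convergence flag).
#' @export
align_shapes <- function(shapes, scale = TRUE, tol = 1e-6, max_iter = 100L) {
  if (length(shapes) < 2L) stop("need at least 2 shapes")
  L <- nrow(shapes[[1]])
  lay <- ring_layout(shapes[[1]])
  for (s in shapes) {
    if (nrow(s) != L) stop("correspondence error: mismatched landmark counts")
    check_shape_rank(unclass(s))
  }
  sizes <- vapply(shapes, function(s) centroid_size(unclass(s)), 0)
  A <- lapply(shapes, function(s) {
    P <- sweep(unclass(s), 2L, colMeans(unclass(s)))
    if (scale) P / centroid_size(P) else P
  })
  mean_shape <- A[[1]]
  iters <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    moved <- 0
    for (i in seq_along(A)) {
      fit <- procrustes_pair(A[[i]], mean_shape, scale = FALSE)
      newP <- apply_similarity(A[[i]], fit)
      moved <- max(moved, max(abs(newP - A[[i]])))
      A[[i]] <- newP
    }
    new_mean <- Reduce(`+`, A) / length(A)
    new_mean <- sweep(new_mean, 2L, colMeans(new_mean))
    if (scale) new_mean <- new_mean / centroid_size(new_mean)
    mean_shape <- new_mean
    if (moved < tol) { converged <- TRUE; break }
  }
  # anchor frame: rotate everything so the mean is in the first shape's
  # original orientation
  first <- sweep(unclass(shapes[[1]]), 2L, colMeans(unclass(shapes[[1]])))
  if (scale) first <- first / centroid_size(first)
  anchor <- procrustes_pair(mean_shape, first, scale = FALSE)
  anchor$t <- c(0, 0, 0)
  mean_shape <- apply_similarity(mean_shape, anchor)
  A <- lapply(A, apply_similarity, sim = anchor)
  aligned <- lapply(A, landmark_set, n_rings = lay$n_rings, n_per = lay$n_per)
  frame <- list(scale_removed = scale, mean_size_mm = mean(sizes),
                tol = tol, iterations = iters, converged = converged,
                rotation_convention = "proper rotation via SVD (Kabsch)")
  list(aligned = aligned,
       mean = landmark_set(mean_shape, lay$n_rings, lay$n_per),
       frame = frame)
}
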