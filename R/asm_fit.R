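#' Configuration for the active-shape surface fit
#'
#' @param profile_length_mm search extent along each landmark normal
#'   (candidates span +/- this distance). Default 15.
#' @param profile_step_mm sampling step along the profile. Default 1.
#' @param boundary_low,boundary_high intensity interval for boundary
#'   candidates, as fractions of the robust (99.5th percentile) maximum.
#'   Defaults 0.25 and 0.85.
#' @param min_edge_drop minimum outward intensity fall (per mm, as a
#'   fraction of the robust maximum) for a candidate edge. Default 0.02.
#' @param max_iterations maximum fit iterations. Default 50.
#' @param convergence_mm stop when the mean landmark movement per iteration
#'   falls below this. Default 0.1.
#' @param clamp_m mode coefficients are clamped to `clamp_m * sqrt(lambda_k)`.
#'   Default 3.
#' @param threshold_frac brain-mask threshold fraction (initialization).
#' @param unmoved_weight projection weight for landmarks whose profile search
#'   found no qualifying edge. Default 0.1.
#' @param pose_iterations similarity-only iterations (all mode coefficients
#'   held at 0) before the modes are released — a coarse-to-fine schedule
#'   that settles the pose before shape detail. Default 10.
#' @param outlier_gate proposals moving more than `outlier_gate` robust SDs
#'   (MAD-based) of the current offsets are treated as unmoved. Default 3.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(profile_length_mm = 15, profile_step_mm = 1,
                       boundary_low = 0.25, boundary_high = 0.85,
                       min_edge_drop = 0.02, max_iterations = 50L,
                       convergence_mm = 0.1, clamp_m = 3,
                       threshold_frac = 0.30, unmoved_weight = 0.1,
                       pose_iterations = 10L, outlier_gate = 3) {
  if (profile_length_mm <= 0) stop("profile_length_mm must be positive")
  if (boundary_low < 0 || boundary_low >= boundary_high || boundary_high > 1) {
    stop("require 0 <= boundary_low < boundary_high <= 1")
  }
  structure(list(profile_length_mm = profile_length_mm,
                 profile_step_mm = profile_step_mm,
                 boundary_low = boundary_low, boundary_high = boundary_high,
                 min_edge_drop = min_edge_drop,
                 max_iterations = as.integer(max_iterations),
                 convergence_mm = convergence_mm, clamp_m = clamp_m,
                 threshold_frac = threshold_frac,
                 unmoved_weight = unmoved_weight,
                 pose_iterations = as.integer(pose_iterations),
                 outlier_gate = outlier_gate),
            class = "fit_config")
}

robust_max <- function(volume) {
  stats::quantile(volume$data, 0.995, names = FALSE)
}

#' Initial similarity placement of the shape model in a volume
#'
#' Matches the model mean shape to the above-threshold voxel cloud: the
#' translation takes the mean-shape centroid to the mask centroid and the
#' scale matches the per-axis bounding-box extents (averaged over axes);
#' rotation is the identity (the volume is assumed oriented). Deterministic.
#'
#' @param model a [shape_model].
#' @param volume an oriented [spect_volume].
#' @param threshold_frac mask threshold fraction of the robust maximum.
#' @return a [shape_params] with `b = 0`.
#' @export
initialize_fit <- function(model, volume, threshold_frac = 0.30) {
  thr <- threshold_frac * robust_max(volume)
  idx <- which(volume$data > thr, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("segmentation error: empty brain mask")
  pts <- sweep(idx - 1, 2L, volume$spacing, "*")
  ctr <- colMeans(pts)
  ext_vol <- apply(pts, 2L, function(v) diff(range(v)))
  M <- unclass(model$mean_shape)
  Mc <- sweep(M, 2L, colMeans(M))
  ext_mod <- apply(Mc, 2L, function(v) diff(range(v)))
  s <- mean(ext_vol / ext_mod)
  shape_params(numeric(length(model$eigenvalues)), scale = s,
               rotation = diag(3), translation = ctr)
}

#' Boundary search along landmark normals
#'
#' For each landmark, intensities are sampled along its outward normal over
#' +/- `profile_length_mm`. Candidate boundary positions must lie inside the
#' configured intensity interval and show a sufficiently steep outward
#' intensity fall; the candidate with the steepest fall wins (ties:
#' nearest to the current position), with sub-step refinement by quadratic
#' interpolation of the gradient. Landmarks with no qualifying candidate
#' keep their position with confidence 0.
#'
#' @param volume a [spect_volume].
#' @param landmarks current [landmark_set].
#' @param normals L x 3 outward unit normals (default: mesh vertex normals).
#' @param config a [fit_config].
#' @return list with `points` (L x 3 suggested positions), `confidence`
#'   (0/1 per landmark) and `offset_mm` (signed movement along the normal).
#' @export
profile_search <- function(volume, landmarks, normals = NULL,
                           config = fit_config()) {
  if (is.null(normals)) normals <- vertex_normals(landmarks)
  P <- unclass(landmarks)
  L <- nrow(P)
  s_off <- seq(-config$profile_length_mm, config$profile_length_mm,
               by = config$profile_step_mm)
  ns <- length(s_off)
  # sample all profiles at once: (L*ns) x 3 points
  pts <- P[rep(seq_len(L), each = ns), ] +
    normals[rep(seq_len(L), each = ns), ] * rep(s_off, times = L)
  vals <- matrix(sample_trilinear(volume, pts), nrow = ns)  # ns x L
  rmax <- robust_max(volume)
  lo <- config$boundary_low * rmax
  hi <- config$boundary_high * rmax
  # central-difference outward gradient (one-sided at the ends)
  step <- config$profile_step_mm
  grad <- (vals[c(2:ns, ns), , drop = FALSE] -
             vals[c(1, 1:(ns - 1)), , drop = FALSE]) / (2 * step)
  grad[1, ] <- grad[1, ] * 2      # one-sided at the ends
  grad[ns, ] <- grad[ns, ] * 2
  drop_req <- -config$min_edge_drop * rmax
  qualify <- vals >= lo & vals <= hi & grad <= drop_req
  conf <- numeric(L)
  offs <- numeric(L)
  new_pts <- P
  cand_any <- colSums(qualify) > 0
  for (i in which(cand_any)) {
    q <- which(qualify[, i])
    g <- grad[q, i]
    best <- q[order(g, abs(s_off[q]))][1]
    s_best <- s_off[best]
    # sub-step refinement: parabola through gradient at best-1, best, best+1
    if (best > 1 && best < ns) {
      g0 <- grad[best - 1, i]; g1 <- grad[best, i]; g2 <- grad[best + 1, i]
      denom <- g0 - 2 * g1 + g2
      if (abs(denom) > 1e-12) {
        delta <- 0.5 * (g0 - g2) / denom
        if (abs(delta) <= 1) s_best <- s_best + delta * step
      }
    }
    offs[i] <- s_best
    conf[i] <- 1
    new_pts[i, ] <- P[i, ] + s_best * normals[i, ]
  }
  list(points = new_pts, confidence = conf, offset_mm = offs)
}

## one fit iteration: profile search with outlier gating, then a robustly
## reweighted model projection (Cauchy weights on the projection residuals)
asm_step <- function(model, volume, landmarks, config, clamp_m) {
  normals <- vertex_normals(landmarks)
  prop <- profile_search(volume, landmarks, normals, config)
  conf <- prop$confidence
  pts <- prop$points
  moved <- conf > 0
  if (any(moved)) {
    md <- stats::median(abs(prop$offset_mm[moved]))
    gate <- max(config$outlier_gate * 1.4826 * md, 2 * config$profile_step_mm)
    bad <- moved & abs(prop$offset_mm) > gate
    pts[bad, ] <- unclass(landmarks)[bad, , drop = FALSE]
    moved <- moved & !bad
  }
  w <- ifelse(moved, 1, config$unmoved_weight)
  target <- restore_landmarks(pts, landmarks)
  params <- project_shape(model, target, weights = w, clamp_m = clamp_m)
  fitted <- synthesize_shape(model, params)
  r <- sqrt(rowSums((pts - unclass(fitted))^2))
  cc <- max(3 * stats::median(r), 1e-6)
  params <- project_shape(model, target, weights = w / (1 + (r / cc)^2),
                          clamp_m = clamp_m)
  params
}

#' Fit the shape model to a volume (active-shape algorithm)
#'
#' Alternates [profile_search()] (find better boundary positions along the
#' surface normals) and [project_shape()] (constrain the suggested points to
#' a plausible shape: confidence-weighted similarity + clamped mode
#' coefficients) until the mean landmark movement drops below
#' `config$convergence_mm` or `config$max_iterations` is reached. The first
#' `config$pose_iterations` iterations fit the similarity pose only (modes
#' held at zero); proposals moving implausibly far (offset outliers, e.g.
#' at the cerebellar-occipital crease) are gated out, and the model
#' projection is robustly reweighted against residual outliers.
#' Non-convergence is reported in the result, never as an error.
#'
#' @param model a [shape_model].
#' @param volume an oriented [spect_volume].
#' @param config a [fit_config].
#' @param init optional starting [shape_params] (default [initialize_fit()]).
#' @return object of class `asm_fit`: fitted `landmarks` (volume mm frame),
#'   `params`, `iterations`, `converged`, `mean_final_movement_mm` and the
#'   per-iteration `movement_mm` history.
#' @export
fit_active_shape <- function(model, volume, config = fit_config(),
                             init = NULL) {
  if (is.null(init)) init <- initialize_fit(model, volume, config$threshold_frac)
  params <- init
  landmarks <- synthesize_shape(model, params)
  history <- numeric(0)
  converged <- FALSE
  iters <- 0L
  if (config$max_iterations > 0L) {
    n_pose <- min(config$pose_iterations, config$max_iterations)
    for (it in seq_len(config$max_iterations)) {
      iters <- it
      clamp_now <- if (it <= n_pose) 0 else config$clamp_m
      params <- asm_step(model, volume, landmarks, config, clamp_now)
      new_landmarks <- synthesize_shape(model, params)
      move <- mean(sqrt(rowSums((unclass(new_landmarks) -
                                   unclass(landmarks))^2)))
      history <- c(history, move)
      landmarks <- new_landmarks
      if (it > n_pose && move <= config$convergence_mm) {
        converged <- TRUE
        break
      }
    }
  }
  structure(list(landmarks = landmarks, params = params,
                 iterations = iters, converged = converged,
                 mean_final_movement_mm = if (length(history)) history[length(history)] else NA_real_,
                 movement_mm = history, config = config),
            class = "asm_fit")
}

#' @export
print.asm_fit <- function(x, ...) {
  cat(sprintf("Active-shape fit: %d landmarks, %d iterations, %s\n",
              nrow(x$landmarks), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  if (is.finite(x$mean_final_movement_mm)) {
    cat(sprintf("  final mean movement: %.4g mm\n", x$mean_final_movement_mm))
  }
  cat("  b =", paste(sprintf("%.4g", x$params$b), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.asm_fit <- function(object, ...) {
  cat(sprintf("Active-shape fit summary\n  iterations: %d (converged: %s)\n",
              object$iterations, object$converged))
  cat(sprintf("  scale: %.4g, translation: [%s] mm\n", object$params$scale,
              paste(sprintf("%.1f", object$params$translation), collapse = ", ")))
  cat("  movement history (mm):",
      paste(sprintf("%.3g", object$movement_mm), collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.asm_fit <- function(x, ...) {
  if (!length(x$movement_mm)) return(invisible(x))
  graphics::plot(seq_along(x$movement_mm), x$movement_mm, type = "b",
                 xlab = "iteration", ylab = "mean movement (mm)",
                 main = "Active-shape fit convergence", ...)
  graphics::abline(h = x$config$convergence_mm, lty = 2)
  invisible(x)
}
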