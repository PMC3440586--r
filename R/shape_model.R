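#' Point-distribution shape model of the brain surface
#'
#' Builds the statistical shape model at the core of the active-shape
#' segmentation: training landmark sets are brought into a common frame by
#' generalized Procrustes alignment, and the principal components of the
#' aligned landmark covariance become the shape "modes". The retained modes
#' (default 5) span the plausible brain-shape variation; any training shape
#' is approximated by the mean shape plus a small mode-coefficient vector b.
#'
#' Landmark vectors are flattened point-major (x1,y1,z1,x2,...); the sample
#' covariance uses the n-1 denominator; each mode's sign is fixed so its
#' largest-magnitude component is positive.
#'
#' @param shapes list of [landmark_set] objects (training examinations).
#' @param n_modes number of principal modes to retain; must be at most
#'   `length(shapes) - 1`. Default 5.
#' @param align run [align_shapes] first (set `FALSE` only if the shapes are
#'   already aligned). Default `TRUE`.
#' @param scale remove isotropic size during alignment. Default `TRUE`.
#' @return object of class `shape_model`: mean shape, mode matrix (3L x K),
#'   eigenvalues, training count and the alignment frame.
#' @seealso [synthesize_shape()], [project_shape()], [fit_active_shape()]
#' @export
shape_model <- function(shapes, n_modes = 5L, align = TRUE, scale = TRUE) {
  n <- length(shapes)
  if (n < 2L) stop("need at least 2 training shapes")
  if (n_modes > n - 1L) {
    stop("rank error: n_modes (", n_modes, ") exceeds n_training - 1 (",
         n - 1L, ")")
  }
  lay <- ring_layout(shapes[[1]])
  if (align) {
    al <- align_shapes(shapes, scale = scale)
    aligned <- al$aligned; frame <- al$frame
  } else {
    aligned <- shapes
    frame <- list(scale_removed = NA, mean_size_mm = mean(
      vapply(shapes, function(s) centroid_size(unclass(s)), 0)),
      note = "shapes supplied pre-aligned")
  }
  L <- nrow(aligned[[1]])
  X <- t(vapply(aligned, function(s) as.numeric(t(unclass(s))), numeric(3L * L)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = min(n - 1L, 3L * L))
  evals <- sv$d^2 / (n - 1L)
  evals <- evals[seq_len(min(n - 1L, 3L * L))]
  modes <- sv$v
  # deterministic sign: largest-magnitude component of each mode positive
  for (k in seq_len(ncol(modes))) {
    j <- which.max(abs(modes[, k]))
    if (modes[j, k] < 0) modes[, k] <- -modes[, k]
  }
  keep <- seq_len(n_modes)
  structure(list(
    mean_shape = landmark_set(matrix(mu, ncol = 3L, byrow = TRUE),
                              lay$n_rings, lay$n_per),
    modes = modes[, keep, drop = FALSE],
    eigenvalues = evals[keep],
    all_eigenvalues = evals,
    full_modes = modes,
    n_training = n,
    n_landmarks = L,
    frame = frame
  ), class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("Point-distribution shape model: %d landmarks, %d modes, %d training shapes\n",
              x$n_landmarks, length(x$eigenvalues), x$n_training))
  tot <- sum(x$all_eigenvalues)
  pct <- if (tot > 0) 100 * sum(x$eigenvalues) / tot else 100
  cat(sprintf("  retained variance: %.1f%%  (scale %s during alignment)\n",
              pct, if (isTRUE(x$frame$scale_removed)) "removed" else "kept"))
  invisible(x)
}

#' @export
summary.shape_model <- function(object, ...) {
  ev <- object$all_eigenvalues
  k <- length(object$eigenvalues)
  tab <- data.frame(
    mode = seq_along(ev),
    eigenvalue = ev,
    sd = sqrt(pmax(ev, 0)),
    pct_var = if (sum(ev) > 0) 100 * ev / sum(ev) else rep(0, length(ev)),
    retained = seq_along(ev) <= k
  )
  structure(list(table = tab, n_training = object$n_training,
                 n_landmarks = object$n_landmarks, frame = object$frame),
            class = "summary.shape_model")
}

#' @export
print.summary.shape_model <- function(x, ...) {
  cat(sprintf("Shape model: %d landmarks, %d training shapes\n",
              x$n_landmarks, x$n_training))
  print(utils::head(x$table, 10), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.shape_model <- function(object, ...) object$eigenvalues

#' @export
plot.shape_model <- function(x, ...) {
  ev <- x$all_eigenvalues
  graphics::plot(seq_along(ev), ev, type = "b", xlab = "mode",
                 ylab = "eigenvalue", main = "Shape-mode variance", ...)
  graphics::abline(v = length(x$eigenvalues) + 0.5, lty = 2)
  invisible(x)
}

#' Shape parameters (mode coefficients + similarity pose)
#'
#' @param b numeric mode coefficients (length K).
#' @param scale isotropic scale s > 0.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 mm translation.
#' @return object of class `shape_params`.
#' @export
shape_params <- function(b, scale = 1, rotation = diag(3), translation = c(0, 0, 0)) {
  if (scale <= 0) stop("scale must be positive")
  structure(list(b = as.numeric(b), scale = scale, rotation = rotation,
                 translation = as.numeric(translation)),
            class = "shape_params")
}

#' @export
print.shape_params <- function(x, ...) {
  cat("Shape parameters: b = [", paste(sprintf("%.4g", x$b), collapse = ", "),
      sprintf("], scale %.4g\n", x$scale))
  if (!is.null(x$residual)) cat(sprintf("  fit residual (RMS): %.4g\n", x$residual))
  invisible(x)
}

#' Synthesize a landmark shape from model parameters
#'
#' Returns `similarity(mean + P b)`: the mean shape displaced along the
#' retained modes by coefficients `b`, then scaled / rotated / translated.
#'
#' @param model a [shape_model].
#' @param params a [shape_params]; `params$b` must have length K.
#' @return a [landmark_set] in the target (e.g. volume mm) frame.
#' @export
synthesize_shape <- function(model, params = shape_params(numeric(length(model$eigenvalues)))) {
  K <- ncol(model$modes)
  if (length(params$b) != K) {
    stop("parameter error: b has length ", length(params$b), ", model has ",
         K, " modes")
  }
  v <- as.numeric(t(unclass(model$mean_shape))) + as.numeric(model$modes %*% params$b)
  P <- matrix(v, ncol = 3L, byrow = TRUE)
  P <- apply_similarity(P, list(s = params$scale, R = params$rotation,
                                t = params$translation))
  restore_landmarks(P, model$mean_shape)
}

#' @export
predict.shape_model <- function(object, params = NULL, ...) {
  if (is.null(params)) params <- shape_params(numeric(length(object$eigenvalues)))
  synthesize_shape(object, params)
}

#' @export
simulate.shape_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(object$eigenvalues)
  lapply(seq_len(nsim), function(i) {
    b <- stats::rnorm(K, sd = sqrt(pmax(object$eigenvalues, 0)))
    synthesize_shape(object, shape_params(b))
  })
}

#' Project a landmark set onto the shape model
#'
#' Finds the similarity pose and mode coefficients that best approximate a
#' given landmark configuration: minimizes the (optionally weighted) sum of
#' squared distances between `similarity(mean + P b)` and the target points,
#' by alternating a weighted similarity Procrustes fit and a weighted
#' least-squares solve for b.
#'
#' @param model a [shape_model].
#' @param landmarks target [landmark_set] (same landmark count as the model).
#' @param weights optional per-point weights (default all 1).
#' @param clamp_m clamp each |b_k| to `clamp_m * sqrt(lambda_k)`; `Inf`
#'   disables clamping (default).
#' @param fit_pose estimate the similarity pose (default); `FALSE` keeps the
#'   identity pose and solves for `b` only (targets already in the model
#'   frame).
#' @param max_iter,tol alternation control.
#' @return a [shape_params] with an added `residual` field (weighted RMS
#'   point distance in the target frame).
#' @export
project_shape <- function(model, landmarks, weights = NULL, clamp_m = Inf,
                          fit_pose = TRUE, max_iter = 100L, tol = 1e-10) {
  L <- model$n_landmarks
  if (nrow(landmarks) != L) {
    stop("correspondence error: landmark count ", nrow(landmarks),
         " does not match model (", L, ")")
  }
  Y <- unclass(landmarks)
  check_shape_rank(Y)
  if (is.null(weights)) weights <- rep(1, L)
  w3 <- rep(weights, each = 3L)
  mu <- as.numeric(t(unclass(model$mean_shape)))
  P <- model$modes
  K <- ncol(P)
  b <- numeric(K)
  lim <- clamp_m * sqrt(pmax(model$eigenvalues, 0))
  sim <- list(s = 1, R = diag(3), t = c(0, 0, 0))
  for (it in seq_len(max_iter)) {
    if (fit_pose) {
      Xb <- matrix(mu + as.numeric(P %*% b), ncol = 3L, byrow = TRUE)
      sim <- procrustes_pair(Xb, Y, w = weights, scale = TRUE)
    }
    # map target into model frame and solve for b (weighted LS)
    Z <- apply_similarity(Y, invert_similarity(sim))
    r <- as.numeric(t(Z)) - mu
    A <- crossprod(P, w3 * P)
    b_new <- as.numeric(solve(A, crossprod(P, w3 * r)))
    if (is.finite(clamp_m)) b_new <- pmin(pmax(b_new, -lim), lim)
    delta <- max(abs(b_new - b))
    b <- b_new
    if (delta < tol) break
  }
  Xb <- matrix(mu + as.numeric(P %*% b), ncol = 3L, byrow = TRUE)
  fitted <- apply_similarity(Xb, sim)
  res <- sqrt(sum(weights * rowSums((fitted - Y)^2)) / sum(weights))
  out <- shape_params(b, scale = sim$s, rotation = sim$R, translation = sim$t)
  out$residual <- res
  out
}

#' Save / load a shape model as JSON
#'
#' The entire model (mean shape, modes, eigenvalues, alignment frame,
#' landmark layout) is stored in one JSON document; loading validates mode
#' orthonormality and eigenvalue ordering.
#'
#' @param model a [shape_model].
#' @param path file path.
#' @export
save_shape_model <- function(model, path) {
  obj <- list(
    format = "asmbrain shape model v1",
    n_landmarks = model$n_landmarks,
    n_rings = attr(model$mean_shape, "n_rings"),
    n_per = attr(model$mean_shape, "n_per"),
    n_training = model$n_training,
    mean_shape = unclass(model$mean_shape),
    modes = model$modes,
    eigenvalues = model$eigenvalues,
    all_eigenvalues = model$all_eigenvalues,
    full_modes = model$full_modes,
    frame = model$frame
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_shape_model
#' @export
load_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(
    mean_shape = landmark_set(obj$mean_shape, obj$n_rings, obj$n_per),
    modes = matrix(obj$modes, ncol = length(obj$eigenvalues)),
    eigenvalues = as.numeric(obj$eigenvalues),
    all_eigenvalues = as.numeric(obj$all_eigenvalues),
    full_modes = matrix(obj$full_modes, nrow = 3L * obj$n_landmarks),
    n_training = obj$n_training,
    n_landmarks = obj$n_landmarks,
    frame = obj$frame
  ), class = "shape_model")
  validate_shape_model(model)
  model
}

validate_shape_model <- function(model) {
  G <- crossprod(model$modes)
  if (max(abs(G - diag(ncol(model$modes)))) > 1e-8) {
    stop("invalid model: modes are not orthonormal")
  }
  ev <- model$eigenvalues
  if (any(ev < -1e-12) || is.unsorted(rev(ev), strictly = FALSE)) {
    if (any(diff(ev) > 1e-12) || any(ev < -1e-12)) {
      stop("invalid model: eigenvalues not non-negative / non-increasing")
    }
  }
  invisible(model)
}
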