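# shared fixtures, built once per test run and cached

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fix)) assign(name, build(), envir = .fix)
  get(name, envir = .fix)
}

# 64^3 / 4 mm noiseless test spec (same anatomy as the 128^3 default)
test_spec <- function(...) {
  phantom_spec(grid_size = 64, voxel_mm = 4, counts_scale = 0, ...)
}

test_phantom <- function() {
  fixture("phantom64", function() generate_brain_phantom(test_spec()))
}

test_lobe_phantoms <- function() {
  fixture("lobes64", function() {
    sp <- test_spec()
    lapply(stats::setNames(brain_regions(), brain_regions()),
           function(r) generate_lobe_phantom(sp, r))
  })
}

test_atlas <- function() {
  fixture("atlas64", function() {
    assign_lobes(test_phantom()$truth$surface_landmarks, test_lobe_phantoms())
  })
}

# uniform phantom: every brain compartment at 100 except the ventricle
uniform_spec <- function(...) {
  test_spec(uptake = c(cortex = 100, white_matter = 100, ventricle = 0,
                       cerebellum = 100, background = 0), ...)
}

test_uniform_phantom <- function() {
  fixture("uniform64", function() generate_brain_phantom(uniform_spec()))
}

test_model <- function() {
  fixture("model64", function() {
    shape_model(generate_training_set(29, test_spec(), seed = 11), n_modes = 5)
  })
}

# small ellipsoid landmark sets for shape-model unit tests (L = 6 x 7 = 42)
ellipsoid_landmarks <- function(axes = c(30, 40, 25), center = c(0, 0, 0),
                                jitter = 0, n_rings = 6L, n_per = 7L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- cos(pi * (seq_len(n_rings) - 0.5) / n_rings)
  phi <- 2 * pi * (seq_len(n_per) - 0.5) / n_per
  P <- matrix(0, n_rings * n_per, 3L)
  i <- 1L
  for (j in seq_len(n_rings)) {
    s <- sqrt(1 - u[j]^2)
    for (k in seq_len(n_per)) {
      P[i, ] <- center + axes * c(u[j], s * cos(phi[k]), s * sin(phi[k]))
      i <- i + 1L
    }
  }
  if (jitter > 0) P <- P + matrix(stats::rnorm(length(P), sd = jitter),
                                  ncol = 3L)
  landmark_set(P, n_rings, n_per)
}

rotmat_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# closed-form two-shape similarity Procrustes oracle (centre, unit-scale,
# optimal rotation by SVD); independent of the package implementation
oracle_pair_align <- function(X, Y) {
  cX <- sweep(X, 2, colMeans(X)); cY <- sweep(Y, 2, colMeans(Y))
  cX <- cX / sqrt(sum(cX^2)); cY <- cY / sqrt(sum(cY^2))
  sv <- svd(t(cY) %*% cX)
  R <- sv$u %*% diag(c(1, 1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
  list(X = cX, Y_aligned = cY %*% R)
}

full_procrustes_dist <- function(X, Y) {
  o <- oracle_pair_align(X, Y)
  sqrt(sum((o$X - o$Y_aligned)^2))
}
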