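# Point-distribution model: alignment, PCA, synthesis, projection

test_that("alignment is invariant to similarity transforms of the inputs", {
  base <- ellipsoid_landmarks()
  transforms <- list(
    translate = function(P) sweep(P, 2, c(10, 0, 0), "+"),
    rotate30z = function(P) P %*% t(rotmat_z(30)),
    scale_shift = function(P) sweep(1.3 * P, 2, c(-5, 8, 2), "+")
  )
  for (nm in names(transforms)) {
    moved <- restore_landmarks(transforms[[nm]](unclass(base)), base)
    al <- align_shapes(list(base, moved))
    expect_lt(max(abs(unclass(al$aligned[[1]]) - unclass(al$aligned[[2]]))),
              1e-6)
  }
})

test_that("generalized Procrustes converges monotonically and matches the two-shape SVD oracle", {
  shapes <- lapply(1:5, function(i) {
    ellipsoid_landmarks(jitter = 1.5, seed = 100 + i)
  })
  # mean Procrustes distance to the evolving mean is non-increasing in sweeps
  dist_k <- vapply(1:5, function(k) {
    al <- align_shapes(shapes, max_iter = k)
    M <- Reduce(`+`, lapply(al$aligned, unclass)) / length(shapes)
    mean(vapply(al$aligned, function(s) sqrt(sum((unclass(s) - M)^2)), 0))
  }, 0)
  expect_true(all(diff(dist_k) <= 1e-9))
  # n = 2: GPA mean equals the closed-form pair alignment mean (up to rotation)
  al2 <- align_shapes(shapes[1:2])
  o <- oracle_pair_align(unclass(shapes[[1]]), unclass(shapes[[2]]))
  # the SVD oracle itself agrees with vegan's symmetric Procrustes residual
  vg <- vegan::procrustes(unclass(shapes[[1]]), unclass(shapes[[2]]),
                          symmetric = TRUE, scale = FALSE)
  expect_equal(sum((o$X - o$Y_aligned)^2), vg$ss, tolerance = 1e-8)
  oracle_mean <- (o$X + o$Y_aligned) / 2
  oracle_mean <- oracle_mean / sqrt(sum(oracle_mean^2))
  expect_lt(full_procrustes_dist(unclass(al2$mean), oracle_mean), 1e-6)
  # aligned shapes are centred at the origin
  for (s in al2$aligned) expect_lt(max(abs(colMeans(unclass(s)))), 1e-8)
})

test_that("alignment rejects mismatched and degenerate inputs", {
  a <- ellipsoid_landmarks()
  b <- ellipsoid_landmarks(n_rings = 7L, n_per = 7L)
  expect_error(align_shapes(list(a, b)), "correspondence")
  line <- landmark_set(cbind(seq_len(42), 0, 0), 6L, 7L)
  expect_error(align_shapes(list(line, line)), "degenerate|collinear")
})

test_that("identical training shapes give a zero-variance model equal to the input", {
  sh <- ellipsoid_landmarks()
  mod <- shape_model(rep(list(sh), 10), n_modes = 2)
  expect_true(all(abs(mod$all_eigenvalues) < 1e-12))
  expect_lt(full_procrustes_dist(unclass(mod$mean_shape), unclass(sh)), 1e-6)
})

test_that("eigenvalues and modes match the dense covariance eigendecomposition (oracle)", {
  set.seed(7)
  L <- 14L  # 42 coordinates <= 50 landmarks
  shapes <- lapply(1:8, function(i) ellipsoid_landmarks(jitter = 2, seed = i,
                                                        n_rings = 2L,
                                                        n_per = 7L))
  mod <- shape_model(shapes, n_modes = 5, align = FALSE)
  X <- t(vapply(shapes, function(s) as.numeric(t(unclass(s))), numeric(42)))
  C <- stats::cov(X)
  eg <- eigen(C, symmetric = TRUE)
  k <- length(mod$all_eigenvalues)
  expect_lt(max(abs(mod$all_eigenvalues - eg$values[seq_len(k)])), 1e-8)
  for (j in 1:5) {
    # up to sign
    expect_lt(min(max(abs(mod$modes[, j] - eg$vectors[, j])),
                  max(abs(mod$modes[, j] + eg$vectors[, j]))), 1e-6)
  }
  # variance conservation
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(abs(sum(mod$all_eigenvalues) - sum(Xc^2) / (nrow(X) - 1)), 1e-8)
  # orthonormality
  G <- crossprod(mod$full_modes)
  expect_lt(max(abs(G - diag(ncol(mod$full_modes)))), 1e-8)
})

test_that("a two-generator population yields exactly two modes spanning the generator plane", {
  set.seed(21)
  base <- ellipsoid_landmarks(n_rings = 3L, n_per = 7L)
  mu <- as.numeric(t(unclass(base)))
  u <- rnorm(length(mu)); u <- u / sqrt(sum(u^2))
  v <- rnorm(length(mu)); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
  shapes <- lapply(1:12, function(i) {
    x <- mu + rnorm(1, sd = 2) * u + rnorm(1, sd = 1) * v
    restore_landmarks(matrix(x, ncol = 3, byrow = TRUE), base)
  })
  mod <- shape_model(shapes, n_modes = 2, align = FALSE)
  expect_true(all(mod$all_eigenvalues[-(1:2)] < 1e-12))
  # principal angles between span(modes) and span(u, v)
  Q1 <- qr.Q(qr(mod$modes))
  Q2 <- qr.Q(qr(cbind(u, v)))
  sv <- svd(t(Q1) %*% Q2)$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-6)
})

test_that("the training configuration retains five modes and caps at n - 1", {
  mod <- test_model()
  expect_identical(ncol(mod$modes), 5L)
  expect_identical(mod$n_training, 29L)
  expect_true(all(diff(mod$eigenvalues) <= 1e-12))
  sh <- generate_training_set(4, test_spec(), seed = 2)
  expect_error(shape_model(sh, n_modes = 4), "rank")
})

test_that("synthesis: b = 0 returns the mean; a unit mode step moves by sqrt(lambda)", {
  mod <- test_model()
  K <- length(mod$eigenvalues)
  s0 <- synthesize_shape(mod, shape_params(numeric(K)))
  expect_equal(unclass(s0), unclass(mod$mean_shape), tolerance = 1e-12)
  b <- c(sqrt(mod$eigenvalues[1]), numeric(K - 1))
  s1 <- synthesize_shape(mod, shape_params(b))
  d2 <- sum((unclass(s1) - unclass(mod$mean_shape))^2)
  expect_lt(abs(d2 - mod$eigenvalues[1]), 1e-6)
  expect_error(synthesize_shape(mod, shape_params(numeric(K + 1))),
               "parameter error")
})

test_that("project_shape recovers synthesis parameters (round trip)", {
  mod <- test_model()
  lamsd <- sqrt(mod$eigenvalues)
  cases <- list(
    list(b = numeric(5), s = 1, R = diag(3), t = c(0, 0, 0)),
    list(b = c(1.2, -0.8, 0.5, 0.3, -1.5) * lamsd, s = 250,
         R = rotmat_z(20), t = c(10, -30, 5)),
    list(b = c(-2, 1, 0, 2, 1) * lamsd, s = 1800, R = rotmat_z(-35),
         t = c(100, 120, 90))
  )
  for (cs in cases) {
    target <- synthesize_shape(mod, shape_params(cs$b, cs$s, cs$R, cs$t))
    rec <- project_shape(mod, target)
    expect_lt(max(abs(rec$b - cs$b)), 1e-6)
    expect_lt(abs(rec$scale - cs$s) / cs$s, 1e-6)
    expect_lt(max(abs(rec$translation - cs$t)), 1e-5)
    expect_lt(rec$residual, 1e-6)
  }
  # mean shape: b = 0, residual 0
  rec0 <- project_shape(mod, mod$mean_shape)
  expect_lt(max(abs(rec0$b)), 1e-8)
  expect_lt(rec0$residual, 1e-8)
})

test_that("projection residual equals the PCA truncation error (oracle)", {
  set.seed(31)
  base <- ellipsoid_landmarks(n_rings = 4L, n_per = 8L)
  shapes <- lapply(1:10, function(i) {
    P <- unclass(base) + matrix(rnorm(length(base), sd = 1.2), ncol = 3)
    restore_landmarks(P, base)
  })
  mod_full <- shape_model(shapes, n_modes = 9, align = FALSE)
  mod_k <- shape_model(shapes, n_modes = 5, align = FALSE)
  X <- t(vapply(shapes, function(s) as.numeric(t(unclass(s))), numeric(96)))
  Xc <- sweep(X, 2, colMeans(X))
  V <- mod_k$modes
  for (i in c(1, 4, 10)) {
    # full-rank modes reconstruct the training shape exactly
    rec <- project_shape(mod_full, shapes[[i]])
    expect_lt(rec$residual, 1e-6)
    # K = 5, pose fixed: residual sum of squares equals the oracle PCA
    # truncation error exactly; with the similarity refit it can only shrink
    oracle_ss <- sum((Xc[i, ] - V %*% crossprod(V, Xc[i, ]))^2)
    aligned_target <- restore_landmarks(
      matrix(colMeans(X) + Xc[i, ], ncol = 3, byrow = TRUE), base)
    rec_fix <- project_shape(mod_k, aligned_target, fit_pose = FALSE)
    expect_lt(abs(rec_fix$residual^2 * nrow(base) - oracle_ss), 1e-8)
    rec_k <- project_shape(mod_k, shapes[[i]])
    expect_lte(rec_k$residual^2 * nrow(base), oracle_ss + 1e-9)
  }
})

test_that("mode-coefficient clamping bounds |b_k| by m * sqrt(lambda_k)", {
  mod <- test_model()
  target <- synthesize_shape(mod, shape_params(c(8, -8, 8, -8, 8) *
                                                 sqrt(mod$eigenvalues)))
  rec <- project_shape(mod, target, clamp_m = 3)
  expect_true(all(abs(rec$b) <= 3 * sqrt(mod$eigenvalues) + 1e-12))
})

test_that("shape model serialization round-trips and validates on load", {
  mod <- test_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_shape_model(mod, path)
  mod2 <- load_shape_model(path)
  expect_equal(unclass(mod2$mean_shape), unclass(mod$mean_shape),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(mod2$modes, mod$modes, tolerance = 1e-12)
  expect_equal(mod2$eigenvalues, mod$eigenvalues, tolerance = 1e-12)
  # corrupt the modes -> loader refuses
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$modes[1] <- obj$modes[1] + 1
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  expect_error(load_shape_model(path), "orthonormal")
})

test_that("simulate() draws plausible shapes and methods print", {
  mod <- test_model()
  sims <- simulate(mod, nsim = 3, seed = 1)
  expect_length(sims, 3)
  for (s in sims) expect_identical(nrow(s), mod$n_landmarks)
  expect_output(print(mod), "Point-distribution")
  expect_output(print(summary(mod)), "mode")
  expect_identical(coef(mod), mod$eigenvalues)
})
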