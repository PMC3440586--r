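# Steps 3-5: normalization, surface projection, regional means, indices

test_that("the surface mesh has exactly the configured point count", {
  lm <- test_phantom()$truth$surface_landmarks
  atlas <- test_atlas()
  mesh <- build_surface_mesh(lm, atlas)
  expect_identical(nrow(mesh$points), 3010L)
  expect_identical(nrow(mesh$inward_normals), 3010L)
  expect_true(all(abs(sqrt(rowSums(mesh$inward_normals^2)) - 1) < 1e-6))
  expect_false(anyNA(mesh$lobe))
  # identity subdivision: target = landmark count returns the landmarks
  mesh0 <- build_surface_mesh(lm, atlas, target_points = nrow(lm))
  expect_equal(mesh0$points, unclass(lm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(build_surface_mesh(lm, atlas, target_points = 10000L),
               "geometry error")
})

test_that("mesh normals on a sphere point at the centre", {
  sph <- ellipsoid_landmarks(axes = c(50, 50, 50), center = c(100, 100, 100),
                             n_rings = 10L, n_per = 12L)
  atlas_lab <- factor(rep("occipital", nrow(sph)), levels = brain_regions())
  # give it a few cerebellar points so downstream code works elsewhere
  mesh <- build_surface_mesh(sph, atlas_lab, target_points = nrow(sph))
  to_ctr <- sweep(mesh$points, 2, c(100, 100, 100))
  to_ctr <- -to_ctr / sqrt(rowSums(to_ctr^2))
  cosang <- rowSums(mesh$inward_normals * to_ctr)
  expect_true(all(acos(pmin(cosang, 1)) < 5 * pi / 180))
})

test_that("reference values: cerebellum max neighbourhood and cortex mean", {
  sp <- uniform_spec(psf_fwhm_mm = 0, partial_volume = FALSE)
  ph <- generate_brain_phantom(sp)
  lm <- ph$truth$surface_landmarks
  mesh <- build_surface_mesh(lm, test_atlas())
  # uniform cerebellum at 100 -> cerebellum_max reference = 100
  ref <- compute_reference_value(ph$volume, mesh, "cerebellum_max")
  expect_equal(ref$reference_raw, 100, tolerance = 1e-9)
  # one interior cerebellar voxel at c + 27 -> reference c + 1
  lab <- ph$truth$lobe_masks
  cer_ids <- match(c("cerebellum_dx", "cerebellum_sin"), brain_regions())
  cer_vox <- which(array(lab %in% cer_ids, dim(lab)), arr.ind = TRUE)
  # pick one whose full 27-neighbourhood is cerebellar shell at 100
  ok <- apply(cer_vox, 1, function(v) {
    nb <- ph$volume$data[(v[1] - 1):(v[1] + 1), (v[2] - 1):(v[2] + 1),
                         (v[3] - 1):(v[3] + 1)]
    all(dim(nb) == 3) && all(nb == 100)
  })
  v <- cer_vox[which(ok)[1], ]
  vol2 <- ph$volume
  vol2$data[v[1], v[2], v[3]] <- 100 + 27
  ref2 <- compute_reference_value(vol2, mesh, "cerebellum_max")
  expect_equal(ref2$reference_raw, 101, tolerance = 1e-9)
  # cortex mean on a shell at 80
  sp80 <- test_spec(psf_fwhm_mm = 0, partial_volume = FALSE,
                    uptake = c(cortex = 80, white_matter = 80, ventricle = 0,
                               cerebellum = 80, background = 0))
  ph80 <- generate_brain_phantom(sp80)
  ref80 <- compute_reference_value(ph80$volume, mesh, "cortex_mean")
  expect_equal(ref80$reference_raw, 80, tolerance = 0.5)
})

test_that("normalization scales voxels so the reference reads 100", {
  ph <- test_phantom()
  mesh <- build_surface_mesh(ph$truth$surface_landmarks, test_atlas())
  raw <- surface_projection(ph$volume, mesh)
  for (m in c("cerebellum_mean", "cerebellum_max", "cortex_mean")) {
    ref <- compute_reference_value(ph$volume, mesh, m, point_values = raw)
    nv <- normalize_volume(ph$volume, ref)
    ref2 <- compute_reference_value(nv, mesh, m,
                                    point_values = raw * ref$scale)
    expect_equal(ref2$reference_raw, 100, tolerance = 1e-6)
    # idempotence: normalizing again with the recomputed reference
    nv2 <- normalize_volume(nv, ref2)
    expect_equal(nv2$data, nv$data, tolerance = 1e-6)
  }
  # simple scalings
  v <- spect_volume(array(7, c(4, 4, 4)), c(1, 1, 1))
  r100 <- structure(list(method = "cortex_mean", reference_raw = 100,
                         scale = 1), class = "normalization_result")
  expect_identical(normalize_volume(v, r100)$data, v$data)
  r50 <- structure(list(method = "cortex_mean", reference_raw = 50,
                        scale = 2), class = "normalization_result")
  expect_identical(normalize_volume(v, r50)$data, v$data * 2)
})

test_that("projection depth is 9% of brain length (166.7 mm -> 15.0 mm)", {
  lm <- test_phantom()$truth$surface_landmarks
  P <- unclass(lm)
  # rescale so the anterior-posterior extent is exactly 166.7 mm
  ctr <- colMeans(P)
  P <- sweep(sweep(P, 2, ctr) * (166.7 / diff(range(P[, 2]))), 2, ctr, "+")
  mesh <- build_surface_mesh(restore_landmarks(P, lm), test_atlas(),
                             target_points = nrow(lm))
  vals <- surface_projection(test_phantom()$volume, mesh)
  expect_equal(attr(vals, "brain_length_mm"), 166.7, tolerance = 1e-9)
  expect_equal(attr(vals, "depth_mm"), 0.09 * 166.7, tolerance = 1e-9)
  expect_equal(attr(vals, "depth_mm"), 15.003, tolerance = 1e-6)
})

test_that("projection reads the shell plateau and picks up a hot cortical stripe", {
  sp <- uniform_spec(psf_fwhm_mm = 0, partial_volume = FALSE)
  ph <- generate_brain_phantom(sp)
  mesh <- build_surface_mesh(ph$truth$surface_landmarks, test_atlas())
  vals <- surface_projection(ph$volume, mesh)
  expect_true(all(abs(vals - 100) < 1e-9))
  # hot stripe: frontal shell voxels at 150
  lab <- ph$truth$lobe_masks
  hot_ids <- match(c("frontal_dx", "frontal_sin", "frontal_med"),
                   brain_regions())
  vol2 <- ph$volume
  vol2$data[array(lab %in% hot_ids, dim(lab))] <- 150
  v2 <- surface_projection(vol2, mesh)
  frontal <- mesh$lobe %in% c("frontal_dx", "frontal_sin", "frontal_med")
  expect_gt(mean(v2[frontal] >= 149), 0.9)
  occ <- mesh$lobe == "occipital"
  expect_true(all(abs(v2[occ] - 100) < 1e-9))
})

test_that("regional means equal the by-label means (brute-force oracle)", {
  mesh <- build_surface_mesh(test_phantom()$truth$surface_landmarks,
                             test_atlas())
  n <- nrow(mesh$points)
  expect_true(all(regional_means(rep(100, n), mesh) == 100))
  vals <- rep(100, n)
  vals[mesh$lobe == "frontal_dx"] <- 80
  rm1 <- regional_means(vals, mesh)
  expect_equal(unname(rm1["frontal_dx"]), 80)
  expect_equal(unname(rm1["occipital"]), 100)
  set.seed(4)
  vr <- runif(n, 50, 150)
  rm2 <- regional_means(vr, mesh)
  for (r in brain_regions()) {
    expect_equal(unname(rm2[r]), mean(vr[mesh$lobe == r]), tolerance = 1e-12)
  }
  cer <- mesh$lobe %in% c("cerebellum_dx", "cerebellum_sin")
  expect_equal(unname(rm2["cerebellum"]), mean(vr[cer]), tolerance = 1e-12)
})

test_that("asymmetry index: formula, antisymmetry, domain", {
  expect_identical(asymmetry_index(100, 100), 0)
  expect_equal(asymmetry_index(110, 90), 20, tolerance = 1e-12)
  for (pair in list(c(105, 95), c(80, 120), c(55, 45))) {
    expect_equal(asymmetry_index(pair[1], pair[2]),
                 -asymmetry_index(pair[2], pair[1]), tolerance = 1e-12)
  }
  expect_error(asymmetry_index(0, 100), "positive")
})

test_that("cortical index counts high-intensity brain voxels", {
  v <- spect_volume(array(100, c(10, 10, 10)), c(1, 1, 1))
  mask <- array(TRUE, c(10, 10, 10))
  expect_identical(cortical_index(v, mask), 100)
  v$data[1:5, , ] <- 10
  expect_identical(cortical_index(v, mask), 50)
  expect_error(cortical_index(v, array(FALSE, c(10, 10, 10))), "empty")
  # ventricle phantom: 100 * (1 - ventricle fraction) within 1
  sp <- uniform_spec(psf_fwhm_mm = 0, partial_volume = FALSE)
  ph <- generate_brain_phantom(sp)
  mesh <- build_surface_mesh(ph$truth$surface_landmarks, test_atlas())
  raw <- surface_projection(ph$volume, mesh)
  ref <- compute_reference_value(ph$volume, mesh, "cortex_mean",
                                 point_values = raw)
  nv <- normalize_volume(ph$volume, ref)
  mask2 <- surface_mask(ph$truth$surface_landmarks, ph$volume)
  ci <- cortical_index(nv, mask2)
  expect_lt(abs(ci - 100 * (1 - ph$truth$ventricle_fraction)), 1)
})

test_that("low-value fraction counts points strictly below threshold", {
  expect_identical(low_value_fraction(rep(100, 3010)), 0)
  vals <- rep(100, 3010)
  vals[1:15] <- 10
  expect_equal(low_value_fraction(vals), 100 * 15 / 3010, tolerance = 1e-12)
  expect_identical(low_value_fraction(vals, threshold_pct = 0), 0)
})

test_that("cross-normalization identity holds per scan (algebraic)", {
  ph <- generate_brain_phantom(
    phantom_spec(grid_size = 64, voxel_mm = 4, counts_scale = 1, seed = 9))
  rep1 <- quantify_scan(ph$volume, ph$truth$surface_landmarks, test_atlas())
  cb_ctx <- rep1$regions["cerebellum", "cortex_mean"]
  lhs <- rep1$regions[, "cortex_mean"]
  rhs <- rep1$regions[, "cerebellum_mean"] * cb_ctx / 100
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("left-right reflection swaps dx/sin regional values (symmetric atlas)", {
  ph <- test_phantom()
  lm <- ph$truth$surface_landmarks
  atlas <- test_atlas()
  rep1 <- quantify_scan(ph$volume, lm, atlas)
  nx <- dim(ph$volume$data)[1]
  vol_f <- spect_volume(ph$volume$data[nx:1, , ], ph$volume$spacing)
  P <- unclass(lm)
  P[, 1] <- (nx - 1) * ph$volume$spacing[1] - P[, 1]
  rep2 <- quantify_scan(vol_f, restore_landmarks(P, lm), atlas)
  swapped <- rep2$regions
  rn <- rownames(swapped)
  sw <- rn
  sw <- sub("_sin$", "_TMP", sw); sw <- sub("_dx$", "_sin", sw)
  sw <- sub("_TMP$", "_dx", sw)
  swapped <- swapped[match(rn, sw), , drop = FALSE]
  expect_lt(max(abs(rep1$regions - swapped)), 1)
  # asymmetry flips sign
  expect_lt(max(abs(rep1$asymmetry + rep2$asymmetry)), 1)
})

test_that("quantify_scan returns a coherent report", {
  ph <- test_phantom()
  rep1 <- quantify_scan(ph$volume, ph$truth$surface_landmarks, test_atlas())
  expect_s3_class(rep1, "rcbf_report")
  expect_identical(dim(rep1$regions), c(13L, 3L))
  expect_identical(rep1$n_points, 3010L)
  expect_true(all(rep1$regions > 0))
  expect_true(all(rep1$cortical_index >= 0 & rep1$cortical_index <= 100))
  expect_output(print(rep1), "Regional means")
})
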