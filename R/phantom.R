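#' Digital brain phantom specification
#'
#' Describes a synthetic SPECT brain: a cerebral ellipsoid fused with an
#' overlapping cerebellar ellipsoid that bulges posterior-inferiorly, a
#' cortical shell of given thickness carrying the tracer uptake, an interior
#' white-matter compartment, a low-uptake ventricular ellipsoid, Gaussian
#' PSF blur and Poisson counting noise. The default field of view is a
#' 128-voxel cube at 2 mm spacing; the default brain is 170 mm long
#' (anterior-posterior) so the 9%-of-length projection depth is ~15 mm; the
#' default PSF is 10 mm FWHM, matching typical reconstructed SPECT
#' resolution.
#'
#' @param grid_size voxels per axis (scalar or length 3). Default 128.
#' @param voxel_mm voxel spacing in mm (scalar or length 3). Default 2.
#' @param brain_axes_mm semi-axes (x,y,z) of the cerebral ellipsoid.
#' @param cortex_thickness_mm radial thickness of the uptake shell.
#' @param cerebellum list(offset=, axes=): cerebellar ellipsoid centre offset
#'   from the brain centre (mm) and semi-axes.
#' @param ventricle list(offset=, axes=): ventricular ellipsoid.
#' @param uptake named compartment intensities: cortex, white_matter,
#'   ventricle, cerebellum, background.
#' @param psf_fwhm_mm Gaussian PSF FWHM in mm (0 = no blur). Default 10.
#' @param partial_volume rasterize boundary voxels with fractional
#'   occupancy (one-voxel linear ramp across the surface), emulating the
#'   smooth boundaries of reconstructed SPECT volumes; `FALSE` gives hard
#'   voxel-centre classification (exactly piecewise-constant compartments).
#'   Default `TRUE`.
#' @param counts_scale Poisson scaling: observed = Pois(counts_scale *
#'   blurred)/counts_scale; 0 = noiseless. Default 1.
#' @param rotation_deg in-sagittal-plane rotation applied to the whole
#'   geometry (positive tilts the anterior end superiorly).
#' @param n_rings,n_per landmark layout (rings x points = landmark count,
#'   default 26 x 21 = 546).
#' @param seed RNG seed for the Poisson noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 128L, voxel_mm = 2,
                         brain_axes_mm = c(65, 82, 60),
                         cortex_thickness_mm = 12,
                         cerebellum = list(offset = c(0, -50, -40),
                                           axes = c(42, 38, 30)),
                         ventricle = list(offset = c(0, 5, 5),
                                          axes = c(18, 25, 15)),
                         uptake = c(cortex = 100, white_matter = 40,
                                    ventricle = 0, cerebellum = 100,
                                    background = 0),
                         psf_fwhm_mm = 10, partial_volume = TRUE,
                         counts_scale = 1,
                         rotation_deg = 0, n_rings = 26L, n_per = 21L,
                         seed = 1L) {
  grid_size <- rep_len(as.integer(grid_size), 3L)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(brain_axes_mm <= 0) || any(cerebellum$axes <= 0) ||
      any(ventricle$axes <= 0)) stop("all semi-axes must be positive")
  if (any(uptake < 0)) stop("uptake values must be non-negative")
  spec <- structure(list(
    grid_size = grid_size, voxel_mm = voxel_mm,
    brain_axes_mm = as.numeric(brain_axes_mm),
    cortex_thickness_mm = cortex_thickness_mm,
    cerebellum = cerebellum, ventricle = ventricle,
    uptake = uptake, psf_fwhm_mm = psf_fwhm_mm,
    partial_volume = isTRUE(partial_volume),
    counts_scale = counts_scale, rotation_deg = rotation_deg,
    n_rings = as.integer(n_rings), n_per = as.integer(n_per),
    seed = seed
  ), class = "phantom_spec")
  fov <- (grid_size - 1) * voxel_mm
  ctr <- fov / 2
  ext <- pmax(brain_axes_mm,
              abs(cerebellum$offset) + cerebellum$axes)
  if (any(ctr - ext < 0) || any(ctr + ext > fov)) {
    stop("geometry error: brain compartments do not fit inside the grid")
  }
  spec
}

REGIONS <- c("cerebellum_dx", "cerebellum_sin",
             "frontal_med", "frontal_dx", "frontal_sin",
             "temporal_dx", "temporal_sin",
             "temporal_med_dx", "temporal_med_sin",
             "parietal_dx", "parietal_sin", "occipital")

PAIRED_REGIONS <- list(cerebellum = c("cerebellum_dx", "cerebellum_sin"),
                       frontal = c("frontal_dx", "frontal_sin"),
                       temporal = c("temporal_dx", "temporal_sin"),
                       temporal_med = c("temporal_med_dx", "temporal_med_sin"),
                       parietal = c("parietal_dx", "parietal_sin"))

#' Atlas region names
#'
#' The 12 atomic surface regions (cerebellum dx/sin, frontal med/dx/sin,
#' temporal dx/sin + medial dx/sin, parietal dx/sin, occipital). Reports add
#' a 13th derived row, total cerebellum. "+x" is the left (sin) side.
#' @return character vector of region labels.
#' @export
brain_regions <- function() REGIONS

## classify unit-direction rows (from the brain centre, upright frame) into
## atlas regions; purely geometric sector rules.
classify_region <- function(dirs) {
  d <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-12)
  dx_ <- d[, 1]; dy_ <- d[, 2]; dz_ <- d[, 3]
  side <- ifelse(dx_ > 0, "sin", "dx")
  out <- character(nrow(d))
  cer <- dy_ < -0.30 & dz_ < -0.30
  occ <- !cer & dy_ < -0.55
  fro <- !cer & !occ & dy_ > 0.40
  par <- !cer & !occ & !fro & dz_ > 0.40
  tmp <- !cer & !occ & !fro & !par
  out[cer] <- paste0("cerebellum_", side[cer])
  out[occ] <- "occipital"
  out[fro] <- ifelse(abs(dx_[fro]) < 0.25, "frontal_med",
                     paste0("frontal_", side[fro]))
  out[par] <- paste0("parietal_", side[par])
  out[tmp] <- ifelse(abs(dx_[tmp]) < 0.30,
                     paste0("temporal_med_", side[tmp]),
                     paste0("temporal_", side[tmp]))
  factor(out, levels = REGIONS)
}

## exit distance of rays p0 + t*d from ellipsoid (centre, axes); NA if the
## ray never leaves the ellipsoid going forward (miss or behind).
ray_ellipsoid_exit <- function(p0, d, center, axes) {
  q <- sweep(sweep(p0, 2L, center), 2L, axes, "/")
  v <- sweep(d, 2L, axes, "/")
  a <- rowSums(v^2); b <- rowSums(q * v); cc <- rowSums(q^2) - 1
  disc <- b^2 - a * cc
  t_exit <- ifelse(disc >= 0, (-b + sqrt(pmax(disc, 0))) / a, NA_real_)
  t_exit[!is.na(t_exit) & t_exit <= 0] <- NA_real_
  t_exit
}

phantom_center <- function(spec) (spec$grid_size - 1) / 2 * spec$voxel_mm

rot_sagittal <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(th), sin(th),
           0, -sin(th), cos(th)), 3L, 3L)  # columns; p %*% t(R)
}

## analytic surface landmarks of the phantom in the *upright* frame
phantom_landmarks_upright <- function(spec) {
  R <- spec$n_rings; m <- spec$n_per
  ctr <- phantom_center(spec)
  u <- cos(pi * (seq_len(R) - 0.5) / R)          # +1 (left) to -1, no 0
  x_ext <- spec$brain_axes_mm[1]
  xs <- ctr[1] + u * x_ext
  phi <- 2 * pi * (seq_len(m) - 0.5) / m
  # all (ring, point) combinations, ring-major
  xg <- rep(xs, each = m)
  ph <- rep(phi, times = R)
  p0 <- cbind(xg, ctr[2], ctr[3])
  dir <- cbind(0, cos(ph), sin(ph))
  t1 <- ray_ellipsoid_exit(p0, dir, ctr, spec$brain_axes_mm)
  t2 <- ray_ellipsoid_exit(p0, dir, ctr + spec$cerebellum$offset,
                           spec$cerebellum$axes)
  tt <- pmax(t1, t2, na.rm = TRUE)
  if (any(!is.finite(tt)) || any(tt <= 0)) {
    stop("geometry error: surface ray failed to intersect the brain")
  }
  landmark_set(p0 + dir * tt, R, m)
}

#' Analytic surface landmarks of a phantom
#'
#' 546 (by default) corresponding points on the true outer surface, laid out
#' as closed rings in sagittal slices, in volume mm coordinates.
#'
#' @param spec a [phantom_spec].
#' @return a [landmark_set].
#' @export
phantom_landmarks <- function(spec) {
  lm <- phantom_landmarks_upright(spec)
  if (spec$rotation_deg != 0) {
    ctr <- phantom_center(spec)
    P <- sweep(unclass(lm), 2L, ctr)
    P <- P %*% t(rot_sagittal(spec$rotation_deg))
    lm <- restore_landmarks(sweep(P, 2L, ctr, "+"), lm)
  }
  lm
}

## per-ring radius resampled on the canonical angular grid; returns list with
## ring x positions (sorted), ring centres (y,z) and radius matrix m x R
ring_radius_grid <- function(landmarks) {
  R <- attr(landmarks, "n_rings"); m <- attr(landmarks, "n_per")
  P <- unclass(landmarks)
  ring <- rep(seq_len(R), each = m)
  xs <- tapply(P[, 1], ring, mean)
  cy <- tapply(P[, 2], ring, mean)
  cz <- tapply(P[, 3], ring, mean)
  phi_c <- -pi + (seq_len(m) - 0.5) * 2 * pi / m
  Rad <- matrix(0, m, R)
  for (j in seq_len(R)) {
    idx <- which(ring == j)
    dy <- P[idx, 2] - cy[j]; dz <- P[idx, 3] - cz[j]
    r <- sqrt(dy^2 + dz^2)
    ph <- atan2(dz, dy)
    o <- order(ph)
    ph <- ph[o]; r <- r[o]
    # periodic padding for interpolation
    php <- c(ph[length(ph)] - 2 * pi, ph, ph[1] + 2 * pi)
    rp <- c(r[length(r)], r, r[1])
    Rad[, j] <- stats::approx(php, rp, xout = phi_c)$y
  }
  o <- order(xs)
  list(x = as.numeric(xs)[o], cy = as.numeric(cy)[o], cz = as.numeric(cz)[o],
       Rad = Rad[, o, drop = FALSE], m = m, R = R)
}

## interpolate ring radius columns at angles phi (vector), column index fixed
interp_ring_radius <- function(radcol, phi, m) {
  u <- (phi + pi) / (2 * pi / m) + 0.5
  k0 <- floor(u)
  f <- u - k0
  i0 <- ((k0 - 1) %% m) + 1
  i1 <- (k0 %% m) + 1
  radcol[i0] * (1 - f) + radcol[i1] * f
}

## pole-augmented radius tables for slice-wise interpolation
radius_tables <- function(g) {
  u1 <- cos(pi * 0.5 / g$R)
  xc_mid <- mean(range(g$x))
  x_pole <- max(abs(g$x - xc_mid)) / u1
  list(xt = c(xc_mid - x_pole, g$x, xc_mid + x_pole),
       Radt = cbind(0, g$Rad, 0),
       cyt = c(g$cy[1], g$cy, g$cy[g$R]),
       czt = c(g$cz[1], g$cz, g$cz[g$R]),
       m = g$m)
}

## surface radius (and slice centre) at slice position wx / angles phi
slice_surface_radius <- function(tb, wx, phi, ddy = NULL, ddz = NULL) {
  iv <- findInterval(wx, tb$xt)
  if (iv < 1L || iv >= length(tb$xt)) return(NULL)
  tfrac <- (wx - tb$xt[iv]) / (tb$xt[iv + 1] - tb$xt[iv])
  cy <- (1 - tfrac) * tb$cyt[iv] + tfrac * tb$cyt[iv + 1]
  cz <- (1 - tfrac) * tb$czt[iv] + tfrac * tb$czt[iv + 1]
  list(iv = iv, tfrac = tfrac, cy = cy, cz = cz)
}

slice_inside <- function(tb, wx, uy, uz) {
  s <- slice_surface_radius(tb, wx)
  if (is.null(s)) return(NULL)
  ddy <- uy - s$cy; ddz <- uz - s$cz
  r <- sqrt(ddy^2 + ddz^2)
  phi <- atan2(ddz, ddy)
  rad_lo <- if (s$iv == 1L) rep(0, length(phi)) else
    interp_ring_radius(tb$Radt[, s$iv], phi, tb$m)
  rad_hi <- if (s$iv + 1L == length(tb$xt)) rep(0, length(phi)) else
    interp_ring_radius(tb$Radt[, s$iv + 1], phi, tb$m)
  Rsurf <- (1 - s$tfrac) * rad_lo + s$tfrac * rad_hi
  list(inside = Rsurf > 0 & r <= Rsurf, Rsurf = Rsurf, r = r)
}

## fractional voxel occupancy of the interior: linear ramp of one voxel
## width across the surface (partial-volume model)
slice_occupancy <- function(si, edge_mm) {
  if (is.null(si)) return(NULL)
  occ <- pmin(1, pmax(0, 0.5 + (si$Rsurf - si$r) / edge_mm))
  occ[si$Rsurf <= 0] <- 0
  occ
}

## Rasterize compartment masks from a landmark surface (upright frame). The
## cortical shell is the region between the surface and the same surface
## eroded radially (in 3D, toward the brain centre) by the cortex thickness,
## so the shell has lateral end caps of roughly uniform thickness.
rasterize_phantom <- function(landmarks_upright, spec) {
  ctr <- phantom_center(spec)
  P <- unclass(landmarks_upright)
  bc <- colMeans(P)                       # brain centre (upright frame)
  th <- spec$cortex_thickness_mm
  r3 <- sqrt(rowSums(sweep(P, 2L, bc)^2))
  shrink <- pmax(1 - th / pmax(r3, 1e-9), 0.05)
  P_in <- sweep(sweep(P, 2L, bc) * shrink, 2L, bc, "+")
  tb_out <- radius_tables(ring_radius_grid(landmarks_upright))
  tb_in <- radius_tables(ring_radius_grid(restore_landmarks(P_in,
                                                            landmarks_upright)))
  nx <- spec$grid_size[1]; ny <- spec$grid_size[2]; nz <- spec$grid_size[3]
  sp <- spec$voxel_mm

  inside <- array(FALSE, spec$grid_size)
  shell <- array(FALSE, spec$grid_size)
  label <- array(0L, spec$grid_size)
  vent <- array(FALSE, spec$grid_size)
  edge <- mean(sp)                       # partial-volume ramp width
  if (isTRUE(spec$partial_volume)) {
    pv_out <- array(0, spec$grid_size)
    pv_core <- array(0, spec$grid_size)
  }

  yz_y <- rep((seq_len(ny) - 1) * sp[2], times = nz)
  yz_z <- rep((seq_len(nz) - 1) * sp[3], each = ny)
  Rinv <- rot_sagittal(-spec$rotation_deg)
  vcen <- ctr + spec$ventricle$offset

  for (ix in seq_len(nx)) {
    wx <- (ix - 1) * sp[1]
    # unrotate sampling coords (sagittal rotation leaves x fixed)
    dy <- yz_y - ctr[2]; dz <- yz_z - ctr[3]
    uy <- Rinv[2, 2] * dy + Rinv[2, 3] * dz + ctr[2]
    uz <- Rinv[3, 2] * dy + Rinv[3, 3] * dz + ctr[3]
    so <- slice_inside(tb_out, wx, uy, uz)
    if (is.null(so)) next
    ins <- so$inside
    si <- slice_inside(tb_in, wx, uy, uz)
    core <- if (is.null(si)) rep(FALSE, length(ins)) else si$inside
    shl <- ins & !core
    # ventricle (upright frame, analytic)
    q <- ((wx - vcen[1]) / spec$ventricle$axes[1])^2 +
      ((uy - vcen[2]) / spec$ventricle$axes[2])^2 +
      ((uz - vcen[3]) / spec$ventricle$axes[3])^2
    vn <- ins & !shl & q <= 1
    inside[ix, , ] <- ins
    shell[ix, , ] <- shl
    vent[ix, , ] <- vn
    if (isTRUE(spec$partial_volume)) {
      occ_out <- slice_occupancy(so, edge)
      occ_core <- if (is.null(si)) numeric(length(occ_out)) else
        slice_occupancy(si, edge)
      occ_core <- pmin(occ_core, occ_out)
      pv_out[ix, , ] <- occ_out
      pv_core[ix, , ] <- occ_core
    }
    need_lab <- if (isTRUE(spec$partial_volume)) {
      shl | (pv_out[ix, , ] - pv_core[ix, , ] > 1e-9)
    } else shl
    if (any(need_lab)) {
      w <- which(need_lab)
      dirs <- cbind(wx - bc[1], uy[w] - bc[2], uz[w] - bc[3])
      lab <- as.integer(classify_region(dirs))
      sl <- label[ix, , ]
      sl[w] <- lab
      label[ix, , ] <- sl
    }
  }
  cer_ids <- match(c("cerebellum_dx", "cerebellum_sin"), REGIONS)
  shell_uptake <- array(ifelse(label %in% cer_ids & label > 0L,
                               spec$uptake[["cerebellum"]],
                               spec$uptake[["cortex"]]), spec$grid_size)
  if (isTRUE(spec$partial_volume)) {
    core_uptake <- array(spec$uptake[["white_matter"]], spec$grid_size)
    core_uptake[vent] <- spec$uptake[["ventricle"]]
    occ_shell <- pmax(pv_out - pv_core, 0)
    img <- spec$uptake[["background"]] * (1 - pv_out) +
      core_uptake * pv_core + shell_uptake * occ_shell
    img <- array(img, spec$grid_size)
  } else {
    img <- array(spec$uptake[["background"]], spec$grid_size)
    img[inside] <- spec$uptake[["white_matter"]]
    img[vent] <- spec$uptake[["ventricle"]]
    img[shell] <- shell_uptake[shell]
  }
  # truth label restricted to the centre-based cortical shell
  label[!shell] <- 0L
  list(image = img, brain_mask = inside, shell = shell, label = label,
       ventricle = vent)
}

finish_phantom <- function(raster, spec, landmarks) {
  vol <- spect_volume(raster$image, spec$voxel_mm)
  if (spec$psf_fwhm_mm > 0) vol <- blur_volume(vol, spec$psf_fwhm_mm)
  if (spec$counts_scale > 0) {
    set.seed(spec$seed)
    lam <- pmax(vol$data * spec$counts_scale, 0)
    vol$data <- array(stats::rpois(length(lam), lam) / spec$counts_scale,
                      dim = dim(lam))
  }
  truth <- list(
    surface_landmarks = landmarks,
    brain_mask = raster$brain_mask,
    lobe_masks = raster$label,          # 0 outside shell, else REGIONS index
    ventricle_mask = raster$ventricle,
    ventricle_fraction = sum(raster$ventricle) / max(sum(raster$brain_mask), 1L),
    true_rotation_deg = spec$rotation_deg,
    region_levels = REGIONS
  )
  list(volume = vol, truth = truth)
}

#' Generate a synthetic SPECT brain phantom
#'
#' Rasterizes the phantom geometry, applies PSF blur then Poisson counting
#' noise (blur before noise, emission statistics), and returns the volume
#' together with its ground truth: the true surface landmarks, brain and
#' ventricle masks, per-voxel lobe labels over the cortical shell, and the
#' applied rotation. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @return list with `volume` (a [spect_volume]) and `truth`.
#' @export
generate_brain_phantom <- function(spec) {
  lm_up <- phantom_landmarks_upright(spec)
  raster <- rasterize_phantom(lm_up, spec)
  finish_phantom(raster, spec, phantom_landmarks(spec))
}

#' Generate a phantom volume from an arbitrary landmark surface
#'
#' Rasterizes a brain volume whose outer surface is the given (ring-layout)
#' landmark set — e.g. a shape synthesized from a [shape_model] — using the
#' compartment/uptake/noise settings of `spec`. The landmark set is taken as
#' upright (no additional rotation is applied).
#'
#' @param landmarks a [landmark_set] in volume mm coordinates.
#' @param spec a [phantom_spec] providing grid, compartments and noise.
#' @return list with `volume` and `truth`, as [generate_brain_phantom()].
#' @export
generate_phantom_from_landmarks <- function(landmarks, spec) {
  spec$rotation_deg <- 0
  raster <- rasterize_phantom(landmarks, spec)
  finish_phantom(raster, spec, landmarks)
}

#' Generate a training set of landmark shapes
#'
#' Samples `n` brain surfaces with six anatomy-like degrees of freedom:
#' independent per-axis scaling of the cerebral ellipsoid (SD `scale_sd`,
#' giving small, medium and large brains and aspect variation), cerebellar
#' size scaling (SD `cerebellum_sd`), a smooth sagittal bending of the
#' vault (amplitude ~ N(0, `bend_sd`), as a fraction of the vertical
#' semi-axis) and an anterior-posterior taper ("egg-shapedness", SD
#' `taper_sd`). Point correspondence is preserved by construction. The SDs
#' are balanced so that, after similarity alignment, the population carries
#' five modes of comparable, substantive variance — mirroring a shape model
#' whose five retained modes all capture real variation.
#'
#' @param n number of shapes (>= 2); the reference configuration uses 29.
#' @param base_spec a [phantom_spec] defining the average geometry.
#' @param scale_sd SD of the per-axis cerebral scale factors. Default 0.05.
#' @param cerebellum_sd SD of the cerebellar scale factor. Default 0.10.
#' @param bend_sd SD of the sagittal bending amplitude. Default 0.12.
#' @param taper_sd SD of the anterior-posterior taper. Default 0.06.
#' @param seed RNG seed.
#' @return list of n [landmark_set] objects.
#' @export
generate_training_set <- function(n, base_spec = phantom_spec(),
                                  scale_sd = 0.05, cerebellum_sd = 0.10,
                                  bend_sd = 0.12, taper_sd = 0.06,
                                  seed = 1L) {
  if (n < 2L) stop("need n >= 2 training shapes")
  set.seed(seed)
  ctr <- phantom_center(base_spec)
  ay <- base_spec$brain_axes_mm[2]; az <- base_spec$brain_axes_mm[3]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s_axes <- stats::rnorm(3, 1, scale_sd)
    s_cer <- stats::rnorm(1, 1, cerebellum_sd)
    bend <- stats::rnorm(1, 0, bend_sd)
    taper <- stats::rnorm(1, 0, taper_sd)
    sp <- base_spec
    sp$brain_axes_mm <- base_spec$brain_axes_mm * s_axes
    sp$cerebellum$axes <- base_spec$cerebellum$axes * s_cer
    sp$cerebellum$offset <- base_spec$cerebellum$offset * s_axes
    lm <- phantom_landmarks_upright(sp)
    P <- unclass(lm)
    # sagittal bend: vertical displacement growing quadratically with |y|
    P[, 3] <- P[, 3] + bend * az * ((P[, 2] - ctr[2]) / ay)^2
    # AP taper: radial scaling linear in y (egg shape)
    fac <- 1 + taper * (P[, 2] - ctr[2]) / ay
    P <- sweep(sweep(P, 2L, ctr) * fac, 2L, ctr, "+")
    out[[i]] <- restore_landmarks(P, lm)
  }
  out
}

#' Generate a single-lobe phantom
#'
#' A noiseless, unblurred volume with uptake only inside one atlas region of
#' the cortical shell and zero elsewhere — used to assign landmarks to lobes
#' when building the atlas.
#'
#' @param spec a [phantom_spec].
#' @param region one of [brain_regions()].
#' @return a [spect_volume].
#' @export
generate_lobe_phantom <- function(spec, region) {
  region <- match.arg(region, REGIONS)
  lm_up <- phantom_landmarks_upright(spec)
  raster <- rasterize_phantom(lm_up, spec)
  img <- array(0, spec$grid_size)
  sel <- raster$shell & raster$label == match(region, REGIONS)
  img[sel] <- spec$uptake[["cortex"]]
  spect_volume(img, spec$voxel_mm)
}
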