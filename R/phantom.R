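#' Canonical marker dimensions for the synthetic valve
#'
#' Physical dimensions of the five-marker constellation used by the phantom
#' generator, in mm, in the canonical frame (valve plane `z = 0`, rotating
#' construct at the origin, RHS marker along `+x`). Only the angular
#' relationships between markers matter to the setting measurement, so these
#' are deliberately configurable stand-ins, chosen so all five shapes are
#' pairwise separated by more than one voxel diagonal of the default 0.6 mm
#' grid (a 26-connected-component segmenter can tell them apart) and the
#' whole valve fits a default phantom volume under arbitrary rotation.
#' They are plausible for a Certas Plus but are not manufacturer drawings.
#'
#' @param rhs_offset Distance RC -> RHS marker along the reference axis.
#' @param tip_offset Distance RC -> distal tip.
#' @param flow_angle_deg In-plane angle of the RC -> tip direction from the
#'   reference axis; 90 keeps the three plane-defining points far from
#'   collinear by construction.
#' @param magnet_offset Distance of each magnet center from the rotor center.
#' @param magnet_radius Radius of the magnet spheres.
#' @param ring_radius,ring_tube_radius Center-line radius and tube radius of
#'   the rotating-construct annulus.
#' @param rhs_radius Radius of the RHS marker sphere.
#' @param tip_radius,tip_length Radius and length of the distal-tip capsule.
#' @param ball_offset,ball_radius Position (from the ball-magnet center,
#'   outward along the indicator) and radius of the small tantalum-ball
#'   intensity core used to disambiguate the two magnets.
#' @return A named list of class `valve_geometry`.
#' @export
valve_geometry <- function(rhs_offset = 11, tip_offset = 20, flow_angle_deg = 90,
                           magnet_offset = 3.5, magnet_radius = 1.6,
                           ring_radius = 7.5, ring_tube_radius = 0.8,
                           rhs_radius = 0.9, tip_radius = 0.8, tip_length = 4,
                           ball_offset = 0.8, ball_radius = 0.5) {
  g <- as.list(environment())
  stopifnot(g$magnet_offset + g$magnet_radius < g$ring_radius - g$ring_tube_radius,
            g$rhs_offset - g$rhs_radius > g$ring_radius + g$ring_tube_radius,
            g$tip_offset > g$rhs_offset)
  structure(g, class = "valve_geometry")
}

#' Exact marker centroids at a given indicator angle
#'
#' Places the five markers in the canonical frame: rotating construct at the
#' origin, RHS marker on `+x`, distal tip in-plane at the flow angle, and the
#' two magnets at `+/- magnet_offset` along the indicator direction — the
#' direction at `angle_deg` measured clockwise about the plane normal from
#' `+x`, with the ball magnet on the positive side. These are mathematical
#' centroids (no rasterization), so feeding them through [valve_frame()] and
#' [indicator_angle()] recovers `angle_deg` to machine precision.
#'
#' @param angle_deg Finite indicator angle in degrees.
#' @param geometry A [valve_geometry()].
#' @return A marker tibble in the same shape as [marker_centroids()] output
#'   (`voxel_count` is set to 1 to mark presence).
#' @export
canonical_markers <- function(angle_deg, geometry = valve_geometry()) {
  stopifnot(is.finite(angle_deg))
  th <- angle_deg * pi / 180
  d <- c(cos(th), -sin(th), 0)          # clockwise about +z normal
  fa <- geometry$flow_angle_deg * pi / 180
  pos <- rbind(
    magnet_with_ball    =  geometry$magnet_offset * d,
    magnet_without_ball = -geometry$magnet_offset * d,
    rotating_construct  = c(0, 0, 0),
    rhs_marker          = c(geometry$rhs_offset, 0, 0),
    distal_tip          = geometry$tip_offset * c(cos(fa), sin(fa), 0))
  tibble::tibble(label = 1:5, name = unname(marker_names()),
                 x = pos[, 1], y = pos[, 2], z = pos[, 3], voxel_count = 1L)
}

#' Rigid poses
#'
#' A pose is a rotation (intrinsic Z-Y-X Euler angles, degrees) plus a
#' translation in mm. `pose_rotation()` returns the 3x3 rotation matrix
#' `Rz %*% Ry %*% Rx`; `transform_markers()` applies the pose to a marker
#' tibble.
#'
#' @param euler_deg Length-3 numeric: rotations about x, y, z in degrees.
#' @param translation Length-3 numeric translation in mm, or `NULL` (phantom
#'   generation then centers the valve in the volume).
#' @return `make_pose()`: a list of class `valve_pose`.
#' @export
make_pose <- function(euler_deg = c(0, 0, 0), translation = NULL) {
  stopifnot(length(euler_deg) == 3, is.null(translation) || length(translation) == 3)
  structure(list(euler_deg = as.numeric(euler_deg), translation = translation),
            class = "valve_pose")
}

#' @rdname make_pose
#' @param pose A `valve_pose`.
#' @export
pose_rotation <- function(pose) {
  a <- pose$euler_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' @rdname make_pose
#' @param markers Marker tibble (columns `x`, `y`, `z`).
#' @export
transform_markers <- function(markers, pose) {
  R <- pose_rotation(pose)
  t <- pose$translation %||% c(0, 0, 0)
  p <- as.matrix(markers[, c("x", "y", "z")]) %*% t(R)
  p <- sweep(p, 2L, t, "+")
  markers$x <- p[, 1]; markers$y <- p[, 2]; markers$z <- p[, 3]
  markers
}

#' Draw a random rigid pose
#'
#' Euler angles uniform over the full rotation ranges and a uniform
#' translation jitter per axis. Uses the current RNG state; seed externally
#' (e.g. [withr::with_seed()]) for reproducibility.
#'
#' @param max_jitter_mm Half-width of the uniform translation jitter (applied
#'   around the volume center during phantom generation).
#' @return A `valve_pose` with a `jitter` translation (interpreted relative to
#'   the volume center by [make_phantom()]).
#' @export
random_pose <- function(max_jitter_mm = 3) {
  p <- make_pose(euler_deg = c(runif(1, -180, 180), runif(1, -90, 90),
                               runif(1, -180, 180)))
  p$jitter <- runif(3, -max_jitter_mm, max_jitter_mm)
  p
}

#' Specification of a synthetic valve phantom
#'
#' Describes one synthetic CT sub-volume containing the five-marker Certas
#' Plus constellation at a known pose and indicator angle. Defaults emulate a
#' retroauricular head-CT sub-volume: sub-millimetre near-isotropic spacing,
#' soft-tissue background against very bright metal, mild reconstruction blur
#' and additive noise.
#'
#' @param setting Discrete setting 1..8, expanded to its expected (zone
#'   center) angle. Ignored when `angle_deg` is given.
#' @param angle_deg Explicit indicator angle in degrees (the physical dial is
#'   continuous, so any angle is valid).
#' @param pose A [make_pose()] / [random_pose()]; `translation = NULL` centers
#'   the valve in the volume.
#' @param spacing Per-axis voxel spacing in mm (default 0.6 isotropic).
#' @param volume_shape Voxel dimensions (default `c(96, 96, 96)`).
#' @param blur_sigma Gaussian blur sigma in mm (default 0.4).
#' @param noise_sd Additive Gaussian noise SD in intensity units (default 15).
#' @param background_level,marker_level Intensities of background and marker
#'   voxels (defaults 40 and 2000, soft tissue vs metal on an HU-like scale).
#' @param ball_level Intensity inside the tantalum-ball core (default 3500).
#' @param streak_artefacts Add cosmetic radial streaks from the marker centers
#'   (default `FALSE`); a stressor for the segmenter, not a scanner model.
#' @param seed Integer seed making blur-independent noise (and streaks)
#'   reproducible.
#' @param geometry A [valve_geometry()].
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(setting = 4, angle_deg = NULL,
                         pose = make_pose(), spacing = c(0.6, 0.6, 0.6),
                         volume_shape = c(96, 96, 96), blur_sigma = 0.4,
                         noise_sd = 15, background_level = 40,
                         marker_level = 2000, ball_level = 3500,
                         streak_artefacts = FALSE, seed = 1L,
                         geometry = valve_geometry()) {
  if (is.null(angle_deg)) angle_deg <- setting_to_expected_angle(setting)
  stopifnot(is.finite(angle_deg), all(spacing > 0), length(spacing) == 3,
            length(volume_shape) == 3, all(volume_shape >= 8),
            marker_level > background_level, blur_sigma >= 0, noise_sd >= 0)
  structure(list(angle_deg = normalize_angle(angle_deg), pose = pose,
                 spacing = as.numeric(spacing),
                 volume_shape = as.integer(volume_shape),
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 background_level = background_level,
                 marker_level = marker_level, ball_level = ball_level,
                 streak_artefacts = isTRUE(streak_artefacts),
                 seed = as.integer(seed), geometry = geometry),
            class = "phantom_spec")
}

# rasterize a predicate over the voxels inside a physical bounding box;
# assumes the phantom's diagonal affine (world = index * spacing)
raster_assign <- function(arr, spacing, lo_mm, hi_mm, predicate, value) {
  dims <- dim(arr)
  lo <- pmax(floor(lo_mm / spacing), 0)
  hi <- pmin(ceiling(hi_mm / spacing), dims - 1L)
  if (any(lo > hi)) return(arr)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  pts <- cbind(rep(ix * spacing[1], times = ny * nz),
               rep(rep(iy * spacing[2], each = nx), times = nz),
               rep(iz * spacing[3], each = nx * ny))
  inside <- predicate(pts)
  if (!any(inside)) return(arr)
  sub <- arr[ix + 1L, iy + 1L, iz + 1L]
  sub[inside] <- value
  arr[ix + 1L, iy + 1L, iz + 1L] <- sub
  arr
}

sphere_pred <- function(center, radius) {
  force(center); force(radius)
  function(p) rowSums(sweep(p, 2L, center)^2) <= radius^2
}

capsule_pred <- function(p1, p2, radius) {
  axis <- p2 - p1; len2 <- sum(axis^2)
  function(p) {
    u <- sweep(p, 2L, p1)
    t <- pmin(pmax((u %*% axis) / len2, 0), 1)
    d2 <- rowSums((u - t %*% rbind(axis))^2)
    d2 <= radius^2
  }
}

torus_pred <- function(center, normal, ring_radius, tube_radius) {
  normal <- unit(normal)
  function(p) {
    u <- sweep(p, 2L, center)
    h <- as.vector(u %*% normal)
    rho <- sqrt(pmax(rowSums(u^2) - h^2, 0))
    (rho - ring_radius)^2 + h^2 <= tube_radius^2
  }
}

# separable 3-D Gaussian blur with edge replication, sigma in mm per axis
gauss_blur_3d <- function(arr, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(arr)
  for (ax in 1:3) {
    sig <- sigma_mm / spacing[ax]
    K <- max(1L, ceiling(3 * sig))
    w <- exp(-((-K:K)^2) / (2 * sig^2)); w <- w / sum(w)
    n <- dim(arr)[ax]
    out <- array(0, dim(arr))
    for (k in -K:K) {
      idx <- pmin(pmax(seq_len(n) + k, 1L), n)
      shifted <- switch(ax, arr[idx, , , drop = FALSE],
                        arr[, idx, , drop = FALSE],
                        arr[, , idx, drop = FALSE])
      out <- out + w[k + K + 1L] * shifted
    }
    arr <- out
  }
  arr
}

#' Generate a synthetic valve phantom
#'
#' Rasterizes the five markers as solid shapes (spheres for the magnets and
#' RHS marker, an annulus for the rotating construct, a capsule for the
#' distal tip) at the posed positions. The label map holds the exact pre-blur
#' rasterization — crisp ground truth, mirroring manual segmentation — while
#' the intensity volume is background plus bright markers (and a brighter
#' tantalum-ball core inside the indicator magnet), Gaussian-blurred and
#' degraded with seeded Gaussian noise. Deterministic given the spec seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `valve_phantom`: `volume` ([voxel_grid()]),
#'   `labels` ([label_map()]), and `truth` — a list with `truth_angle_deg`,
#'   `truth_setting`, `pose`, the posed marker centroid tibble, and the spec.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  sp <- spec$spacing
  dims <- spec$volume_shape
  extent <- (dims - 1L) * sp
  pose <- spec$pose
  if (is.null(pose$translation)) {
    pose$translation <- extent / 2 + (pose$jitter %||% c(0, 0, 0))
  }
  mk <- transform_markers(canonical_markers(spec$angle_deg, g), pose)
  R <- pose_rotation(pose)
  n_posed <- as.vector(R %*% c(0, 0, 1))
  flow_posed <- unit(marker_point(mk, "distal_tip") - marker_point(mk, "rotating_construct"))
  ind_dir <- unit(marker_point(mk, "magnet_with_ball") - marker_point(mk, "magnet_without_ball"))

  margin <- c(g$magnet_radius, g$magnet_radius,
              g$ring_radius + g$ring_tube_radius,
              g$rhs_radius, g$tip_length / 2 + g$tip_radius) + 3 * spec$blur_sigma
  ctr <- as.matrix(mk[, c("x", "y", "z")])
  if (any(sweep(ctr, 1L, margin) < 0) ||
      any(sweep(sweep(ctr, 1L, margin, "+"), 2L, extent) > 0))
    abort("phantom out of bounds: posed markers do not fit the volume")

  labels <- array(0L, dims)
  shapes <- list(
    list(label = 1L, pred = sphere_pred(ctr[1, ], g$magnet_radius), r = g$magnet_radius, c = ctr[1, ]),
    list(label = 2L, pred = sphere_pred(ctr[2, ], g$magnet_radius), r = g$magnet_radius, c = ctr[2, ]),
    list(label = 3L, pred = torus_pred(ctr[3, ], n_posed, g$ring_radius, g$ring_tube_radius),
         r = g$ring_radius + g$ring_tube_radius, c = ctr[3, ]),
    list(label = 4L, pred = sphere_pred(ctr[4, ], g$rhs_radius), r = g$rhs_radius, c = ctr[4, ]),
    list(label = 5L, pred = capsule_pred(ctr[5, ] - g$tip_length / 2 * flow_posed,
                                         ctr[5, ] + g$tip_length / 2 * flow_posed,
                                         g$tip_radius),
         r = g$tip_length / 2 + g$tip_radius, c = ctr[5, ]))
  for (sh in shapes)
    labels <- raster_assign(labels, sp, sh$c - sh$r - max(sp), sh$c + sh$r + max(sp),
                            sh$pred, sh$label)

  intens <- array(spec$background_level, dims)
  intens[labels > 0L] <- spec$marker_level
  ball_c <- ctr[1, ] + g$ball_offset * ind_dir
  intens <- raster_assign(intens, sp, ball_c - g$ball_radius - max(sp),
                          ball_c + g$ball_radius + max(sp),
                          sphere_pred(ball_c, g$ball_radius), spec$ball_level)
  intens <- gauss_blur_3d(intens, spec$blur_sigma, sp)
  withr::with_seed(spec$seed, {
    if (spec$streak_artefacts)
      intens <- add_streaks(intens, sp, ctr, spec$marker_level * 0.25)
    if (spec$noise_sd > 0)
      intens <- intens + array(rnorm(prod(dims), 0, spec$noise_sd), dims)
  })

  affine <- diag(c(sp, 1))
  truth <- list(truth_angle_deg = spec$angle_deg,
                truth_setting = angle_to_setting(spec$angle_deg)$setting,
                pose = pose, markers = mk, spec = spec)
  structure(list(volume = voxel_grid(intens, affine),
                 labels = label_map(labels, affine),
                 truth = truth),
            class = "valve_phantom")
}

# cosmetic radial streaks from marker centers (uses current RNG state)
add_streaks <- function(intens, spacing, centers, amplitude, n_rays = 6) {
  dims <- dim(intens)
  for (i in seq_len(nrow(centers))) {
    for (ray in seq_len(n_rays)) {
      dir <- unit(rnorm(3))
      steps <- seq(0, 15, by = min(spacing) / 2)
      pts <- sweep(outer(steps, dir), 2L, centers[i, ], "+")
      vox <- round(sweep(pts, 2L, spacing, "/")) + 1L
      keep <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
              vox[, 2] >= 1 & vox[, 2] <= dims[2] &
              vox[, 3] >= 1 & vox[, 3] <= dims[3]
      vox <- vox[keep, , drop = FALSE]
      if (nrow(vox) > 0)
        intens[vox] <- intens[vox] + amplitude * exp(-steps[keep] / 5)
    }
  }
  intens
}

#' Default setting frequencies for synthetic cohorts
#'
#' Skewed toward the mid-range with setting 4 the most frequent, emulating
#' the clinical distribution of prescribed opening pressures (extreme
#' settings 1 and 8 are rare).
#'
#' @return Named numeric vector of 8 weights (unnormalized).
#' @export
default_setting_weights <- function() {
  setNames(c(2, 6, 10, 25, 15, 9, 5, 3), as.character(1:8))
}

#' Generate a cohort of synthetic phantoms with ground truth
#'
#' Draws each case's discrete setting from `setting_weights`, then a
#' continuous indicator angle uniform within that setting's 45-degree zone —
#' the physical dial is continuous, so truth angles do not cluster at zone
#' centers — plus an independent random rigid pose and a fresh noise seed.
#' Cases are grouped into synthetic "patients" (1-3 scans each) so grouped
#' train/test splitting can be exercised without leakage.
#'
#' Volumes are not materialized up front: the manifest row carries the full
#' [phantom_spec()], and [make_phantom()] is applied per case (or the cohort
#' is written to disk with [write_cohort()]).
#'
#' @param n Number of cases (> 0).
#' @param setting_weights 8 nonnegative weights, sum > 0.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param max_jitter_mm Translation jitter half-width passed to [random_pose()].
#' @param ... Further arguments passed to [phantom_spec()] (noise, spacing...).
#' @return A list of class `valve_cohort`: `manifest` (tibble with `case_id`,
#'   `patient_id`, `truth_setting`, `truth_angle_deg`, `seed`, pose columns)
#'   and `specs` (list of `phantom_spec`).
#' @export
make_cohort <- function(n, setting_weights = default_setting_weights(),
                        seed = 1L, max_jitter_mm = 3, ...) {
  if (!is.numeric(n) || n < 1) abort("`n` must be a positive count")
  n <- as.integer(n)
  w <- as.numeric(setting_weights)
  if (length(w) != 8 || any(w < 0) || sum(w) <= 0)
    abort("`setting_weights` must be 8 nonnegative weights with positive sum")
  w <- w / sum(w)
  withr::with_seed(as.integer(seed), {
    settings <- sample.int(8L, n, replace = TRUE, prob = w)
    zb <- zone_bounds(settings)
    angles <- runif(n, zb$zone_lo, zb$zone_hi)
    poses <- lapply(seq_len(n), function(i) random_pose(max_jitter_mm))
    case_seeds <- sample.int(.Machine$integer.max - 1L, n)
    patient_id <- assign_patients(n)
  })
  specs <- lapply(seq_len(n), function(i) {
    phantom_spec(angle_deg = angles[i], pose = poses[[i]],
                 seed = case_seeds[i], ...)
  })
  eul <- t(vapply(poses, function(p) p$euler_deg, numeric(3)))
  jit <- t(vapply(poses, function(p) p$jitter, numeric(3)))
  manifest <- tibble::tibble(
    case_id = sprintf("case_%03d", seq_len(n)),
    patient_id = sprintf("patient_%03d", patient_id),
    truth_setting = settings, truth_angle_deg = angles,
    seed = case_seeds,
    euler_x = eul[, 1], euler_y = eul[, 2], euler_z = eul[, 3],
    jitter_x = jit[, 1], jitter_y = jit[, 2], jitter_z = jit[, 3])
  structure(list(manifest = manifest, specs = specs, seed = as.integer(seed)),
            class = "valve_cohort")
}

# 1-3 scans per synthetic patient, consuming the current RNG stream
assign_patients <- function(n) {
  sizes <- integer(0)
  while (sum(sizes) < n) sizes <- c(sizes, sample(1:3, 1, prob = c(.5, .35, .15)))
  rep(seq_along(sizes), sizes)[seq_len(n)]
}

#' Write a cohort to disk as NIfTI pairs plus a manifest CSV
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, augmented with `volume_path` and
#'   `labels_path`, invisibly; also written as `manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "valve_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$volume_path <- file.path(dir, paste0(man$case_id, "_ct.nii.gz"))
  man$labels_path <- file.path(dir, paste0(man$case_id, "_labels.nii.gz"))
  for (i in seq_len(nrow(man))) {
    ph <- make_phantom(cohort$specs[[i]])
    write_volume(ph$volume, man$volume_path[i])
    write_labelmap(ph$labels, man$labels_path[i])
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
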