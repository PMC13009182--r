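#' Physical-space centroids of the five valve markers
#'
#' For each label 1..5, the centroid is the unweighted mean of the physical
#' (mm) coordinates of its member voxels — the binary center of mass of the
#' segmentation, not intensity-weighted. Absent labels are recorded with
#' `voxel_count = 0` and `NA` coordinates; absence is data here, not failure
#' (a missing marker only becomes an error when the valve frame needs it).
#'
#' @param labelmap A [label_map()].
#' @return A tibble with one row per label 1..5: `label`, `name`, `x`, `y`,
#'   `z` (mm, `NA` when absent) and `voxel_count`.
#' @export
marker_centroids <- function(labelmap) {
  stopifnot(inherits(labelmap, "label_map"))
  dims <- dim(labelmap$labels)
  out <- tibble::tibble(label = 1:5, name = unname(marker_names()),
                        x = NA_real_, y = NA_real_, z = NA_real_,
                        voxel_count = 0L)
  hit <- which(labelmap$labels > 0L)
  if (length(hit) > 0) {
    idx0 <- arrayInd(hit, dims) - 1L    # 0-based voxel indices
    lab <- labelmap$labels[hit]
    world <- voxel_to_world(idx0, labelmap, check = FALSE)
    for (l in sort(unique(lab))) {
      sel <- lab == l
      out[l, c("x", "y", "z")] <- as.list(colMeans(world[sel, , drop = FALSE]))
      out$voxel_count[l] <- sum(sel)
    }
  }
  out
}

marker_point <- function(markers, name) {
  row <- markers[markers$name == name, ]
  if (nrow(row) != 1L || row$voxel_count == 0L || anyNA(c(row$x, row$y, row$z)))
    return(NULL)
  unname(c(row$x, row$y, row$z))
}

missing_marker_names <- function(markers, needed) {
  needed[vapply(needed, function(nm) is.null(marker_point(markers, nm)), logical(1))]
}

unit <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Valve plane and orientation frame
#'
#' The valve plane is defined by three centroids: the rotating construct (RC,
#' the frame origin), the right-hand-side marker (RHS) and the distal tip
#' (TIP). The frame consists of the in-plane reference axis
#' `r = unit(RHS - RC)`, the plane normal `n = unit((RHS - RC) x (TIP - RC))`
#' — whose sign, fixed by the RHS/TIP chirality, makes the indicator angle
#' independent of which valve face points toward the scanner — and the flow
#' axis `unit(TIP - RC)` (reporting only).
#'
#' @param markers A marker-centroid tibble from [marker_centroids()] or
#'   [canonical_markers()].
#' @param min_altitude_mm Collinearity guard: the RC/RHS/TIP triangle must
#'   have minimum altitude at least this many mm (default 0.1, below voxel
#'   scale the normal is noise).
#' @return An object of class `valve_frame`: `origin`, `ref_axis`, `normal`,
#'   `flow_axis`.
#' @export
valve_frame <- function(markers, min_altitude_mm = 0.1) {
  needed <- c("rotating_construct", "rhs_marker", "distal_tip")
  missing <- missing_marker_names(markers, needed)
  if (length(missing) > 0)
    abort("setting undeterminable: missing ", paste(missing, collapse = ", "),
          class = "certasdial_missing_marker",
          missing_markers = missing)
  rc  <- marker_point(markers, "rotating_construct")
  rhs <- marker_point(markers, "rhs_marker")
  tip <- marker_point(markers, "distal_tip")
  u <- rhs - rc
  v <- tip - rc
  nvec <- cross3(u, v)
  # min altitude of the triangle = 2*area / longest side
  area2 <- sqrt(sum(nvec^2))                   # = 2 * area
  sides <- c(sqrt(sum(u^2)), sqrt(sum(v^2)), sqrt(sum((v - u)^2)))
  if (any(sides < 1e-12) || area2 / max(sides) < min_altitude_mm)
    abort("degenerate valve plane: rotating construct, RHS marker and distal tip are collinear",
          class = "certasdial_degenerate")
  structure(list(origin = rc,
                 ref_axis = unit(u),
                 normal = unit(nvec),
                 flow_axis = unit(v)),
            class = "valve_frame")
}

#' @export
print.valve_frame <- function(x, ...) {
  cat("<valve_frame>\n",
      sprintf("  origin    (%.2f, %.2f, %.2f) mm\n", x$origin[1], x$origin[2], x$origin[3]),
      sprintf("  ref_axis  (%.4f, %.4f, %.4f)\n", x$ref_axis[1], x$ref_axis[2], x$ref_axis[3]),
      sprintf("  normal    (%.4f, %.4f, %.4f)\n", x$normal[1], x$normal[2], x$normal[3]),
      sep = "")
  invisible(x)
}

#' Normalize an angle into the reporting range [-90, 270)
#'
#' @param angle_deg Numeric vector of angles in degrees.
#' @return Angles shifted by multiples of 360 into `[-90, 270)`.
#' @export
normalize_angle <- function(angle_deg) {
  ((angle_deg + 90) %% 360) - 90
}

#' Signed indicator angle in the valve plane
#'
#' The setting indicator direction is the line through both magnet centroids,
#' oriented from the magnet without the tantalum ball toward the magnet with
#' it (the ball marks the pointer end of the nearly symmetric rotor, resolving
#' the 180-degree ambiguity between opposing settings). The direction is
#' projected into the valve plane and the signed angle from the reference axis
#' is measured clockwise about the plane normal:
#' `atan2((r x d) . (-n), r . d)`, reported in degrees in `[-90, 270)`.
#' An angle of 0 means the indicator is superimposed on the RC-to-RHS axis.
#'
#' @param markers Marker-centroid tibble (needs both magnets).
#' @param frame A [valve_frame()]; computed from `markers` if omitted.
#' @param min_projection Reject when the projected indicator direction has
#'   norm below this fraction of the unprojected one (default 1e-6), i.e. the
#'   indicator is essentially perpendicular to the valve plane.
#' @return An object of class `angle_result`: `angle_deg`, `frame`, `markers`.
#' @export
indicator_angle <- function(markers, frame = valve_frame(markers),
                            min_projection = 1e-6) {
  needed <- c("magnet_with_ball", "magnet_without_ball")
  missing <- missing_marker_names(markers, needed)
  if (length(missing) > 0)
    abort("setting undeterminable: missing ", paste(missing, collapse = ", "),
          class = "certasdial_missing_marker",
          missing_markers = missing)
  ball <- marker_point(markers, "magnet_with_ball")
  noball <- marker_point(markers, "magnet_without_ball")
  d <- ball - noball
  n <- frame$normal
  r <- frame$ref_axis
  d_plane <- d - sum(d * n) * n
  if (sqrt(sum(d_plane^2)) < min_projection * max(sqrt(sum(d^2)), 1e-12))
    abort("degenerate indicator direction: magnet axis is perpendicular to the valve plane",
          class = "certasdial_degenerate")
  d_plane <- unit(d_plane)
  ang <- atan2(sum(cross3(r, d_plane) * (-n)), sum(r * d_plane)) * 180 / pi
  structure(list(angle_deg = normalize_angle(ang),
                 frame = frame, markers = markers),
            class = "angle_result")
}

#' @export
print.angle_result <- function(x, ...) {
  s <- angle_to_setting(x$angle_deg)
  cat(sprintf("<angle_result> indicator angle %.2f deg -> setting %d (zone [%g, %g))\n",
              x$angle_deg, s$setting, s$zone_lo, s$zone_hi))
  invisible(x)
}
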