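#' Construct a voxel grid (3-D scalar image with physical geometry)
#'
#' A `voxel_grid` couples a 3-D intensity array with the 4x4 affine that maps
#' 0-based voxel indices (voxel centers) to physical millimetre coordinates,
#' following the NIfTI convention. All downstream geometry is computed in
#' physical mm, so anisotropic spacing is handled transparently.
#'
#' @param data 3-D numeric array of intensities (Hounsfield-unit-like).
#' @param affine 4x4 numeric matrix, voxel-index -> mm. Must be invertible and
#'   have unit last row `(0,0,0,1)`.
#' @return An object of class `voxel_grid` with elements `data`, `affine` and
#'   derived per-axis `spacing` (mm).
#' @seealso [read_volume()], [voxel_to_world()]
#' @export
voxel_grid <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3-D array; got dimensions: ",
          paste(dim(data), collapse = "x"))
  affine <- check_affine(affine)
  structure(list(data = data, affine = affine, spacing = affine_spacing(affine)),
            class = "voxel_grid")
}

#' Construct a marker label map
#'
#' Integer 3-D volume sharing a [voxel_grid()]'s geometry. Labels 0 (background)
#' and 1..5 for the five valve markers (see [marker_names()]).
#'
#' @param labels 3-D array of integers in `{0,...,5}`.
#' @param affine 4x4 voxel-to-mm affine (as in [voxel_grid()]).
#' @return An object of class `label_map` with elements `labels`, `affine`,
#'   `spacing` and the fixed `label_names` dictionary.
#' @export
label_map <- function(labels, affine = diag(4)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    abort("`labels` must be a 3-D array; got dimensions: ",
          paste(dim(labels), collapse = "x"))
  v <- as.vector(labels)
  if (anyNA(v) || any(v != round(v)))
    abort("label map voxels must be exactly integral")
  bad <- sort(unique(v[!(v %in% 0:5)]))
  if (length(bad) > 0)
    abort("label map contains labels outside {0..5}: ",
          paste(bad, collapse = ", "))
  affine <- check_affine(affine)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, affine = affine,
                 spacing = affine_spacing(affine),
                 label_names = marker_names()),
            class = "label_map")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    abort("`affine` must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-8)
    abort("`affine` last row must be (0, 0, 0, 1)")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12)
    abort("`affine` is singular; cannot map voxels to physical space")
  affine
}

# per-axis spacing = column norms of the 3x3 part
affine_spacing <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = 6L)
  cat("<label_map> ", paste(dim(x$labels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  voxels per label: ",
      paste(sprintf("%s=%d", c("bg", x$label_names), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read a CT volume from a NIfTI file
#'
#' @param path Path to a NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @return A [voxel_grid()] with the affine taken from the file header
#'   (sform/qform as resolved by RNifti) and intensities unmodified.
#' @export
read_volume <- function(path) {
  img <- read_nifti_3d(path)
  voxel_grid(unclass_nifti(img), RNifti::xform(img))
}

#' Read a marker label map from a NIfTI file
#'
#' Voxel values must be exactly integral and within `{0..5}`; anything else is
#' an error naming the offending labels.
#'
#' @inheritParams read_volume
#' @return A [label_map()].
#' @export
read_labelmap <- function(path) {
  img <- read_nifti_3d(path)
  arr <- unclass_nifti(img)
  if (any(arr != round(arr)))
    abort("label map voxels must be exactly integral: ", path)
  label_map(array(as.integer(round(arr)), dim(arr)), RNifti::xform(img))
}

read_nifti_3d <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    abort("expected 3D volume, got ", length(d), "D image: ", path)
  img
}

unclass_nifti <- function(img) {
  array(as.numeric(img), dim(img))
}

#' Write a voxel grid or label map to NIfTI
#'
#' The affine is stored as the sform (code 2) so a write/read round trip
#' preserves geometry exactly; labels are written as integers and survive
#' bit-exactly.
#'
#' @param x A [voxel_grid()] or [label_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  write_nifti_impl(x$data, x$affine, path, datatype = "double")
}

#' @rdname write_volume
#' @export
write_labelmap <- function(x, path) {
  stopifnot(inherits(x, "label_map"))
  write_nifti_impl(x$labels, x$affine, path, datatype = "int16")
}

write_nifti_impl <- function(arr, affine, path, datatype) {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort("directory does not exist: ", dir)
  if (file.access(dir, 2L) != 0L) abort("directory not writable: ", dir)
  img <- RNifti::asNifti(arr, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Map voxel indices to physical coordinates
#'
#' Applies the grid affine to 0-based voxel indices (voxel centers).
#'
#' @param index Integer triple, or an n x 3 matrix of 0-based voxel indices.
#' @param grid A [voxel_grid()] or [label_map()].
#' @param check Check that indices fall inside the array (default `TRUE`).
#' @return An n x 3 matrix of physical mm coordinates (a 1 x 3 matrix for a
#'   single triple).
#' @export
voxel_to_world <- function(index, grid, check = TRUE) {
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 3L)
  if (ncol(idx) != 3L) abort("`index` must have 3 columns")
  dims <- dim(grid$data %||% grid$labels)
  if (check && (any(idx < 0) || any(sweep(idx, 2L, dims - 1L) > 0)))
    abort("voxel index out of bounds for grid of dim ",
          paste(dims, collapse = "x"))
  out <- idx %*% t(grid$affine[1:3, 1:3])
  sweep(out, 2L, grid$affine[1:3, 4], "+")
}

#' Check the acquisition-resolution inclusion rule
#'
#' Reliable marker centroids need a resolution of at least 1 mm in each
#' dimension; this optional validator flags grids whose spacing exceeds the
#' cutoff on any axis. It is not enforced on load.
#'
#' @param grid A [voxel_grid()] or [label_map()].
#' @param max_spacing Per-axis spacing cutoff in mm (default 1).
#' @return `TRUE` if all spacing components are `<= max_spacing`.
#' @export
check_resolution <- function(grid, max_spacing = 1.0) {
  all(grid$spacing <= max_spacing + 1e-9)
}

#' Write the marker label dictionary as a JSON sidecar
#'
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_label_dictionary <- function(path) {
  jsonlite::write_json(as.list(marker_names()), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
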