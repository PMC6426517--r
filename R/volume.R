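#' CT volume in Hounsfield units
#'
#' A `ct_volume` is a 3D scalar grid of CT numbers (HU) together with its
#' geometry: per-axis voxel spacing in mm and the world coordinate of the
#' center of voxel (1,1,1). The fixed patient coordinate convention used
#' throughout the package is: x = patient-left positive, y = patient-posterior
#' positive, z = patient-superior positive; world units are mm; voxel extents
#' are half-open around each center.
#'
#' @param voxels 3D numeric array of HU values (finite).
#' @param spacing numeric length 3, voxel size in mm per axis (all > 0).
#' @param origin numeric length 3, world position (mm) of the center of the
#'   first voxel.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("ct_volume: voxels must be a rank-3 array, got rank ", length(dim(voxels)))
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: spacing must be three strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("ct_volume: origin must be three finite values")
  if (any(!is.finite(voxels)))
    stop("ct_volume: HU values must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' Binary structure mask on a CT grid
#'
#' @param voxels 3D logical (or 0/1) array on the same grid as its parent CT.
#' @param spacing,origin grid geometry, as in [ct_volume()].
#' @param label structure name.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(voxels, spacing, origin = c(0, 0, 0), label = "structure") {
  if (length(dim(voxels)) != 3L)
    stop("structure_mask: voxels must be a rank-3 array")
  storage.mode(voxels) <- "logical"
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (any(spacing <= 0)) stop("structure_mask: spacing must be positive")
  structure(list(voxels = voxels, spacing = spacing, origin = origin, label = label),
            class = "structure_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm; HU range [%.0f, %.0f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Structure mask '%s': %d x %d x %d voxels, %d set (%.1f cc)\n",
              x$label, d[1], d[2], d[3], sum(x$voxels),
              sum(x$voxels) * prod(x$spacing) / 1000))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Convert world coordinates (mm) to fractional 0-based voxel indices
#'
#' The mapping is `(p - origin) / spacing` per axis, with no rounding, so it is
#' the exact inverse of [voxel_to_world()]. Out-of-grid positions are returned
#' as-is; the caller clips.
#'
#' @param volume a `ct_volume` or `structure_mask` (grid carrier).
#' @param p numeric length 3 world point, or an n x 3 matrix of points.
#' @return fractional 0-based voxel indices, same shape as `p`.
#' @export
world_to_voxel <- function(volume, p) {
  if (is.matrix(p)) {
    sweep(sweep(p, 2, volume$origin, "-"), 2, volume$spacing, "/")
  } else {
    (as.numeric(p) - volume$origin) / volume$spacing
  }
}

#' @rdname world_to_voxel
#' @param idx fractional 0-based voxel indices (length 3 or n x 3 matrix).
#' @export
voxel_to_world <- function(volume, idx) {
  if (is.matrix(idx)) {
    sweep(sweep(idx, 2, volume$spacing, "*"), 2, volume$origin, "+")
  } else {
    volume$origin + as.numeric(idx) * volume$spacing
  }
}

# nearest (1-based) voxel index for a world point, clipped to the grid
nearest_voxel <- function(volume, p) {
  idx <- round(world_to_voxel(volume, p)) + 1
  pmin(pmax(idx, 1), dim(volume$voxels))
}

#' Read a volumetric image from NIfTI
#'
#' Reads a NIfTI-1 file written by [save_volume()] or another tool. The grid
#' affine must be axis-aligned with positive scales (oblique orientations are
#' out of scope); intensities are interpreted as HU, unscaled.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("load_volume: file not found: ", path)
  img <- RNifti::readNifti(path, internal = FALSE)
  d <- dim(img)
  if (length(d) != 3L)
    stop("load_volume: expected a rank-3 volume, got rank ", length(d))
  hdr <- RNifti::niftiHeader(img)
  if (hdr$sform_code > 0) {
    aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
    rot <- aff[1:3, 1:3]
    if (max(abs(rot - diag(diag(rot)))) > 1e-4)
      stop("load_volume: oblique orientation not supported")
    spacing <- diag(rot)
    origin <- aff[1:3, 4]
  } else {
    spacing <- hdr$pixdim[2:4]
    origin <- c(0, 0, 0)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("load_volume: missing or invalid spacing metadata (pixdim/sform)")
  vox <- array(as.numeric(img), dim = d)
  ct_volume(vox, spacing = spacing, origin = origin)
}

#' Write a volume or mask to NIfTI
#'
#' CT volumes are stored as signed 16-bit HU; masks as unsigned 8-bit 0/1.
#' The grid geometry goes into the sform (diagonal affine, code 2) and pixdim,
#' so `load_volume(save_volume(v, f))` round-trips voxels, spacing and origin
#' exactly.
#'
#' @param volume a [ct_volume()] or [structure_mask()].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  if (!dir.exists(dirname(path)))
    stop("save_volume: directory does not exist: ", dirname(path))
  is_mask <- inherits(volume, "structure_mask")
  arr <- volume$voxels
  if (is_mask) {
    arr <- array(as.integer(arr), dim = dim(arr))
  } else {
    arr <- array(as.integer(round(arr)), dim = dim(arr))
  }
  img <- RNifti::asNifti(structure(arr, pixdim = volume$spacing))
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "int16")
  invisible(path)
}

#' @rdname save_volume
#' @param label structure name to attach to the loaded mask.
#' @export
load_mask <- function(path, label = "structure") {
  v <- load_volume(path)
  structure_mask(v$voxels != 0, spacing = v$spacing, origin = v$origin, label = label)
}
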