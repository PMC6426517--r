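#' Detect the treatment couch
#'
#' Computes, for each anteroposterior row (y), the sum over x and z of voxels
#' above the couch-material HU threshold, then scans from the posterior edge of
#' the grid anteriorly for the first contiguous run of occupied rows that is
#' slab-like: anteroposteriorly thin (run thickness below `max_thickness_mm`)
#' and laterally wide (at least `min_width_frac` of the widest occupied row in
#' the volume). The gating prevents locking onto the posterior body wall, which
#' forms a much thicker run. Absence of a qualifying run is signaled with
#' `found = FALSE`, not an error.
#'
#' @param volume a [ct_volume()].
#' @param couch_hu_threshold HU above which a voxel counts as couch material
#'   (default -500; couch shells and body tissue both exceed it, air does not).
#' @param max_thickness_mm maximum anteroposterior thickness of a couch slab.
#' @param min_width_frac minimum lateral width relative to the widest row.
#' @return list with `found`, `couch_top_row` (1-based y row of the couch
#'   anterior surface) and `peak_score` (occupied fraction of the peak row).
#' @export
detect_couch <- function(volume, couch_hu_threshold = -500,
                         max_thickness_mm = 30, min_width_frac = 0.5) {
  d <- dim(volume$voxels)
  above <- volume$voxels >= couch_hu_threshold
  cnt <- apply(above, 2, sum)
  # lateral width per row: extent of occupied x columns
  width <- vapply(seq_len(d[2]), function(j) {
    xs <- which(apply(above[, j, , drop = FALSE], 1, any))
    if (length(xs) == 0L) 0L else diff(range(xs)) + 1L
  }, integer(1))
  max_width <- max(width)
  occ <- cnt > 0L
  if (!any(occ) || max_width == 0L)
    return(list(found = FALSE, couch_top_row = NA_integer_, peak_score = 0))
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  for (ri in rev(runs)) {  # posterior -> anterior
    j0 <- starts[ri]; j1 <- ends[ri]
    thick <- (j1 - j0 + 1L) * volume$spacing[2]
    wide <- max(width[j0:j1]) >= min_width_frac * max_width
    if (thick <= max_thickness_mm && wide) {
      return(list(found = TRUE, couch_top_row = j0,
                  peak_score = max(cnt[j0:j1]) / (d[1] * d[3])))
    }
  }
  list(found = FALSE, couch_top_row = NA_integer_, peak_score = 0)
}

#' Remove the couch from a CT volume
#'
#' Sets every voxel posterior to (and including) the detected couch top row to
#' the CT number of air (-1000 HU). If the detection reported `found = FALSE`
#' the volume is returned unchanged.
#'
#' @param volume a [ct_volume()].
#' @param couch result of [detect_couch()].
#' @return a [ct_volume()].
#' @export
remove_couch <- function(volume, couch) {
  if (!isTRUE(couch$found)) return(volume)
  j <- couch$couch_top_row
  v <- volume$voxels
  v[, j:dim(v)[2], ] <- -1000
  ct_volume(v, volume$spacing, volume$origin)
}

#' Delineate the external body contour
#'
#' Thresholds the (couch-removed) CT into a binary mask, keeps the largest
#' 26-connected component, fills internal cavities so gas pockets stay inside
#' the body, and smooths the surface with a morphological closing followed by
#' an opening using a Euclidean ball of `smooth_radius_mm`. The final mask is
#' again reduced to its largest component and re-filled so that the result is
#' guaranteed to be a single, hole-free component.
#'
#' @param volume a [ct_volume()] (couch already removed; see [remove_couch()]).
#' @param body_hu_threshold HU threshold separating body from air.
#' @param smooth_radius_mm structuring-element radius for the smoothing.
#' @param hole_fill `"3d"` (default), `"2d"` (slice-wise) or `"both"`.
#' @return a [structure_mask()] labeled `"body"`.
#' @export
segment_body <- function(volume, body_hu_threshold = -300,
                         smooth_radius_mm = 3, hole_fill = "3d") {
  bin <- volume$voxels >= body_hu_threshold
  if (!any(bin))
    stop("segment_body: segmentation failed, threshold mask is empty")
  m <- largest_component(bin, 26L)
  m <- fill_holes(m, hole_fill)
  if (smooth_radius_mm > 0) {
    se <- ball_offsets(smooth_radius_mm, volume$spacing)
    m <- mask_open(mask_close(m, se), se)
  }
  m <- largest_component(m, 26L)
  m <- fill_holes(m, hole_fill)
  structure_mask(m, volume$spacing, volume$origin, "body")
}
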