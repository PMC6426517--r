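#' Build the fiducial search domain (body-surface shell)
#'
#' Returns the shell of voxels whose center lies within `bandwidth_mm` of the
#' body surface, on both sides: background voxels within the bandwidth of a
#' body voxel center, and body voxels within the bandwidth of a background
#' voxel center. Skin fiducials always fall in this shell; dense structures
#' deep inside the body (bone, contrast) do not.
#'
#' @param volume a [ct_volume()] (grid carrier; intensities unused).
#' @param body body [structure_mask()].
#' @param bandwidth_mm half-width of the shell (default 10 mm).
#' @return a [structure_mask()] labeled `"search_domain"`.
#' @export
build_search_domain <- function(volume, body, bandwidth_mm = 10) {
  arr <- body$voxels
  if (!any(arr)) stop("build_search_domain: body mask is empty")
  d <- dim(arr)
  se <- ball_offsets(bandwidth_mm, body$spacing)
  near_body <- array(.dilate_seeds(.boundary_voxels(arr, d, FALSE), se, d), d)
  near_bg <- array(.dilate_seeds(.boundary_voxels(!arr, d, FALSE), se, d), d)
  shell <- (near_body & !arr) | (near_bg & arr)
  structure_mask(shell, body$spacing, body$origin, "search_domain")
}

#' Find fiducial candidates by CT number within the search domain
#'
#' Connected components (26-connectivity) of voxels at or above the fiducial
#' HU threshold, restricted to the search domain. Each component yields an
#' intensity-weighted centroid in world mm, its voxel count and mean HU, and
#' (when `body` is supplied) the distance from the centroid to the nearest
#' body-boundary voxel center.
#'
#' @param volume a [ct_volume()].
#' @param domain search-domain [structure_mask()] from [build_search_domain()].
#' @param fiducial_hu_threshold HU threshold for radiopaque material.
#' @param body optional body mask for the `surface_distance` column.
#' @return data.frame with columns `x, y, z, voxel_count, mean_hu,
#'   surface_distance, role` (possibly zero rows).
#' @export
find_fiducial_candidates <- function(volume, domain, fiducial_hu_threshold = 800,
                                     body = NULL) {
  m <- (volume$voxels >= fiducial_hu_threshold) & domain$voxels
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      voxel_count = integer(0), mean_hu = numeric(0),
                      surface_distance = numeric(0), role = character(0))
  if (!any(m)) return(empty)
  lab <- label_components(m, 26L)
  ncomp <- max(lab)
  idx <- which(lab > 0L)
  ai <- arrayInd(idx, dim(m))
  labs <- lab[idx]
  w <- volume$voxels[idx]
  world <- voxel_to_world(volume, cbind(ai[, 1] - 1, ai[, 2] - 1, ai[, 3] - 1))
  out <- do.call(rbind, lapply(seq_len(ncomp), function(g) {
    sel <- labs == g
    wt <- w[sel]
    ctr <- colSums(world[sel, , drop = FALSE] * wt) / sum(wt)
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
               voxel_count = sum(sel), mean_hu = mean(wt),
               surface_distance = NA_real_, role = "unassigned",
               stringsAsFactors = FALSE)
  }))
  if (!is.null(body)) {
    bidx <- boundary_index_matrix(body$voxels)
    bw <- voxel_to_world(body, bidx)
    for (r in seq_len(nrow(out))) {
      dv <- sweep(bw, 2, c(out$x[r], out$y[r], out$z[r]), "-")
      out$surface_distance[r] <- sqrt(min(rowSums(dv^2)))
    }
  }
  out
}

# geometric inconsistency of a candidate triple under roles
# (anterior = most anterior; laterals = the other two, left = larger x):
# laterals should agree in y and all three in z, and the anterior mark should
# sit laterally centered between the laterals.
triple_score <- function(cand) {
  o <- order(cand$y)
  ant <- cand[o[1], ]
  lat <- cand[o[2:3], ]
  left <- lat[which.max(lat$x), ]
  right <- lat[which.min(lat$x), ]
  zspread <- max(cand$z) - min(cand$z)
  list(score = abs(left$y - right$y) + zspread +
         abs(ant$x - (left$x + right$x) / 2),
       roles = c(anterior = o[1],
                 left_lateral = o[if (lat$x[1] >= lat$x[2]) 2 else 3],
                 right_lateral = o[if (lat$x[1] >= lat$x[2]) 3 else 2]),
       residual = max(abs(left$y - right$y), zspread))
}

#' Filter fiducial candidates down to the best triple
#'
#' Removes components outside the size bounds, then enumerates every remaining
#' triple, assigns roles by position (the most anterior candidate is the
#' anterior mark; of the other two, patient-left is `left_lateral`), and scores
#' each triple's geometric inconsistency: disagreement of the laterals in y,
#' spread of all three in z, and lateral off-centering of the anterior mark.
#' The lowest-score triple wins; ties break by larger total voxel count, then
#' smaller residual.
#'
#' @param candidates data.frame from [find_fiducial_candidates()].
#' @param body body mask (unused by the default criteria but part of the
#'   interface for location-based filters).
#' @param size_min_vox,size_max_vox component size bounds in voxels.
#' @return three-row data.frame with `role` set to `anterior`, `left_lateral`,
#'   `right_lateral`.
#' @export
filter_candidates <- function(candidates, body = NULL,
                              size_min_vox = 1, size_max_vox = 200) {
  n0 <- nrow(candidates)
  keep <- candidates$voxel_count >= size_min_vox &
    candidates$voxel_count <= size_max_vox
  cand <- candidates[keep, , drop = FALSE]
  if (nrow(cand) < 3)
    stop(sprintf(paste0("filter_candidates: detection failed, %d candidate(s) ",
                        "remain after size filtering (started with %d; ",
                        "%d removed by size bounds [%g, %g])"),
                 nrow(cand), n0, n0 - nrow(cand), size_min_vox, size_max_vox))
  combs <- utils::combn(nrow(cand), 3)
  best <- NULL
  for (ci in seq_len(ncol(combs))) {
    tri <- cand[combs[, ci], , drop = FALSE]
    sc <- triple_score(tri)
    sc$rows <- combs[, ci]
    sc$total_vox <- sum(tri$voxel_count)
    better <- is.null(best) ||
      sc$score < best$score - 1e-12 ||
      (abs(sc$score - best$score) <= 1e-12 &&
         (sc$total_vox > best$total_vox ||
            (sc$total_vox == best$total_vox && sc$residual < best$residual)))
    if (better) best <- sc
  }
  out <- cand[best$rows, , drop = FALSE]
  roles <- character(3)
  roles[best$roles] <- names(best$roles)
  out$role <- roles
  rownames(out) <- NULL
  out[order(match(out$role, c("anterior", "left_lateral", "right_lateral"))), ]
}

#' Combine three fiducials into the marked isocenter
#'
#' Skin marks constrain exactly these axes: the anterior fiducial fixes x, the
#' two laterals fix y (averaged), and all three fix z (averaged). The residual
#' is the maximum per-axis spread among the contributing fiducials' implied
#' values, so the adjacent-slice failure mode (fiducials not on one axial
#' slice) is observable rather than silent.
#'
#' @param fiducials three-row data.frame with distinct roles as produced by
#'   [filter_candidates()].
#' @return list with `isocenter` (world mm), `fiducials`, `residual` (mm).
#' @export
compute_isocenter <- function(fiducials) {
  if (nrow(fiducials) != 3 ||
      !setequal(fiducials$role, c("anterior", "left_lateral", "right_lateral")))
    stop("compute_isocenter: need exactly one fiducial per role")
  ant <- fiducials[fiducials$role == "anterior", ]
  ll <- fiducials[fiducials$role == "left_lateral", ]
  rl <- fiducials[fiducials$role == "right_lateral", ]
  iso <- c(ant$x, mean(c(ll$y, rl$y)), mean(fiducials$z))
  residual <- max(abs(ll$y - rl$y), max(fiducials$z) - min(fiducials$z))
  list(isocenter = iso, fiducials = fiducials, residual = residual)
}

#' Detect the marked isocenter from a CT volume and body mask
#'
#' Convenience wrapper chaining [build_search_domain()],
#' [find_fiducial_candidates()], [filter_candidates()] and
#' [compute_isocenter()].
#'
#' @param volume a [ct_volume()].
#' @param body body [structure_mask()].
#' @param bandwidth_mm search-domain half-width.
#' @param fiducial_hu_threshold HU threshold for fiducial material.
#' @param size_min_vox,size_max_vox candidate size bounds.
#' @return see [compute_isocenter()].
#' @export
detect_isocenter <- function(volume, body, bandwidth_mm = 10,
                             fiducial_hu_threshold = 800,
                             size_min_vox = 1, size_max_vox = 200) {
  domain <- build_search_domain(volume, body, bandwidth_mm)
  cand <- find_fiducial_candidates(volume, domain, fiducial_hu_threshold, body)
  if (nrow(cand) < 3)
    stop("detect_isocenter: detection failed, only ", nrow(cand),
         " fiducial candidate(s) found in the search domain")
  sel <- filter_candidates(cand, body, size_min_vox, size_max_vox)
  compute_isocenter(sel)
}
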