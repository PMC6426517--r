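# Internal voxel-mask machinery shared by all pipeline stages. Masks are plain
# logical 3D arrays here; the exported API wraps them in structure_mask objects.

# structuring-element offsets for a Euclidean ball of radius r_mm
ball_offsets <- function(r_mm, spacing) {
  ni <- floor(r_mm / spacing)
  g <- expand.grid(di = -ni[1]:ni[1], dj = -ni[2]:ni[2], dk = -ni[3]:ni[3])
  d2 <- (g$di * spacing[1])^2 + (g$dj * spacing[2])^2 + (g$dk * spacing[3])^2
  m <- as.matrix(g[d2 <= r_mm^2 + 1e-9, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

mask_dilate <- function(arr, offsets) {
  bd <- .boundary_voxels(arr, dim(arr), FALSE)
  out <- arr | array(.dilate_seeds(bd, offsets, dim(arr)), dim(arr))
  out
}

# erosion treats the grid border as inside (a mask clipped by the grid is not
# eaten away at the clip plane)
mask_erode <- function(arr, offsets) {
  bd <- .boundary_voxels(!arr, dim(arr), FALSE)
  arr & !array(.dilate_seeds(bd, offsets, dim(arr)), dim(arr))
}

mask_close <- function(arr, offsets) mask_erode(mask_dilate(arr, offsets), offsets)
mask_open <- function(arr, offsets) mask_dilate(mask_erode(arr, offsets), offsets)

label_components <- function(arr, connectivity = 26L) {
  lab <- .cc_label_3d(arr, dim(arr), as.integer(connectivity))
  array(lab, dim(arr))
}

largest_component <- function(arr, connectivity = 26L) {
  lab <- label_components(arr, connectivity)
  n <- max(lab)
  if (n == 0L) return(array(FALSE, dim(arr)))
  tab <- tabulate(lab[lab > 0L], nbins = n)
  lab == which.max(tab)
}

# fill enclosed background cavities; mode "3d" labels the 3D background
# (6-connected) and fills components not reaching the grid border, "2d" does
# the same slice by slice (4-connected in-plane), "both" applies 2d then 3d.
fill_holes <- function(arr, mode = c("3d", "2d", "both")) {
  mode <- match.arg(mode)
  fill3 <- function(a) {
    lab <- label_components(!a, 6L)
    border <- unique(c(lab[1, , ], lab[dim(a)[1], , ],
                       lab[, 1, ], lab[, dim(a)[2], ],
                       lab[, , 1], lab[, , dim(a)[3]]))
    border <- border[border > 0L]
    a | !(lab == 0L | array(lab %in% border, dim(a)))
  }
  fill2 <- function(a) {
    for (k in seq_len(dim(a)[3])) {
      sl <- array(a[, , k], c(dim(a)[1:2], 1L))
      lab <- label_components(!sl, 6L)  # 4-connected in-plane
      border <- unique(c(lab[1, , 1], lab[dim(a)[1], , 1],
                         lab[, 1, 1], lab[, dim(a)[2], 1]))
      border <- border[border > 0L]
      a[, , k] <- sl[, , 1] | (lab[, , 1] > 0L & !(lab[, , 1] %in% border))
    }
    a
  }
  switch(mode, "3d" = fill3(arr), "2d" = fill2(arr), "both" = fill3(fill2(arr)))
}

boundary_index_matrix <- function(arr) {
  bd <- .boundary_voxels(arr, dim(arr), TRUE)
  if (length(bd) == 0L) return(matrix(integer(0), 0, 3))
  d <- dim(arr)
  i <- bd %% d[1]
  j <- (bd %/% d[1]) %% d[2]
  k <- bd %/% (d[1] * d[2])
  m <- cbind(i, j, k)
  storage.mode(m) <- "integer"
  m
}

#' Compare two structure masks (Dice, mean surface distance, Hausdorff)
#'
#' Dice is `2|A n B| / (|A| + |B|)`. Surface distances are computed between the
#' center points of boundary voxels (mask voxels with at least one face-adjacent
#' background neighbor; the grid border counts as background), in mm. The mean
#' surface distance is the average of the two directed means; the Hausdorff
#' distance is the maximum of the two directed maxima (or of the two directed
#' percentiles if `hausdorff_pct < 100`).
#'
#' @param a,b [structure_mask()] objects on the same grid.
#' @param hausdorff_pct percentile of the directed distance distributions used
#'   for the Hausdorff statistic; 100 (default) is the strict Hausdorff.
#' @return list with elements `dice`, `mean_surface_distance`, `hausdorff` (mm).
#'   If exactly one mask is empty, `dice` is 0 and the distances are `NA` (with
#'   a warning); two empty masks are an error.
#' @export
compare_masks <- function(a, b, hausdorff_pct = 100) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  if (!same_grid(a, b)) stop("compare_masks: masks are not on the same grid")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na == 0L && nb == 0L) stop("compare_masks: both masks empty; metrics undefined")
  if (na == 0L || nb == 0L) {
    warning("compare_masks: one mask empty; surface distances undefined")
    return(list(dice = 0, mean_surface_distance = NA_real_, hausdorff = NA_real_))
  }
  dice <- 2 * sum(a$voxels & b$voxels) / (na + nb)
  ia <- boundary_index_matrix(a$voxels)
  ib <- boundary_index_matrix(b$voxels)
  occ_a <- array(FALSE, dim(a$voxels)); occ_a[ia + 1L] <- TRUE
  occ_b <- array(FALSE, dim(b$voxels)); occ_b[ib + 1L] <- TRUE
  dab <- .surface_dist_directed(ia, occ_b, dim(a$voxels), a$spacing)
  dba <- .surface_dist_directed(ib, occ_a, dim(a$voxels), a$spacing)
  msd <- (mean(dab) + mean(dba)) / 2
  if (hausdorff_pct >= 100) {
    hd <- max(max(dab), max(dba))
  } else {
    q <- hausdorff_pct / 100
    hd <- max(stats::quantile(dab, q, names = FALSE),
              stats::quantile(dba, q, names = FALSE))
  }
  list(dice = dice, mean_surface_distance = msd, hausdorff = hd)
}
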