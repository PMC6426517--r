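#' Segment surrogate bony anatomy by threshold and geometric rules
#'
#' Thresholds HU inside the body and labels the resulting 26-connected
#' components with geometric rules: the two most lateral components are the
#' femoral heads, the largest midline component is the bony pelvis ring,
#' components well superior to the ring's center of mass are vertebral bodies
#' (topmost = L4, next = L5), and the most posterior remaining midline
#' component is the sacrum. A single fused vertebral component is split at an
#' interior waist minimum of its axial cross-section profile; if no waist
#' exists a partial-labeling warning is recorded (and raised), emulating the
#' vertebral mis-segmentation failure mode that shifts superior field borders.
#'
#' Alternatively a ground-truth label map can be passed through unchanged for
#' pipeline testing (`truth` argument).
#'
#' @param volume a [ct_volume()].
#' @param body body [structure_mask()].
#' @param bone_hu_threshold HU threshold for bone (default 200).
#' @param truth optional labeled array to pass through unchanged.
#' @param min_volume_mm3 components smaller than this are discarded as specks.
#' @param lateral_offset_mm minimum lateral centroid offset for femoral heads.
#' @param vertebral_offset_mm minimum superior centroid offset (vs the ring)
#'   for vertebral components.
#' @return object of class `bone_label_map`: list with `labels` (integer array,
#'   codes per [bone_labels()]), `warnings` (character), and the grid geometry.
#' @export
segment_bones <- function(volume, body, bone_hu_threshold = 200, truth = NULL,
                          min_volume_mm3 = 1500, lateral_offset_mm = 60,
                          vertebral_offset_mm = 60) {
  if (!is.null(truth)) {
    labs <- if (is.list(truth)) truth$labels else truth
    return(structure(list(labels = labs, warnings = character(0),
                          spacing = volume$spacing, origin = volume$origin),
                     class = "bone_label_map"))
  }
  if (!any(body$voxels)) stop("segment_bones: body mask is empty")
  m <- (volume$voxels >= bone_hu_threshold) & body$voxels
  if (!any(m)) stop("segment_bones: no bone voxels above threshold")
  lab <- label_components(m, 26L)
  ncomp <- max(lab)
  voxvol <- prod(volume$spacing)
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  keep <- which(sizes * voxvol >= min_volume_mm3)
  if (length(keep) == 0L) stop("segment_bones: no bone component above minimum volume")

  idx <- which(lab > 0L & array(lab %in% keep, dim(lab)))
  ai <- arrayInd(idx, dim(lab))
  world <- voxel_to_world(volume, cbind(ai[, 1] - 1, ai[, 2] - 1, ai[, 3] - 1))
  labs_at <- lab[idx]
  cent <- t(vapply(keep, function(g) colMeans(world[labs_at == g, , drop = FALSE]),
                   numeric(3)))
  comp <- data.frame(id = keep, size = sizes[keep],
                     cx = cent[, 1], cy = cent[, 2], cz = cent[, 3])

  bidx <- which(body$voxels)
  bx <- voxel_to_world(volume, cbind(arrayInd(bidx, dim(lab))[, 1] - 1, 0, 0))[, 1]
  body_cx <- mean(bx)

  lb <- bone_labels()
  warnings <- character(0)
  assign_id <- integer(0)  # per component: assigned label code, 0 = unassigned
  code <- stats::setNames(rep(0L, nrow(comp)), comp$id)

  dx <- comp$cx - body_cx
  lat <- abs(dx) >= lateral_offset_mm
  left <- which(lat & dx > 0); right <- which(lat & dx < 0)
  if (length(left)) code[left[which.max(comp$size[left])]] <- lb[["femoral_head_L"]]
  if (length(right)) code[right[which.max(comp$size[right])]] <- lb[["femoral_head_R"]]

  mid <- which(!lat)
  if (length(mid) == 0L) stop("segment_bones: no midline bone component found")
  ring <- mid[which.max(comp$size[mid])]
  code[ring] <- lb[["bony_pelvis"]]

  rest <- setdiff(mid, ring)
  vert <- rest[comp$cz[rest] - comp$cz[ring] >= vertebral_offset_mm]
  rest <- setdiff(rest, vert)
  if (length(rest)) {
    sac <- rest[which.max(comp$cy[rest])]
    code[sac] <- lb[["sacrum"]]
  } else {
    warnings <- c(warnings, "sacrum: no posterior midline component found")
  }

  out <- array(0L, dim(lab))
  for (r in seq_len(nrow(comp)))
    if (code[r] > 0L) out[lab == comp$id[r]] <- code[r]

  if (length(vert) >= 2) {
    o <- vert[order(comp$cz[vert], decreasing = TRUE)]
    out[lab == comp$id[o[1]]] <- lb[["L4"]]
    out[lab == comp$id[o[2]]] <- lb[["L5"]]
    if (length(vert) > 2)
      warnings <- c(warnings, "vertebrae: more than two vertebral components; extras ignored")
  } else if (length(vert) == 1) {
    vid <- comp$id[vert]
    vm <- lab == vid
    prof <- apply(vm, 3, sum)
    kz <- which(prof > 0)
    interior <- kz[kz > min(kz) & kz < max(kz)]
    split_k <- NA_integer_
    if (length(interior)) {
      pm <- interior[which.min(prof[interior])]
      if (prof[pm] <= 0.5 * stats::median(prof[kz])) split_k <- pm
    }
    if (!is.na(split_k)) {
      sel_up <- vm; sel_up[, , seq_len(split_k)] <- FALSE
      sel_lo <- vm; sel_lo[, , split_k:dim(vm)[3]] <- FALSE
      out[sel_up] <- lb[["L4"]]
      out[sel_lo] <- lb[["L5"]]
      out[vm & !(sel_up | sel_lo)] <- lb[["L5"]]
    } else {
      out[vm] <- lb[["L5"]]
      warnings <- c(warnings,
                    "vertebrae: single fused vertebral component, no waist to split at; partial labeling (L4 missing)")
    }
  } else {
    warnings <- c(warnings, "vertebrae: fewer than two vertebral components; partial labeling")
  }

  if (length(warnings)) warning(paste(warnings, collapse = "; "))
  structure(list(labels = out, warnings = warnings,
                 spacing = volume$spacing, origin = volume$origin),
            class = "bone_label_map")
}

#' Extract one labeled bone as a structure mask
#'
#' @param bones a `bone_label_map` (or truth `$bones` array plus grid info via
#'   `spacing`/`origin`).
#' @param name structure name, one of `names(bone_labels())`.
#' @param spacing,origin grid geometry if `bones` is a bare array.
#' @return a [structure_mask()].
#' @export
bone_mask <- function(bones, name, spacing = NULL, origin = NULL) {
  lb <- bone_labels()
  if (!name %in% names(lb)) stop("bone_mask: unknown structure ", name)
  if (inherits(bones, "bone_label_map")) {
    arr <- bones$labels == lb[[name]]
    structure_mask(arr, bones$spacing, bones$origin, name)
  } else {
    structure_mask(bones == lb[[name]], spacing, origin, name)
  }
}
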