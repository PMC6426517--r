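#' Beam geometry for the four-field box
#'
#' Gantry convention (IEC, head-first supine): 0 = anteroposterior (source
#' anterior), 180 = posteroanterior, 90 = left lateral (source at the
#' patient's left), 270 = right lateral. All four beams are coplanar and share
#' one isocenter. The beam's-eye-view axes are `v` = patient-superior and
#' `u = axis x v` so that in the AP view patient-left is +u; opposed beams have
#' mirrored u, as seen from their source.
#'
#' @param name one of `"AP"`, `"PA"`, `"LL"`, `"RL"`.
#' @param isocenter world point (mm).
#' @param sad source-axis distance in mm (default 1000).
#' @return list of class `beam_geometry` with `name`, `gantry_angle`,
#'   `isocenter`, `sad`, `source`, and unit vectors `axis`, `e_u`, `e_v`.
#' @export
beam_geometry <- function(name = c("AP", "PA", "LL", "RL"),
                          isocenter, sad = 1000) {
  name <- match.arg(name)
  stopifnot(sad > 0, length(isocenter) == 3, all(is.finite(isocenter)))
  angle <- c(AP = 0, PA = 180, LL = 90, RL = 270)[[name]]
  th <- angle * pi / 180
  source <- isocenter + sad * c(sin(th), -cos(th), 0)
  axis <- c(-sin(th), cos(th), 0)           # unit, source -> isocenter
  e_v <- c(0, 0, 1)
  e_u <- c(axis[2] * e_v[3] - axis[3] * e_v[2],
           axis[3] * e_v[1] - axis[1] * e_v[3],
           axis[1] * e_v[2] - axis[2] * e_v[1])  # axis x e_v
  structure(list(name = name, gantry_angle = angle, isocenter = isocenter,
                 sad = sad, source = source, axis = axis, e_u = e_u, e_v = e_v),
            class = "beam_geometry")
}

#' @rdname beam_geometry
#' @export
four_beams <- function(isocenter, sad = 1000) {
  stats::setNames(lapply(c("AP", "PA", "LL", "RL"), beam_geometry,
                         isocenter = isocenter, sad = sad),
                  c("AP", "PA", "LL", "RL"))
}

# divergent projection of world points onto the isocenter plane of a beam;
# returns u, v in mm (isocenter-plane scale)
project_points <- function(points, beam) {
  w <- sweep(points, 2, beam$source, "-")
  ta <- w %*% beam$axis
  f <- beam$sad / as.numeric(ta)
  q <- sweep(w * f, 2, beam$source, "+")
  rel <- sweep(q, 2, beam$isocenter, "-")
  cbind(u = as.numeric(rel %*% beam$e_u), v = as.numeric(rel %*% beam$e_v))
}

#' Project a structure mask into a beam's eye view
#'
#' Perspective (divergent) projection from the beam's point source through
#' every mask voxel onto the isocenter plane perpendicular to the beam axis.
#' Each voxel contributes its projected footprint (the voxel extent, magnified
#' by the similar-triangles factor of its depth plane, centered on the
#' projection of the voxel center); a BEV pixel is set iff at least one
#' voxel's footprint overlaps it, so silhouettes stay gap-free even when the
#' slice spacing exceeds the BEV pixel size. A point at the isocenter plane
#' projects at unit magnification; a point 100 mm upstream projects magnified
#' by SAD/(SAD-100).
#'
#' @param mask a nonempty [structure_mask()].
#' @param beam a [beam_geometry()].
#' @param pixel_mm BEV pixel size in isocenter-plane mm.
#' @param pad_mm margin added around the projected extent.
#' @return object of class `bev_image`: list with the logical pixel matrix
#'   `img` (rows = u, cols = v), `u0`, `v0` (world of pixel (1,1) center),
#'   `pixel_mm`, `label` and `beam`.
#' @export
project_to_bev <- function(mask, beam, pixel_mm = 1.5, pad_mm = 9) {
  idx <- which(mask$voxels)
  if (length(idx) == 0L) stop("project_to_bev: mask '", mask$label, "' is empty")
  ai <- arrayInd(idx, dim(mask$voxels))
  pts <- voxel_to_world(mask, cbind(ai[, 1] - 1, ai[, 2] - 1, ai[, 3] - 1))
  w <- sweep(pts, 2, beam$source, "-")
  f <- beam$sad / as.numeric(w %*% beam$axis)   # per-voxel magnification
  uv <- project_points(pts, beam)
  # half-footprint of the voxel box along u and v (support function of the
  # axis-aligned box), magnified at the voxel's depth plane
  hu <- f * sum(abs(beam$e_u) * mask$spacing) / 2
  hv <- f * sum(abs(beam$e_v) * mask$spacing) / 2
  u_lo <- uv[, 1] - hu; u_hi <- uv[, 1] + hu
  v_lo <- uv[, 2] - hv; v_hi <- uv[, 2] + hv
  u0 <- floor((min(u_lo) - pad_mm) / pixel_mm) * pixel_mm
  v0 <- floor((min(v_lo) - pad_mm) / pixel_mm) * pixel_mm
  nu <- as.integer(ceiling((max(u_hi) + pad_mm - u0) / pixel_mm) + 1)
  nv <- as.integer(ceiling((max(v_hi) + pad_mm - v0) / pixel_mm) + 1)
  iu_lo <- pmin(pmax(floor((u_lo - u0) / pixel_mm) + 1L, 1L), nu)
  iu_hi <- pmin(pmax(floor((u_hi - u0) / pixel_mm) + 1L, 1L), nu)
  iv_lo <- pmin(pmax(floor((v_lo - v0) / pixel_mm) + 1L, 1L), nv)
  iv_hi <- pmin(pmax(floor((v_hi - v0) / pixel_mm) + 1L, 1L), nv)
  img <- matrix(FALSE, nu, nv)
  for (a in 0:max(iu_hi - iu_lo)) {
    iua <- pmin(iu_lo + a, iu_hi)
    for (b in 0:max(iv_hi - iv_lo)) {
      img[cbind(iua, pmin(iv_lo + b, iv_hi))] <- TRUE
    }
  }
  structure(list(img = img, u0 = u0, v0 = v0, pixel_mm = pixel_mm,
                 label = mask$label, beam = beam),
            class = "bev_image")
}

# pixel-center coordinates of set (or specified) pixels of a bev_image
bev_pixel_centers <- function(bev, which_idx = NULL) {
  if (is.null(which_idx)) which_idx <- which(bev$img)
  ai <- arrayInd(which_idx, dim(bev$img))
  cbind(u = bev$u0 + (ai[, 1] - 0.5) * bev$pixel_mm,
        v = bev$v0 + (ai[, 2] - 0.5) * bev$pixel_mm)
}

# enclosed background regions (holes) of a BEV silhouette: background
# components (4-connected) that do not touch the image border
bev_holes <- function(bev) {
  a <- array(!bev$img, c(dim(bev$img), 1L))
  lab <- label_components(a, 6L)[, , 1]
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  ids <- setdiff(unique(lab[lab > 0L]), border)
  lapply(ids, function(g) which(lab == g))
}

#' Extract the bony landmarks that anchor the field borders
#'
#' From the AP projection of the bony pelvis: the pelvic inlet is the enclosed
#' opening with the widest u extent; its extreme u pixel centers give
#' `inlet_u_min`/`inlet_u_max`, and the inferior extent of the remaining
#' enclosed openings (the obturator foramina) gives `obturator_inferior_v`.
#' From the AP projections of L4 and L5: `l4l5_v` is the midpoint between the
#' inferior extent of L4 and the superior extent of L5. From the right-lateral
#' projections (u = anterior-positive): `symphysis_anterior_u` is the anterior
#' extreme of the bony pelvis and `sacrum_posterior_u` the posterior extreme of
#' the sacrum. All values are isocenter-plane mm.
#'
#' @param bevs named list of [project_to_bev()] results with elements
#'   `ap_bony_pelvis`, `ap_l4`, `ap_l5`, `rl_bony_pelvis`, `rl_sacrum`.
#' @return object of class `landmark_set`.
#' @export
extract_landmarks <- function(bevs) {
  need <- c("ap_bony_pelvis", "ap_l4", "ap_l5", "rl_bony_pelvis", "rl_sacrum")
  missing <- setdiff(need, names(bevs))
  if (length(missing))
    stop("extract_landmarks: missing structure projection(s): ",
         paste(missing, collapse = ", "))
  holes <- bev_holes(bevs$ap_bony_pelvis)
  if (length(holes) == 0L)
    stop("extract_landmarks: bony pelvis projection has no enclosed inlet opening")
  hc <- lapply(holes, function(ix) bev_pixel_centers(bevs$ap_bony_pelvis, ix))
  widths <- vapply(hc, function(m) diff(range(m[, "u"])), numeric(1))
  inlet <- hc[[which.max(widths)]]
  others <- hc[-which.max(widths)]
  warn <- character(0)
  if (length(others) == 0L) {
    warn <- "no distinct obturator openings; using the inlet opening's inferior extent"
    obturator_inferior_v <- min(inlet[, "v"])
  } else {
    obturator_inferior_v <- min(vapply(others, function(m) min(m[, "v"]), numeric(1)))
  }
  l5 <- bev_pixel_centers(bevs$ap_l5)
  if (is.null(bevs$ap_l4)) {
    # L4 could not be labeled (e.g. fused vertebral column): fall back to the
    # top of L5 and flag the superior border for review
    warn <- c(warn, "L4 projection unavailable; superior border set at the top of L5")
    l4l5_v <- max(l5[, "v"])
  } else {
    l4 <- bev_pixel_centers(bevs$ap_l4)
    l4l5_v <- (min(l4[, "v"]) + max(l5[, "v"])) / 2
  }
  lm <- structure(list(
    inlet_u_min = min(inlet[, "u"]),
    inlet_u_max = max(inlet[, "u"]),
    l4l5_v = l4l5_v,
    obturator_inferior_v = obturator_inferior_v,
    symphysis_anterior_u = max(bev_pixel_centers(bevs$rl_bony_pelvis)[, "u"]),
    sacrum_posterior_u = min(bev_pixel_centers(bevs$rl_sacrum)[, "u"]),
    warnings = warn), class = "landmark_set")
  if (lm$inlet_u_min >= lm$inlet_u_max)
    stop("extract_landmarks: degenerate inlet extent")
  if (lm$l4l5_v <= lm$obturator_inferior_v)
    stop("extract_landmarks: L4/L5 interspace not superior to the obturator openings")
  lm
}
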