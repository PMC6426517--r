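#' Construct the treated volume
#'
#' The treated volume is the region intersected by all beams — a voxel belongs
#' iff it is inside the body and its divergent projection lies inside every
#' beam's MLC opening — contracted by a morphological erosion of
#' `margin_mm` (default 5 mm, i.e. the conventional 0.5 cm) to exclude the
#' rapid dose drop-off at the field edges.
#'
#' @param body body [structure_mask()].
#' @param beams named list of four [beam_geometry()] objects.
#' @param apertures matching named list of apertures (MLC fitted on demand).
#' @param margin_mm contraction margin in mm.
#' @return list of class `treated_volume` with `mask` (a [structure_mask()])
#'   and `contraction_margin_mm`.
#' @export
build_treated_volume <- function(body, beams, apertures, margin_mm = 5) {
  stopifnot(margin_mm >= 0)
  inter <- body$voxels
  d <- dim(inter)
  for (nm in names(beams)) {
    ap <- apertures[[nm]]
    if (is.null(ap$mlc)) ap <- fit_mlc(ap)
    bg <- beams[[nm]]
    m <- ap$mlc
    infield <- array(.infield_mask(d, body$spacing, body$origin, bg$source,
                                   bg$isocenter, bg$axis, bg$e_u, bg$e_v, bg$sad,
                                   m$v_first, m$leaf_width, m$leaf_u), d)
    inter <- inter & infield
  }
  if (!any(inter)) stop("build_treated_volume: beam intersection is empty")
  if (margin_mm > 0)
    inter <- mask_erode(inter, ball_offsets(margin_mm, body$spacing))
  if (!any(inter)) stop("build_treated_volume: treated volume empty after contraction")
  structure(list(mask = structure_mask(inter, body$spacing, body$origin, "treated"),
                 contraction_margin_mm = margin_mm), class = "treated_volume")
}

# exact non-negative least squares for a small number of beams: enumerate
# active sets, solve the unconstrained normal equations on each subset, and
# return the solution satisfying primal feasibility and the KKT gradient
# condition. Deterministic (fixed enumeration order); the problem is convex so
# any KKT point is the global minimum.
nnls_small <- function(A, b) {
  p <- length(b)
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  scale <- max(abs(A)) + max(abs(b))
  for (S in subsets) {
    w <- rep(0, p)
    if (length(S)) {
      ws <- tryCatch(solve(A[S, S, drop = FALSE], b[S]), error = function(e) NULL)
      if (is.null(ws)) next
      if (any(ws < -1e-9 * scale)) next
      w[S] <- pmax(ws, 0)
    }
    grad <- A %*% w - b    # half-gradient of ||Dw - R||^2
    if (all(grad[setdiff(seq_len(p), S)] >= -1e-7 * scale)) return(w)
  }
  stop("nnls_small: no KKT point found (singular system?)")
}

#' Optimize beam weights by non-negative least squares
#'
#' Minimizes the dose heterogeneity inside the treated volume,
#' `sum_{v in treated} (sum_b w_b d_b(v) - R)^2` over weights `w >= 0`
#' (negative beam weights are physically meaningless), then rescales the
#' weights so that the normalization reference — the total dose at the
#' isocenter voxel by default, or the treated-volume mean — equals the
#' prescription exactly. The solver is a deterministic exact active-set
#' enumeration.
#'
#' @param per_beam list of four unit-weight [compute_beam_dose()] grids.
#' @param treated a [build_treated_volume()] result.
#' @param prescription prescription dose R (the reference level).
#' @param normalization `"isocenter"` (default) or `"mean_treated"`.
#' @param isocenter world point for isocenter normalization.
#' @return list of class `beam_weights`: `weights` (named, rescaled),
#'   `weights_raw` (the NNLS optimum before rescaling), `objective` (at the
#'   optimum, per unit prescription-squared), `normalization`.
#' @export
optimize_weights <- function(per_beam, treated, prescription,
                             normalization = c("isocenter", "mean_treated"),
                             isocenter = NULL) {
  normalization <- match.arg(normalization)
  idx <- which(treated$mask$voxels)
  if (length(idx) == 0L) stop("optimize_weights: treated volume is empty")
  D <- vapply(per_beam, function(g) g$voxels[idx], numeric(length(idx)))
  if (all(D == 0)) stop("optimize_weights: all-zero dose in the treated volume")
  A <- crossprod(D)
  b <- colSums(D) * prescription
  w <- nnls_small(A, b)
  obj <- sum((D %*% w - prescription)^2)
  names(w) <- names(per_beam)
  wn <- normalize_weights(w, per_beam, treated, prescription, normalization, isocenter)
  structure(list(weights = wn, weights_raw = w, objective = obj,
                 normalization = normalization, prescription = prescription),
            class = "beam_weights")
}

normalize_weights <- function(w, per_beam, treated, prescription,
                              normalization, isocenter) {
  if (normalization == "isocenter") {
    if (is.null(isocenter))
      stop("optimize_weights: isocenter required for isocenter normalization")
    ref <- sum(vapply(seq_along(per_beam), function(b) {
      g <- per_beam[[b]]
      i <- nearest_voxel(g, isocenter)
      w[b] * g$voxels[i[1], i[2], i[3]]
    }, numeric(1)))
  } else {
    idx <- which(treated$mask$voxels)
    D <- vapply(per_beam, function(g) g$voxels[idx], numeric(length(idx)))
    ref <- mean(D %*% w)
  }
  if (ref <= 0) stop("optimize_weights: zero dose at the normalization reference")
  w * prescription / ref
}

#' Equally weighted beams (the non-optimized reference plan)
#'
#' Each beam contributes the same dose, R/4, at the isocenter calculation
#' point, matching the conventional non-optimized four-field plan.
#'
#' @param per_beam list of four unit-weight dose grids.
#' @param prescription prescription dose R.
#' @param isocenter calculation point (world mm).
#' @return a `beam_weights` object (weights only; objective `NA`).
#' @export
equal_weights <- function(per_beam, prescription, isocenter) {
  d_iso <- vapply(per_beam, function(g) {
    i <- nearest_voxel(g, isocenter)
    g$voxels[i[1], i[2], i[3]]
  }, numeric(1))
  if (any(d_iso <= 0))
    stop("equal_weights: zero dose at the calculation point for beam(s) ",
         paste(names(per_beam)[d_iso <= 0], collapse = ", "))
  w <- (prescription / length(per_beam)) / d_iso
  names(w) <- names(per_beam)
  structure(list(weights = w, weights_raw = w, objective = NA_real_,
                 normalization = "isocenter", prescription = prescription),
            class = "beam_weights")
}

# least-squares heterogeneity objective of a weight vector on the treated volume
plan_objective <- function(per_beam, treated, prescription, weights) {
  idx <- which(treated$mask$voxels)
  D <- vapply(per_beam, function(g) g$voxels[idx], numeric(length(idx)))
  sum((D %*% weights - prescription)^2)
}

#' Plan quality metrics: hottest 1 cc and V95
#'
#' `d_max_1cc` is the minimum dose among the highest-dose voxel set whose
#' cumulative volume first reaches 1 cc (voxels sorted descending over the
#' evaluation region — the whole body by default, matching "tissue"),
#' expressed as a percentage of the prescription. `v95_treated` is the
#' percentage of treated-volume voxels receiving at least 95% of the
#' prescription. Plans with `d_max_1cc >= hot_threshold_pct` (107% by
#' convention) are flagged as hot.
#'
#' @param total total [total_dose()] grid.
#' @param treated a [build_treated_volume()] result.
#' @param prescription prescription dose R.
#' @param body optional body mask restricting the hot-spot search region;
#'   defaults to all voxels with nonzero dose (the body, since dose is zero
#'   outside it).
#' @param hot_threshold_pct hot-plan flag boundary, % of prescription.
#' @return list of class `plan_metrics` with `d_max_1cc`, `v95_treated`
#'   (both %), `flag_high_dmax`.
#' @export
compute_plan_metrics <- function(total, treated, prescription, body = NULL,
                                 hot_threshold_pct = 107) {
  voxvol <- prod(total$spacing)
  region <- if (is.null(body)) total$voxels > 0 else body$voxels
  d <- total$voxels[region]
  if (length(d) == 0L) stop("compute_plan_metrics: empty evaluation region")
  n1 <- min(length(d), max(1L, as.integer(ceiling(1000 / voxvol))))
  ds <- sort(d, decreasing = TRUE)
  d_max_1cc <- 100 * ds[n1] / prescription
  tv <- total$voxels[treated$mask$voxels]
  v95 <- 100 * mean(tv >= 0.95 * prescription)
  structure(list(d_max_1cc = d_max_1cc, v95_treated = v95,
                 flag_high_dmax = d_max_1cc >= hot_threshold_pct,
                 hot_threshold_pct = hot_threshold_pct),
            class = "plan_metrics")
}
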