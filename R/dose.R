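#' Parameters of the simplified photon dose model
#'
#' A primary-attenuation divergent-beam model: per unit beam weight, the dose
#' at a voxel at radiological depth d (cm, water-equivalent path inside the
#' body) and source distance r (mm) is
#' `B(d) * exp(-mu_eff * max(0, d - buildup)) * (SAD / r)^2`,
#' where B ramps linearly from 0 to 1 over the buildup depth. There is no
#' scatter kernel, no penumbra (the field edge is binary) and no heterogeneity
#' correction beyond body/air; the optimization and plan-metric layers only
#' require a dose field that is linear in the beam weights and realistically
#' asymmetric with patient geometry.
#'
#' @param mu_eff effective linear attenuation, 1/cm (default 0.02 for the
#'   18 MV energy label).
#' @param buildup_cm buildup depth in cm (default 3.2 for 18 MV).
#' @param sad source-axis distance in mm.
#' @param step_mm ray-sampling step; defaults to half the smallest voxel size.
#' @param energy energy label recorded in provenance.
#' @return list of class `dose_params`.
#' @export
dose_params <- function(mu_eff = 0.02, buildup_cm = 3.2, sad = 1000,
                        step_mm = NULL, energy = "18MV") {
  stopifnot(mu_eff > 0, buildup_cm >= 0, sad > 0)
  structure(list(mu_eff = mu_eff, buildup_cm = buildup_cm, sad = sad,
                 step_mm = step_mm, energy = energy), class = "dose_params")
}

default_step <- function(volume, params) {
  if (!is.null(params$step_mm)) params$step_mm else min(volume$spacing) / 2
}

#' Radiological depth of a point along a beam's ray
#'
#' Length (cm) of the source-to-point ray segment inside the body mask,
#' water-equivalent (unit density inside the body, zero outside), by uniform
#' midpoint sampling at steps no larger than half a voxel.
#'
#' @param volume a [ct_volume()] (grid carrier).
#' @param body body [structure_mask()].
#' @param beam a [beam_geometry()].
#' @param p world point (mm), inside the grid.
#' @param step_mm sampling step override.
#' @return depth in cm.
#' @export
radiological_depth <- function(volume, body, beam, p, step_mm = NULL) {
  idx <- world_to_voxel(volume, p)
  if (any(idx < -0.5) || any(idx > dim(volume$voxels) - 0.5))
    stop("radiological_depth: point outside the grid")
  step <- if (is.null(step_mm)) min(volume$spacing) / 2 else step_mm
  .ray_depth_mm(body$voxels, dim(body$voxels), body$spacing, body$origin,
                beam$source, as.numeric(p), step) / 10
}

#' Compute the unit-weight dose grid of one beam
#'
#' Applies the [dose_params()] model at every voxel inside the body whose
#' divergent projection falls inside the beam's MLC opening; dose is zero
#' outside the field or the body. The grid is linear in beam weight by
#' construction (scaling the weight scales every voxel).
#'
#' @param volume a [ct_volume()].
#' @param body body [structure_mask()].
#' @param beam a [beam_geometry()].
#' @param aperture the beam's aperture (MLC fitted with [fit_mlc()] if not
#'   already).
#' @param params a [dose_params()].
#' @return object of class `dose_grid`: list with `voxels` (array, fraction of
#'   reference dose per unit weight), grid geometry, `beam` name and
#'   `provenance`.
#' @export
compute_beam_dose <- function(volume, body, beam, aperture, params = dose_params()) {
  if (!identical(aperture$beam$name, beam$name))
    stop("compute_beam_dose: aperture belongs to beam ", aperture$beam$name,
         ", not ", beam$name)
  if (is.null(aperture$mlc)) aperture <- fit_mlc(aperture)
  m <- aperture$mlc
  step <- default_step(volume, params)
  dose <- .beam_dose(body$voxels, dim(body$voxels), body$spacing, body$origin,
                     beam$source, beam$isocenter, beam$axis, beam$e_u, beam$e_v,
                     beam$sad, m$v_first, m$leaf_width, m$leaf_u,
                     params$mu_eff, params$buildup_cm, step)
  structure(list(voxels = array(dose, dim(body$voxels)),
                 spacing = body$spacing, origin = body$origin,
                 beam = beam$name,
                 provenance = list(energy = params$energy, mu_eff = params$mu_eff,
                                   buildup_cm = params$buildup_cm,
                                   sad = params$sad, step_mm = step)),
            class = "dose_grid")
}

#' Weighted total dose
#'
#' Voxelwise `sum_b w_b d_b`; exact superposition of the per-beam unit-weight
#' grids.
#'
#' @param per_beam list of [compute_beam_dose()] grids on one grid.
#' @param weights numeric vector of non-negative beam weights, one per grid.
#' @return a `dose_grid` with beam name `"total"`.
#' @export
total_dose <- function(per_beam, weights) {
  stopifnot(length(per_beam) == length(weights))
  d0 <- per_beam[[1]]
  tot <- array(0, dim(d0$voxels))
  for (b in seq_along(per_beam)) {
    db <- per_beam[[b]]
    if (!identical(dim(db$voxels), dim(d0$voxels)) ||
        any(abs(db$spacing - d0$spacing) > 1e-9))
      stop("total_dose: dose grids are not congruent")
    tot <- tot + weights[b] * db$voxels
  }
  structure(list(voxels = tot, spacing = d0$spacing, origin = d0$origin,
                 beam = "total", provenance = list(weights = as.numeric(weights))),
            class = "dose_grid")
}
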