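#' Plan order: the physician's input to automatic planning
#'
#' @param patient_id opaque identifier.
#' @param prescription_gy prescription dose in Gy (> 0).
#' @param fractions number of fractions (>= 1).
#' @param machine machine name keying the machine geometry.
#' @param rule_set name of the aperture rule set (recorded in provenance).
#' @return list of class `plan_order`.
#' @export
plan_order <- function(patient_id = "anon", prescription_gy = 45,
                       fractions = 25L, machine = "default",
                       rule_set = "four_field_box") {
  stopifnot(prescription_gy > 0, fractions >= 1)
  structure(list(patient_id = patient_id, prescription_gy = prescription_gy,
                 fractions = as.integer(fractions), machine = machine,
                 rule_set = rule_set), class = "plan_order")
}

#' Layered pipeline configuration
#'
#' Every threshold and margin the pipeline uses lives here (package defaults,
#' overridable per call) and is echoed into the plan report, so no planning
#' decision is hard-coded or silent.
#'
#' @param body_hu_threshold HU threshold for the external contour.
#' @param couch_hu_threshold HU threshold for couch material.
#' @param smooth_radius_mm body-contour smoothing radius.
#' @param hole_fill `"3d"`, `"2d"` or `"both"` cavity filling.
#' @param bandwidth_mm fiducial search-domain half-width.
#' @param fiducial_hu_threshold HU threshold for fiducials.
#' @param size_min_vox,size_max_vox fiducial candidate size bounds.
#' @param bone_hu_threshold HU threshold for bone.
#' @param bev_pixel_mm BEV raster pixel size.
#' @param rules a [rule_config()] of aperture margins.
#' @param sad source-axis distance, mm.
#' @param mu_eff,buildup_cm dose-model parameters (see [dose_params()]).
#' @param dose_step_mm ray-sampling step override (NULL = half min voxel).
#' @param treated_margin_mm treated-volume contraction margin.
#' @param normalization weight normalization reference.
#' @param hot_threshold_pct hot-plan flag boundary (% of prescription).
#' @param energy beam energy label.
#' @return list of class `plan_config`.
#' @export
plan_config <- function(body_hu_threshold = -300, couch_hu_threshold = -500,
                        smooth_radius_mm = 3, hole_fill = "3d",
                        bandwidth_mm = 10, fiducial_hu_threshold = 800,
                        size_min_vox = 1, size_max_vox = 200,
                        bone_hu_threshold = 200, bev_pixel_mm = 1.5,
                        rules = rule_config(), sad = 1000,
                        mu_eff = 0.02, buildup_cm = 3.2, dose_step_mm = NULL,
                        treated_margin_mm = 5,
                        normalization = "isocenter",
                        hot_threshold_pct = 107, energy = "18MV") {
  structure(as.list(environment()), class = "plan_config")
}

stage_error <- function(stage, message) {
  stop(structure(class = c("fourfield_stage_error", "error", "condition"),
                 list(message = sprintf("[stage %s] %s", stage, message),
                      call = NULL, stage = stage)))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "fourfield_stage_error")) stop(e)
    stage_error(stage, conditionMessage(e))
  })
}

#' Fully automatic four-field box treatment planning
#'
#' Runs the whole planning chain on a CT volume: couch detection and removal,
#' body contouring, marked-isocenter detection from the three skin fiducials,
#' bone segmentation, BEV projection and landmark extraction, aperture design
#' and MLC fitting, per-beam dose calculation, treated-volume construction,
#' beam-weight optimization, and plan metrics. Deterministic for a fixed input
#' and configuration. Stage failures abort with a classed condition
#' (`fourfield_stage_error`) naming the failed stage.
#'
#' @param ct a [ct_volume()] (or path to a NIfTI file).
#' @param order a [plan_order()].
#' @param config a [plan_config()].
#' @param truth_bones optional ground-truth bone label array to bypass the
#'   surrogate bone segmenter (pipeline testing).
#' @param compute_dose set `FALSE` to stop after aperture design.
#' @param keep_doses keep the per-beam and total dose grids in the returned
#'   object (they are large).
#' @return object of class `fourfield_plan`; see [plan_report()] for the
#'   serializable summary. Key elements: `isocenter`, `apertures`, `weights`,
#'   `weights_equal`, `metrics`, `metrics_equal`, `warnings`.
#' @export
auto_plan <- function(ct, order = plan_order(), config = plan_config(),
                      truth_bones = NULL, compute_dose = TRUE,
                      keep_doses = TRUE) {
  t_all <- proc.time()[["elapsed"]]
  timings <- numeric(0)
  tick <- function(name, t0) {
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  warns <- character(0)

  if (is.character(ct)) ct <- with_stage("load", load_volume(ct))
  stopifnot(inherits(ct, "ct_volume"), inherits(order, "plan_order"))

  t0 <- proc.time()[["elapsed"]]
  couch <- with_stage("couch", detect_couch(ct, config$couch_hu_threshold))
  ct_nocouch <- remove_couch(ct, couch)
  tick("couch", t0)

  t0 <- proc.time()[["elapsed"]]
  body <- with_stage("body_contour",
                     segment_body(ct_nocouch, config$body_hu_threshold,
                                  config$smooth_radius_mm, config$hole_fill))
  tick("body_contour", t0)

  t0 <- proc.time()[["elapsed"]]
  iso <- with_stage("isocenter",
                    detect_isocenter(ct_nocouch, body, config$bandwidth_mm,
                                     config$fiducial_hu_threshold,
                                     config$size_min_vox, config$size_max_vox))
  tick("isocenter", t0)

  t0 <- proc.time()[["elapsed"]]
  bones <- with_stage("bone_segmentation",
                      withCallingHandlers(
                        segment_bones(ct_nocouch, body, config$bone_hu_threshold,
                                      truth = truth_bones),
                        warning = function(w) {
                          warns <<- c(warns, conditionMessage(w))
                          invokeRestart("muffleWarning")
                        }))
  tick("bone_segmentation", t0)

  t0 <- proc.time()[["elapsed"]]
  beams <- four_beams(iso$isocenter, config$sad)
  l4_mask <- bone_mask(bones, "L4")
  bevs <- with_stage("bev_projection", list(
    ap_bony_pelvis = project_to_bev(bone_mask(bones, "bony_pelvis"), beams$AP,
                                    config$bev_pixel_mm),
    ap_l4 = if (any(l4_mask$voxels))
      project_to_bev(l4_mask, beams$AP, config$bev_pixel_mm),
    ap_l5 = project_to_bev(bone_mask(bones, "L5"), beams$AP, config$bev_pixel_mm),
    rl_bony_pelvis = project_to_bev(bone_mask(bones, "bony_pelvis"), beams$RL,
                                    config$bev_pixel_mm),
    rl_sacrum = project_to_bev(bone_mask(bones, "sacrum"), beams$RL,
                               config$bev_pixel_mm)))
  landmarks <- with_stage("landmarks", extract_landmarks(bevs))
  warns <- c(warns, landmarks$warnings)
  tick("landmarks", t0)

  t0 <- proc.time()[["elapsed"]]
  apertures <- with_stage("aperture_design",
                          design_apertures(landmarks, config$rules, beams))
  apertures <- lapply(apertures, fit_mlc)
  if (any(grepl("vertebra", warns)))
    warns <- c(warns,
               "superior border: review recommended, vertebral labeling was incomplete")
  tick("aperture_design", t0)

  plan <- list(order = order, config = config, couch = couch, body = body,
               isocenter = iso, bones_warnings = bones$warnings,
               landmarks = landmarks, beams = beams, apertures = apertures,
               warnings = warns, timings = NULL,
               version = as.character(utils::packageVersion("fourfield")))

  if (compute_dose) {
    t0 <- proc.time()[["elapsed"]]
    params <- dose_params(config$mu_eff, config$buildup_cm, config$sad,
                          config$dose_step_mm, config$energy)
    doses <- with_stage("dose", lapply(names(beams), function(nm)
      compute_beam_dose(ct_nocouch, body, beams[[nm]], apertures[[nm]], params)))
    names(doses) <- names(beams)
    tick("dose", t0)

    t0 <- proc.time()[["elapsed"]]
    treated <- with_stage("treated_volume",
                          build_treated_volume(body, beams, apertures,
                                               config$treated_margin_mm))
    R <- order$prescription_gy
    wopt <- with_stage("optimize",
                       optimize_weights(doses, treated, R,
                                        config$normalization, iso$isocenter))
    weq <- with_stage("optimize", equal_weights(doses, R, iso$isocenter))
    tot_opt <- total_dose(doses, wopt$weights)
    tot_eq <- total_dose(doses, weq$weights)
    metrics <- compute_plan_metrics(tot_opt, treated, R, body,
                                    config$hot_threshold_pct)
    metrics_eq <- compute_plan_metrics(tot_eq, treated, R, body,
                                       config$hot_threshold_pct)
    if (metrics$flag_high_dmax)
      warns <- c(warns, sprintf("high maximum dose: hottest 1 cc at %.1f%% (>= %g%%)",
                                metrics$d_max_1cc, config$hot_threshold_pct))
    tick("optimize", t0)

    plan$treated <- treated
    plan$weights <- wopt
    plan$weights_equal <- weq
    plan$metrics <- metrics
    plan$metrics_equal <- metrics_eq
    plan$objective_equal <- plan_objective(doses, treated, R, weq$weights)
    plan$warnings <- warns
    if (keep_doses) {
      plan$doses <- doses
      plan$total <- tot_opt
    }
  }

  plan$timings <- c(timings, total = round(proc.time()[["elapsed"]] - t_all, 3))
  structure(plan, class = "fourfield_plan")
}

#' @export
print.fourfield_plan <- function(x, ...) {
  cat("Four-field box plan for patient", x$order$patient_id, "\n")
  cat(sprintf("  isocenter: (%.1f, %.1f, %.1f) mm, residual %.2f mm\n",
              x$isocenter$isocenter[1], x$isocenter$isocenter[2],
              x$isocenter$isocenter[3], x$isocenter$residual))
  for (nm in names(x$apertures)) {
    a <- x$apertures[[nm]]
    cat(sprintf("  %s aperture: u [%.1f, %.1f] mm, v [%.1f, %.1f] mm\n",
                nm, a$u_min, a$u_max, a$v_min, a$v_max))
  }
  if (!is.null(x$weights)) {
    cat("  beam weights (optimized):",
        paste(sprintf("%s=%.3f", names(x$weights$weights), x$weights$weights),
              collapse = ", "), "\n")
    cat(sprintf("  hottest 1 cc: %.1f%%; V95(treated): %.1f%%%s\n",
                x$metrics$d_max_1cc, x$metrics$v95_treated,
                if (x$metrics$flag_high_dmax) "  [HOT]" else ""))
  }
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = " | "), "\n")
  invisible(x)
}

#' @export
summary.fourfield_plan <- function(object, ...) {
  print(object)
  if (!is.null(object$metrics_equal))
    cat(sprintf("  equal-weight reference: hottest 1 cc %.1f%%, V95 %.1f%%\n",
                object$metrics_equal$d_max_1cc, object$metrics_equal$v95_treated))
  cat("  stage timings (s):",
      paste(sprintf("%s=%.2f", names(object$timings), object$timings),
            collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.fourfield_plan <- function(object, ...) {
  if (is.null(object$weights)) stop("plan has no optimized weights (dose not computed)")
  object$weights$weights
}

#' Plot a plan: BEV apertures or an axial dose slice
#'
#' @param x a `fourfield_plan`.
#' @param type `"bev"` draws the aperture rectangles and MLC openings of all
#'   four beams; `"dose"` draws the axial total-dose slice through the
#'   isocenter with the body outline (requires `keep_doses = TRUE`).
#' @param ... ignored.
#' @export
plot.fourfield_plan <- function(x, type = c("bev", "dose"), ...) {
  type <- match.arg(type)
  if (type == "bev") {
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (nm in names(x$apertures)) {
      a <- x$apertures[[nm]]
      graphics::plot(NA, xlim = c(a$u_min, a$u_max) + c(-30, 30),
                     ylim = c(a$v_min, a$v_max) + c(-30, 30),
                     xlab = "u (mm)", ylab = "v (mm)", main = paste(nm, "aperture"))
      m <- a$mlc
      for (i in seq_len(nrow(m$leaf_u))) {
        if (m$leaf_u[i, 1] > m$leaf_u[i, 2]) next
        graphics::rect(m$leaf_u[i, 1], m$bands[i, 1], m$leaf_u[i, 2], m$bands[i, 2],
                       border = "grey60")
      }
      graphics::rect(a$u_min, a$v_min, a$u_max, a$v_max, border = "red", lwd = 2)
    }
  } else {
    if (is.null(x$total)) stop("plot type 'dose' needs keep_doses = TRUE")
    k <- nearest_voxel(x$total, x$isocenter$isocenter)[3]
    sl <- x$total$voxels[, , k]
    graphics::image(sl, col = grDevices::hcl.colors(64, "inferno"),
                    main = sprintf("total dose, axial slice %d", k),
                    xlab = "x", ylab = "y")
    graphics::contour(x$body$voxels[, , k] * 1, levels = 0.5, add = TRUE,
                      drawlabels = FALSE)
  }
  invisible(x)
}
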