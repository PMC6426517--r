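#' Build the serializable plan report
#'
#' Collects every pipeline decision — detected couch row, body-contour
#' summary, isocenter and residual, landmarks, apertures with their MLC leaf
#' positions, beam weights, plan metrics, warnings — together with the full
#' configuration echo and software version, for the plan-review document.
#'
#' @param plan a [auto_plan()] result.
#' @param include_timings include stage wall-times (excluded when byte-stable
#'   output is wanted).
#' @return nested list ready for [write_report()].
#' @export
plan_report <- function(plan, include_timings = TRUE) {
  stopifnot(inherits(plan, "fourfield_plan"))
  ap <- lapply(plan$apertures, function(a) {
    m <- a$mlc
    list(beam = a$beam$name, gantry_angle = a$beam$gantry_angle,
         u_min = a$u_min, u_max = a$u_max, v_min = a$v_min, v_max = a$v_max,
         leaf_width = m$leaf_width, v_first = m$v_first,
         leaves = lapply(seq_len(nrow(m$leaf_u)), function(i)
           list(v0 = m$bands[i, 1], v1 = m$bands[i, 2],
                u_open = if (m$leaf_u[i, 1] <= m$leaf_u[i, 2])
                  c(m$leaf_u[i, 1], m$leaf_u[i, 2]) else NULL)))
  })
  fid <- plan$isocenter$fiducials
  rep <- list(
    software = list(name = "fourfield", version = plan$version),
    patient_id = plan$order$patient_id,
    prescription_gy = plan$order$prescription_gy,
    fractions = plan$order$fractions,
    machine = plan$order$machine,
    rule_set = plan$order$rule_set,
    config = local({
      cfg <- unclass(plan$config)
      cfg$rules <- unclass(cfg$rules)
      cfg[!vapply(cfg, is.null, logical(1))]
    }),
    couch = list(found = plan$couch$found,
                 couch_top_row = plan$couch$couch_top_row,
                 peak_score = plan$couch$peak_score),
    body = list(voxel_count = sum(plan$body$voxels),
                volume_cc = sum(plan$body$voxels) * prod(plan$body$spacing) / 1000),
    isocenter = list(position_mm = as.numeric(plan$isocenter$isocenter),
                     residual_mm = plan$isocenter$residual,
                     fiducials = lapply(seq_len(nrow(fid)), function(i)
                       list(role = fid$role[i],
                            position_mm = c(fid$x[i], fid$y[i], fid$z[i]),
                            voxel_count = fid$voxel_count[i],
                            mean_hu = fid$mean_hu[i]))),
    landmarks = plan$landmarks[c("inlet_u_min", "inlet_u_max", "l4l5_v",
                                 "obturator_inferior_v", "symphysis_anterior_u",
                                 "sacrum_posterior_u")],
    apertures = ap,
    warnings = as.list(plan$warnings)
  )
  if (!is.null(plan$weights)) {
    rep$weights <- list(optimized = as.list(plan$weights$weights),
                        equal = as.list(plan$weights_equal$weights),
                        normalization = plan$weights$normalization,
                        objective = plan$weights$objective,
                        objective_equal = plan$objective_equal)
    rep$metrics <- list(
      optimized = list(d_max_1cc_pct = plan$metrics$d_max_1cc,
                       v95_treated_pct = plan$metrics$v95_treated,
                       flag_high_dmax = plan$metrics$flag_high_dmax),
      equal = list(d_max_1cc_pct = plan$metrics_equal$d_max_1cc,
                   v95_treated_pct = plan$metrics_equal$v95_treated,
                   flag_high_dmax = plan$metrics_equal$flag_high_dmax))
    rep$treated_volume_cc <- sum(plan$treated$mask$voxels) *
      prod(plan$treated$mask$spacing) / 1000
  }
  if (include_timings) rep$timings_s <- as.list(plan$timings)
  rep
}

#' Write or read a plan report as JSON
#'
#' @param report a [plan_report()] list (or a `fourfield_plan`).
#' @param path output JSON path.
#' @param include_timings see [plan_report()].
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, include_timings = TRUE) {
  if (inherits(report, "fourfield_plan"))
    report <- plan_report(report, include_timings)
  if (!include_timings) report$timings_s <- NULL
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a plan report against the shipped JSON schema
#'
#' A light structural validator: checks the required properties (recursively)
#' and elementary types declared in the schema at
#' `system.file("extdata", "plan-report-schema.json", package = "fourfield")`.
#'
#' @param report a report list, a `fourfield_plan`, or a path to a report JSON.
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_report <- function(report) {
  if (inherits(report, "fourfield_plan")) report <- plan_report(report)
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata", "plan-report-schema.json",
                                            package = "fourfield"))
  check <- function(obj, sch, where) {
    ty <- sch$type
    if (!is.null(ty)) {
      ok <- switch(ty,
                   object = is.list(obj),
                   array = is.list(obj) || is.vector(obj),
                   string = is.character(obj),
                   number = is.numeric(obj),
                   integer = is.numeric(obj),
                   boolean = is.logical(obj),
                   TRUE)
      if (!ok) stop("validate_report: ", where, " should have type ", ty)
    }
    for (req in sch$required)
      if (is.null(obj[[req]]))
        stop("validate_report: missing required field ", where, "/", req)
    for (nm in names(sch$properties))
      if (!is.null(obj[[nm]]))
        check(obj[[nm]], sch$properties[[nm]], paste0(where, "/", nm))
    invisible(TRUE)
  }
  check(report, schema, "")
  invisible(TRUE)
}

#' Write a phantom fixture to disk
#'
#' Generates a phantom (or cohort) and writes the CT, the truth masks, a truth
#' sidecar JSON and a matching plan order, for tests and demos.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @param seed overrides `spec$seed`.
#' @param n if greater than 1, writes an n-phantom cohort into numbered
#'   subdirectories.
#' @return invisible character vector of written files.
#' @export
generate_fixture <- function(spec = phantom_spec(), out_dir, seed = NULL, n = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  if (n > 1) {
    specs <- cohort_specs(spec, n, seed = spec$seed)
    files <- unlist(lapply(seq_len(n), function(i)
      generate_fixture(specs[[i]], file.path(out_dir, sprintf("phantom%02d", i)))))
    return(invisible(files))
  }
  ph <- generate_phantom(spec)
  files <- c(ct = file.path(out_dir, "ct.nii.gz"),
             body = file.path(out_dir, "body.nii.gz"),
             couch = file.path(out_dir, "couch.nii.gz"),
             bones = file.path(out_dir, "bones.nii.gz"),
             truth = file.path(out_dir, "truth.json"),
             order = file.path(out_dir, "order.json"))
  save_volume(ph$ct, files[["ct"]])
  save_volume(ph$truth$body, files[["body"]])
  save_volume(ph$truth$couch, files[["couch"]])
  save_volume(structure_mask(ph$truth$bones > 0L, ph$ct$spacing, ph$ct$origin,
                             "bones"), files[["bones"]])
  jsonlite::write_json(list(isocenter = ph$truth$isocenter,
                            fiducials = apply(ph$truth$fiducials, 1, as.numeric,
                                              simplify = FALSE),
                            landmarks = ph$truth$landmarks,
                            seed = spec$seed),
                       files[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(plan_order()), files[["order"]],
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
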