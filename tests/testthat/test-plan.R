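test_that("end-to-end planning on the default phantom succeeds with a complete result", {
  plan <- default_plan()
  ph <- default_phantom()
  expect_s3_class(plan, "fourfield_plan")
  expect_length(plan$apertures, 4)
  expect_true(all(unlist(coef(plan)) > 0))
  expect_length(coef(plan), 4)
  # detected isocenter close to truth; body contour matches truth
  expect_lt(sqrt(sum((plan$isocenter$isocenter - ph$truth$isocenter)^2)), 2)
  expect_gte(compare_masks(plan$body, ph$truth$body)$dice, 0.99)
  # optimization does not lose to equal weighting on its own objective
  expect_lte(plan$weights$objective, plan$objective_equal + 1e-9)
  # all four apertures contain the projected truth bony anatomy silhouettes
  for (nm in c("AP", "RL")) {
    for (bone in c("bony_pelvis", "sacrum")) {
      bm <- structure_mask(ph$truth$bones == bone_labels()[[bone]],
                           ph$ct$spacing, ph$ct$origin, bone)
      bev <- project_to_bev(bm, plan$beams[[nm]], 3)
      pc <- fourfield:::bev_pixel_centers(bev)
      a <- plan$apertures[[nm]]
      # silhouettes sit within the rule margins of the aperture rectangle
      expect_lt(max(pc[, "v"]) - a$v_max, 25)
      expect_gt(min(pc[, "v"]) - a$v_min, -25)
    }
  }
})

test_that("the plan report is schema-valid, complete, and byte-stable across reruns", {
  plan <- default_plan()
  expect_silent(validate_report(plan))
  rep <- plan_report(plan)
  # every configuration default is echoed
  expect_true(all(c("body_hu_threshold", "couch_hu_threshold", "bandwidth_mm",
                    "fiducial_hu_threshold", "bone_hu_threshold",
                    "treated_margin_mm", "hot_threshold_pct") %in%
                    names(rep$config)))
  expect_equal(rep$config$treated_margin_mm, 5)

  td <- withr::local_tempdir()
  ph <- default_phantom()
  plan2 <- auto_plan(ph$ct, plan_order(), plan_config(), keep_doses = FALSE)
  f1 <- file.path(td, "r1.json"); f2 <- file.path(td, "r2.json")
  write_report(plan, f1, include_timings = FALSE)
  write_report(plan2, f2, include_timings = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a phantom without fiducials aborts at the isocenter stage", {
  sp <- phantom_spec()
  sp$fiducial_hu <- 500   # below the detection threshold: effectively absent
  sp$bone_hu <- 390
  sp$shape <- c(160L, 120L, 48L)
  sp$spacing <- c(2, 2, 4)
  sp$body_halfaxes <- c(140, 90)
  sp$couch_top_y <- 80
  ph <- generate_phantom(sp)
  err <- tryCatch(auto_plan(ph$ct, plan_order(), plan_config()),
                  fourfield_stage_error = function(e) e)
  expect_s3_class(err, "fourfield_stage_error")
  expect_equal(err$stage, "isocenter")
  expect_match(conditionMessage(err), "detection failed")
})

test_that("vertebral labeling trouble surfaces as a superior-border review flag", {
  sp <- phantom_spec()
  sp$l4l5_gap <- 0
  ph <- generate_phantom(sp)
  plan <- auto_plan(ph$ct, plan_order(), plan_config(), compute_dose = FALSE)
  expect_true(any(grepl("superior border", plan$warnings)))
})

test_that("fixture generation writes a loadable, reproducible file set", {
  td <- withr::local_tempdir()
  sp <- phantom_spec(shape = c(80L, 64L, 24L), spacing = c(3, 3, 6),
                     body_halfaxes = c(100, 70), couch_top_y = 78,
                     isocenter = c(0, -15, 0), inlet_width = 70,
                     ring_thickness = 10, body_center_y = -15,
                     femoral_centers = rbind(c(70, -20, -25), c(-70, -20, -25)),
                     femoral_radius = 14, vert_radius = 12, vert_center_y = 12,
                     l4l5_interspace_z = 34, obturator_inferior_z = -48,
                     sacrum_box = rbind(c(-20, 10, -30), c(20, 32, 6)),
                     symphysis_box = rbind(c(-10, -55, -30), c(10, -30, -12)))
  files <- generate_fixture(sp, td, seed = 4L)
  expect_true(all(file.exists(files)))
  ct <- load_volume(files[["ct"]])
  expect_identical(dim(ct$voxels), c(80L, 64L, 24L))
  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$isocenter, c(0, -15, 0))
  # byte-reproducible for a fixed seed
  td2 <- withr::local_tempdir()
  files2 <- generate_fixture(sp, td2, seed = 4L)
  expect_identical(readBin(files[["ct"]], "raw", file.size(files[["ct"]])),
                   readBin(files2[["ct"]], "raw", file.size(files2[["ct"]])))
  # cohort mode writes numbered subdirectories
  td3 <- withr::local_tempdir()
  generate_fixture(sp, td3, seed = 4L, n = 3)
  expect_length(list.dirs(td3, recursive = FALSE), 3)
})

test_that("report validation catches missing required fields", {
  plan <- default_plan()
  rep <- plan_report(plan)
  rep$isocenter$residual_mm <- NULL
  expect_error(validate_report(rep), "residual_mm")
})
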