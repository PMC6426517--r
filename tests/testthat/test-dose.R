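test_that("radiological depth: skin entry, slab thickness, oblique oracle", {
  bx <- box_phantom()
  beam <- beam_geometry("AP", c(0, 0, 0), 1000)
  # entry point on the anterior skin surface
  d_entry <- radiological_depth(bx$ct, bx$body, beam, c(0, -80, 0))
  expect_lt(d_entry, 0.45)  # within one sampling step of zero
  # exit point: full slab thickness 160 mm = 16 cm
  d_exit <- radiological_depth(bx$ct, bx$body, beam, c(0, 80, 0))
  expect_lt(abs(d_exit - 16), 0.45)
  # oblique ray vs fine-step (0.1 mm) integration, within 1%
  for (p in list(c(40, 60, 20), c(-64, 30, -24), c(12, 76, 36))) {
    got <- radiological_depth(bx$ct, bx$body, beam, p)
    want <- oracle_ray_depth(bx$body, beam$source, p, step = 0.1) / 10
    expect_lt(abs(got - want), max(0.01 * want, 0.06))
  }
  expect_error(radiological_depth(bx$ct, bx$body, beam, c(0, 0, 1e4)), "outside")
})

test_that("beam dose follows the attenuation/inverse-square closed form on the central axis", {
  # slab filling the grid in y, so central-axis depths are exact (the skin
  # coincides with the ray-clipping plane and sampling introduces no bias)
  bx <- box_phantom(half = c(80, 400, 40))
  y_entry <- bx$ct$origin[2] - bx$ct$spacing[2] / 2
  beam <- beam_geometry("AP", c(0, 0, 0), 1000)
  ap <- open_aperture(beam)
  pars <- dose_params(mu_eff = 0.02, buildup_cm = 3.2, sad = 1000, step_mm = 0.25)
  dg <- compute_beam_dose(bx$ct, bx$body, beam, ap, pars)
  # two voxels on the central axis past buildup: exact ratio
  iv1 <- fourfield:::nearest_voxel(bx$ct, c(0, -20, 0))
  iv2 <- fourfield:::nearest_voxel(bx$ct, c(0, 40, 0))
  y1 <- bx$ct$origin[2] + (iv1[2] - 1) * bx$ct$spacing[2]
  y2 <- bx$ct$origin[2] + (iv2[2] - 1) * bx$ct$spacing[2]
  d1 <- (y1 - y_entry) / 10; d2 <- (y2 - y_entry) / 10  # depths in cm
  r1 <- 1000 + y1; r2 <- 1000 + y2
  want <- exp(-0.02 * (d2 - d1)) * (r1 / r2)^2
  got <- dg$voxels[iv2[1], iv2[2], iv2[3]] / dg$voxels[iv1[1], iv1[2], iv1[3]]
  expect_lt(abs(got / want - 1), 1e-6)
  # outside the aperture projection: zero dose inside the body
  ap_narrow <- open_aperture(beam, half_u = 100, half_v = 20)
  dgn <- compute_beam_dose(bx$ct, bx$body, beam, ap_narrow, pars)
  out_v <- fourfield:::nearest_voxel(bx$ct, c(0, 0, 34))  # v ~ 34 mm > 20
  expect_true(bx$body$voxels[out_v[1], out_v[2], out_v[3]])
  expect_equal(dgn$voxels[out_v[1], out_v[2], out_v[3]], 0)
  in_v <- fourfield:::nearest_voxel(bx$ct, c(0, 0, 6))
  expect_gt(dgn$voxels[in_v[1], in_v[2], in_v[3]], 0)
  # outside the body: zero
  expect_true(all(dg$voxels[!bx$body$voxels] == 0))
  # linearity: weighting scales every voxel
  expect_equal(total_dose(list(dg), 2.5)$voxels, 2.5 * dg$voxels)
})

test_that("monotone depth falloff past buildup and buildup ramp near the surface", {
  bx <- box_phantom()
  beam <- beam_geometry("AP", c(0, 0, 0), 1000)
  dg <- compute_beam_dose(bx$ct, bx$body, beam, open_aperture(beam),
                          dose_params(step_mm = 0.5))
  ix <- fourfield:::nearest_voxel(bx$ct, c(0, 0, 0))
  prof <- dg$voxels[ix[1], , ix[3]]
  ys <- bx$ct$origin[2] + (seq_along(prof) - 1) * bx$ct$spacing[2]
  inside <- ys > -80 & ys < 80
  depth_cm <- (ys[inside] + 80) / 10
  p <- prof[inside]
  past <- depth_cm > 3.6
  expect_true(all(diff(p[past]) < 0))
  expect_lt(p[1], max(p))  # surface dose below the peak: buildup visible
})

test_that("AP and PA doses mirror in a symmetric phantom; totals superpose and commute", {
  bx <- box_phantom()
  iso <- c(0, 0, 0)
  beams <- four_beams(iso, 1000)
  pars <- dose_params(step_mm = 1)
  aps <- lapply(beams, open_aperture)
  dgs <- lapply(names(beams), function(nm)
    compute_beam_dose(bx$ct, bx$body, beams[[nm]], aps[[nm]], pars))
  names(dgs) <- names(beams)
  # mirror the PA dose grid in y: must equal AP (grid symmetric about y = 0)
  pa_flip <- dgs$PA$voxels[, rev(seq_len(dim(dgs$PA$voxels)[2])), ]
  ap <- dgs$AP$voxels
  rel <- abs(pa_flip - ap) / pmax(ap, 1e-12)
  expect_lt(max(rel[ap > 1e-9]), 1e-6)
  # identity and permutation invariance of the weighted sum
  expect_equal(total_dose(dgs, c(1, 0, 0, 0))$voxels, dgs$AP$voxels)
  t1 <- total_dose(dgs, c(0.4, 0.3, 0.2, 0.1))
  t2 <- total_dose(dgs[c(3, 1, 4, 2)], c(0.2, 0.4, 0.1, 0.3))
  expect_equal(t1$voxels, t2$voxels)
  # left-right symmetric phantom + equal weights -> mirror-symmetric total
  te <- total_dose(dgs, c(1, 1, 1, 1))
  tf <- te$voxels[rev(seq_len(dim(te$voxels)[1])), , ]
  rel2 <- abs(tf - te$voxels) / pmax(te$voxels, 1e-12)
  expect_lt(max(rel2[te$voxels > 1e-9]), 1e-6)
  expect_error(total_dose(list(dgs$AP, structure(list(voxels = array(0, c(2, 2, 2)),
                                                      spacing = c(1, 1, 1)),
                                                 class = "dose_grid")), c(1, 1)),
               "congruent")
})
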