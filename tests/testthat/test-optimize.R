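test_that("treated volume: no-op erosion, exact 5 mm contraction, brute-force oracle", {
  bx <- box_phantom(n = c(40, 40, 24), spacing = c(5, 5, 5))
  iso <- c(0, 0, 0)
  beams <- four_beams(iso, 1000)
  aps <- lapply(beams, open_aperture, half_u = 150, half_v = 70)
  # huge apertures, margin 0: treated volume is the whole body
  tv0 <- build_treated_volume(bx$body, beams, aps, margin_mm = 0)
  expect_identical(tv0$mask$voxels, bx$body$voxels)

  # rectangular-field intersection forming a box, 5 mm margin: each axis
  # shrinks by exactly 2 * 5 mm (one voxel each side at 5 mm spacing)
  aps_small <- lapply(beams, open_aperture, half_u = 52.5, half_v = 52.5)
  tv <- build_treated_volume(bx$body, beams, aps_small, margin_mm = 5)
  idx <- which(tv$mask$voxels)
  ai <- arrayInd(idx, dim(tv$mask$voxels))
  ext <- apply(ai, 2, function(ix) diff(range(ix)) + 1) * 5
  tv_raw <- build_treated_volume(bx$body, beams, aps_small, margin_mm = 0)
  ai0 <- arrayInd(which(tv_raw$mask$voxels), dim(tv$mask$voxels))
  ext0 <- apply(ai0, 2, function(ix) diff(range(ix)) + 1) * 5
  expect_equal(ext0 - ext, c(10, 10, 10))

  # voxelwise oracle on a coarse grid with asymmetric apertures
  aps_odd <- aps_small
  aps_odd$AP <- fit_mlc(fourfield:::new_aperture(beams$AP, -40, 55, -35, 50, 10))
  tv2 <- build_treated_volume(bx$body, beams, aps_odd, margin_mm = 0)
  want <- oracle_treated(bx$body, beams, aps_odd)
  expect_identical(tv2$mask$voxels, want)

  expect_error(build_treated_volume(bx$body, beams,
                                    lapply(beams, open_aperture, half_u = 150,
                                           half_v = 70), margin_mm = 60),
               "empty")
})

test_that("NNLS weight optimization matches a dense grid-search oracle on toy problems", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    D <- matrix(runif(n * 4, 0.2, 1.2), n, 4)
    if (rep %% 3 == 0) D[, 2] <- D[, 1] * 0.9 + 0.05  # near-collinear columns
    R <- 1
    A <- crossprod(D); b <- colSums(D) * R
    w <- fourfield:::nnls_small(A, b)
    w_or <- oracle_nnls_grid(D, R, w_max = 3, step = 1e-3)
    obj <- function(x) sum((D %*% x - R)^2)
    expect_true(all(w >= 0))
    # objective agreement (the oracle may sit on a flat ridge when columns
    # are collinear, so compare objectives, then weights)
    expect_lt(obj(w), obj(w_or) + 1e-5)
    if (abs(det(A)) > 1e-3) expect_lt(max(abs(w - w_or)), 2e-3)
  }
})

test_that("optimized weights respect symmetry and beat equal weights on the objective", {
  bx <- box_phantom()
  iso <- c(0, 0, 0)
  beams <- four_beams(iso, 1000)
  aps <- lapply(beams, open_aperture, half_u = 60, half_v = 30)
  pars <- dose_params(step_mm = 1)
  dgs <- lapply(names(beams), function(nm)
    compute_beam_dose(bx$ct, bx$body, beams[[nm]], aps[[nm]], pars))
  names(dgs) <- names(beams)
  tv <- build_treated_volume(bx$body, beams, aps, margin_mm = 5)
  w <- optimize_weights(dgs, tv, 45, isocenter = iso)
  expect_lt(abs(w$weights[["LL"]] - w$weights[["RL"]]), 1e-6 * w$weights[["LL"]])
  expect_lt(abs(w$weights[["AP"]] - w$weights[["PA"]]), 1e-6 * w$weights[["AP"]])
  # normalization: total at the isocenter voxel equals the prescription
  tot <- total_dose(dgs, w$weights)
  iv <- fourfield:::nearest_voxel(tot, iso)
  expect_equal(tot$voxels[iv[1], iv[2], iv[3]], 45, tolerance = 1e-9)

  we <- equal_weights(dgs, 45, iso)
  expect_lte(w$objective,
             fourfield:::plan_objective(dgs, tv, 45, we$weights_raw) + 1e-9)

  # permuting the beams permutes the weights identically
  perm <- c(2, 4, 1, 3)
  w2 <- optimize_weights(dgs[perm], tv, 45, isocenter = iso)
  expect_equal(unname(w2$weights), unname(w$weights[perm]), tolerance = 1e-9)

  # single-beam problem: weight forced by the normalization
  w1 <- optimize_weights(dgs["AP"], tv, 45, isocenter = iso)
  d_iso <- dgs$AP$voxels[iv[1], iv[2], iv[3]]
  expect_equal(unname(w1$weights), 45 / d_iso, tolerance = 1e-9)
})

test_that("equal weights deliver R/4 per beam at the calculation point", {
  mkg <- function(val) structure(list(voxels = array(val, c(3, 3, 3)),
                                      spacing = c(1, 1, 1), origin = c(-1, -1, -1),
                                      beam = "x", provenance = list()),
                                 class = "dose_grid")
  dgs <- list(AP = mkg(2), PA = mkg(1), LL = mkg(1), RL = mkg(1))
  w <- equal_weights(dgs, 100, c(0, 0, 0))
  expect_equal(unname(w$weights), c(12.5, 25, 25, 25))
  tot <- total_dose(dgs, w$weights)
  expect_equal(tot$voxels[2, 2, 2], 100)
  expect_error(equal_weights(list(AP = mkg(0)), 100, c(0, 0, 0)), "zero dose")
})

test_that("plan metrics: uniform dose, constructed 1 cc hot spot, 107% flag, V95 monotonicity", {
  sp <- c(5, 5, 5)  # 125 mm^3 voxels; 8 voxels = 1 cc
  dims <- c(12, 12, 12)
  mkdose <- function(vals) structure(list(voxels = array(vals, dims), spacing = sp,
                                          origin = c(0, 0, 0), beam = "total",
                                          provenance = list()), class = "dose_grid")
  treated <- structure(list(mask = structure_mask(array(TRUE, dims), sp, c(0, 0, 0),
                                                  "treated"),
                            contraction_margin_mm = 5), class = "treated_volume")
  uni <- mkdose(100)
  m <- compute_plan_metrics(uni, treated, 100)
  expect_equal(m$d_max_1cc, 100)
  expect_equal(m$v95_treated, 100)
  expect_false(m$flag_high_dmax)

  # exactly 8 voxels (1 cc) at 120% over a 100% background
  v <- array(100, dims); v[1:8, 1, 1] <- 120
  m2 <- compute_plan_metrics(mkdose(v), treated, 100)
  expect_equal(m2$d_max_1cc, 120)
  expect_true(m2$flag_high_dmax)

  # flag boundary exactly at 107.0
  v3 <- array(100, dims); v3[1:8, 1, 1] <- 107
  m3 <- compute_plan_metrics(mkdose(v3), treated, 100)
  expect_equal(m3$d_max_1cc, 107)
  expect_true(m3$flag_high_dmax)
  v4 <- array(100, dims); v4[1:8, 1, 1] <- 106.9
  expect_false(compute_plan_metrics(mkdose(v4), treated, 100)$flag_high_dmax)

  # V95 never decreases when every voxel's dose increases
  set.seed(5)
  base <- array(runif(prod(dims), 80, 110), dims)
  inc <- base + runif(prod(dims), 0, 10)
  expect_gte(compute_plan_metrics(mkdose(inc), treated, 100)$v95_treated,
             compute_plan_metrics(mkdose(base), treated, 100)$v95_treated)
})
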