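test_that("search domain equals the brute-force distance-to-surface shell", {
  arr <- array(FALSE, c(14, 12, 8))
  arr[4:10, 4:9, 3:6] <- TRUE
  sm <- structure_mask(arr, c(2, 2, 3), c(0, 0, 0), "body")
  vol <- ct_volume(array(0, dim(arr)), sm$spacing, sm$origin)
  for (bw in c(2.5, 4.5)) {
    dom <- build_search_domain(vol, sm, bw)
    want <- oracle_shell(arr, sm$spacing, bw)
    expect_identical(dom$voxels, want)
  }
  expect_error(build_search_domain(vol, structure_mask(array(FALSE, dim(arr)),
                                                       sm$spacing, sm$origin), 5),
               "empty")
})

test_that("deep interior is excluded from the shell, the boundary included", {
  seg <- default_segmented()
  dom <- build_search_domain(seg$ct, seg$body, 10)
  ctr <- fourfield:::nearest_voxel(seg$ct, c(0, -20, 0))
  expect_false(dom$voxels[ctr[1], ctr[2], ctr[3]])
  bd <- fourfield:::boundary_index_matrix(seg$body$voxels)[1, ] + 1
  expect_true(dom$voxels[bd[1], bd[2], bd[3]])
})

test_that("candidate finding hits the three truth fiducials and excludes deep bone", {
  phc <- noiseless_phantom()
  ctn <- remove_couch(phc$ct, detect_couch(phc$ct))
  body <- segment_body(ctn)
  dom <- build_search_domain(ctn, body, 10)
  cand <- find_fiducial_candidates(ctn, dom, 800, body)
  expect_equal(nrow(cand), 3)
  # each candidate within one voxel of a truth fiducial center
  f <- phc$truth$fiducials
  for (i in seq_len(3)) {
    d <- sqrt(rowSums(sweep(f, 2, c(cand$x[i], cand$y[i], cand$z[i]))^2))
    expect_lt(min(d), max(phc$ct$spacing))
  }
  expect_true(all(cand$mean_hu >= 800))
  expect_true(all(cand$surface_distance <= 10))
  # bone voxels are far above threshold count but outside the shell: verify no
  # candidate sits at the vertebral column
  expect_true(all(abs(cand$y - phc$truth$spec$vert_center_y) > 20 |
                    abs(cand$x) > 50))
})

test_that("filtering removes oversized and posterior decoys and equals the exhaustive-triple oracle", {
  phc <- noiseless_phantom()
  ctn <- remove_couch(phc$ct, detect_couch(phc$ct))
  body <- segment_body(ctn)
  dom <- build_search_domain(ctn, body, 10)

  ct2 <- ctn
  # oversized blob on the anterior skin, lateral of midline
  bv <- fourfield:::nearest_voxel(ct2, c(60, -119, -10))
  ct2$voxels[bv[1] + (-6:6), bv[2] + (-4:4), bv[3] + (-3:3)] <- 1500
  # small posterior-midline decoy on the skin (plausible size, wrong geometry)
  pv <- fourfield:::nearest_voxel(ct2, c(0, 84, -10))
  ct2$voxels[pv[1] + (0:1), pv[2] + (0:1), pv[3]] <- 1900
  cand <- find_fiducial_candidates(ct2, dom, 800, body)
  expect_gte(nrow(cand), 5)
  sel <- filter_candidates(cand, body, 1, 200)
  expect_setequal(sel$role, c("anterior", "left_lateral", "right_lateral"))
  # the selected triple is the true one: all near the truth fiducials
  f <- phc$truth$fiducials
  for (i in seq_len(3)) {
    d <- sqrt(rowSums(sweep(f, 2, c(sel$x[i], sel$y[i], sel$z[i]))^2))
    expect_lt(min(d), max(phc$ct$spacing))
  }

  # independent oracle: exhaustive enumeration over all surviving triples with
  # the documented inconsistency score
  surv <- cand[cand$voxel_count >= 1 & cand$voxel_count <= 200, ]
  combs <- combn(nrow(surv), 3)
  scores <- apply(combs, 2, function(ix) {
    tri <- surv[ix, ]
    o <- order(tri$y)
    lat <- tri[o[2:3], ]
    abs(lat$y[1] - lat$y[2]) + (max(tri$z) - min(tri$z)) +
      abs(tri$x[o[1]] - mean(lat$x))
  })
  best <- surv[combs[, which.min(scores)], ]
  expect_setequal(round(sort(best$x), 6), round(sort(sel$x), 6))
})

test_that("too few candidates fail with a per-criterion diagnostic", {
  cand <- data.frame(x = c(0, 1, 2, 3), y = c(0, 0, 0, 0), z = 0,
                     voxel_count = c(500, 400, 2, 3), mean_hu = 1500,
                     surface_distance = 1, role = "unassigned")
  expect_error(filter_candidates(cand, NULL, 1, 200), "size")
})

test_that("isocenter combination rule and residual behave as documented", {
  mkf <- function(xyz, roles) {
    data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], voxel_count = 5,
               mean_hu = 2000, surface_distance = 1, role = roles)
  }
  roles <- c("anterior", "left_lateral", "right_lateral")
  # perfect intersection at P
  P <- c(3, -40, 12)
  f <- mkf(rbind(c(3, -120, 12), c(160, -40, 12), c(-160, -40, 12)), roles)
  r <- compute_isocenter(f)
  expect_equal(r$isocenter, P)
  expect_equal(r$residual, 0)
  # laterals on adjacent 2.5 mm slices: z averaged, residual reported
  f2 <- mkf(rbind(c(3, -120, 12), c(160, -40, 12), c(-160, -40, 14.5)), roles)
  r2 <- compute_isocenter(f2)
  expect_equal(r2$isocenter[3], mean(c(12, 12, 14.5)))
  expect_gte(r2$residual, 2.5)
  # duplicate roles rejected
  f3 <- f; f3$role <- c("anterior", "anterior", "right_lateral")
  expect_error(compute_isocenter(f3), "role")
})

test_that("detected isocenter is accurate, inside the body, and translation-equivariant", {
  seg <- default_segmented()
  iso <- detect_isocenter(seg$ct, seg$body)
  err <- sqrt(sum((iso$isocenter - seg$ph$truth$isocenter)^2))
  expect_lt(err, 2)
  iv <- fourfield:::nearest_voxel(seg$ct, iso$isocenter)
  expect_true(seg$body$voxels[iv[1], iv[2], iv[3]])

  # translation equivariance: shift the whole phantom by whole voxels
  # (positive shifts chosen so nothing wraps into anatomy)
  sh <- c(3, 4, 2) # voxels
  ph <- seg$ph
  shift_mm <- sh * ph$ct$spacing
  cshift <- function(n, s) c((n - s + 1):n, 1:(n - s))
  d <- dim(ph$ct$voxels)
  v2 <- ph$ct$voxels[cshift(d[1], sh[1]), cshift(d[2], sh[2]), cshift(d[3], sh[3])]
  ct2 <- ct_volume(v2, ph$ct$spacing, ph$ct$origin)
  ctn2 <- remove_couch(ct2, detect_couch(ct2))
  body2 <- segment_body(ctn2)
  iso2 <- detect_isocenter(ctn2, body2)
  expect_lt(max(abs(iso2$isocenter - (iso$isocenter + shift_mm))),
            0.5 * max(ph$ct$spacing))
})
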