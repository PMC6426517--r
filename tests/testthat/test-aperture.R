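mk_landmarks <- function(inlet = c(-120, 120), l4l5 = 90, obt = -80,
                         symph = 60, sacr = -75) {
  structure(list(inlet_u_min = inlet[1], inlet_u_max = inlet[2], l4l5_v = l4l5,
                 obturator_inferior_v = obt, symphysis_anterior_u = symph,
                 sacrum_posterior_u = sacr, warnings = character(0)),
            class = "landmark_set")
}

test_that("the 2 cm inlet margin rule and the zero-margin identity hold exactly", {
  beams <- four_beams(c(0, 0, 0), 1000)
  aps <- design_apertures(mk_landmarks(), rule_config(), beams)
  # inlet extremes +-120 with 20 mm margin -> AP borders +-140
  expect_equal(aps$AP$u_min, -140)
  expect_equal(aps$AP$u_max, 140)
  expect_equal(aps$AP$u_max - aps$AP$u_min, 240 + 2 * 20)
  # default superior/inferior margins are zero: v borders equal the landmarks
  expect_equal(aps$AP$v_max, 90)
  expect_equal(aps$AP$v_min, -80)
  # lateral fields: anterior 10 mm beyond the symphysis, posterior 5 mm
  # beyond the sacrum
  expect_equal(aps$RL$u_max, 60 + 10)
  expect_equal(aps$RL$u_min, -75 - 5)

  zero <- rule_config(lateral_margin_mm = 0, anterior_margin_mm = 0,
                      posterior_margin_mm = 0)
  aps0 <- design_apertures(mk_landmarks(), zero, beams)
  expect_equal(c(aps0$AP$u_min, aps0$AP$u_max, aps0$AP$v_min, aps0$AP$v_max),
               c(-120, 120, -80, 90))
})

test_that("opposed beams describe the same world-space opening (u mirror)", {
  beams <- four_beams(c(3, -10, 5), 1000)
  aps <- design_apertures(mk_landmarks(inlet = c(-100, 80)), rule_config(), beams)
  expect_equal(aps$PA$u_min, -aps$AP$u_max)
  expect_equal(aps$PA$u_max, -aps$AP$u_min)
  expect_equal(aps$LL$u_min, -aps$RL$u_max)
  expect_equal(aps$LL$u_max, -aps$RL$u_min)
  expect_equal(aps$PA$v_min, aps$AP$v_min)
  # world consistency: e_u of opposed beams are opposite vectors
  expect_equal(beams$AP$e_u, -beams$PA$e_u)
  expect_equal(beams$RL$e_u, -beams$LL$e_u)
})

test_that("aperture width is affine in the inlet width (monotonicity)", {
  beams <- four_beams(c(0, 0, 0), 1000)
  w0 <- design_apertures(mk_landmarks(inlet = c(-100, 100)), rule_config(), beams)
  for (delta in c(10, 25.5)) {
    w1 <- design_apertures(mk_landmarks(inlet = c(-100, 100 + delta)),
                           rule_config(), beams)
    expect_equal((w1$AP$u_max - w1$AP$u_min) - (w0$AP$u_max - w0$AP$u_min), delta)
  }
  expect_error(design_apertures(mk_landmarks(inlet = c(50, -50)), rule_config(),
                                beams), "degenerate")
})

test_that("MLC fitting: alignment, pair counting, and polygon band extents", {
  beam <- beam_geometry("AP", c(0, 0, 0))
  # rectangle aligned to leaf boundaries: every in-field pair opens exactly
  ap <- fourfield:::new_aperture(beam, -50, 70, -40, 60, 10)
  m <- fit_mlc(ap)$mlc
  open <- m$leaf_u[, 1] <= m$leaf_u[, 2]
  expect_equal(sum(open), 10)
  expect_true(all(abs(m$leaf_u[open, 1] + 50) < 1e-9))
  expect_true(all(abs(m$leaf_u[open, 2] - 70) < 1e-9))

  # v extent 95 mm -> 10 pairs open (coverage rounds up)
  ap2 <- fit_mlc(fourfield:::new_aperture(beam, -50, 50, 0, 95, 10))
  expect_equal(sum(ap2$mlc$leaf_u[, 1] <= ap2$mlc$leaf_u[, 2]), 10)

  # 45-degree corner cut: each band's opening equals the polygon's min/max u
  ap3 <- fourfield:::new_aperture(beam, -60, 60, -30, 50, 10)
  ap3$polygon <- cbind(u = c(-60, 60, 60, -20, -60),
                       v = c(-30, -30, 50, 50, 10))  # cut corner upper-left
  m3 <- fit_mlc(ap3)$mlc
  for (i in seq_len(nrow(m3$leaf_u))) {
    b0 <- m3$bands[i, 1]; b1 <- m3$bands[i, 2]
    vs <- seq(max(b0, -30), min(b1, 50), length.out = 9)
    if (vs[1] > vs[length(vs)]) next
    # exhaustive per-band scan of the polygon edge x-extent
    left_edge <- function(v) if (v <= 10) -60 else -60 + (v - 10)
    want <- range(vapply(vs, left_edge, numeric(1)), 60)
    expect_lt(abs(m3$leaf_u[i, 1] - want[1]), 1e-6)
    expect_equal(m3$leaf_u[i, 2], 60)
  }
})

test_that("rasterized MLC opening covers the polygon for random corner-cut fields", {
  set.seed(17)
  beam <- beam_geometry("AP", c(0, 0, 0))
  for (rep in 1:20) {
    u0 <- runif(1, -120, -40); u1 <- runif(1, 40, 120)
    v0 <- runif(1, -100, -30); v1 <- runif(1, 30, 100)
    cut <- runif(2, 5, 40)
    poly <- cbind(u = c(u0, u1, u1, u0 + cut[1], u0),
                  v = c(v0, v0, v1, v1, v1 - cut[2]))
    ap <- fourfield:::new_aperture(beam, u0, u1, v0, v1, 10)
    ap$polygon <- poly
    ap <- fit_mlc(ap)
    us <- seq(u0 - 5, u1 + 5, by = 2.5)
    vs <- seq(v0 - 5, v1 + 5, by = 2.5)
    inpoly <- rasterize_polygon_uv(poly, us, vs)
    uv <- expand.grid(u = us, v = vs)
    inmlc <- matrix(aperture_contains(ap, uv$u, uv$v), length(us))
    expect_true(all(inmlc[inpoly]))  # never under-covers
    # over-coverage bounded: everything opened lies within one leaf width of
    # the polygon's v-range and inside its u-range
    expect_true(all(uv$v[inmlc] >= v0 - 10 & uv$v[inmlc] <= v1 + 10))
  }
})
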