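#' Bone label codes used by the phantom and the bone segmenter
#'
#' @return named integer vector mapping structure names to label codes.
#' @export
bone_labels <- function() {
  c(bony_pelvis = 1L, femoral_head_L = 2L, femoral_head_R = 3L,
    sacrum = 4L, L4 = 5L, L5 = 6L)
}

#' Specification of a synthetic pelvis CT phantom
#'
#' Defines a schematic supine female pelvis on a flat treatment couch: an
#' elliptical soft-tissue body, a bony pelvis ring (whose inner opening is the
#' pelvic inlet) with an inferior obturator frame and an anterior pubic
#' symphysis block, two femoral heads, a sacrum slab, L4 and L5 vertebral
#' bodies, and three radiopaque skin fiducials whose axis lines intersect at
#' the intended isocenter. The anatomy is deliberately schematic (ellipses,
#' annuli, boxes, spheres): the planning rules downstream consume projected
#' silhouettes and landmark geometry, which these shapes provide with exact,
#' recoverable ground truth.
#'
#' All lengths in mm, HU for intensities. The default grid is 248 x 184 x 80
#' voxels at (1.5, 1.5, 3.0) mm, i.e. planning-CT-like in-plane resolution so
#' that small radiopaque skin fiducials are resolvable.
#'
#' @param shape integer length 3 grid shape.
#' @param spacing voxel spacing mm.
#' @param body_halfaxes lateral and anteroposterior half-axes of the body
#'   ellipse.
#' @param body_center_y anteroposterior position of the body ellipse center.
#' @param couch_top_y y of the couch anterior surface; `couch_thickness`,
#'   `couch_hu` describe the slab (set `couch_top_y = NA` for no couch).
#' @param soft_hu,bone_hu,couch_hu,fiducial_hu tissue CT numbers.
#' @param isocenter intended marked isocenter (world mm); must be inside the
#'   body.
#' @param inlet_width pelvic inlet width (inner diameter of the pelvic ring).
#' @param ring_thickness radial thickness of the pelvic ring.
#' @param ring_center_z,ring_y z center of the ring and its y (depth) range.
#' @param femoral_radius,femoral_centers femoral head spheres.
#' @param l4_height,l5_height,l4l5_gap,l4l5_interspace_z vertebral column: body
#'   heights, interspace gap and the world z of the interspace center.
#' @param vert_radius,vert_center_y vertebral body cylinder radius and depth.
#' @param obturator_inferior_z inferior z of the obturator foramina openings;
#'   `obturator_radius` their radius.
#' @param sacrum_box,symphysis_box 2 x 3 matrices (rows = min/max corners) for
#'   the sacrum slab and pubic symphysis block.
#' @param fiducial_diameter diameter of the skin fiducial spheres.
#' @param contrast_n,contrast_hu,contrast_radius optional bowel-contrast blobs.
#' @param noise_sigma additive Gaussian HU noise standard deviation.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(248L, 184L, 80L),
                         spacing = c(1.5, 1.5, 3.0),
                         body_halfaxes = c(170, 105),
                         body_center_y = -20,
                         couch_top_y = 95,
                         couch_thickness = 24,
                         couch_hu = -100,
                         soft_hu = 40,
                         bone_hu = 400,
                         fiducial_hu = 2000,
                         isocenter = c(0, -20, -10),
                         inlet_width = 130,
                         ring_thickness = 15,
                         ring_center_z = -5,
                         ring_y = c(-45, -5),
                         femoral_radius = 24,
                         femoral_centers = rbind(c(105, -25, -55), c(-105, -25, -55)),
                         l4_height = 28,
                         l5_height = 28,
                         l4l5_gap = 8,
                         l4l5_interspace_z = 80,
                         vert_radius = 20,
                         vert_center_y = 18,
                         obturator_inferior_z = -91,
                         obturator_radius = 13,
                         sacrum_box = rbind(c(-35, 10, -60), c(35, 55, 20)),
                         symphysis_box = rbind(c(-15, -80, -60), c(15, -40, -20)),
                         fiducial_diameter = 4,
                         contrast_n = 0L,
                         contrast_hu = 300,
                         contrast_radius = 15,
                         noise_sigma = 15,
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(spacing <= 0) || any(shape < 4)) stop("phantom_spec: bad grid")
    if (!(fiducial_hu > bone_hu && bone_hu > soft_hu && soft_hu > -1000))
      stop("phantom_spec: need fiducial HU > bone HU > soft-tissue HU > air")
    if (any(c(body_halfaxes, inlet_width, ring_thickness, femoral_radius,
              l4_height, l5_height, fiducial_diameter) <= 0))
      stop("phantom_spec: lengths must be positive")
    e <- (isocenter[1] / body_halfaxes[1])^2 +
      ((isocenter[2] - body_center_y) / body_halfaxes[2])^2
    if (e >= 1) stop("phantom_spec: isocenter outside the body ellipse")
    ext <- (shape - 1) * spacing / 2
    fx <- body_halfaxes[1] * sqrt(1 - ((isocenter[2] - body_center_y) / body_halfaxes[2])^2)
    if (fx + fiducial_diameter / 2 > ext[1])
      stop("phantom_spec: lateral fiducial placement off-grid")
    y_ant <- body_center_y - body_halfaxes[2] * sqrt(1 - (isocenter[1] / body_halfaxes[1])^2)
    if (y_ant - fiducial_diameter / 2 < -ext[2])
      stop("phantom_spec: anterior fiducial placement off-grid")
  })
  invisible(spec)
}

grid_axes <- function(spec) {
  ext <- (spec$shape - 1) * spec$spacing / 2
  origin <- -ext
  list(origin = origin,
       x = origin[1] + (seq_len(spec$shape[1]) - 1) * spec$spacing[1],
       y = origin[2] + (seq_len(spec$shape[2]) - 1) * spec$spacing[2],
       z = origin[3] + (seq_len(spec$shape[3]) - 1) * spec$spacing[3])
}

# world positions of the three skin fiducials implied by the spec:
# one anterior sharing (x, z) with the isocenter, two lateral sharing (y, z)
fiducial_centers <- function(spec) {
  a <- spec$body_halfaxes[1]; b <- spec$body_halfaxes[2]; cy <- spec$body_center_y
  iso <- spec$isocenter
  y_ant <- cy - b * sqrt(1 - (iso[1] / a)^2)
  x_lat <- a * sqrt(1 - ((iso[2] - cy) / b)^2)
  rbind(anterior = c(iso[1], y_ant, iso[3]),
        left = c(x_lat, iso[2], iso[3]),
        right = c(-x_lat, iso[2], iso[3]))
}

#' Generate a synthetic pelvis CT phantom with ground truth
#'
#' Rasterizes the [phantom_spec()] anatomy onto the grid (voxel centers inside
#' a shape get its HU; fiducials use partial-volume mixing from supersampling),
#' then adds Gaussian HU noise. Truth masks are the noiseless rasterizations.
#' Deterministic for a fixed spec (the RNG state is isolated and restored).
#'
#' @param spec a [phantom_spec()].
#' @return list with `ct` (a [ct_volume()]) and `truth`, a `phantom_truth`
#'   holding `body` and `couch` masks, a labeled `bones` array (codes per
#'   [bone_labels()]), the `isocenter`, the three `fiducials` (world mm), and
#'   the world-space `landmarks` (inlet lateral extremes, L4/L5 interspace z,
#'   obturator inferior z, symphysis anterior y, sacrum posterior y).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  ax <- grid_axes(spec)
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  dims <- c(nx, ny, nz)

  X <- array(ax$x, dims)
  Y <- array(rep(ax$y, each = nx), dims)
  Z <- array(rep(ax$z, each = nx * ny), dims)

  a <- spec$body_halfaxes[1]; b <- spec$body_halfaxes[2]; cy <- spec$body_center_y
  body <- (X / a)^2 + ((Y - cy) / b)^2 <= 1

  bones <- array(0L, dims)
  lb <- bone_labels()

  # pelvic ring: annulus in (x, z) so the AP projection encloses the inlet
  r_in <- spec$inlet_width / 2
  r_out <- r_in + spec$ring_thickness
  R2 <- X^2 + (Z - spec$ring_center_z)^2
  ring <- R2 >= r_in^2 & R2 <= r_out^2 &
    Y >= spec$ring_y[1] & Y <= spec$ring_y[2]

  # obturator frame: plate below the inlet with two circular openings
  obt_cz <- spec$obturator_inferior_z + spec$obturator_radius
  obt_cx <- 28
  frame <- abs(X) <= 60 & Z >= spec$obturator_inferior_z - 9 & Z <= -40 &
    Y >= spec$ring_y[1] & Y <= spec$ring_y[2]
  holes <- ((X - obt_cx)^2 + (Z - obt_cz)^2 <= spec$obturator_radius^2) |
    ((X + obt_cx)^2 + (Z - obt_cz)^2 <= spec$obturator_radius^2)
  frame <- frame & !holes

  inbox <- function(B) {
    X >= B[1, 1] & X <= B[2, 1] & Y >= B[1, 2] & Y <= B[2, 2] &
      Z >= B[1, 3] & Z <= B[2, 3]
  }
  symph <- inbox(spec$symphysis_box)
  bones[(ring | frame | symph) & body] <- lb[["bony_pelvis"]]

  for (s in 1:2) {
    fc <- spec$femoral_centers[s, ]
    sph <- (X - fc[1])^2 + (Y - fc[2])^2 + (Z - fc[3])^2 <= spec$femoral_radius^2
    bones[sph & body] <- if (fc[1] > 0) lb[["femoral_head_L"]] else lb[["femoral_head_R"]]
  }
  bones[inbox(spec$sacrum_box) & body] <- lb[["sacrum"]]

  l5_top <- spec$l4l5_interspace_z - spec$l4l5_gap / 2
  l4_bot <- spec$l4l5_interspace_z + spec$l4l5_gap / 2
  vert <- X^2 + (Y - spec$vert_center_y)^2 <= spec$vert_radius^2
  bones[vert & Z >= l4_bot & Z <= l4_bot + spec$l4_height & body] <- lb[["L4"]]
  bones[vert & Z <= l5_top & Z >= l5_top - spec$l5_height & body] <- lb[["L5"]]

  couch <- array(FALSE, dims)
  if (is.finite(spec$couch_top_y)) {
    # the patient rests on the couch: keep the couch top posterior to the body
    # surface with a visible air gap (>= 3 voxels)
    top <- max(spec$couch_top_y, cy + b + 3 * spec$spacing[2])
    couch <- Y >= top & Y <= top + spec$couch_thickness
  }

  hu <- array(-1000, dims)
  hu[body] <- spec$soft_hu
  hu[bones > 0L] <- spec$bone_hu
  hu[couch] <- spec$couch_hu

  # deterministic RNG scope
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(spec$seed)

  if (spec$contrast_n > 0) {
    for (q in seq_len(spec$contrast_n)) {
      cc <- c(stats::runif(1, -0.45 * a, 0.45 * a),
              cy + stats::runif(1, -0.45 * b, 0.45 * b),
              stats::runif(1, min(ax$z) * 0.6, max(ax$z) * 0.6))
      blob <- (X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2 <= spec$contrast_radius^2
      sel <- blob & body & bones == 0L
      hu[sel] <- spec$contrast_hu
    }
  }

  fids <- fiducial_centers(spec)
  hu <- rasterize_fiducials(hu, spec, ax, fids)

  if (spec$noise_sigma > 0)
    hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sigma), dims)

  ct <- ct_volume(hu, spacing = spec$spacing, origin = ax$origin)
  truth <- structure(list(
    body = structure_mask(body, spec$spacing, ax$origin, "body"),
    couch = structure_mask(couch, spec$spacing, ax$origin, "couch"),
    bones = bones,
    isocenter = spec$isocenter,
    fiducials = fids,
    landmarks = list(
      inlet_x = c(-r_in, r_in),
      inlet_width = spec$inlet_width,
      l4l5_interspace_z = spec$l4l5_interspace_z,
      obturator_inferior_z = spec$obturator_inferior_z,
      symphysis_anterior_y = spec$symphysis_box[1, 2],
      sacrum_posterior_y = spec$sacrum_box[2, 2]),
    spec = spec), class = "phantom_truth")
  list(ct = ct, truth = truth)
}

# partial-volume rasterization of the small fiducial spheres: each voxel in the
# sphere's bounding box gets HU mixed by the fraction of 5^3 subsamples inside
rasterize_fiducials <- function(hu, spec, ax, fids) {
  r <- spec$fiducial_diameter / 2
  ss <- 5L
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  sub <- as.matrix(expand.grid(dx = off * spec$spacing[1],
                               dy = off * spec$spacing[2],
                               dz = off * spec$spacing[3]))
  for (f in seq_len(nrow(fids))) {
    ctr <- fids[f, ]
    lo <- floor((ctr - r - ax$origin) / spec$spacing) + 1
    hi <- ceiling((ctr + r - ax$origin) / spec$spacing) + 1
    lo <- pmax(lo, 1); hi <- pmin(hi, spec$shape)
    if (any(lo > hi)) stop("phantom_spec: fiducial placement off-grid")
    for (i in lo[1]:hi[1]) for (j in lo[2]:hi[2]) for (k in lo[3]:hi[3]) {
      cpos <- ax$origin + (c(i, j, k) - 1) * spec$spacing
      d2 <- sweep(sub, 2, cpos - ctr, "+")
      frac <- mean(rowSums(d2^2) <= r^2)
      if (frac > 0)
        hu[i, j, k] <- frac * spec$fiducial_hu + (1 - frac) * hu[i, j, k]
    }
  }
  hu
}

#' Jittered phantom cohort specifications
#'
#' Derives `n` phantom specs from a base spec with anatomy jittered uniformly:
#' body half-axes (+-12, +-8 mm), inlet width (+-12 mm), isocenter
#' (+-10, +-8, +-9 mm), couch top (+-6 mm). Per-item seeds are derived
#' deterministically from `seed`.
#'
#' @param base base [phantom_spec()].
#' @param n number of phantoms (>= 1).
#' @param seed cohort seed.
#' @param iso_x_range optional length-2 range overriding the isocenter lateral
#'   jitter (used to build deliberately off-center cohorts).
#' @return list of `n` `phantom_spec` objects.
#' @export
cohort_specs <- function(base = phantom_spec(), n, seed = 1L, iso_x_range = c(-10, 10)) {
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base
    sp$body_halfaxes <- base$body_halfaxes + c(stats::runif(1, -12, 12),
                                               stats::runif(1, -8, 8))
    sp$inlet_width <- base$inlet_width + stats::runif(1, -12, 12)
    sp$isocenter <- base$isocenter + c(stats::runif(1, iso_x_range[1], iso_x_range[2]),
                                       stats::runif(1, -8, 8),
                                       stats::runif(1, -9, 9))
    sp$couch_top_y <- base$couch_top_y + stats::runif(1, -6, 6)
    sp$seed <- as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483647)
    validate_phantom_spec(sp)
    out[[i]] <- sp
  }
  out
}

#' Generate a reproducible cohort of phantoms
#'
#' Equivalent to `lapply(cohort_specs(base, n, seed), generate_phantom)`;
#' emulates a retrospective scan cohort with per-patient anatomical variation.
#'
#' @inheritParams cohort_specs
#' @return list of `n` `list(ct, truth)` phantoms.
#' @export
generate_cohort <- function(base = phantom_spec(), n, seed = 1L) {
  lapply(cohort_specs(base, n, seed), generate_phantom)
}
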