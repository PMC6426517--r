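# Shared fixtures, memoized so expensive phantoms/plans are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

default_phantom <- function() memo("default_phantom", generate_phantom(phantom_spec()))

noiseless_phantom <- function() memo("noiseless_phantom", {
  sp <- phantom_spec()
  sp$noise_sigma <- 0
  generate_phantom(sp)
})

# couch removed + body segmented for the default noisy phantom
default_segmented <- function() memo("default_segmented", {
  ph <- default_phantom()
  cd <- detect_couch(ph$ct)
  ctn <- remove_couch(ph$ct, cd)
  list(ph = ph, couch = cd, ct = ctn, body = segment_body(ctn))
})

# full default plan (with dose), reused across pipeline and acceptance tests
default_plan <- function() memo("default_plan", {
  ph <- default_phantom()
  auto_plan(ph$ct, plan_order(), plan_config())
})

# a small water-box phantom for dose-model tests: homogeneous box body,
# symmetric about the isocenter, coarse grid for speed
box_phantom <- function(n = c(60, 60, 30), spacing = c(4, 4, 4), hu = 0,
                        half = c(80, 80, 40)) {
  ext <- (n - 1) * spacing / 2
  origin <- -ext
  vox <- array(-1000, n)
  ax <- list(x = origin[1] + (seq_len(n[1]) - 1) * spacing[1],
             y = origin[2] + (seq_len(n[2]) - 1) * spacing[2],
             z = origin[3] + (seq_len(n[3]) - 1) * spacing[3])
  X <- array(ax$x, n)
  Y <- array(rep(ax$y, each = n[1]), n)
  Z <- array(rep(ax$z, each = n[1] * n[2]), n)
  body <- abs(X) <= half[1] & abs(Y) <= half[2] & abs(Z) <= half[3]
  vox[body] <- hu
  list(ct = ct_volume(vox, spacing, origin),
       body = structure_mask(body, spacing, origin, "body"))
}

# large open aperture for a beam (everything inside a big rectangle)
open_aperture <- function(beam, half_u = 100, half_v = 50, leaf_width = 10) {
  ap <- design_apertures(
    structure(list(inlet_u_min = -half_u + 20, inlet_u_max = half_u - 20,
                   l4l5_v = half_v, obturator_inferior_v = -half_v,
                   symphysis_anterior_u = half_u - 10,
                   sacrum_posterior_u = -half_u + 5, warnings = character(0)),
              class = "landmark_set"),
    rule_config(), stats::setNames(lapply(c("AP", "PA", "LL", "RL"),
                                          function(nm) beam_geometry(nm, beam$isocenter, beam$sad)),
                                   c("AP", "PA", "LL", "RL")))[[beam$name]]
  fit_mlc(ap)
}
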