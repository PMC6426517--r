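#' Aperture design rules (margins in isocenter-plane mm)
#'
#' The anterior/posterior/lateral/superior/inferior margins are applied
#' outward from the corresponding landmark; the published example rule for the
#' lateral border of the AP/PA fields is "2 cm wider than the pelvic inlet",
#' interpreted (per clinical convention) as a 20 mm margin on each side. All
#' margins are configuration, not constants, so the rule set can be adjusted
#' for a range of disease presentations.
#'
#' @param lateral_margin_mm AP/PA lateral margin beyond the inlet (each side).
#' @param superior_margin_mm margin above the L4/L5 interspace.
#' @param inferior_margin_mm margin below the obturator foramina.
#' @param anterior_margin_mm lateral-field margin in front of the pubic
#'   symphysis.
#' @param posterior_margin_mm lateral-field margin behind the sacrum.
#' @param leaf_width_mm MLC leaf width.
#' @return list of class `rule_config`.
#' @export
rule_config <- function(lateral_margin_mm = 20, superior_margin_mm = 0,
                        inferior_margin_mm = 0, anterior_margin_mm = 10,
                        posterior_margin_mm = 5, leaf_width_mm = 10) {
  structure(list(lateral_margin_mm = lateral_margin_mm,
                 superior_margin_mm = superior_margin_mm,
                 inferior_margin_mm = inferior_margin_mm,
                 anterior_margin_mm = anterior_margin_mm,
                 posterior_margin_mm = posterior_margin_mm,
                 leaf_width_mm = leaf_width_mm), class = "rule_config")
}

new_aperture <- function(beam, u_min, u_max, v_min, v_max, leaf_width) {
  if (!(u_min < u_max && v_min < v_max))
    stop("design_apertures: degenerate aperture rectangle for beam ", beam$name)
  polygon <- cbind(u = c(u_min, u_max, u_max, u_min),
                   v = c(v_min, v_min, v_max, v_max))
  structure(list(beam = beam, u_min = u_min, u_max = u_max,
                 v_min = v_min, v_max = v_max, polygon = polygon,
                 mlc = NULL, leaf_width = leaf_width), class = "aperture")
}

#' Design the four beam apertures from the bony landmarks
#'
#' AP field borders: laterally the pelvic inlet extremes plus the lateral
#' margin on each side; superiorly the L4/L5 interspace (plus margin);
#' inferiorly the obturator foramina (minus margin). Lateral fields share the
#' superior/inferior borders and run from in front of the pubic symphysis to
#' behind the sacrum. The PA and left-lateral apertures are the u-mirrors of
#' the AP and right-lateral apertures, so all four describe consistent
#' world-space openings. Rules are affine in the landmarks, so widening the
#' inlet by some amount widens the AP aperture by exactly that amount.
#'
#' @param landmarks a [extract_landmarks()] result.
#' @param rules a [rule_config()].
#' @param beams named list of the four [beam_geometry()] objects
#'   (see [four_beams()]).
#' @return named list of four `aperture` objects (`AP`, `PA`, `LL`, `RL`).
#' @export
design_apertures <- function(landmarks, rules = rule_config(), beams) {
  stopifnot(all(c("AP", "PA", "LL", "RL") %in% names(beams)))
  v_min <- landmarks$obturator_inferior_v - rules$inferior_margin_mm
  v_max <- landmarks$l4l5_v + rules$superior_margin_mm
  ap_u <- c(landmarks$inlet_u_min - rules$lateral_margin_mm,
            landmarks$inlet_u_max + rules$lateral_margin_mm)
  rl_u <- c(landmarks$sacrum_posterior_u - rules$posterior_margin_mm,
            landmarks$symphysis_anterior_u + rules$anterior_margin_mm)
  lw <- rules$leaf_width_mm
  list(
    AP = new_aperture(beams$AP, ap_u[1], ap_u[2], v_min, v_max, lw),
    PA = new_aperture(beams$PA, -ap_u[2], -ap_u[1], v_min, v_max, lw),
    LL = new_aperture(beams$LL, -rl_u[2], -rl_u[1], v_min, v_max, lw),
    RL = new_aperture(beams$RL, rl_u[1], rl_u[2], v_min, v_max, lw)
  )
}

# u extent of a polygon clipped to the band v in [b0, b1]; NULL if disjoint.
# Vertices inside the band plus edge intersections with the band planes give
# the exact extremes for straight-edged polygons.
poly_band_extent <- function(poly, b0, b1) {
  n <- nrow(poly)
  us <- numeric(0)
  for (i in seq_len(n)) {
    p <- poly[i, ]; q <- poly[if (i == n) 1L else i + 1L, ]
    if (p[2] >= b0 && p[2] <= b1) us <- c(us, p[1])
    for (vb in c(b0, b1)) {
      if ((p[2] - vb) * (q[2] - vb) < 0) {
        t <- (vb - p[2]) / (q[2] - p[2])
        us <- c(us, p[1] + t * (q[1] - p[1]))
      }
    }
  }
  if (length(us) == 0L) return(NULL)
  range(us)
}

#' Fit multileaf-collimator leaves to an aperture
#'
#' Leaves travel along u in fixed-width pairs partitioning v, with leaf edges
#' aligned to multiples of the leaf width around v = 0 (collimator angle 0).
#' Each pair covering part of the aperture polygon opens to the polygon's u
#' extent within its v band, so the fitted opening always covers the polygon
#' and over-covers by at most one leaf width in v; pairs outside the field
#' stay closed.
#'
#' @param aperture an `aperture` from [design_apertures()].
#' @param leaf_width_mm leaf width; defaults to the aperture's.
#' @return the aperture with `mlc` populated: `v_first`, `leaf_width`,
#'   `leaf_u` (k x 2 open intervals, min > max means closed) and `bands`.
#' @export
fit_mlc <- function(aperture, leaf_width_mm = NULL) {
  lw <- if (is.null(leaf_width_mm)) aperture$leaf_width else leaf_width_mm
  stopifnot(lw > 0)
  v_first <- floor(aperture$v_min / lw) * lw
  k <- as.integer(ceiling((aperture$v_max - v_first) / lw))
  leaf_u <- matrix(rep(c(1, -1), each = k), k, 2)
  bands <- cbind(v_first + (seq_len(k) - 1) * lw, v_first + seq_len(k) * lw)
  for (i in seq_len(k)) {
    ext <- poly_band_extent(aperture$polygon, bands[i, 1], bands[i, 2])
    if (!is.null(ext) && diff(ext) > 1e-9) leaf_u[i, ] <- ext
  }
  aperture$mlc <- list(v_first = v_first, leaf_width = lw,
                       leaf_u = leaf_u, bands = bands)
  aperture$leaf_width <- lw
  aperture
}

#' Test whether BEV points fall inside an aperture's MLC opening
#'
#' @param aperture an aperture with fitted MLC (see [fit_mlc()]).
#' @param u,v isocenter-plane coordinates (vectors, mm).
#' @return logical vector.
#' @export
aperture_contains <- function(aperture, u, v) {
  if (is.null(aperture$mlc)) aperture <- fit_mlc(aperture)
  m <- aperture$mlc
  band <- floor((v - m$v_first) / m$leaf_width) + 1
  ok <- band >= 1 & band <= nrow(m$leaf_u)
  res <- logical(length(u))
  bi <- band[ok]
  res[ok] <- u[ok] >= m$leaf_u[bi, 1] & u[ok] <= m$leaf_u[bi, 2]
  res
}
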