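# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles (exhaustive enumeration, closed forms) without calling
# the implementation paths they check.

# boundary voxels (same definition as the package documents: mask voxel with a
# face-adjacent background neighbor, grid border counting as background),
# found by explicit neighbor loops
oracle_boundary <- function(arr) {
  d <- dim(arr)
  out <- matrix(integer(0), 0, 3)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!arr[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    isb <- any(vapply(nb, function(p) {
      if (any(p < 1) || any(p > d)) TRUE else !arr[p[1], p[2], p[3]]
    }, logical(1)))
    if (isb) out <- rbind(out, c(i, j, k))
  }
  out
}

# all-pairs directed surface distances between two boundary point sets (mm)
oracle_surface_metrics <- function(a_arr, b_arr, spacing, hausdorff_pct = 100) {
  ba <- oracle_boundary(a_arr)
  bb <- oracle_boundary(b_arr)
  pa <- sweep(ba - 1, 2, spacing, "*")
  pb <- sweep(bb - 1, 2, spacing, "*")
  dmat <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), Vectorize(function(r, s)
    sqrt(sum((pa[r, ] - pb[s, ])^2))))
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  q <- hausdorff_pct / 100
  list(msd = (mean(dab) + mean(dba)) / 2,
       hd = if (q >= 1) max(max(dab), max(dba)) else
         max(stats::quantile(dab, q, names = FALSE),
             stats::quantile(dba, q, names = FALSE)))
}

# per-point distance-to-surface shell selection (the search-domain definition)
oracle_shell <- function(body_arr, spacing, bandwidth) {
  d <- dim(body_arr)
  idx_in <- which(body_arr); idx_out <- which(!body_arr)
  pts <- function(ix) sweep(arrayInd(ix, d) - 1, 2, spacing, "*")
  pin <- pts(idx_in); pout <- pts(idx_out)
  shell <- array(FALSE, d)
  for (r in seq_along(idx_in)) {
    dmin <- sqrt(min(colSums((t(pout) - pin[r, ])^2)))
    if (dmin <= bandwidth) shell[idx_in[r]] <- TRUE
  }
  for (r in seq_along(idx_out)) {
    dmin <- sqrt(min(colSums((t(pin) - pout[r, ])^2)))
    if (dmin <= bandwidth) shell[idx_out[r]] <- TRUE
  }
  shell
}

# per-voxel similar-triangles BEV projection with footprint splatting,
# written as an explicit scalar loop
oracle_bev <- function(mask, beam, pixel_mm, bev) {
  d <- dim(mask$voxels)
  img <- matrix(FALSE, nrow(bev$img), ncol(bev$img))
  fu_h <- sum(abs(beam$e_u) * mask$spacing) / 2
  fv_h <- sum(abs(beam$e_v) * mask$spacing) / 2
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask$voxels[i, j, k]) next
    p <- mask$origin + (c(i, j, k) - 1) * mask$spacing
    w <- p - beam$source
    t_ax <- sum(w * beam$axis)
    f <- beam$sad / t_ax
    q <- beam$source + f * w
    rel <- q - beam$isocenter
    u <- sum(rel * beam$e_u); v <- sum(rel * beam$e_v)
    for (iu in floor((u - f * fu_h - bev$u0) / pixel_mm):floor((u + f * fu_h - bev$u0) / pixel_mm))
      for (iv in floor((v - f * fv_h - bev$v0) / pixel_mm):floor((v + f * fv_h - bev$v0) / pixel_mm)) {
        ii <- min(max(iu + 1, 1), nrow(img)); jj <- min(max(iv + 1, 1), ncol(img))
        img[ii, jj] <- TRUE
      }
  }
  img
}

# fine-step ray integration of path length inside a mask (mm)
oracle_ray_depth <- function(body, source, p, step = 0.1) {
  d <- p - source
  len <- sqrt(sum(d^2))
  m <- ceiling(len / step)
  ts <- (seq_len(m) - 0.5) / m
  inside <- 0L
  dims <- dim(body$voxels)
  for (t in ts) {
    pos <- source + t * d
    ijk <- round((pos - body$origin) / body$spacing) + 1
    if (any(ijk < 1) || any(ijk > dims)) next
    if (body$voxels[ijk[1], ijk[2], ijk[3]]) inside <- inside + 1L
  }
  inside * len / m
}

# voxelwise treated-volume membership: test every voxel against every aperture
oracle_treated <- function(body, beams, apertures) {
  d <- dim(body$voxels)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!body$voxels[i, j, k]) next
    p <- body$origin + (c(i, j, k) - 1) * body$spacing
    ok <- TRUE
    for (nm in names(beams)) {
      b <- beams[[nm]]
      w <- p - b$source
      f <- b$sad / sum(w * b$axis)
      q <- b$source + f * w - b$isocenter
      u <- sum(q * b$e_u); v <- sum(q * b$e_v)
      if (!aperture_contains(apertures[[nm]], u, v)) { ok <- FALSE; break }
    }
    out[i, j, k] <- ok
  }
  out
}

# dense grid search for the non-negative least-squares beam weights:
# coordinate refinement over a shrinking grid, independent of the active-set
# solver
oracle_nnls_grid <- function(D, R, w_max = NULL, step = 1e-3) {
  p <- ncol(D)
  obj <- function(w) sum((D %*% w - R)^2)
  if (is.null(w_max)) w_max <- max(1, 2 * R / max(D))
  w <- rep(w_max / 2, p)
  width <- w_max
  while (width > step / 4) {
    repeat {
      moved <- FALSE
      for (b in seq_len(p)) {
        cand <- pmax(0, w[b] + seq(-width, width, length.out = 81))
        vals <- vapply(cand, function(x) { ww <- w; ww[b] <- x; obj(ww) }, numeric(1))
        new <- cand[which.min(vals)]
        if (abs(new - w[b]) > width / 200) moved <- TRUE
        w[b] <- new
      }
      if (!moved) break
    }
    width <- width / 2
  }
  w
}

rasterize_polygon_uv <- function(poly, us, vs) {
  # point-in-polygon by ray casting, vectorized over a pixel grid
  inp <- function(u, v) {
    n <- nrow(poly); cross <- 0
    for (i in seq_len(n)) {
      p1 <- poly[i, ]; p2 <- poly[if (i == n) 1 else i + 1, ]
      if ((p1[2] > v) != (p2[2] > v)) {
        xin <- p1[1] + (v - p1[2]) / (p2[2] - p1[2]) * (p2[1] - p1[1])
        if (u < xin) cross <- cross + 1
      }
    }
    cross %% 2 == 1
  }
  outer(us, vs, Vectorize(inp))
}
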