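# Independent oracles and fixture builders used across the suite.

# Brute-force Feret diameters by projection onto n_angles directions over
# half a turn (independent of the convex-hull / rotating-calipers path).
feret_oracle <- function(pts, n_angles = 720) {
  widths <- vapply(seq_len(n_angles), function(k) {
    th <- (k - 1) * pi / n_angles
    pr <- pts[, 1] * cos(th) + pts[, 2] * sin(th)
    max(pr) - min(pr)
  }, 0)
  c(max = max(widths), min = min(widths))
}

# Brute-force connected components by BFS flood fill.
cc_oracle <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j]) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c2 <- p[2] + nb[k, 2]
        if (r >= 1 && r <= nr && c2 >= 1 && c2 <= nc &&
            mask[r, c2] && !lab[r, c2]) {
          lab[r, c2] <- cur
          queue[[length(queue) + 1L]] <- c(r, c2)
        }
      }
    }
  }
  lab
}

# Plain-R capsule rasterizer (independent of the package's C++ fill):
# pixel centers within B/2 of the central segment.
raster_capsule <- function(L, B, theta, n, value = 200, cx = n / 2, cy = n / 2) {
  a <- (L - B) / 2
  x1 <- cx - a * cos(theta); y1 <- cy - a * sin(theta)
  x2 <- cx + a * cos(theta); y2 <- cy + a * sin(theta)
  px <- matrix(rep(seq_len(n) - 0.5, each = n), n)      # column coord
  py <- matrix(rep(seq_len(n) - 0.5, times = n), n)     # row coord
  dx <- x2 - x1; dy <- y2 - y1; l2 <- dx^2 + dy^2
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
  d2 <- (px - x1 - t * dx)^2 + (py - y1 - t * dy)^2
  m <- matrix(0, n, n)
  m[d2 <= (B / 2)^2] <- value
  m
}

# disc fixture at (cy, cx) on an existing matrix
add_disc <- function(m, cy, cx, r, value = 400) {
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- value
  m
}

fixed_params <- function(thr = 150, ...)
  seg_params(marker_threshold_method = "fixed", marker_fixed_threshold = thr, ...)

# a small multi-condition run: generate wells per condition, analyze, return
# per-well summaries with a condition column
run_conditions <- function(presets, wells_per_cond, fields_per_well,
                           field_size, seed, noise_sd = 8, blur_sigma = 1) {
  conds <- rep(names(presets), each = wells_per_cond)
  wells <- sprintf("%s%02d", rep(LETTERS[seq_along(presets)],
                                 each = wells_per_cond),
                   rep(seq_len(wells_per_cond), length(presets)))
  spec <- plate_spec(setNames(lapply(conds, function(k) presets[[k]]), wells),
                     fields_per_well = fields_per_well,
                     field_size = field_size, rng_seed = seed,
                     noise_sd = noise_sd, blur_sigma = blur_sigma)
  set.seed(seed)
  out <- vector("list", length(wells))
  gt_obj <- vector("list", length(wells))
  gt_nuc <- vector("list", length(wells))
  myot <- vector("list", length(wells))
  for (i in seq_along(wells)) {
    fs <- generate_well_fields(spec$wells[[i]], spec, wells[i])
    an <- suppressWarnings(analyze_fields(lapply(fs, `[[`, "field")))
    out[[i]] <- cbind(cond = conds[i], an$wells)
    gt_obj[[i]] <- cbind(cond = conds[i], do.call(rbind, lapply(fs, `[[`, "objects")))
    gt_nuc[[i]] <- do.call(rbind, lapply(fs, `[[`, "nuclei"))
    an$myotubes$cond <- conds[i]
    myot[[i]] <- an$myotubes
  }
  list(wells = do.call(rbind, out), objects = do.call(rbind, gt_obj),
       nuclei = do.call(rbind, gt_nuc), myotubes = do.call(rbind, myot))
}
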