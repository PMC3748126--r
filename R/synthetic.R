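#' Plate specification for the synthetic renderer
#'
#' Describes the acquisition geometry of a synthetic screen: which wells are
#' imaged under which [condition_preset], how many non-overlapping fields are
#' recorded per well (36 in the emulated assay), the field size and spatial
#' calibration, and the imaging noise model (Gaussian blur followed by
#' additive Gaussian noise).
#'
#' @param wells named list mapping well ids (`"A01"`..`"H12"`) to
#'   [condition_preset] objects.
#' @param fields_per_well images recorded per well (default 36).
#' @param field_size `c(width, height)` in pixels.
#' @param pixel_size spatial calibration, um per pixel.
#' @param noise_sd additive Gaussian noise SD, camera counts.
#' @param blur_sigma point-spread blur SD, pixels; 0 disables blur.
#' @param rng_seed integer seed; the same seed reproduces the plate
#'   bit-identically.
#' @param background_level camera counts outside any object.
#' @param nuclear_intensity camera counts inside a nucleus on the DAPI-like
#'   channel.
#' @return an object of class `plate_spec`.
#' @export
plate_spec <- function(wells, fields_per_well = 36,
                       field_size = c(1392, 1040), pixel_size = 0.65,
                       noise_sd = 8, blur_sigma = 1, rng_seed = 1,
                       background_level = 100, nuclear_intensity = 500) {
  if (!is.list(wells) || is.null(names(wells)) || length(wells) == 0)
    stop("wells must be a non-empty named list of condition_preset objects")
  bad <- !grepl("^[A-H](0[1-9]|1[0-2])$", names(wells))
  if (any(bad))
    stop("invalid 96-well ids: ", paste(names(wells)[bad], collapse = ", "))
  if (anyDuplicated(names(wells))) stop("duplicate well ids")
  if (!all(vapply(wells, inherits, TRUE, "condition_preset")))
    stop("every well must map to a condition_preset")
  if (fields_per_well < 1) stop("fields_per_well must be >= 1")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (length(field_size) != 2 || any(field_size < 8))
    stop("field_size must be c(width, height), each >= 8 px")
  if (noise_sd < 0 || blur_sigma < 0) stop("noise_sd and blur_sigma must be >= 0")
  structure(list(wells = wells, fields_per_well = as.integer(fields_per_well),
                 field_size = as.integer(field_size), pixel_size = pixel_size,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 rng_seed = as.integer(rng_seed),
                 background_level = background_level,
                 nuclear_intensity = nuclear_intensity),
            class = "plate_spec")
}

# Reference field over which preset densities are defined (um^2):
# 1392 x 1040 px at 0.65 um/px.
REFERENCE_FIELD_UM2 <- (1392 * 0.65) * (1040 * 0.65)

# -- capsule geometry ---------------------------------------------------------
# A myotube is modeled as a capsule (stadium): the set of points within B/2 of
# a segment of length L - B, so the end-to-end length is L and the width B.

capsule_endpoints <- function(x, y, theta, length_um, breadth_um) {
  a <- (length_um - breadth_um) / 2
  c(x - a * cos(theta), y - a * sin(theta),
    x + a * cos(theta), y + a * sin(theta))
}

#' Analytic capsule area and perimeter
#'
#' For a capsule of end-to-end length `L` and width `B`:
#' area `L*B - B^2 + pi*(B/2)^2`, perimeter `2*(L - B) + pi*B`.
#'
#' @param length_um,breadth_um capsule dimensions.
#' @return list with `area` and `perimeter`.
#' @export
capsule_geometry <- function(length_um, breadth_um) {
  list(area = length_um * breadth_um - breadth_um^2 + pi * (breadth_um / 2)^2,
       perimeter = 2 * (length_um - breadth_um) + pi * breadth_um)
}

point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  t <- if (l2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2)) else 0
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

segment_segment_dist <- function(s1, s2) {
  # minimum distance between two segments given as c(x1,y1,x2,y2)
  d <- min(point_segment_dist(s1[1], s1[2], s2[1], s2[2], s2[3], s2[4]),
           point_segment_dist(s1[3], s1[4], s2[1], s2[2], s2[3], s2[4]),
           point_segment_dist(s2[1], s2[2], s1[1], s1[2], s1[3], s1[4]),
           point_segment_dist(s2[3], s2[4], s1[1], s1[2], s1[3], s1[4]))
  if (segments_intersect(s1, s2)) 0 else d
}

segments_intersect <- function(s1, s2) {
  ccw <- function(ax, ay, bx, by, cx, cy) (cy - ay) * (bx - ax) > (by - ay) * (cx - ax)
  ccw(s1[1], s1[2], s2[1], s2[2], s2[3], s2[4]) !=
    ccw(s1[3], s1[4], s2[1], s2[2], s2[3], s2[4]) &&
  ccw(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2]) !=
    ccw(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4])
}

# Minimum clearance (um) kept between rendered structures so that blur cannot
# fuse adjacent objects and segmentation recall stays exact on clean fields.
NUCLEUS_GAP_UM <- 3
MYOTUBE_GAP_UM <- 6

#' Sample one myotube from a condition preset
#'
#' Draws length, breadth and nuclei count from the preset's truncated normal
#' distributions (truncation at 0.1 x mean keeps all quantities positive),
#' picks a uniform orientation and, if `field_um` is given, a uniform center,
#' then places the nuclei uniformly inside the capsule by rejection sampling
#' so that nuclear discs do not overlap.
#'
#' Uses R's global random number stream; seed with [set.seed()] (or via
#' [generate_plate()], which seeds from its `plate_spec`).
#'
#' @param preset a [condition_preset].
#' @param field_um optional `c(width, height)` of the field in um; when
#'   `NULL` the capsule is centered at the origin.
#' @param max_tries rejection-sampling budget per nucleus; exceeding it
#'   (an overcrowded capsule) is an error.
#' @return list with class `"synthetic_myotube"`: `x`, `y`, `theta`,
#'   `length_um`, `breadth_um`, `intensity`, and a data.frame `nuclei`
#'   (`x_um`, `y_um`, `area_um2`, `radius_um`).
#' @export
sample_myotube <- function(preset, field_um = NULL, max_tries = 200L) {
  stopifnot(inherits(preset, "condition_preset"))
  for (k in seq_len(50L)) {
    L <- rtruncnorm1(1, preset$mean_length, preset$sd_length)
    B <- rtruncnorm1(1, preset$mean_breadth, preset$sd_breadth)
    if (B < L) break
  }
  if (B >= L) stop("could not draw breadth < length from this preset")
  theta <- runif(1, 0, pi)
  if (is.null(field_um)) {
    x <- 0; y <- 0
  } else {
    x <- runif(1, 0, field_um[1]); y <- runif(1, 0, field_um[2])
  }
  n_nuc <- max(1L, as.integer(round(rtruncnorm1(
    1, preset$mean_nuclei_per_myotube, preset$sd_nuclei, lower = 0.5))))
  seg <- capsule_endpoints(x, y, theta, L, B)
  # rejection-place all nuclei; an unlucky early placement can block the
  # rest, so restart the whole arrangement a few times before giving up
  for (restart in seq_len(10L)) {
    nx <- ny <- narea <- nrad <- numeric(n_nuc)
    all_placed <- TRUE
    for (i in seq_len(n_nuc)) {
      area <- rtruncnorm1(1, preset$nucleus_area_mean, preset$nucleus_area_sd)
      r <- sqrt(area / pi)
      reach <- max(B / 2 - r, 0)  # erode so the disc stays inside when it fits
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cx <- runif(1, min(seg[1], seg[3]) - reach, max(seg[1], seg[3]) + reach)
        cy <- runif(1, min(seg[2], seg[4]) - reach, max(seg[2], seg[4]) + reach)
        if (point_segment_dist(cx, cy, seg[1], seg[2], seg[3], seg[4]) > reach) next
        if (i > 1) {
          d <- sqrt((cx - nx[seq_len(i - 1)])^2 + (cy - ny[seq_len(i - 1)])^2)
          if (any(d < r + nrad[seq_len(i - 1)] + NUCLEUS_GAP_UM)) next
        }
        nx[i] <- cx; ny[i] <- cy; narea[i] <- area; nrad[i] <- r
        placed <- TRUE
        break
      }
      if (!placed) { all_placed <- FALSE; break }
    }
    if (all_placed) break
  }
  if (!all_placed)
    stop("nucleus placement failed after ", max_tries,
         " tries: capsule too crowded for ", n_nuc, " nuclei")
  structure(list(class = "myotube", x = x, y = y, theta = theta,
                 length_um = L, breadth_um = B,
                 intensity = preset$marker_intensity_mean,
                 nuclei = data.frame(x_um = nx, y_um = ny, area_um2 = narea,
                                     radius_um = nrad)),
            class = "synthetic_myotube")
}

sample_background_cell <- function(preset, field_um, avoid_segs, avoid_radii,
                                   other_nuclei, max_tries = 200L) {
  area <- rtruncnorm1(1, preset$bg_nucleus_area_mean, preset$bg_nucleus_area_sd)
  r <- sqrt(area / pi)
  for (t in seq_len(max_tries)) {
    cx <- runif(1, 0, field_um[1]); cy <- runif(1, 0, field_um[2])
    ok <- TRUE
    for (j in seq_along(avoid_segs)) {
      s <- avoid_segs[[j]]
      if (point_segment_dist(cx, cy, s[1], s[2], s[3], s[4]) <
          avoid_radii[j] + r + NUCLEUS_GAP_UM) { ok <- FALSE; break }
    }
    if (ok && nrow(other_nuclei)) {
      d <- sqrt((cx - other_nuclei$x_um)^2 + (cy - other_nuclei$y_um)^2)
      if (any(d < r + other_nuclei$radius_um + NUCLEUS_GAP_UM)) ok <- FALSE
    }
    if (ok)
      return(structure(list(class = "cell", x = cx, y = cy, theta = 0,
                            length_um = 2 * r, breadth_um = 2 * r,
                            intensity = 0,
                            nuclei = data.frame(x_um = cx, y_um = cy,
                                                area_um2 = area, radius_um = r)),
                       class = "synthetic_cell"))
  }
  # a field can be too full to take another free nucleus (e.g. a myotube
  # spanning a very small field): drop the cell rather than fail the plate
  warning("background-cell placement failed after ", max_tries,
          " tries: dropping one cell from an overfull field")
  NULL
}

place_myotubes <- function(preset, spec, n_myotubes) {
  field_um <- spec$field_size * spec$pixel_size
  objs <- vector("list", n_myotubes)
  segs <- list(); radii <- numeric(0)
  for (i in seq_len(n_myotubes)) {
    for (t in seq_len(200L)) {
      m <- sample_myotube(preset, field_um)
      s <- capsule_endpoints(m$x, m$y, m$theta, m$length_um, m$breadth_um)
      ok <- TRUE
      for (j in seq_along(segs)) {
        if (segment_segment_dist(s, segs[[j]]) <
            (m$breadth_um + objs[[j]]$breadth_um) / 2 + MYOTUBE_GAP_UM) {
          ok <- FALSE; break
        }
      }
      if (ok) { objs[[i]] <- m; segs[[i]] <- s; radii[i] <- m$breadth_um / 2; break }
    }
    if (is.null(objs[[i]]))
      stop("myotube placement failed: field too crowded for ", n_myotubes,
           " myotubes")
  }
  list(objs = objs, segs = segs, radii = radii)
}

place_background_cells <- function(preset, spec, placed, n_cells) {
  field_um <- spec$field_size * spec$pixel_size
  all_nuclei <- if (length(placed$objs))
    do.call(rbind, lapply(placed$objs, `[[`, "nuclei"))
  else data.frame(x_um = numeric(0), y_um = numeric(0),
                  area_um2 = numeric(0), radius_um = numeric(0))
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell <- sample_background_cell(preset, field_um, placed$segs,
                                   placed$radii, all_nuclei)
    cells[i] <- list(cell)
    if (!is.null(cell)) all_nuclei <- rbind(all_nuclei, cell$nuclei)
  }
  Filter(Negate(is.null), cells)
}

#' Sample all objects of one field
#'
#' Places `n_myotubes` capsules (rejecting placements whose capsules would
#' come closer than a small clearance, so distinct myotubes never merge) and
#' `n_cells` marker-negative mononucleated cells whose nuclei avoid the
#' myotubes and each other.
#'
#' @param preset a [condition_preset].
#' @param spec a [plate_spec].
#' @param n_myotubes,n_cells object counts for this field.
#' @return list of synthetic objects, myotubes first.
#' @export
sample_field_objects <- function(preset, spec, n_myotubes, n_cells) {
  placed <- place_myotubes(preset, spec, n_myotubes)
  c(placed$objs, place_background_cells(preset, spec, placed, n_cells))
}

#' Render one two-channel field with ground truth
#'
#' Rasterizes the objects at the spec's calibration: myotube capsules onto the
#' marker (FITC-like) channel at their marker intensity, every nucleus onto
#' the nuclear (DAPI-like) channel, over a uniform camera background. The
#' field is then Gaussian-blurred and additive Gaussian noise applied, and
#' intensities quantized to 16-bit counts. Zero objects yield a valid
#' background-plus-noise field.
#'
#' @param objects list of objects from [sample_myotube()] /
#'   [sample_field_objects()].
#' @param spec a [plate_spec].
#' @param plate,well,site identity stamped on the output.
#' @return list with `field` (a [field_image]), `objects` (ground-truth
#'   data.frame: one row per object with analytic morphometry and a `clipped`
#'   flag), and `nuclei` (one row per nucleus with centroid and area).
#' @export
render_field <- function(objects, spec, plate = "plate1", well = "A01",
                         site = 1L) {
  ps <- spec$pixel_size
  w <- spec$field_size[1]; h <- spec$field_size[2]
  marker <- matrix(spec$background_level, nrow = h, ncol = w)
  nuclear <- matrix(spec$background_level, nrow = h, ncol = w)

  n <- length(objects)
  gt <- data.frame(plate = character(n), well = character(n),
                   site = integer(n), object_id = integer(n),
                   class = character(n), x_um = numeric(n), y_um = numeric(n),
                   theta = numeric(n), length_um = numeric(n),
                   breadth_um = numeric(n), area_um2 = numeric(n),
                   perimeter_um = numeric(n), n_nuclei = integer(n),
                   clipped = logical(n))
  nuc_list <- vector("list", n)

  for (i in seq_len(n)) {
    ob <- objects[[i]]
    # nuclei whose centers fall outside the field are not imaged: drop them
    # from the rendered truth (their parent object is flagged clipped below)
    keep <- ob$nuclei$x_um >= 0 & ob$nuclei$x_um <= w * ps &
      ob$nuclei$y_um >= 0 & ob$nuclei$y_um <= h * ps
    ob$nuclei <- ob$nuclei[keep, , drop = FALSE]
    if (ob$class == "myotube") {
      seg <- capsule_endpoints(ob$x, ob$y, ob$theta, ob$length_um, ob$breadth_um)
      .fill_capsule(marker, seg[1] / ps, seg[2] / ps, seg[3] / ps, seg[4] / ps,
                    ob$breadth_um / 2 / ps, ob$intensity)
      geom <- capsule_geometry(ob$length_um, ob$breadth_um)
      a <- (ob$length_um - ob$breadth_um) / 2; r <- ob$breadth_um / 2
      hx <- a * abs(cos(ob$theta)) + r; hy <- a * abs(sin(ob$theta)) + r
    } else {
      r <- ob$breadth_um / 2
      geom <- list(area = pi * r^2, perimeter = 2 * pi * r)
      hx <- hy <- r
    }
    for (k in seq_len(nrow(ob$nuclei))) {
      nu <- ob$nuclei[k, ]
      .fill_capsule(nuclear, nu$x_um / ps, nu$y_um / ps, nu$x_um / ps,
                    nu$y_um / ps, nu$radius_um / ps, spec$nuclear_intensity)
    }
    gt[i, c("plate", "well", "class")] <- c(plate, well, ob$class)
    gt$site[i] <- site; gt$object_id[i] <- i
    gt$x_um[i] <- ob$x; gt$y_um[i] <- ob$y; gt$theta[i] <- ob$theta
    gt$length_um[i] <- ob$length_um; gt$breadth_um[i] <- ob$breadth_um
    gt$area_um2[i] <- geom$area; gt$perimeter_um[i] <- geom$perimeter
    gt$n_nuclei[i] <- nrow(ob$nuclei)
    gt$clipped[i] <- (ob$x - hx < 0) || (ob$y - hy < 0) ||
      (ob$x + hx > w * ps) || (ob$y + hy > h * ps)
    nk <- nrow(ob$nuclei)
    nuc_list[[i]] <- data.frame(plate = rep(plate, nk), well = rep(well, nk),
                                site = rep(site, nk), object_id = rep(i, nk),
                                nucleus_id = seq_len(nk),
                                x_px = ob$nuclei$x_um / ps,
                                y_px = ob$nuclei$y_um / ps,
                                x_um = ob$nuclei$x_um, y_um = ob$nuclei$y_um,
                                area_um2 = ob$nuclei$area_um2)
  }

  if (spec$blur_sigma > 0) {
    marker <- EBImage::gblur(marker, sigma = spec$blur_sigma)
    nuclear <- EBImage::gblur(nuclear, sigma = spec$blur_sigma)
  }
  if (spec$noise_sd > 0) {
    marker <- marker + rnorm(length(marker), 0, spec$noise_sd)
    nuclear <- nuclear + rnorm(length(nuclear), 0, spec$noise_sd)
  }
  marker <- matrix(pmin(pmax(round(marker), 0), 65535), nrow = h)
  nuclear <- matrix(pmin(pmax(round(nuclear), 0), 65535), nrow = h)

  nuclei <- if (n) do.call(rbind, nuc_list) else
    data.frame(plate = character(0), well = character(0), site = integer(0),
               object_id = integer(0), nucleus_id = integer(0),
               x_px = numeric(0), y_px = numeric(0), x_um = numeric(0),
               y_um = numeric(0), area_um2 = numeric(0))
  list(field = field_image(marker, nuclear, plate = plate, well = well,
                           site = site, pixel_size = ps),
       objects = gt, nuclei = nuclei)
}

# Split a well's expected object count into deterministic per-field counts:
# plating density per well is experimentally controlled, so only placement,
# morphology and camera noise are stochastic. Remainder objects go to evenly
# spaced sites.
split_counts <- function(total, nfields) {
  base <- total %/% nfields
  counts <- rep(base, nfields)
  extra <- total - base * nfields
  if (extra > 0)
    counts[round(seq(1, nfields, length.out = extra))] <-
      counts[round(seq(1, nfields, length.out = extra))] + 1L
  counts
}

#' Generate all fields of one well (in memory)
#'
#' Expected object counts scale with field area relative to the reference
#' field so that spatial density matches the preset. The myotube count is
#' fixed per well (plating density is experimentally controlled) and split
#' deterministically across the well's sites. The background-cell count is
#' then coupled to the realized in-field myotube nuclei so that the well's
#' expected fusion index equals the value the preset's densities imply
#' (`fused / (fused + background)`), rather than drifting with integer
#' rounding of object counts at small field sizes.
#'
#' @param preset a [condition_preset]; @param spec a [plate_spec].
#' @param well well id; @param plate plate id.
#' @return list of [render_field()] results, one per site.
#' @export
generate_well_fields <- function(preset, spec, well = "A01", plate = "plate1") {
  scale <- prod(spec$field_size) * spec$pixel_size^2 / REFERENCE_FIELD_UM2
  nf <- spec$fields_per_well
  field_um <- spec$field_size * spec$pixel_size
  n_myo <- split_counts(as.integer(round(preset$myotube_density * scale * nf)), nf)
  placed <- lapply(seq_len(nf), function(s)
    place_myotubes(preset, spec, n_myo[s]))
  in_field <- vapply(placed, function(p) {
    if (!length(p$objs)) return(0L)
    nuc <- do.call(rbind, lapply(p$objs, `[[`, "nuclei"))
    sum(nuc$x_um >= 0 & nuc$x_um <= field_um[1] &
          nuc$y_um >= 0 & nuc$y_um <= field_um[2])
  }, 0L)
  # unfused-to-fused odds implied by the preset densities
  odds <- preset$background_cell_density /
    (preset$myotube_density * preset$mean_nuclei_per_myotube)
  n_bg_total <- as.integer(round(sum(in_field) * odds))
  if (sum(in_field) == 0)
    n_bg_total <- as.integer(round(preset$background_cell_density * scale * nf))
  n_bg <- split_counts(n_bg_total, nf)
  lapply(seq_len(nf), function(s) {
    objs <- c(placed[[s]]$objs,
              place_background_cells(preset, spec, placed[[s]], n_bg[s]))
    render_field(objs, spec, plate = plate, well = well, site = s)
  })
}

#' Generate and write a synthetic plate
#'
#' Renders every field of every well in the spec and writes one 16-bit
#' grayscale TIFF per field per channel (`{plate}_{well}_{site}_{channel}.tif`,
#' channels `FITC` and `DAPI`), plus ground-truth tables `objects.csv` and
#' `nuclei.csv` and the acquisition metadata `plate.yaml`. Generation is
#' seeded from `spec$rng_seed`: the same spec reproduces byte-identical
#' output.
#'
#' @param spec a [plate_spec].
#' @param outdir output directory (created if needed).
#' @param plate plate id used in file names.
#' @return invisibly, a list with `dir`, the `images` manifest and the two
#'   ground-truth tables.
#' @export
generate_plate <- function(spec, outdir, plate = "plate1") {
  stopifnot(inherits(spec, "plate_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$rng_seed)
  all_obj <- list(); all_nuc <- list(); manifest <- list()
  for (well in names(spec$wells)) {
    fields <- generate_well_fields(spec$wells[[well]], spec, well = well,
                                   plate = plate)
    for (fr in fields) {
      paths <- write_field(fr$field, outdir)
      manifest[[length(manifest) + 1L]] <-
        data.frame(plate = plate, well = well, site = fr$field$site,
                   marker_path = paths["marker"], nuclear_path = paths["nuclear"],
                   row.names = NULL)
      all_obj[[length(all_obj) + 1L]] <- fr$objects
      all_nuc[[length(all_nuc) + 1L]] <- fr$nuclei
    }
  }
  objects <- do.call(rbind, all_obj)
  nuclei <- do.call(rbind, all_nuc)
  write.csv(objects, file.path(outdir, "objects.csv"), row.names = FALSE)
  write.csv(nuclei, file.path(outdir, "nuclei.csv"), row.names = FALSE)
  meta <- list(plate = plate, wells = names(spec$wells),
               conditions = vapply(spec$wells, `[[`, "", "name"),
               fields_per_well = spec$fields_per_well,
               field_size = spec$field_size, pixel_size = spec$pixel_size,
               noise_sd = spec$noise_sd, blur_sigma = spec$blur_sigma,
               rng_seed = spec$rng_seed)
  yaml::write_yaml(meta, file.path(outdir, "plate.yaml"))
  invisible(list(dir = outdir, images = do.call(rbind, manifest),
                 objects = objects, nuclei = nuclei))
}
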