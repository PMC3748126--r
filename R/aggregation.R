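#' Myogenic fusion index
#'
#' Percentage of nuclei residing within marker-positive myotube outlines,
#' the standard readout of fusion efficiency:
#' `100 * assigned / total`. With no nuclei at all the index is undefined
#' and returned as `NA` (missing, never zero).
#'
#' @param assigned nuclei inside myotube outlines.
#' @param total all detected nuclei (must be >= `assigned`).
#' @return percentage in `[0, 100]`, or `NA` when `total` is 0.
#' @export
myogenic_fusion_index <- function(assigned, total) {
  if (any(assigned < 0) || any(total < assigned))
    stop("need 0 <= assigned <= total")
  ifelse(total > 0, 100 * assigned / total, NA_real_)
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

#' Summarize one well
#'
#' Collapses the per-object tables of a well (all its fields pooled) to the
#' per-well readouts: myotube count, morphometry means, fusion index, and
#' the undifferentiated (marker-negative) cell pool. Morphometry means are
#' computed over non-border myotubes only (clipped shapes bias length and
#' breadth downward); counts and the fusion index use all objects. An empty
#' well reports missing (`NA`) means, never zeros.
#'
#' @param myotubes data.frame of measured, nuclei-assigned (and filtered)
#'   myotube records for this well.
#' @param cells data.frame of per-nucleus records (`object_id` NA for
#'   marker-negative nuclei).
#' @param well well id.
#' @param factors optional one-row data.frame of treatment factors (e.g. a
#'   [load_layout()] row) prepended to the output.
#' @return one-row data.frame (a WellSummary).
#' @export
summarize_well <- function(myotubes, cells, well, factors = NULL) {
  inner <- myotubes[!myotubes$border, , drop = FALSE]
  assigned_surviving <- sum(myotubes$n_nuclei)
  assigned_any <- sum(!is.na(cells$object_id))
  total <- nrow(cells)
  unassigned <- sum(is.na(cells$object_id))
  out <- data.frame(
    well = well,
    myotube_count = nrow(myotubes),
    mean_length_um = mean_or_na(inner$length_um),
    mean_breadth_um = mean_or_na(inner$breadth_um),
    mean_area_um2 = mean_or_na(inner$area_um2),
    mean_perimeter_um = mean_or_na(inner$perimeter_um),
    mean_integrated_intensity = mean_or_na(inner$integrated_intensity),
    mean_nuclei_per_myotube = mean_or_na(inner$n_nuclei),
    mean_myonuclear_area_um2 = mean_or_na(unlist(inner$myonuclear_areas)),
    mean_tnt_neg_nuclear_area_um2 =
      mean_or_na(cells$nuclear_area_um2[is.na(cells$object_id)]),
    undifferentiated_cells = unassigned,
    mfi = if (total > 0) myogenic_fusion_index(assigned_surviving, total)
          else NA_real_,
    # variant restricted to nuclei of marker-positive cells only (differs
    # from `mfi` only when a minimum-nuclei myotube filter is in force)
    mfi_tnt = if (assigned_any > 0)
      myogenic_fusion_index(assigned_surviving, assigned_any) else NA_real_)
  if (!is.null(factors)) out <- cbind(factors, out[, -1, drop = FALSE])
  out
}

#' Segment, measure and assign one field
#'
#' Runs the full per-field pipeline: myotube segmentation on the marker
#' channel, nucleus detection with size gating on the nuclear channel,
#' per-region morphometry, centroid-rule nucleus assignment, and the
#' minimum-nuclei myotube filter.
#'
#' @param field a [field_image].
#' @param params a [seg_params].
#' @param min_nuclei myotube filter threshold (see [filter_myotubes()]).
#' @return list: `myotubes` (records with identity columns), `cells`
#'   (per-nucleus records), `n_nuclei` (total detected).
#' @export
analyze_field <- function(field, params = seg_params(), min_nuclei = 1L) {
  stopifnot(inherits(field, "field_image"))
  mmask <- segment_myotubes(field$marker, params, field$pixel_size)
  det <- detect_nuclei(field$nuclear, params, field$pixel_size)
  rec <- measure_regions(mmask, field$marker, field$pixel_size)
  asg <- assign_nuclei(mmask, det)
  rec <- merge(rec, asg$per_myotube, by = "object_id")
  rec <- filter_myotubes(rec, min_nuclei)
  id <- data.frame(plate = field$plate, well = field$well, site = field$site)
  myotubes <- if (nrow(rec)) cbind(id[rep(1, nrow(rec)), , drop = FALSE], rec)
              else cbind(id[0, ], rec)
  cells <- asg$cells
  cells$nucleus_in_filtered <- !is.na(cells$object_id) &
    cells$object_id %in% rec$object_id
  cells <- cbind(id[rep(1, max(nrow(cells), 1))[seq_len(nrow(cells))], ,
                    drop = FALSE], cells)
  rownames(myotubes) <- rownames(cells) <- NULL
  list(myotubes = myotubes, cells = cells, n_nuclei = nrow(cells))
}

#' Analyze a set of fields into well summaries
#'
#' @param fields list of [field_image] objects (typically all sites of one
#'   or more wells).
#' @param layout optional [load_layout()] table supplying treatment factors;
#'   wells present in the images but absent from a non-NULL layout are an
#'   error.
#' @param params a [seg_params]; @param min_nuclei myotube filter.
#' @return list: `wells` (one WellSummary row per well), `myotubes` and
#'   `cells` (pooled object tables).
#' @export
analyze_fields <- function(fields, layout = NULL, params = seg_params(),
                           min_nuclei = 1L) {
  res <- lapply(fields, analyze_field, params = params,
                min_nuclei = min_nuclei)
  myotubes <- do.call(rbind, lapply(res, `[[`, "myotubes"))
  cells <- do.call(rbind, lapply(res, `[[`, "cells"))
  wells <- unique(vapply(fields, `[[`, "", "well"))
  summaries <- lapply(wells, function(w) {
    fac <- NULL
    if (!is.null(layout)) {
      row <- layout[layout$well == w, , drop = FALSE]
      if (!nrow(row)) stop("well ", w, " not present in layout")
      fac <- row
    }
    summarize_well(myotubes[myotubes$well == w, , drop = FALSE],
                   cells[cells$well == w, , drop = FALSE], w, fac)
  })
  list(wells = do.call(rbind, summaries), myotubes = myotubes, cells = cells)
}

#' Analyze a plate directory written by [generate_plate()]
#'
#' Pairs `{plate}_{well}_{site}_FITC.tif` / `..._DAPI.tif` files, reads the
#' calibration from `plate.yaml` (overridable), and runs [analyze_fields()].
#'
#' @param dir plate directory.
#' @param layout optional layout table or path (see [load_layout()]).
#' @param params a [seg_params]; @param min_nuclei myotube filter.
#' @param pixel_size um per pixel; default taken from `plate.yaml`.
#' @return as [analyze_fields()].
#' @export
analyze_plate <- function(dir, layout = NULL, params = seg_params(),
                          min_nuclei = 1L, pixel_size = NULL) {
  if (is.null(pixel_size)) {
    metap <- file.path(dir, "plate.yaml")
    if (!file.exists(metap))
      stop("no plate.yaml in ", dir, "; supply pixel_size explicitly")
    pixel_size <- yaml::read_yaml(metap)$pixel_size
  }
  if (is.character(layout)) layout <- load_layout(layout)
  fitc <- sort(list.files(dir, pattern = "_FITC\\.tif$", full.names = TRUE))
  if (!length(fitc)) stop("no *_FITC.tif images in ", dir)
  fields <- lapply(fitc, function(fp) {
    parts <- strsplit(sub("\\.tif$", "", basename(fp)), "_")[[1]]
    np <- sub("_FITC\\.tif$", "_DAPI.tif", fp)
    load_field(fp, np, plate = paste(parts[seq_len(length(parts) - 3L)],
                                     collapse = "_"),
               well = parts[length(parts) - 2L],
               site = as.integer(parts[length(parts) - 1L]),
               pixel_size = pixel_size)
  })
  analyze_fields(fields, layout, params, min_nuclei)
}
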