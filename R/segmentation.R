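#' Segmentation parameters
#'
#' @param marker_threshold_method `"otsu"` (per-field Otsu on the marker
#'   channel, the default; robust to plate-level illumination drift) or
#'   `"fixed"`.
#' @param marker_fixed_threshold intensity threshold, required when the
#'   method is `"fixed"`; pixels strictly above it are foreground.
#' @param marker_min_area smallest marker-positive region kept, um^2.
#' @param nucleus_min_area the nuclear size gate, um^2: detected nuclei below
#'   it are discarded. The assay this emulates used a pre-determined cutoff
#'   whose value was not published; 40 um^2 is our declared default and well
#'   below any plausible C2C12 nucleus (~130-170 um^2).
#' @param nucleus_max_area optional upper gate, um^2.
#' @param nucleus_typical_area typical single-nucleus area, um^2; connected
#'   components larger than 1.5x this are split by watershed on the
#'   distance transform.
#' @param fill_holes fill enclosed holes in marker regions before labeling.
#' @param connectivity 4 or 8 (default 8) for connected components.
#' @return object of class `seg_params`.
#' @export
seg_params <- function(marker_threshold_method = c("otsu", "fixed"),
                       marker_fixed_threshold = NULL,
                       marker_min_area = 50,
                       nucleus_min_area = 40,
                       nucleus_max_area = NULL,
                       nucleus_typical_area = 133,
                       fill_holes = TRUE,
                       connectivity = 8L) {
  method <- match.arg(marker_threshold_method)
  if (method == "fixed" && is.null(marker_fixed_threshold))
    stop("fixed thresholding requires marker_fixed_threshold")
  if (marker_min_area <= 0 || nucleus_min_area <= 0)
    stop("minimum areas must be > 0")
  if (!is.null(nucleus_max_area) && nucleus_max_area <= nucleus_min_area)
    stop("nucleus_max_area must exceed nucleus_min_area")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(marker_threshold_method = method,
                 marker_fixed_threshold = marker_fixed_threshold,
                 marker_min_area = marker_min_area,
                 nucleus_min_area = nucleus_min_area,
                 nucleus_max_area = nucleus_max_area,
                 nucleus_typical_area = nucleus_typical_area,
                 fill_holes = isTRUE(fill_holes),
                 connectivity = as.integer(connectivity)),
            class = "seg_params")
}

label_mask <- function(labels, role, n = max(labels, 0L)) {
  structure(list(labels = labels, role = role, n = as.integer(n)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask (%s): %d objects in %d x %d px\n", x$role, x$n,
              ncol(x$labels), nrow(x$labels)))
  invisible(x)
}

# threshold a raster; constant images under otsu give an empty mask with a
# warning rather than failing
threshold_raster <- function(x, method, fixed = NULL) {
  if (method == "fixed") return(x > fixed)
  if (diff(range(x)) == 0) {
    warning("constant-intensity image: Otsu threshold undefined, returning empty mask")
    return(matrix(FALSE, nrow(x), ncol(x)))
  }
  top <- max(x, 65535)
  thr <- EBImage::otsu(EBImage::Image(x / top), range = c(0, 1),
                       levels = 65536L) * top
  # Guard against fields with no real foreground: on pure camera noise Otsu
  # bisects the noise distribution, which would turn half the field into
  # "objects". Genuine staining puts the threshold above the background
  # (median) by more than 3 robust SDs (MAD); assumes stained area is a
  # minority of the field, which holds for sparse myotube cultures.
  if (thr - stats::median(x) < 3 * stats::mad(x)) {
    warning("no foreground detected above background noise: empty mask")
    return(matrix(FALSE, nrow(x), ncol(x)))
  }
  x > thr
}

# keep the listed labels and renumber them 1..k in first-appearance
# (column-major raster) order
relabel_keep <- function(lab, keep) {
  if (!length(keep)) return(matrix(0L, nrow(lab), ncol(lab)))
  map <- integer(max(lab))
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  out[nz] <- map[lab[nz]]
  # renumber by first appearance so labels are scan-order deterministic
  first <- match(seq_along(keep), out[out > 0L])
  ord <- order(first)
  map2 <- integer(length(keep)); map2[ord] <- seq_along(keep)
  out[out > 0L] <- map2[out[out > 0L]]
  out
}

label_areas_px <- function(lab) tabulate(lab[lab > 0L], nbins = max(lab, 0L))

#' Segment myotubes on the marker channel
#'
#' Thresholds the marker (TnT/FITC-like) raster, optionally fills holes,
#' labels connected components, and removes regions below the minimum-area
#' gate. Raising the gate can only reduce the object count.
#'
#' @param marker 2-D non-negative intensity matrix.
#' @param params a [seg_params]; @param pixel_size um per pixel.
#' @return a `label_mask` with role `"marker"`.
#' @export
segment_myotubes <- function(marker, params = seg_params(), pixel_size) {
  stopifnot(is.matrix(marker), pixel_size > 0)
  bin <- threshold_raster(marker, params$marker_threshold_method,
                          params$marker_fixed_threshold)
  if (params$fill_holes && any(bin))
    bin <- EBImage::fillHull(bin) > 0
  lab <- .label_components(bin, params$connectivity)
  if (max(lab) == 0L) return(label_mask(lab, "marker", 0L))
  areas <- label_areas_px(lab) * pixel_size^2
  keep <- which(areas >= params$marker_min_area)
  out <- relabel_keep(lab, keep)
  label_mask(out, "marker", length(keep))
}

#' Detect nuclei on the nuclear channel
#'
#' Thresholds the nuclear (DAPI-like) raster and labels components. Any
#' component larger than 1.5x `nucleus_typical_area` is split by watershed
#' on its distance transform (touching nuclei). Components outside the
#' `[nucleus_min_area, nucleus_max_area]` gate are discarded.
#'
#' @param nuclear 2-D intensity matrix.
#' @param params a [seg_params]; @param pixel_size um per pixel.
#' @return list: `mask` (a `label_mask`, role `"nuclear"`) and `nuclei`, a
#'   data.frame with `nucleus_id`, centroid `x_px`/`y_px` (0-based pixel
#'   coordinates), `area_um2`, and a `border` flag.
#' @export
detect_nuclei <- function(nuclear, params = seg_params(), pixel_size) {
  stopifnot(is.matrix(nuclear), pixel_size > 0)
  bin <- threshold_raster(nuclear, params$marker_threshold_method,
                          params$marker_fixed_threshold)
  lab <- .label_components(bin, params$connectivity)
  n <- max(lab)
  if (n > 0L) {
    areas_px <- label_areas_px(lab)
    # 1.5x: two overlapping nuclei always exceed it (their union is below
    # 2x a single area by the overlap), while lone nuclei stay under it and
    # are in any case not split by watershed on a unimodal distance map
    big <- which(areas_px * pixel_size^2 > 1.5 * params$nucleus_typical_area)
    if (length(big)) lab <- split_components(lab, big)
  }
  if (max(lab) > 0L) {
    areas <- label_areas_px(lab) * pixel_size^2
    keep <- which(areas >= params$nucleus_min_area &
                    (is.null(params$nucleus_max_area) |
                       areas <= (params$nucleus_max_area %||% Inf)))
    lab <- relabel_keep(lab, keep)
  }
  mask <- label_mask(lab, "nuclear", max(lab))
  list(mask = mask, nuclei = centroid_table(lab, pixel_size))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Watershed-split the listed labels on the distance transform, working on
# each component's bounding box
split_components <- function(lab, big_ids) {
  nr <- nrow(lab); nc <- ncol(lab)
  next_label <- max(lab)
  for (id in big_ids) {
    idx <- which(lab == id)
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
    sub <- lab[r0:r1, c0:c1, drop = FALSE] == id
    d <- EBImage::distmap(sub)
    w <- EBImage::watershed(d, tolerance = 1, ext = 1)
    w <- matrix(as.integer(w), nrow(sub))
    k <- max(w)
    if (k <= 1L) next
    piece <- lab[r0:r1, c0:c1, drop = FALSE]
    piece[sub] <- next_label + w[sub]
    lab[r0:r1, c0:c1] <- piece
    next_label <- next_label + k
  }
  # renumber to consecutive scan order
  relabel_keep(lab, sort(unique(lab[lab > 0L])))
}

# per-label centroid (0-based pixel-center coordinates) and area table
centroid_table <- function(lab, pixel_size) {
  n <- max(lab)
  if (n == 0L)
    return(data.frame(nucleus_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_um2 = numeric(0),
                      border = logical(0)))
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- (idx - 1L) %% nr   # 0-based
  cols <- (idx - 1L) %/% nr
  cnt <- tabulate(l, n)
  data.frame(nucleus_id = seq_len(n),
             x_px = rowsum(cols, l)[, 1] / cnt + 0.5,
             y_px = rowsum(rows, l)[, 1] / cnt + 0.5,
             area_um2 = cnt * pixel_size^2,
             border = as.logical(rowsum(as.numeric(rows == 0L | rows == nr - 1L |
                                                     cols == 0L | cols == nc - 1L),
                                        l)[, 1] > 0))
}
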