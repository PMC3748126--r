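#' Two-channel acquisition field
#'
#' One imaged site of one well: co-registered marker (myotube stain) and
#' nuclear (DAPI) intensity rasters with plate/well/site identity and spatial
#' calibration. Rasters are numeric matrices in row-major screen convention:
#' `[row, col]` with the origin at the top-left pixel; pixel coordinates are
#' 0-based. All physical measurements downstream are reported in um / um^2
#' through `pixel_size`.
#'
#' @param marker,nuclear 2-D non-negative intensity matrices of equal shape.
#' @param plate plate id.
#' @param well well id on a 96-well grid (`"A01"`..`"H12"`).
#' @param site acquisition site index, 1-based.
#' @param pixel_size um per pixel, > 0.
#' @return object of class `field_image`.
#' @export
field_image <- function(marker, nuclear, plate = "plate1", well, site = 1L,
                        pixel_size) {
  if (!is.matrix(marker) || !is.matrix(nuclear))
    stop("marker and nuclear must be 2-D matrices")
  if (!all(dim(marker) == dim(nuclear)))
    stop("channel shape mismatch: marker ", paste(dim(marker), collapse = "x"),
         " vs nuclear ", paste(dim(nuclear), collapse = "x"))
  if (!grepl("^[A-H](0[1-9]|1[0-2])$", well))
    stop("invalid 96-well id: ", well)
  if (missing(pixel_size) || !is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size (um/px) must be a positive number")
  if (site < 1) stop("site must be >= 1")
  structure(list(marker = marker, nuclear = nuclear,
                 plate = as.character(plate), well = well,
                 site = as.integer(site), pixel_size = pixel_size),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("field_image %s/%s site %d: %d x %d px at %g um/px\n",
              x$plate, x$well, x$site, ncol(x$marker), nrow(x$marker),
              x$pixel_size))
  invisible(x)
}

field_basename <- function(field, channel)
  sprintf("%s_%s_%d_%s.tif", field$plate, field$well, field$site, channel)

#' Write a field as two 16-bit grayscale TIFFs
#'
#' Files are named `{plate}_{well}_{site}_{channel}.tif` with channels
#' `FITC` (marker) and `DAPI` (nuclear). Intensities must already be integer
#' camera counts in 0..65535; they round-trip bit-exactly.
#'
#' @param field a [field_image]; @param dir output directory.
#' @return named character vector with the `marker` and `nuclear` paths.
#' @export
write_field <- function(field, dir) {
  stopifnot(inherits(field, "field_image"))
  paths <- c(marker = file.path(dir, field_basename(field, "FITC")),
             nuclear = file.path(dir, field_basename(field, "DAPI")))
  tiff::writeTIFF(field$marker / 65535, paths["marker"],
                  bits.per.sample = 16L, compression = "none")
  tiff::writeTIFF(field$nuclear / 65535, paths["nuclear"],
                  bits.per.sample = 16L, compression = "none")
  paths
}

#' Load a field from per-channel TIFFs
#'
#' @param marker_path,nuclear_path single-channel grayscale TIFF files.
#' @param plate,well,site identity metadata.
#' @param pixel_size spatial calibration, um per pixel (required; TIFFs from
#'   screening systems rarely carry a trustworthy one).
#' @return a [field_image] with integer camera counts.
#' @export
load_field <- function(marker_path, nuclear_path, plate = "plate1", well,
                       site = 1L, pixel_size) {
  read1 <- function(p) {
    if (!file.exists(p)) stop("no such image: ", p)
    x <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1]
    if (length(dim(x)) != 2L) stop("not a single-channel 2-D raster: ", p)
    x
  }
  field_image(read1(marker_path), read1(nuclear_path), plate = plate,
              well = well, site = site, pixel_size = pixel_size)
}

#' Plate layout: wells to treatment factors
#'
#' Reads (or validates) the sidecar table binding each imaged well to its
#' treatment: the two crossed boolean factors of the factorial design
#' (`ethanol`, `gsi`), an optional free-text `treatment` label (e.g.
#' "rapamycin"), and a `replicate` id. Accepts a data.frame, a CSV path, or
#' a YAML path (a list of per-well records).
#'
#' @param x data.frame or path to a CSV/YAML file with columns/fields
#'   `well`, `ethanol`, `gsi`, and optionally `treatment`, `replicate`.
#' @return a `plate_layout`: data.frame with one validated row per well.
#' @export
load_layout <- function(x) {
  if (is.character(x)) {
    x <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE))
      do.call(rbind, lapply(yaml::read_yaml(x), as.data.frame))
    else read.csv(x)
  }
  if (!is.data.frame(x)) stop("layout must be a data.frame or a CSV/YAML path")
  if (!nrow(x)) {
    out <- data.frame(well = character(0), ethanol = logical(0),
                      gsi = logical(0), treatment = character(0),
                      replicate = integer(0))
    return(structure(out, class = c("plate_layout", "data.frame")))
  }
  need <- c("well", "ethanol", "gsi")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("layout is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$well))
    stop("duplicate wells in layout: ",
         paste(unique(x$well[duplicated(x$well)]), collapse = ", "))
  bad <- !grepl("^[A-H](0[1-9]|1[0-2])$", x$well)
  if (any(bad)) stop("invalid well ids: ", paste(x$well[bad], collapse = ", "))
  to_bool <- function(v, nm) {
    if (is.logical(v)) return(v)
    lv <- tolower(as.character(v))
    if (!all(lv %in% c("true", "false", "0", "1", "yes", "no")))
      stop("factor '", nm, "' has levels outside TRUE/FALSE: ",
           paste(unique(v), collapse = ", "))
    lv %in% c("true", "1", "yes")
  }
  x$ethanol <- to_bool(x$ethanol, "ethanol")
  x$gsi <- to_bool(x$gsi, "gsi")
  if (is.null(x$treatment)) x$treatment <- NA_character_
  if (is.null(x$replicate)) x$replicate <- seq_len(nrow(x))
  out <- x[, c("well", "ethanol", "gsi", "treatment", "replicate")]
  rownames(out) <- NULL
  structure(out, class = c("plate_layout", "data.frame"))
}
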