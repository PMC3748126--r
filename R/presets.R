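#' Condition preset for the synthetic plate renderer
#'
#' A `condition_preset` bundles the morphological distribution a treatment
#' condition imposes on differentiating C2C12 cultures: myotube length and
#' breadth (drawn from truncated normals), nuclei per myotube, nuclear areas
#' for fused (myotube) and unfused (marker-negative) nuclei, marker intensity,
#' and plating densities. Densities are expressed as expected objects per
#' *reference field* (1392 x 1040 px at 0.65 um/px, about 0.61 mm^2); the
#' renderer rescales them by the actual field area so that spatial density is
#' what is held fixed.
#'
#' @param name condition label.
#' @param mean_length,sd_length myotube end-to-end length, um.
#' @param mean_breadth,sd_breadth myotube breadth (width), um.
#' @param mean_nuclei_per_myotube,sd_nuclei nuclei count per myotube.
#' @param myotube_density expected myotubes per reference field.
#' @param background_cell_density expected mononucleated marker-negative
#'   cells per reference field.
#' @param marker_intensity_mean myotube marker-channel intensity (camera
#'   counts on a 16-bit scale).
#' @param nucleus_area_mean,nucleus_area_sd myotube (fused) nuclear area, um^2.
#' @param bg_nucleus_area_mean,bg_nucleus_area_sd marker-negative cell
#'   nuclear area, um^2.
#' @return an object of class `condition_preset`.
#' @export
condition_preset <- function(name,
                             mean_length, sd_length,
                             mean_breadth, sd_breadth,
                             mean_nuclei_per_myotube, sd_nuclei,
                             myotube_density,
                             background_cell_density,
                             marker_intensity_mean,
                             nucleus_area_mean, nucleus_area_sd,
                             bg_nucleus_area_mean = 140,
                             bg_nucleus_area_sd = 7.37) {
  p <- list(
    name = as.character(name),
    mean_length = mean_length, sd_length = sd_length,
    mean_breadth = mean_breadth, sd_breadth = sd_breadth,
    mean_nuclei_per_myotube = mean_nuclei_per_myotube, sd_nuclei = sd_nuclei,
    myotube_density = myotube_density,
    background_cell_density = background_cell_density,
    marker_intensity_mean = marker_intensity_mean,
    nucleus_area_mean = nucleus_area_mean, nucleus_area_sd = nucleus_area_sd,
    bg_nucleus_area_mean = bg_nucleus_area_mean,
    bg_nucleus_area_sd = bg_nucleus_area_sd)
  means <- c(p$mean_length, p$mean_breadth, p$mean_nuclei_per_myotube,
             p$marker_intensity_mean, p$nucleus_area_mean,
             p$bg_nucleus_area_mean)
  sds <- c(p$sd_length, p$sd_breadth, p$sd_nuclei, p$nucleus_area_sd,
           p$bg_nucleus_area_sd)
  if (any(!is.finite(means)) || any(means <= 0))
    stop("all preset means must be positive")
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all preset sds must be non-negative")
  if (p$mean_length <= p$mean_breadth)
    stop("mean_length must exceed mean_breadth")
  if (p$myotube_density < 0 || p$background_cell_density < 0)
    stop("densities must be non-negative")
  structure(p, class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("condition_preset '%s': length %g (%g) um, breadth %g (%g) um, %g (%g) nuclei/myotube\n",
              x$name, x$mean_length, x$sd_length, x$mean_breadth, x$sd_breadth,
              x$mean_nuclei_per_myotube, x$sd_nuclei))
  invisible(x)
}

#' Built-in differentiation condition presets
#'
#' Presets encoding the per-myotube morphology reported for C2C12 cultures
#' differentiated for 7 days under vehicle, 100 mM ethanol, or 100 nM
#' rapamycin: mean (SD) length 178 (11.3) / 147 (13) / 117 (6.86) um,
#' breadth 46.2 (5.3) / 32.1 (2.33) / 30.0 (3.29) um, nuclei per myotube
#' 6 (1) / 4 (1) / 3 (1), myonuclear area 133 (3.77) / 140 (3.25) /
#' 140 (3.42) um^2, and marker-negative nuclear area 140 (7.37) /
#' 164 (8.81) / 169 (9.78) um^2.
#'
#' Plating densities are chosen so that a well's expected myogenic fusion
#' index matches the reported condition values (14.9 / 13.5 / 12.5 percent)
#' given the expected nuclei-per-myotube. Marker intensities are set so that
#' the expected integrated intensity per myotube (intensity times the mean
#' capsule area in pixels at the default 0.65 um/px calibration) matches the
#' reported magnitudes (3.55e6 / 2.49e6 / 1.29e6 IIU).
#'
#' @return named list of three [condition_preset] objects
#'   (`vehicle`, `ethanol`, `rapamycin`).
#' @export
differentiation_presets <- function() {
  list(
    vehicle = condition_preset("vehicle",
      mean_length = 178, sd_length = 11.3,
      mean_breadth = 46.2, sd_breadth = 5.3,
      mean_nuclei_per_myotube = 6, sd_nuclei = 1,
      myotube_density = 6, background_cell_density = 206,
      marker_intensity_mean = 193,
      nucleus_area_mean = 133, nucleus_area_sd = 3.77,
      bg_nucleus_area_mean = 140, bg_nucleus_area_sd = 7.37),
    ethanol = condition_preset("ethanol",
      mean_length = 147, sd_length = 13,
      mean_breadth = 32.1, sd_breadth = 2.33,
      mean_nuclei_per_myotube = 4, sd_nuclei = 1,
      myotube_density = 5, background_cell_density = 128,
      marker_intensity_mean = 234,
      nucleus_area_mean = 140, nucleus_area_sd = 3.25,
      bg_nucleus_area_mean = 164, bg_nucleus_area_sd = 8.81),
    rapamycin = condition_preset("rapamycin",
      mean_length = 117, sd_length = 6.86,
      mean_breadth = 30.0, sd_breadth = 3.29,
      mean_nuclei_per_myotube = 3, sd_nuclei = 1,
      myotube_density = 4, background_cell_density = 84,
      marker_intensity_mean = 165,
      nucleus_area_mean = 140, nucleus_area_sd = 3.42,
      bg_nucleus_area_mean = 169, bg_nucleus_area_sd = 9.78))
}

# truncated-normal draw: redraw until >= lower (default 0.1 * mean), so all
# morphological quantities stay strictly positive.
rtruncnorm1 <- function(n, mean, sd, lower = 0.1 * mean) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- lower
  x
}
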