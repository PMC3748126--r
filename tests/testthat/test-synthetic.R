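test_that("preset validation rejects impossible morphologies", {
  expect_s3_class(differentiation_presets()$vehicle, "condition_preset")
  expect_error(condition_preset("bad", mean_length = 40, sd_length = 1,
                                mean_breadth = 50, sd_breadth = 1,
                                mean_nuclei_per_myotube = 3, sd_nuclei = 1,
                                myotube_density = 1, background_cell_density = 1,
                                marker_intensity_mean = 100,
                                nucleus_area_mean = 130, nucleus_area_sd = 4),
               "mean_length")
  expect_error(condition_preset("bad", mean_length = -1, sd_length = 1,
                                mean_breadth = 50, sd_breadth = 1,
                                mean_nuclei_per_myotube = 3, sd_nuclei = 1,
                                myotube_density = 1, background_cell_density = 1,
                                marker_intensity_mean = 100,
                                nucleus_area_mean = 130, nucleus_area_sd = 4),
               "positive")
})

test_that("sampled myotubes follow the preset distributions", {
  pr <- differentiation_presets()
  set.seed(401)
  for (cond in c("vehicle", "ethanol")) {
    p <- pr[[cond]]
    draws <- replicate(5000, {
      m <- sample_myotube(p)
      c(m$length_um, m$breadth_um, nrow(m$nuclei))
    })
    # sample means within 2% (5% for the discretized nuclei counts) of the
    # preset means; at n = 5000 these bands sit many standard errors out
    expect_lt(abs(mean(draws[1, ]) / p$mean_length - 1), 0.02)
    expect_lt(abs(mean(draws[2, ]) / p$mean_breadth - 1), 0.02)
    expect_lt(abs(mean(draws[3, ]) / p$mean_nuclei_per_myotube - 1), 0.05)
    expect_true(all(draws[1, ] > 0) && all(draws[2, ] > 0))
    expect_true(all(draws[3, ] >= 1))
  }
})

test_that("degenerate sd draws are exactly the mean", {
  p <- condition_preset("fixed", mean_length = 100, sd_length = 0,
                        mean_breadth = 20, sd_breadth = 0,
                        mean_nuclei_per_myotube = 3, sd_nuclei = 0,
                        myotube_density = 1, background_cell_density = 1,
                        marker_intensity_mean = 300,
                        nucleus_area_mean = 130, nucleus_area_sd = 0)
  set.seed(1)
  for (i in 1:20) {
    m <- sample_myotube(p)
    expect_identical(m$length_um, 100)
    expect_identical(m$breadth_um, 20)
    expect_identical(nrow(m$nuclei), 3L)
  }
})

test_that("nucleus centroids lie inside the capsule and do not overlap", {
  pr <- differentiation_presets()
  set.seed(77)
  for (i in 1:50) {
    m <- sample_myotube(pr$vehicle)
    seg <- myotubeHCS:::capsule_endpoints(m$x, m$y, m$theta, m$length_um,
                                          m$breadth_um)
    d <- myotubeHCS:::point_segment_dist(m$nuclei$x_um, m$nuclei$y_um,
                                         seg[1], seg[2], seg[3], seg[4])
    expect_true(all(d <= m$breadth_um / 2))
    if (nrow(m$nuclei) > 1) {
      dd <- as.matrix(dist(m$nuclei[, c("x_um", "y_um")]))
      rr <- outer(m$nuclei$radius_um, m$nuclei$radius_um, "+")
      expect_true(all(dd[upper.tri(dd)] >= rr[upper.tri(rr)]))
    }
  }
})

test_that("overcrowded capsules raise an explicit placement error", {
  p <- condition_preset("crowded", mean_length = 30, sd_length = 0,
                        mean_breadth = 25, sd_breadth = 0,
                        mean_nuclei_per_myotube = 12, sd_nuclei = 0,
                        myotube_density = 1, background_cell_density = 1,
                        marker_intensity_mean = 300,
                        nucleus_area_mean = 130, nucleus_area_sd = 0)
  set.seed(2)
  expect_error(sample_myotube(p), "placement failed")
})

test_that("rendered capsule area matches the analytic formula", {
  pr <- differentiation_presets()
  spec <- plate_spec(list(A01 = pr$vehicle), fields_per_well = 1,
                     field_size = c(128, 128), pixel_size = 1,
                     noise_sd = 0, blur_sigma = 0)
  obj <- structure(list(class = "myotube", x = 64, y = 64, theta = 0.4,
                        length_um = 40, breadth_um = 10, intensity = 200,
                        nuclei = data.frame(x_um = 64, y_um = 64,
                                            area_um2 = 50,
                                            radius_um = sqrt(50 / pi))),
                   class = "synthetic_myotube")
  rf <- render_field(list(obj), spec)
  analytic <- capsule_geometry(40, 10)$area        # L*B - B^2 + pi*(B/2)^2
  expect_equal(analytic, 378.5398, tolerance = 1e-6)
  npos <- sum(rf$field$marker != spec$background_level)
  expect_lt(abs(npos / analytic - 1), 0.02)
  expect_false(rf$objects$clipped)
  expect_equal(rf$objects$area_um2, analytic)
  expect_equal(rf$objects$perimeter_um, capsule_geometry(40, 10)$perimeter)
})

test_that("empty and background-only fields render correctly", {
  pr <- differentiation_presets()
  spec <- plate_spec(list(A01 = pr$vehicle), fields_per_well = 1,
                     field_size = c(96, 96), pixel_size = 1,
                     noise_sd = 0, blur_sigma = 0)
  rf <- render_field(list(), spec)
  expect_equal(nrow(rf$objects), 0)
  expect_true(all(rf$field$marker == spec$background_level))
  expect_true(all(rf$field$nuclear == spec$background_level))
  # one background cell: blank marker, one nuclear component
  set.seed(3)
  cell <- myotubeHCS:::sample_background_cell(
    pr$vehicle, c(96, 96), list(), numeric(0),
    data.frame(x_um = numeric(0), y_um = numeric(0), area_um2 = numeric(0),
               radius_um = numeric(0)))
  rf2 <- render_field(list(cell), spec)
  expect_true(all(rf2$field$marker == spec$background_level))
  comp <- cc_oracle(rf2$field$nuclear > spec$background_level)
  expect_equal(max(comp), 1)
  expect_equal(rf2$objects$class, "cell")
})

test_that("generated plates are seeded-deterministic and sized correctly", {
  pr <- differentiation_presets()
  spec <- plate_spec(list(A01 = pr$vehicle, B02 = pr$ethanol),
                     fields_per_well = 2, field_size = c(64, 64),
                     rng_seed = 99)
  d1 <- file.path(tempdir(), "plate_det1")
  d2 <- file.path(tempdir(), "plate_det2")
  r1 <- suppressWarnings(generate_plate(spec, d1))
  r2 <- suppressWarnings(generate_plate(spec, d2))
  expect_equal(nrow(r1$images), 2 * 2)   # wells x fields
  expect_length(list.files(d1, pattern = "_FITC\\.tif$"), 4)
  expect_length(list.files(d1, pattern = "_DAPI\\.tif$"), 4)
  for (f in list.files(d1, pattern = "\\.tif$"))
    expect_identical(readBin(file.path(d1, f), "raw", 5e5),
                     readBin(file.path(d2, f), "raw", 5e5))
  expect_identical(r1$objects, r2$objects)
  spec3 <- plate_spec(list(A01 = pr$vehicle, B02 = pr$ethanol),
                      fields_per_well = 2, field_size = c(64, 64),
                      rng_seed = 100)
  r3 <- suppressWarnings(generate_plate(spec3, file.path(tempdir(), "plate_det3")))
  expect_false(identical(r1$objects, r3$objects))
  unlink(c(d1, d2, file.path(tempdir(), "plate_det3")), recursive = TRUE)
})

test_that("ground-truth nuclei are conserved across object classes", {
  pr <- differentiation_presets()
  spec <- plate_spec(list(A01 = pr$vehicle), fields_per_well = 3,
                     field_size = c(400, 400), rng_seed = 12)
  set.seed(12)
  fs <- generate_well_fields(pr$vehicle, spec, "A01")
  for (fr in fs) {
    per_class <- tapply(fr$objects$n_nuclei, fr$objects$class, sum)
    expect_equal(sum(per_class), nrow(fr$nuclei))
    # every nucleus belongs to exactly one object
    expect_true(all(table(paste(fr$nuclei$object_id, fr$nuclei$nucleus_id)) == 1))
    expect_true(all(fr$objects$breadth_um <= fr$objects$length_um))
  }
})

test_that("condition presets order myotube size vehicle > ethanol > rapamycin", {
  pr <- differentiation_presets()
  set.seed(9)
  tr <- sapply(pr, function(p) {
    d <- replicate(400, { m <- sample_myotube(p); c(m$length_um, m$breadth_um) })
    rowMeans(d)
  })
  expect_true(all(diff(tr[1, c("rapamycin", "ethanol", "vehicle")]) > 0))
  expect_true(all(diff(tr[2, c("rapamycin", "ethanol", "vehicle")]) > 0))
})
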