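test_that("rectangle morphometry matches analytic geometry", {
  img <- matrix(10, 60, 60)
  img[11:20, 11:50] <- 200                       # 40 wide x 10 tall
  mask <- segment_myotubes(img, fixed_params(100), 1)
  r <- measure_regions(mask, img, 1)
  expect_equal(r$area_um2, 400)
  expect_equal(r$integrated_intensity, 400 * 200)
  expect_equal(r$breadth_um, 10, tolerance = 0.01)
  # corner-to-corner diagonal, within 2% (sub-pixel outline rounds corners)
  expect_equal(r$length_um, sqrt(40^2 + 10^2), tolerance = 0.02)
  expect_lt(abs(r$perimeter_um / 100 - 1), 0.05)
  expect_false(r$border)
})

test_that("calipers agree with the 720-angle projection oracle", {
  set.seed(51)
  shapes <- c(lapply(runif(6, 0, pi), function(th) raster_capsule(60, 16, th, 100)),
              lapply(runif(4, 0, pi / 2), function(th) {
        # rotated rectangle via thin capsule with flat-ish ends
        raster_capsule(70, 24, th, 120)
      }))
  for (img in shapes) {
    mask <- segment_myotubes(img, fixed_params(100, marker_min_area = 10), 1)
    r <- measure_regions(mask, img, 1)
    polys <- myotubeHCS:::contour_polygons(mask$labels == 1)
    pts <- do.call(rbind, lapply(polys, function(cc) cbind(cc$x, cc$y)))
    orc <- feret_oracle(pts)
    expect_equal(r$length_um, orc["max"], tolerance = 0.01,
                 ignore_attr = TRUE)
    expect_equal(r$breadth_um, orc["min"], tolerance = 0.01,
                 ignore_attr = TRUE)
  }
})

test_that("vehicle-scale capsules recover their analytic dimensions", {
  set.seed(52)
  for (th in runif(5, 0, pi)) {
    img <- raster_capsule(178, 46, th, 260)
    mask <- segment_myotubes(img, fixed_params(100), 1)
    r <- measure_regions(mask, img, 1)
    expect_lt(abs(r$length_um - 178), 2)
    expect_lt(abs(r$breadth_um - 46), 2)
    geom <- capsule_geometry(178, 46)
    expect_lt(abs(r$area_um2 / geom$area - 1), 0.02)
    expect_lt(abs(r$perimeter_um / geom$perimeter - 1), 0.05)
    # discretization-tolerant shape invariants
    expect_lte(4 * pi * r$area_um2, r$perimeter_um^2 * 1.02)
    expect_lte(r$area_um2, r$length_um * r$breadth_um * 1.02)
  }
})

test_that("degenerate one-pixel regions use the declared convention", {
  lab <- matrix(0L, 10, 10); lab[5, 5] <- 1L
  mask <- myotubeHCS:::label_mask(lab, "marker", 1L)
  r <- measure_regions(mask, matrix(3, 10, 10), 2)
  expect_equal(r$area_um2, 4)          # 1 px at 2 um/px
  expect_equal(r$length_um, 2)
  expect_equal(r$breadth_um, 2)
  expect_equal(r$perimeter_um, 8)
  expect_equal(r$integrated_intensity, 3)
})

test_that("measurements scale linearly with pixel size", {
  img <- raster_capsule(60, 16, 0.7, 100)
  mask <- segment_myotubes(img, fixed_params(100), 1)
  r1 <- measure_regions(mask, img, 1)
  r2 <- measure_regions(mask, img, 2)
  expect_equal(r2$length_um, 2 * r1$length_um)
  expect_equal(r2$breadth_um, 2 * r1$breadth_um)
  expect_equal(r2$perimeter_um, 2 * r1$perimeter_um)
  expect_equal(r2$area_um2, 4 * r1$area_um2)
  expect_equal(r2$integrated_intensity, r1$integrated_intensity)
})

test_that("measure_region extracts a single label", {
  img <- matrix(10, 50, 50)
  img[5:14, 5:24] <- 200
  img[30:44, 30:39] <- 150
  mask <- segment_myotubes(img, fixed_params(100), 1)
  expect_equal(mask$n, 2)
  all2 <- measure_regions(mask, img, 1)
  one <- measure_region(mask, 2, img, 1)
  expect_equal(one$area_um2, all2$area_um2[2])
  expect_equal(one$integrated_intensity, all2$integrated_intensity[2])
  expect_error(measure_region(mask, 3, img, 1), "no such label")
})

test_that("nuclei are assigned by the centroid rule", {
  # myotube occupies columns 10..40, rows 10..30
  lab <- matrix(0L, 60, 60); lab[10:30, 10:40] <- 1L
  mask <- myotubeHCS:::label_mask(lab, "marker", 1L)
  nuclei <- data.frame(nucleus_id = 1:3,
                       x_px = c(20, 40.6, 50),   # inside, just outside, far
                       y_px = c(20, 20, 50),
                       area_um2 = c(120, 130, 140))
  asg <- assign_nuclei(mask, nuclei)
  expect_equal(asg$cells$object_id, c(1L, NA, NA))
  expect_equal(asg$per_myotube$n_nuclei, 1L)
  expect_equal(asg$per_myotube$myonuclear_areas[[1]], 120)
})

test_that("a straddling nucleus with centroid outside stays unassigned", {
  lab <- matrix(0L, 40, 40); lab[1:40, 1:20] <- 1L   # region = left half
  mask <- myotubeHCS:::label_mask(lab, "marker", 1L)
  # disc of radius 5 centered 1 px right of the outline: ~40% overlaps
  nuc <- matrix(10, 40, 40)
  nuc <- add_disc(nuc, 20, 21.5, 5)
  det <- detect_nuclei(nuc, fixed_params(100, nucleus_min_area = 10), 1)
  expect_equal(nrow(det$nuclei), 1)
  expect_gt(det$nuclei$x_px, 20)
  asg <- assign_nuclei(mask, det)
  expect_true(is.na(asg$cells$object_id[1]))
})

test_that("bookkeeping: counts split between myotube and free nuclei", {
  lab <- matrix(0L, 100, 100); lab[20:80, 20:60] <- 1L
  mask <- myotubeHCS:::label_mask(lab, "marker", 1L)
  nuclei <- data.frame(nucleus_id = 1:5,
                       x_px = c(30, 40, 50, 80, 90),
                       y_px = c(30, 40, 50, 90, 95),
                       area_um2 = 101:105)
  asg <- assign_nuclei(mask, nuclei)
  expect_equal(asg$per_myotube$n_nuclei, 3L)
  expect_equal(sum(is.na(asg$cells$object_id)), 2)
  expect_equal(sum(asg$per_myotube$n_nuclei) + sum(is.na(asg$cells$object_id)),
               nrow(nuclei))
})

test_that("the minimum-nuclei filter keeps exactly the qualifying records", {
  rec <- data.frame(object_id = 1:3, n_nuclei = c(0L, 1L, 3L))
  expect_equal(filter_myotubes(rec, 1)$object_id, c(2L, 3L))
  expect_equal(filter_myotubes(rec, 2)$object_id, 3L)
  expect_equal(filter_myotubes(rec, 0), rec)
})
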