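# Per-object shape descriptors: hand-derivable fixtures, invariants, and a
# spot oracle check (the full 200-blob oracle sweep lives in the
# acceptance suite).

test_that("perimeter follows the chain-code convention on hand-traceable shapes", {
  expect_equal(object_perimeter(matrix(1, 1, 1)), 4)      # documented convention
  expect_equal(object_perimeter(matrix(1, 3, 3)), 8)      # ring of 8 axial steps
  expect_equal(object_perimeter(matrix(1, 1, 9)), 16)     # out-and-back trace
  expect_equal(object_perimeter(matrix(1, 2, 2)), 4)
  d <- matrix(0, 2, 2); d[1, 1] <- 1; d[2, 2] <- 1
  expect_equal(object_perimeter(d), 2 * sqrt(2))          # diagonal domino
})

test_that("moment ellipse matches the discrete-uniform line and symmetry cases", {
  me <- moment_ellipse(matrix(1, 1, 9))
  expect_equal(me$orientation, 0)
  expect_equal(me$eccentricity, 1)
  expect_equal(me$major_axis_length, 4 * sqrt(80 / 12))   # var (n^2-1)/12
  expect_equal(moment_ellipse(matrix(1, 9, 1))$orientation, 90)
  disk <- outer(1:101, 1:101, function(r, c) (r - 51)^2 + (c - 51)^2 <= 50^2)
  expect_lt(moment_ellipse(disk)$eccentricity, 0.05)
})

test_that("extent, compactness and form factor match direct arithmetic", {
  plus <- matrix(0, 3, 3); plus[2, ] <- 1; plus[, 2] <- 1
  expect_equal(object_extent(plus), 5 / 9)
  expect_equal(object_extent(matrix(1, 4, 7)), 1)
  expect_equal(compactness(matrix(1, 1, 1)), 0)           # single-pixel convention
  expect_equal(compactness(matrix(1, 1, 9)), 2 * pi * (60 / 9) / 9)
  expect_equal(form_factor(9, 8), 4 * pi * 9 / 64)        # 3x3 square
  expect_equal(form_factor(9, 16), 4 * pi * 9 / 256)      # 1x9 line
})

test_that("euler number counts enclosed 4-connected holes", {
  expect_equal(object_euler(matrix(1, 4, 4)), 1L)
  ann <- matrix(1, 5, 5); ann[3, 3] <- 0
  expect_equal(object_euler(ann), 0L)
  two <- matrix(1, 5, 9); two[3, 3] <- 0; two[3, 7] <- 0
  expect_equal(object_euler(two), -1L)
})

test_that("feret diameters: exhaustive pairs and caliper widths", {
  f <- feret_diameters(matrix(1, 3, 3))
  expect_equal(f$max_feret, 2 * sqrt(2))
  expect_equal(f$min_feret, 2)
  f2 <- feret_diameters(matrix(1, 1, 9))
  expect_equal(f2$max_feret, 8)
  expect_equal(f2$min_feret, 0)                            # collinear convention
  f3 <- feret_diameters(cbind(5L, 5L))
  expect_equal(f3$max_feret, 0)
})

test_that("radius statistics come from the exact distance transform", {
  r <- radius_stats(matrix(1, 3, 3))
  expect_equal(r$max_radius, 2)
  expect_equal(r$mean_radius, 10 / 9)
  expect_equal(r$median_radius, 1)                         # lower median
  r1 <- radius_stats(cbind(1L, 1L))
  expect_equal(unlist(r1), c(max_radius = 1, mean_radius = 1,
                             median_radius = 1))
  rl <- radius_stats(matrix(1, 1, 11))
  expect_equal(rl$max_radius, 1)                           # all pixels border bg
})

test_that("solidity uses the rasterized convex hull", {
  expect_equal(convex_solidity(matrix(1, 4, 7)), 1)
  L <- matrix(1, 5, 5); L[1:3, 3:5] <- 0                   # L-shape, area 16
  expect_equal(convex_solidity(L), 16 / 19)
  star <- make_star_fixture()
  expect_lt(convex_solidity(star), 0.7)
})

test_that("empty pixel sets are rejected", {
  for (f in list(object_area, object_perimeter, moment_ellipse,
                 object_extent, object_euler, feret_diameters,
                 radius_stats, convex_solidity, compactness)) {
    expect_error(f(matrix(FALSE, 3, 3)))
  }
})

test_that("descriptors are translation invariant and obey the type invariants", {
  set.seed(71)
  for (i in 1:40) {
    px <- random_blob(sample(2:60, 1))
    o <- measure_object(blob_to_mask(px) * 1L, 1L)
    expect_lte(o$minor_axis_length, o$major_axis_length + 1e-12)
    expect_lte(o$min_feret, o$max_feret + 1e-12)
    expect_lte(o$median_radius, o$max_radius + 1e-12)
    expect_lte(o$mean_radius, o$max_radius + 1e-12)
    expect_lte(o$extent, 1)
    expect_lte(o$solidity, 1 + 1e-12)
    expect_gte(o$eccentricity, 0); expect_lte(o$eccentricity, 1)
    expect_gt(o$orientation, -90); expect_lte(o$orientation, 90)
    # translation changes only the centroid
    shifted <- measure_pixels_shifted(px, 13L, 7L)
    for (nm in morph_object_descriptors()) {
      expect_equal(shifted[[nm]], o[[nm]], tolerance = 1e-12)
    }
  }
})

test_that("a 90-degree rotation maps orientation and swaps axis-aligned extents", {
  set.seed(72)
  for (i in 1:20) {
    px <- random_blob(sample(5:60, 1))
    rot <- cbind(px[, 2], max(px[, 1]) + 1L - px[, 1])     # 90 deg rotation
    o1 <- histomorph:::measure_pixels(px)
    o2 <- histomorph:::measure_pixels(rot)
    th <- o1$orientation + 90
    if (th > 90) th <- th - 180
    if (o1$eccentricity > 1e-6) {
      expect_equal(o2$orientation, th, tolerance = 1e-6)
    }
    expect_equal(o2$max_feret, o1$max_feret, tolerance = 1e-9)
    expect_equal(o2$min_feret, o1$min_feret, tolerance = 1e-9)
    expect_equal(o2$major_axis_length, o1$major_axis_length,
                 tolerance = 1e-9)
  }
})

test_that("measure_roi aggregates occupancy totals and unweighted means", {
  lab <- matrix(0L, 10, 12)
  lab[2:4, 2:4] <- 1L
  lab[6:8, 7:9] <- 2L
  roi <- measure_roi(lab)
  expect_equal(roi$area_occupied, 18)
  expect_equal(roi$count, 2L)
  expect_equal(roi$total_perimeter, 16)
  expect_equal(roi$area, 9)
  expect_equal(names(roi), morph_parameters())
  empty <- measure_roi(matrix(0L, 5, 5))
  expect_equal(empty$count, 0L)
  expect_equal(empty$area_occupied, 0)
  expect_true(all(is.na(empty[morph_object_descriptors()])))
})

test_that("measure_object rejects unknown labels", {
  expect_error(measure_object(matrix(0L, 3, 3), 2L), "unknown label")
})

test_that("descriptors agree with the brute-force oracles on random blobs", {
  set.seed(73)
  for (i in 1:30) {
    px <- random_blob(sample(2:50, 1))
    o <- histomorph:::measure_pixels_list(px)
    expect_identical(o$area, as.numeric(nrow(px)))
    expect_equal(o$perimeter, oracle_perimeter(px), tolerance = 1e-12)
    expect_equal(o$euler_number, oracle_euler(px))
    expect_equal(o$max_feret, oracle_max_feret(px), tolerance = 1e-12)
    expect_equal(o$min_feret, oracle_min_feret(px), tolerance = 1e-12)
    expect_equal(o$solidity, nrow(px) / oracle_convex_area(px),
                 tolerance = 1e-12)
    rad <- oracle_radii(px)
    expect_equal(o$max_radius, rad$max_radius, tolerance = 1e-12)
    expect_equal(o$mean_radius, rad$mean_radius, tolerance = 1e-12)
    expect_equal(o$median_radius, rad$median_radius, tolerance = 1e-12)
  }
})
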