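# Optical density, colour deconvolution, Otsu thresholding and tile
# segmentation.

test_that("optical density transform clamps and inverts intensity", {
  t255 <- array(255, c(2, 2, 3))
  expect_equal(rgb_to_od(t255), array(0, c(2, 2, 3)))
  t0 <- array(0, c(2, 2, 3))
  expect_equal(rgb_to_od(t0), array(log10(255), c(2, 2, 3)))  # clamp at 1
  t <- array(25.5, c(1, 1, 3))
  expect_equal(rgb_to_od(t), array(1, c(1, 1, 3)))            # -log10(0.1)
  expect_error(rgb_to_od(array(0, c(2, 2, 2))), "RGB")
  expect_error(rgb_to_od(array(300, c(2, 2, 3))))
  # monotone decreasing in intensity
  v <- rgb_to_od(array(c(10, 100, 200), c(1, 1, 3)))
  expect_true(all(diff(as.vector(v)) < 0))
})

test_that("deconvolution inverts the stain mixing exactly before clipping", {
  v <- default_stain_vectors()
  expect_equal(unname(rowSums(v^2)), rep(1, 3))
  set.seed(42)
  conc_true <- array(runif(30 * 30 * 3, 0, 1.5), c(30, 30, 3))
  od <- array(matrix(conc_true, ncol = 3) %*% v, c(30, 30, 3))
  conc <- deconvolve(od, v)
  expect_equal(as.vector(conc), as.vector(conc_true), tolerance = 1e-9)
  # reconstruction of arbitrary OD without clipping is exact
  od_rand <- array(runif(300, -0.2, 2), c(10, 10, 3))
  c2 <- deconvolve(od_rand, v, clip = FALSE)
  rec <- array(matrix(c2, ncol = 3) %*% v, dim(od_rand))
  expect_lt(max(abs(rec - od_rand)), 1e-9)
  # clipping floors negatives at zero
  expect_gte(min(deconvolve(od_rand, v)), 0)
  bad <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0) / sqrt(2))
  bad[3, ] <- bad[1, ] + bad[2, ]
  expect_error(deconvolve(od, bad), "singular")
})

test_that("a tile rendered with known DAB density deconvolves to it", {
  v <- default_stain_vectors()
  m <- matrix(FALSE, 20, 20); m[5:14, 5:14] <- TRUE
  tile <- render_tile(list(m), hema_bg = 0, dab_od = 0.8, noise_sd = 0)
  conc <- deconvolve(rgb_to_od(tile), v)
  expect_equal(mean(conc[, , "dab"][m]), 0.8, tolerance = 0.01)  # 8-bit quantized
  expect_lt(max(conc[, , "dab"][!m]), 0.05)
})

test_that("Otsu threshold separates bimodal data and matches the scan oracle", {
  x <- c(rep(0.1, 60), rep(0.9, 40))
  t1 <- otsu_threshold(x)
  expect_gt(t1, 0.1); expect_lt(t1, 0.9)
  set.seed(9)
  x2 <- c(rnorm(500, 0.2, 0.05), rnorm(500, 0.8, 0.05))
  t2 <- otsu_threshold(x2)
  expect_gte(t2, 0.35); expect_lte(t2, 0.65)
  for (i in 1:5) {
    g <- matrix(runif(32 * 32), 32)
    expect_equal(otsu_threshold(g), oracle_otsu(g), tolerance = 1e-12)
  }
  expect_error(otsu_threshold(matrix(0.5, 4, 4)), "degenerate histogram")
})

test_that("segment_tile recovers noiseless planted objects pixel-exactly", {
  f <- make_disk_tile(5)
  lab <- segment_tile(f$tile)
  expect_equal(max(lab), 5L)
  expect_equal(lab > 0, f$gt > 0)
  # object-wise pixel sets match ground truth
  for (k in seq_len(max(f$gt))) {
    ids <- unique(lab[f$gt == k])
    expect_length(ids, 1L)
  }
})

test_that("the min_area filter removes specks and is monotone", {
  f <- make_disk_tile(3)
  tile <- f$tile
  # plant a 2-px speck away from the disks
  speck <- matrix(FALSE, nrow(f$gt), ncol(f$gt))
  bgpx <- which(histomorph:::dilate_box(f$gt > 0, 4) == FALSE, arr.ind = TRUE)
  bgpx <- bgpx[bgpx[, 1] > 2 & bgpx[, 1] < 70 & bgpx[, 2] > 2 & bgpx[, 2] < 70, ]
  speck[bgpx[1, 1], bgpx[1, 2]] <- TRUE
  speck[bgpx[1, 1], bgpx[1, 2] + 1L] <- TRUE
  tile2 <- render_tile(c(f$placed$masks, list(speck)),
                       tile_shape = dim(f$gt), noise_sd = 0)
  expect_equal(max(segment_tile(tile2, min_area = 4L)), 3L)
  expect_equal(max(segment_tile(tile2, min_area = 1L)), 4L)
  counts <- vapply(c(1L, 4L, 20L, 80L, 200L),
                   function(a) max(segment_tile(tile2, min_area = a)),
                   integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("blank tiles yield zero labels without error", {
  blank <- render_tile(list(), tile_shape = c(32L, 32L), noise_sd = 0)
  lab <- segment_tile(blank)
  expect_equal(max(lab), 0L)
  expect_length(attr(lab, "areas"), 0L)
})

test_that("segmentation is robust to a global intensity shift", {
  f <- make_disk_tile(5)
  dim3 <- dim(f$tile)
  dimmed <- array(histomorph:::round_half_up(f$tile * 0.9), dim3)
  expect_equal(max(segment_tile(dimmed)), max(segment_tile(f$tile)))
})

test_that("malformed images are rejected", {
  expect_error(segment_tile(matrix(1, 4, 4)))
  expect_error(segment_tile(array(0, c(4, 4, 4))))
})

test_that("labels are contiguous, 8-connected, with a correct area index", {
  f <- make_disk_tile(4, seed = 9)
  lab <- segment_tile(f$tile)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  expect_equal(sort(ids), seq_len(max(lab)))
  areas <- attr(lab, "areas")
  expect_equal(areas, as.vector(table(lab[lab > 0])[as.character(ids)]),
               ignore_attr = TRUE)
  for (i in ids) {
    expect_equal(max(label_components(lab == i, connectivity = 8)), 1L)
  }
})
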