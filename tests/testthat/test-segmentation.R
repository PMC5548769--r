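test_that("median filter: identity, constancy, impulse rejection", {
  v <- array(runif(5^3), c(5, 5, 5))
  expect_identical(median_filter_3d(v, 0L), v)
  const <- array(7, c(6, 6, 6))
  expect_true(all(median_filter_3d(const, 1L) == 7))
  imp <- array(1, c(7, 7, 7)); imp[4, 4, 4] <- 100
  expect_true(all(median_filter_3d(imp, 1L) == 1))
})

test_that("Otsu matches the exhaustive value-based maximizer", {
  # perfect bimodal volume
  two <- array(rep(c(50, 200), each = 32), c(4, 4, 4))
  thr <- otsu_threshold(two, 256L)
  expect_gt(thr, 50); expect_lte(thr, 200)
  expect_identical(thr, r_otsu_brute(as.vector(two), 256L))
  # 20 random 16^3 volumes
  for (sd in 1:20) {
    set.seed(sd)
    x <- array(c(rnorm(2048, 0, 1), rnorm(2048, 3 * runif(1), 1)),
               c(16, 16, 16))
    expect_equal(otsu_threshold(x, 64L), r_otsu_brute(as.vector(x), 64L),
                 tolerance = 1e-12)
  }
  # shift equivariance to within one bin
  set.seed(99)
  x <- array(rnorm(4096), c(16, 16, 16))
  binw <- diff(range(x)) / 256
  expect_equal(otsu_threshold(x + 5, 256L), otsu_threshold(x, 256L) + 5,
               tolerance = 1.5 * binw)
  expect_error(otsu_threshold(array(1, c(4, 4, 4))), "constant")
})

test_that("component labeling matches flood fill and orders by size", {
  m <- array(FALSE, c(12, 12, 6))
  m[2:4, 2:4, 2:4] <- TRUE      # 27 voxels
  m[7:11, 7:11, 2:5] <- TRUE    # 100 voxels
  lv <- label_components(m, voxel_size = 2)
  expect_identical(max(lv$labels), 2L)
  expect_identical(unname(lv$labels[8, 8, 3]), 1L)  # larger = label 1
  expect_identical(unname(lv$labels[3, 3, 3]), 2L)
  # min_voxels above both sizes -> empty labeling
  lv0 <- label_components(m, min_voxels = 1000L, voxel_size = 2)
  expect_identical(max(lv0$labels), 0L)
  # flood-fill oracle on random fields
  for (sd in 1:10) {
    set.seed(sd)
    r <- array(runif(16^3) < 0.25, c(16, 16, 16))
    expect_identical(max(label_components(r, voxel_size = 2)$labels),
                     max(r_flood_label6(r)))
  }
})

test_that("VOI selection maps segmented labels to truth by overlap", {
  p <- make_ossicle("pyramid", list(base = 60, height = 50), seed = 1)
  lv <- labeled_volume(p$labels, p$voxel_size)
  voi <- select_voi(lv, p)
  expect_identical(unname(voi$mapping["1"]), 1L)
  expect_identical(unname(voi$overlap_fraction["1"]), 1)
  expect_length(voi$unmatched_truth, 0)

  # segmentation missing an ossicle: that truth label is reported unmatched
  tr2 <- array(0L, c(20, 8, 8))
  tr2[2:5, 2:5, 2:5] <- 1L
  tr2[12:15, 2:5, 2:5] <- 2L
  sg2 <- array(0L, c(20, 8, 8))
  sg2[2:5, 2:5, 2:5] <- 1L
  voi2 <- select_voi(labeled_volume(sg2, 2), labeled_volume(tr2, 2))
  expect_true(2L %in% voi2$unmatched_truth)

  # exact overlap tie is ambiguous
  tr <- array(0L, c(8, 4, 4)); tr[2:3, 2, 2] <- 1L; tr[6:7, 2, 2] <- 2L
  sg <- array(0L, c(8, 4, 4)); sg[c(3, 6), 2, 2] <- 1L
  expect_error(select_voi(labeled_volume(sg, 2), labeled_volume(tr, 2)),
               "tie")
})

test_that("eroded phantoms still map onto their originating truth labels", {
  p <- make_ossicle("sphere", list(r = 40), seed = 4, porosity = 0.15)
  pe <- erode_phantom(p, erosion_spec(0.11, seed = 9))
  voi <- select_voi(labeled_volume(pe$labels, 2), p)
  expect_identical(unname(voi$mapping["1"]), 1L)
  expect_gt(unname(voi$overlap_fraction["1"]), 0.5)
})

test_that("noise-free reconstructions segment with Dice > 0.98", {
  p <- make_ossicle("sphere", list(r = 60), seed = 5)
  ps <- flat_correct(project(p, geometry(n_projections = 120L)))
  rv <- fbp_reconstruct(phase_retrieve(ps, 0))
  lv <- segment_volume(rv)
  expect_gt(dice_coefficient(lv, p), 0.98)
  expect_true(lv$threshold_used > min(rv$volume) &&
                lv$threshold_used < max(rv$volume))
})
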