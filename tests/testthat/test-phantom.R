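test_that("solid sphere phantom matches analytic volume and surface", {
  p <- make_ossicle("sphere", list(r = 50), voxel_size = 2, seed = 1)
  r_mm <- 0.05
  expect_equal(p$truth$BV_mm3, (4 / 3) * pi * r_mm^3, tolerance = 0.02)
  expect_equal(p$truth$BS_mm2, 4 * pi * r_mm^2, tolerance = 0.05)
  expect_equal(p$truth$BS_BV, 3 / r_mm, tolerance = 0.10)
  # truth carries the analytic values alongside
  expect_equal(p$truth$analytic_BV_mm3, (4 / 3) * pi * r_mm^3)
  # BV is exactly voxel count x voxel volume
  expect_identical(p$truth$BV_mm3, sum(p$labels == 1L) * (2e-3)^3)
  expect_gte(p$truth$TV_mm3, p$truth$BV_mm3)
})

test_that("phantom generation is deterministic and shapes are single bodies", {
  for (args in list(list("sphere", list(r = 30)),
                    list("pyramid", list(base = 60, height = 50)),
                    list("lunula", list(r_outer = 40, height = 36)))) {
    p1 <- make_ossicle(args[[1]], args[[2]], seed = 7)
    p2 <- make_ossicle(args[[1]], args[[2]], seed = 7)
    expect_identical(p1$labels, p2$labels)
    expect_identical(max(r_flood_label6(p1$labels > 0L)), 1L)
  }
})

test_that("truth ratios are self-consistent to 1e-12", {
  for (seed in 1:3) {
    p <- make_ossicle("pyramid", list(base = 80, height = 70), seed = seed)
    expect_equal(p$truth$BV_TV * p$truth$BS_BV, p$truth$BS_TV,
                 tolerance = 1e-12)
    expect_equal(p$truth$BV_TV, p$truth$BV_mm3 / p$truth$TV_mm3,
                 tolerance = 1e-12)
  }
})

test_that("voxelized sphere volume converges to analytic for large radii", {
  # r = 25 voxels at 1 um voxels
  p <- make_ossicle("sphere", list(r = 25), voxel_size = 1, seed = 1)
  expect_equal(p$truth$BV_mm3, (4 / 3) * pi * (25e-3)^3, tolerance = 0.02)
})

test_that("objects touching the grid boundary are rejected", {
  expect_error(make_ossicle("sphere", list(r = 30), voxel_size = 2, margin = 2L,
                            porosity = 0),
               NA) # fits
  # a margin below the 2-voxel minimum is rejected outright
  expect_error(make_ossicle("sphere", list(r = 30), margin = 1L), "margin")
})

test_that("zero erosion target returns the phantom unchanged", {
  p <- make_ossicle("sphere", list(r = 40), seed = 2, porosity = 0.2)
  pe <- erode_phantom(p, erosion_spec(0, seed = 9))
  expect_identical(pe$labels, p$labels)
  expect_identical(pe$truth, p$truth)
})

test_that("erosion hits the programmed BV/TV drop and roughens the surface", {
  # stochastic-roughening oracle over 5 seeds: recompute truth through the
  # morphometry module after erosion
  for (sd in 1:5) {
    p <- make_ossicle("sphere", list(r = 50), seed = sd, porosity = 0.2)
    pe <- erode_phantom(p, erosion_spec(0.11, seed = sd + 100))
    ratio <- pe$truth$BV_TV / p$truth$BV_TV
    expect_gte(ratio, 0.89 - 0.011)
    expect_lte(ratio, 0.89 + 0.011)
    expect_gt(pe$truth$BS_BV, p$truth$BS_BV)
    # monotonicity: eroded BV below, BS/TV above the unperturbed values
    expect_lt(pe$truth$BV_mm3, p$truth$BV_mm3)
    expect_gt(pe$truth$BS_TV, p$truth$BS_TV)
    # the eroded label is still one 6-connected body
    expect_identical(max(r_flood_label6(pe$labels > 0L)), 1L)
  }
})

test_that("the erosion kernel only ever removes exposed voxels", {
  p <- make_ossicle("sphere", list(r = 30), seed = 3, porosity = 0.15)
  surf <- ossict:::cpp_surface_voxels(p$labels, 1L)
  interior <- setdiff(which(p$labels == 1L) - 1L, surf)
  filled <- ossict:::cpp_fill_holes(p$labels == 1L)
  outside <- p$labels == 0L & !(filled & !(p$labels == 1L))
  # feed the kernel interior candidates only, with point removals
  res <- ossict:::cpp_erode_batch(p$labels, 1L, as.integer(interior), 1000L, outside, 0, 1L)
  expect_identical(res$removed, 0L)
  # surface candidates are removable
  res2 <- ossict:::cpp_erode_batch(p$labels, 1L, as.integer(surf), 50L, outside, 0, 1L)
  expect_gt(res2$removed, 0L)
  removed <- which(p$labels == 1L & res2$labels == 0L) - 1L
  expect_true(all(removed %in% surf))
})

test_that("unreachable erosion targets error with the achieved drop", {
  p <- make_ossicle("sphere", list(r = 24), seed = 1, porosity = 0)  # solid
  expect_error(erode_phantom(p, erosion_spec(0.11, max_iters = 4L)),
               "achieved drop")
})

test_that("cohorts are balanced, deterministic and collapse under zero effect", {
  co <- make_cohort(3, erosion_spec(0.11, seed = 2), between_animal_cv = 0.03,
                    seed = 5, size_params = list(base = 70, height = 60))
  expect_length(co, 6L)
  expect_identical(sum(sapply(co, `[[`, "group") == "control"), 3L)
  expect_identical(sum(sapply(co, `[[`, "group") == "arthritis"), 3L)
  co2 <- make_cohort(3, erosion_spec(0.11, seed = 2), between_animal_cv = 0.03,
                     seed = 5, size_params = list(base = 70, height = 60))
  expect_identical(lapply(co, function(e) e$phantom$labels),
                   lapply(co2, function(e) e$phantom$labels))

  co0 <- make_cohort(2, erosion_spec(0), between_animal_cv = 0, seed = 1,
                     size_params = list(base = 60, height = 50))
  ctl <- Filter(function(e) e$group == "control", co0)
  art <- Filter(function(e) e$group == "arthritis", co0)
  for (k in 1:2)
    expect_identical(ctl[[k]]$phantom$labels, art[[k]]$phantom$labels)
})

test_that("erosion_spec validates its ranges", {
  expect_error(erosion_spec(-0.1), "target_bvtv_drop")
  expect_error(erosion_spec(1.0), "target_bvtv_drop")
  expect_error(erosion_spec(0.1, removal_prob = 0), "removal_prob")
})
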