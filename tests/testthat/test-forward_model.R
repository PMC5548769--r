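geom <- function(n_ang = 24L, nu = NULL, range = 360)
  geometry(n_projections = n_ang, angular_range_deg = range, det_width_px = nu)

test_that("geometry derives the wavelength and validates its ranges", {
  g <- geometry()
  expect_equal(g$wavelength_A, 12.398 / 25, tolerance = 1e-4)
  expect_identical(g$n_projections, 2400L)
  expect_error(geometry(angular_range_deg = 90), "180 or 360")
  expect_error(geometry(pixel_size_um = 0))
})

test_that("projections of an empty phantom equal the flat field", {
  p <- as_phantom(array(0L, c(24, 24, 6)))
  ps <- project(p, geom(12), mu_background = 0, flat_value = 1000,
                aa_sigma_px = 0)
  expect_true(all(ps$projections == 1000))
  # flat-field consistency invariant: proj / flat == 1
  expect_true(all(abs(sweep(ps$projections, c(1, 2), ps$flats[, , 1], `/`) - 1) <
                    1e-12))
})

test_that("a single voxel at the rotation center projects mu * voxel", {
  lab <- array(0L, c(25, 25, 5))
  lab[13, 13, 3] <- 1L
  ps <- project(as_phantom(lab), geom(16, nu = 25), mu_bone = 0.5,
                mu_background = 0, aa_sigma_px = 0)
  li <- -log(ps$projections[13, 3, ])  # center column, all angles
  expect_equal(li, rep(0.5 * 2e-3, 16), tolerance = 1e-10)
})

test_that("Beer-Lambert line integrals are linear in mu", {
  p <- make_ossicle("sphere", list(r = 20), seed = 1)
  ps1 <- project(p, geom(8), mu_bone = 0.2, mu_background = 0)
  ps2 <- project(p, geom(8), mu_bone = 0.4, mu_background = 0)
  expect_equal(-log(ps2$projections), -2 * log(ps1$projections),
               tolerance = 1e-10)
})

test_that("sinogram mass is conserved across angles", {
  p <- make_ossicle("pyramid", list(base = 40, height = 36), seed = 2)
  ps <- project(p, geom(24), mu_background = 0)
  mass <- apply(-log(ps$projections), 3, sum)
  expect_lt(diff(range(mass)) / mean(mass), 1e-6)
})

test_that("propagation is the exact inverse of phase retrieval", {
  p <- make_ossicle("sphere", list(r = 30), seed = 1)
  ps <- project(p, geom(10), mu_background = 0)
  # delta/beta = 0 leaves projections unchanged
  expect_identical(propagate(ps, 0)$projections, ps$projections)
  # zero distance likewise
  g0 <- geometry(distance_cm = 0, n_projections = 10L)
  ps0 <- ps; ps0$geometry <- g0
  expect_identical(propagate(ps0, 300)$projections, ps0$projections)
  # inverse-pair contract at delta/beta = 300, relative error < 1e-8
  pp <- propagate(ps, 300)
  pr <- phase_retrieve(pp, 300)
  ref <- -log(ps$projections)
  expect_lt(max(abs(pr$projections - ref)) / max(abs(ref)), 1e-8)
})

test_that("propagation enhances edges", {
  p <- make_ossicle("pyramid", list(base = 50, height = 44), seed = 1)
  ps <- project(p, geom(6), mu_background = 0)
  pp <- propagate(ps, 300)
  expect_gt(var(as.vector(pp$projections[, , 1])),
            var(as.vector(ps$projections[, , 1])))
})

test_that("Poisson noise is seeded, unbiased and has variance ~ mean", {
  p <- as_phantom(array(0L, c(110, 110, 110)))
  ps <- project(p, geom(2), mu_background = 0, aa_sigma_px = 0)
  n1 <- add_noise(ps, mean_counts = 1e4, seed = 3)
  n2 <- add_noise(ps, mean_counts = 1e4, seed = 3)
  expect_identical(n1$projections, n2$projections)
  # variance ~ mean on a flat region with >= 1e4 pixels (dark offset removed)
  x <- as.vector(n1$projections) - 10
  expect_gt(length(x), 1e4)
  expect_equal(var(x) / mean(x), 1, tolerance = 0.1)
  # infinite-count limit reproduces the clean signal
  hi <- add_noise(ps, mean_counts = 1e9, seed = 4)
  rel <- abs((hi$projections - 10) / 1e9 - ps$projections) / ps$projections
  expect_lt(max(rel), 1e-3)
})

test_that("extended-FOV split halves the detector and records the offset", {
  p <- make_ossicle("sphere", list(r = 30), seed = 1)
  ps <- project(p, geom(8, nu = 96))
  sp <- split_extended_fov(ps, 10)
  expect_identical(dim(sp$projections)[1], 96L %/% 2L + 10L)
  expect_identical(sp$geometry$fov_offset_px, 10L)
  # offset 0 is a pure crop of the right half
  sp0 <- split_extended_fov(ps, 0)
  expect_identical(sp0$projections, ps$projections[49:96, , , drop = FALSE])
  # a 180-degree set cannot be split
  ps180 <- project(p, geom(8, nu = 96, range = 180))
  expect_error(split_extended_fov(ps180, 10), "360")
})
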