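# analytic sinogram of a centered disk: p(s) = 2 mu sqrt(r^2 - s^2)
disk_sino_set <- function(nu = 128L, n_ang = 360L, mu = 0.3, r_px = 40,
                          range = 180) {
  ds <- 2e-3
  s <- ((1:nu) - (nu + 1) / 2) * ds
  p1 <- 2 * mu * sqrt(pmax(0, (r_px * ds)^2 - s^2))
  g <- geometry(pixel_size_um = 2, n_projections = n_ang,
                angular_range_deg = range, det_width_px = nu)
  ossict:::new_projection_set(array(rep(p1, n_ang), c(nu, 1L, n_ang)),
                              ossict:::.angles_deg(g),
                              array(1, c(nu, 1, 1)), array(0, c(nu, 1, 1)),
                              g, is_log = TRUE)
}

# pixel-coverage (4x4 supersampled) disk: the exact discretization of the
# continuous object the analytic sinogram describes
disk_reference <- function(nu = 128L, mu = 0.3, r_px = 40) {
  o <- (1:4 - 0.5) / 4 - 0.5
  cov <- matrix(0, nu, nu)
  for (a in o) for (b in o)
    cov <- cov + (outer(((1:nu) - (nu + 1) / 2 + a)^2,
                        ((1:nu) - (nu + 1) / 2 + b)^2, `+`) <= r_px^2)
  mu * cov / 16
}

test_that("flat correction normalizes, clips and detects bad flats", {
  g <- geometry(n_projections = 2L, det_width_px = 8L)
  mk <- function(proj, flat, dark)
    ossict:::new_projection_set(proj, c(0, 180), flat, dark, g)
  proj <- array(500, c(8, 4, 2))
  flat <- array(500, c(8, 4, 1)); dark <- array(0, c(8, 4, 1))
  fc <- flat_correct(mk(proj, flat, dark))
  expect_true(all(fc$projections == 1))
  # raw = dark -> epsilon floor
  fc2 <- flat_correct(mk(array(20, c(8, 4, 2)), flat, array(20, c(8, 4, 1))),
                      eps = 1e-6)
  expect_true(all(fc2$projections == 1e-6))
  # scaling raw and flat together leaves the output unchanged
  fc3 <- flat_correct(mk(proj * 7, flat * 7, dark))
  expect_equal(fc3$projections, fc$projections)
  # mean flat <= mean dark is an error naming the pixel count
  bad <- flat
  bad[1:3, 1, 1] <- 0
  expect_error(flat_correct(mk(proj, bad, dark)), "3 pixel")
})

test_that("phase retrieval at delta/beta = 0 is exactly -log", {
  p <- make_ossicle("sphere", list(r = 24), seed = 1)
  ps <- flat_correct(project(p, geometry(n_projections = 6L)))
  pr <- phase_retrieve(ps, 0)
  expect_identical(pr$projections, -log(ps$projections))
  expect_true(pr$is_log)
  # nonpositive intensities are rejected with a pointer to flat correction
  bad <- ps
  bad$projections[1] <- 0
  expect_error(phase_retrieve(bad, 0), "flat_correct")
})

test_that("phase retrieval is a low-pass on white noise", {
  set.seed(42)
  g <- geometry(n_projections = 1L, det_width_px = 64L)
  noise <- array(exp(rnorm(64 * 64, 0, 0.05)), c(64, 64, 1))
  ps <- ossict:::new_projection_set(noise, 0, array(1, c(64, 64, 1)),
                                    array(0, c(64, 64, 1)), g,
                                    corrected = TRUE)
  pr <- phase_retrieve(ps, 300)
  expect_lt(var(as.vector(pr$projections)),
            var(as.vector(-log(noise))))
})

test_that("FBP reconstructs the analytic disk to its attenuation value", {
  ps <- disk_sino_set(n_ang = 360L)
  rv <- fbp_reconstruct(ps)
  expect_s3_class(rv, "recon_volume")
  sl <- rv$volume[, , 1]
  xy <- outer(((1:128) - 64.5)^2, ((1:128) - 64.5)^2, `+`)
  expect_equal(mean(sl[xy <= 32^2]), 0.3, tolerance = 0.02)
  expect_lt(sqrt(mean((sl - disk_reference())^2)), 0.05 * 0.3)
})

test_that("FBP error decreases monotonically with angle count", {
  ref <- disk_reference()
  rmse <- sapply(c(45L, 90L, 180L, 360L), function(na) {
    sl <- fbp_reconstruct(disk_sino_set(n_ang = na))$volume[, , 1]
    sqrt(mean((sl - ref)^2))
  })
  expect_true(all(diff(rmse) < 0))
})

test_that("FBP is linear and rejects degenerate inputs", {
  ps <- disk_sino_set(n_ang = 45L)
  v1 <- fbp_reconstruct(ps)$volume
  ps3 <- ps; ps3$projections <- 3 * ps$projections
  expect_equal(fbp_reconstruct(ps3)$volume, 3 * v1, tolerance = 1e-10)
  z <- ps; z$projections[] <- 0
  expect_true(all(fbp_reconstruct(z)$volume == 0))
  one <- ps
  one$projections <- ps$projections[, , 1, drop = FALSE]
  one$angles <- ps$angles[1]
  one$geometry$n_projections <- 1L
  expect_error(fbp_reconstruct(one), "2 projection")
  raw <- ps; raw$is_log <- FALSE
  expect_error(fbp_reconstruct(raw), "phase_retrieve")
})

test_that("split + stitch reproduces the direct full-FOV sinogram", {
  p <- make_ossicle("sphere", list(r = 40), seed = 1)
  ps <- project(p, geometry(n_projections = 40L, det_width_px = 96L),
                mu_background = 0)
  stc <- stitch_360(split_extended_fov(ps, 16))
  ref <- ps$projections[, , 1:20]
  expect_identical(dim(stc$projections), dim(ref))
  expect_identical(stc$geometry$angular_range_deg, 180)
  rmse <- sqrt(mean((stc$projections - ref)^2)) / diff(range(ref))
  expect_lt(rmse, 0.01)
  # overlap blend stays between the contributing values (convexity): the
  # stitched columns never exceed the range of the two source projections
  expect_lte(max(stc$projections), max(ps$projections) + 1e-12)
  expect_gte(min(stc$projections), min(ps$projections) - 1e-12)
})

test_that("stitching demands 360-degree data with even pairing", {
  p <- make_ossicle("sphere", list(r = 30), seed = 1)
  ps <- project(p, geometry(n_projections = 8L, angular_range_deg = 180,
                            det_width_px = 80L))
  expect_error(stitch_360(ps), "360")
  odd <- project(p, geometry(n_projections = 9L, det_width_px = 80L))
  odd <- split_extended_fov(odd, 8)
  expect_error(stitch_360(odd), "odd|partner")
})

test_that("full chain reaches > 0.95 voxel correlation with the phantom", {
  p <- make_ossicle("pyramid", list(base = 160, height = 140), seed = 2)
  g <- geometry(n_projections = 200L)
  ps <- add_noise(propagate(project(p, g), 300), 1e5, seed = 3)
  rv <- fbp_reconstruct(phase_retrieve(flat_correct(ps), 300))
  d <- dim(p$labels)
  attn <- array(0, d)
  ctr <- (d[1:2] + 1) / 2
  xy <- outer((seq_len(d[1]) - ctr[1])^2, (seq_len(d[2]) - ctr[2])^2, `+`)
  attn[rep(xy <= (min(d[1:2]) / 2 - 1)^2, d[3])] <- 0.05
  attn[p$labels > 0L] <- 0.25
  expect_gt(cor(as.vector(rv$volume), as.vector(attn)), 0.95)
})
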