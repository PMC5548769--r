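#' Ossicle phantom generator
#'
#' Builds a 3D binary ossicle-like object on a voxel grid with analytically
#' known ground-truth morphometry. Three shape families are provided:
#' `"sphere"` (calibration object with closed-form volume and surface),
#' `"pyramid"` (the anterior meniscal ossicle archetype) and `"lunula"`
#' (the crescent-shaped posterior ossicle archetype). Optionally, enclosed
#' spherical pores emulating marrow spaces are carved into the interior so
#' that BV/TV starts below 1 and surface erosion has a measurable effect on
#' the bone volume fraction.
#'
#' Ground truth is computed with the very same operators the morphometry
#' module exposes ([bone_volume()], [bone_surface()], [total_volume()]), so
#' truth is self-consistent with the analysis chain; for a solid sphere the
#' analytic values \eqn{4\pi r^2} and \eqn{(4/3)\pi r^3} are stored alongside.
#'
#' @param shape_kind one of `"sphere"`, `"pyramid"`, `"lunula"`
#' @param size_params named list of lengths in micrometres:
#'   sphere `list(r = )`; pyramid `list(base = , height = )`;
#'   lunula `list(r_outer = , height = )`
#' @param voxel_size voxel edge in micrometres (default 2, the acquisition
#'   pixel size)
#' @param seed integer RNG seed controlling pore placement
#' @param porosity target enclosed-pore volume fraction of TV; default 0 for
#'   spheres (so analytic checks apply) and 0.12 otherwise
#' @param margin background margin in voxels on every grid face (minimum 2)
#' @return object of class `phantom`: fields `labels` (integer array, 0 =
#'   background), `voxel_size`, `seed`, `shape`, `truth` (per-label
#'   morphometry data.frame)
#' @export
make_ossicle <- function(shape_kind = c("sphere", "pyramid", "lunula"),
                         size_params, voxel_size = 2, seed = 1L,
                         porosity = NULL, margin = 4L) {
  shape_kind <- match.arg(shape_kind)
  if (margin < 2L) stop("margin must be >= 2 voxels")
  porosity <- porosity %||% if (shape_kind == "sphere") 0 else 0.12
  vs <- voxel_size
  px <- function(um) um / vs  # micrometres -> voxels

  if (shape_kind == "sphere") {
    r <- px(size_params$r %||% stop("sphere needs size_params$r"))
    n <- ceiling(2 * r) + 2L * margin + 1L
    dims <- c(n, n, n)
    ctr <- (dims + 1) / 2
    pred <- function(x, y, z)
      (x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2 <= r^2
  } else if (shape_kind == "pyramid") {
    a <- px(size_params$base %||% stop("pyramid needs size_params$base"))
    h <- px(size_params$height %||% stop("pyramid needs size_params$height"))
    # grid sized to the rotation diagonal so the base corners stay inside
    # the detector field of view at every projection angle
    side <- ceiling(a * sqrt(2)) + 2L * margin + 1L
    dims <- c(side, side, ceiling(h) + 2L * margin + 1L)
    ctr <- (dims + 1) / 2
    z0 <- margin + 1
    pred <- function(x, y, z) {
      t <- (z - z0) / h
      t >= 0 & t <= 1 &
        abs(x - ctr[1]) <= (a / 2) * (1 - t) &
        abs(y - ctr[2]) <= (a / 2) * (1 - t)
    }
  } else { # lunula: crescent cross-section extruded with rounded z profile
    R <- px(size_params$r_outer %||% stop("lunula needs size_params$r_outer"))
    h <- px(size_params$height %||% stop("lunula needs size_params$height"))
    R2 <- 0.85 * R
    off <- 0.55 * R
    dims <- c(ceiling(2 * R) + 2L * margin + 1L, ceiling(2 * R) + 2L * margin + 1L,
              ceiling(h) + 2L * margin + 1L)
    ctr <- (dims + 1) / 2
    pred <- function(x, y, z) {
      rho2 <- (x - ctr[1])^2 + (y - ctr[2])^2
      rho2 <= R^2 &
        (x - ctr[1] - off)^2 + (y - ctr[2])^2 > R2^2 &
        abs(z - ctr[3]) <= (h / 2) * sqrt(pmax(0, 1 - 0.5 * rho2 / R^2))
    }
  }

  xs <- seq_len(dims[1]); ys <- seq_len(dims[2]); zs <- seq_len(dims[3])
  g <- expand.grid(x = xs, y = ys, z = zs)
  mask <- array(pred(g$x, g$y, g$z), dims)
  if (!any(mask)) stop("size_params produce an empty object at this voxel size")
  if (.touches_boundary(mask, 2L))
    stop("object touches the grid boundary; its surface would be clipped")

  labels <- array(0L, dims)
  labels[mask] <- 1L
  if (porosity > 0) {
    labels <- with_seed(seed, .carve_pores(labels, mask, porosity))
    # overlapping pores can strand bone slivers inside a cavity; keep the
    # main body so each label is a single 6-connected component
    cc <- cpp_label6(labels > 0L, 1L)
    labels[cc != 1L] <- 0L
  }
  if (max(cpp_label6(labels > 0L, 1L)) != 1L)
    stop("internal error: phantom bone is not a single 6-connected component")

  p <- structure(list(labels = labels, voxel_size = vs, seed = as.integer(seed),
                      shape = shape_kind, size_params = size_params,
                      porosity = porosity, truth = NULL),
                 class = "phantom")
  p$truth <- compute_morphometry(p)
  if (shape_kind == "sphere" && porosity == 0) {
    r_mm <- size_params$r * 1e-3
    p$truth$analytic_BV_mm3 <- (4 / 3) * pi * r_mm^3
    p$truth$analytic_BS_mm2 <- 4 * pi * r_mm^2
  }
  p
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s, %s voxels @ %g um, %d label(s), seed %d\n",
              x$shape, paste(dim(x$labels), collapse = "x"), x$voxel_size,
              max(x$labels), x$seed))
  print(x$truth)
  invisible(x)
}

.touches_boundary <- function(mask, margin = 1L) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  any(idx <= margin) || any(sweep(idx, 2, d - margin) > 0)
}

# Carve enclosed spherical pores totalling `porosity` of the solid volume.
# Pore centers keep a (pore radius + 6)-voxel bone shell to the outer
# surface so cavities stay enclosed behind walls thick enough (>= 12 um)
# to survive the imaging chain's blur.
.carve_pores <- function(labels, solid, porosity, max_attempts = 2000L) {
  dims <- dim(labels)
  solid_count <- sum(solid)
  target <- porosity * solid_count
  # pore radii sized to the instrument: the delta/beta = 300 retrieval blur
  # spans ~13 um (~7 voxels at 2 um), so marrow-space pores are kept well
  # above it to remain resolvable through the imaging chain
  r_eff <- (3 * solid_count / (4 * pi))^(1 / 3)
  rmin <- max(4, 0.18 * r_eff); rmax <- max(5, 0.28 * r_eff)
  dirs <- rbind(diag(3), -diag(3),
                as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3))
  carved <- 0
  idx_solid <- which(solid, arr.ind = TRUE)
  for (a in seq_len(max_attempts)) {
    if (carved >= target) break
    rp <- runif(1, rmin, rmax)
    ci <- idx_solid[sample.int(nrow(idx_solid), 1L), ]
    probes <- sweep(dirs * (rp + 6), 2, as.numeric(ci), `+`)
    probes <- round(probes)
    ok <- all(probes >= 1) &&
      all(sweep(probes, 2, dims) <= 0) &&
      all(solid[probes])
    if (!ok) next
    lo <- pmax(floor(ci - rp), 1); hi <- pmin(ceiling(ci + rp), dims)
    sub <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    inside <- (sub$x - ci[1])^2 + (sub$y - ci[2])^2 + (sub$z - ci[3])^2 <= rp^2
    lin <- (sub$x[inside]) + dims[1] * ((sub$y[inside] - 1) +
             dims[2] * (sub$z[inside] - 1))
    newly <- sum(labels[lin] != 0L)
    labels[lin] <- 0L
    carved <- carved + newly
  }
  labels
}

#' Erosion specification
#'
#' Parameters of the stochastic surface-erosion operator that emulates
#' arthritic marginal erosion: exposed bone voxels are removed at random
#' until the bone volume fraction has dropped by the programmed amount.
#'
#' @param target_bvtv_drop fractional BV/TV decrease to program (e.g. 0.11
#'   for the arthritic effect size); must lie in `[0, 1)`
#' @param removal_prob per-surface-voxel probability per iteration of
#'   nucleating a removal at that voxel, in `(0, 1]`
#' @param max_iters iteration cap
#' @param seed integer RNG seed
#' @param bite_radius_um radius (micrometres) of the focal erosion pit
#'   carved around each nucleation site; 0 removes single voxels. The
#'   default 10 um keeps erosion features resolvable by the 2 um / delta-beta
#'   300 imaging chain, mirroring the focal (pit-like) morphology of
#'   arthritic marginal erosion
#' @return object of class `erosion_spec`
#' @export
erosion_spec <- function(target_bvtv_drop = 0.11, removal_prob = 0.05,
                         max_iters = 400L, seed = 1L, bite_radius_um = 10) {
  if (target_bvtv_drop < 0 || target_bvtv_drop >= 1)
    stop("target_bvtv_drop must be in [0, 1)")
  if (removal_prob <= 0 || removal_prob > 1)
    stop("removal_prob must be in (0, 1]")
  structure(list(target_bvtv_drop = target_bvtv_drop,
                 removal_prob = removal_prob,
                 max_iters = as.integer(max_iters),
                 seed = as.integer(seed),
                 bite_radius_um = bite_radius_um),
            class = "erosion_spec")
}

.count_tv_vox <- function(labels, id) {
  cr <- .crop_mask(labels == id, pad = 1L)
  sum(cpp_fill_holes(cr$mask))
}

#' Stochastic surface erosion of a phantom
#'
#' Iteratively removes exposed bone voxels (bone voxels with at least one of
#' their six face neighbors in the background, on the outer surface or lining
#' internal cavities) with the given per-voxel probability, until the bone
#' volume fraction BV/TV of each label has dropped by
#' `spec$target_bvtv_drop` (within 0.01) or `max_iters` is reached. Voxels
#' whose removal would disconnect the label (non-simple points for the
#' (6,26) adjacency pair) are skipped, so each ossicle remains a single body.
#' Near the target the per-iteration removal budget is throttled using the
#' observed BV/TV sensitivity to avoid overshooting the tolerance band.
#'
#' @param p a `phantom`
#' @param spec an [erosion_spec()]
#' @return a new `phantom` with updated labels and recomputed truth
#' @export
erode_phantom <- function(p, spec) {
  stopifnot(inherits(p, "phantom"), inherits(spec, "erosion_spec"))
  ids <- sort(setdiff(unique(as.vector(p$labels)), 0L))
  if (length(ids) == 0L) stop("phantom has no labeled ossicle")
  if (spec$target_bvtv_drop == 0) return(p)
  tol <- 0.01
  labels <- p$labels
  with_seed(spec$seed, {
    for (id in ids) {
      bv0 <- sum(labels == id)
      tv0 <- .count_tv_vox(labels, id)
      bvtv0 <- bv0 / tv0
      sens <- NA_real_
      drop_now <- 0
      cap_limit <- max(1L, ceiling(0.005 * bv0))
      # classify background once as exterior vs enclosed cavity; the C++
      # kernel maintains the classification across removals, so BV and TV
      # can be tracked incrementally (only exterior removals shrink TV)
      bone <- labels == id
      filled <- cpp_fill_holes(bone)
      outside_bg <- labels == 0L & !(filled & !bone)
      bv <- bv0; tv <- tv0
      for (it in seq_len(spec$max_iters)) {
        drop_now <- 1 - (bv / tv) / bvtv0
        # aim at the target itself; the sensitivity-throttled batches keep
        # the overshoot inside the +/- tol acceptance band
        if (drop_now >= spec$target_bvtv_drop - 0.2 * tol) break
        surf <- cpp_surface_voxels(labels, id)
        keep <- runif(length(surf)) < spec$removal_prob
        sel <- surf[keep]
        if (length(sel) == 0L) next
        sel <- sample(sel)
        # a bite consumes ~10^2 voxels; passing more nuclei than the batch
        # cap can use only burns candidate scans in the kernel
        sel <- sel[seq_len(min(length(sel), ceiling(cap_limit / 30)))]
        need <- spec$target_bvtv_drop - drop_now
        cap <- if (is.na(sens) || sens <= 0) max(1L, ceiling(0.004 * bv))
               else max(1L, floor(0.7 * need / sens))
        # per-voxel sensitivity is heterogeneous (cavity removals move BV/TV,
        # outer removals barely do); bound each batch so a cavity-only batch
        # cannot overshoot the +/- 0.01 acceptance band
        cap <- min(cap, cap_limit)
        res <- cpp_erode_batch(labels, id, sel, cap, outside_bg,
                               (spec$bite_radius_um %||% 0) / p$voxel_size,
                               4L)
        if (res$removed > 0L) {
          labels <- res$labels
          outside_bg <- res$outside_bg
          bv2 <- bv - res$removed
          tv2 <- tv - res$removed_outside
          drop2 <- 1 - (bv2 / tv2) / bvtv0
          if (drop2 > drop_now) sens <- (drop2 - drop_now) / res$removed
          bv <- bv2; tv <- tv2
        }
      }
      drop_now <- 1 - (bv / tv) / bvtv0
      if (drop_now < spec$target_bvtv_drop - tol)
        stop(sprintf(
          "erosion target %.3f not reachable for label %d within %d iterations (achieved drop %.3f)",
          spec$target_bvtv_drop, id, spec$max_iters, drop_now))
      if (drop_now > spec$target_bvtv_drop + tol)
        stop(sprintf(
          "erosion overshot target %.3f for label %d (achieved drop %.3f)",
          spec$target_bvtv_drop, id, drop_now))
    }
  })
  out <- p
  out$labels <- labels
  out$truth <- compute_morphometry(out)
  out
}

#' Generate a two-group phantom cohort
#'
#' Emulates the control/arthritis study design: `n_per_group` base phantoms
#' with isotropic size jitter at the stated between-animal coefficient of
#' variation form the control group; the arthritis group re-uses the same
#' base generation seeds (same animals, independent size jitter) and passes
#' each phantom through [erode_phantom()]. With zero jitter and a zero
#' erosion target the two groups are identical.
#'
#' @param n_per_group phantoms per group (>= 2; the study design used 3)
#' @param effect an [erosion_spec()] programming the arthritic effect size
#' @param between_animal_cv coefficient of variation of isotropic size
#'   scaling between animals
#' @param seed integer master seed; per-phantom seeds are derived by fixed
#'   offsets
#' @param shape_kind,size_params,voxel_size,porosity passed to
#'   [make_ossicle()]; defaults give a pyramid (anterior-type) ossicle
#' @param class_tag ossicle class label attached to every entry
#'   (`"anterior"` or `"posterior"`)
#' @return object of class `ossicle_cohort`: list of entries
#'   `list(phantom, group, id, class)`
#' @export
make_cohort <- function(n_per_group = 3L, effect = erosion_spec(0.11),
                        between_animal_cv = 0.05, seed = 1L,
                        shape_kind = "pyramid", size_params = NULL,
                        voxel_size = 2, porosity = NULL,
                        class_tag = "anterior") {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  size_params <- size_params %||% switch(shape_kind,
    sphere  = list(r = 80),
    pyramid = list(base = 160, height = 140),
    lunula  = list(r_outer = 90, height = 90))
  z <- with_seed(seed, rnorm(2L * n_per_group))
  scl <- 1 + between_animal_cv * pmax(pmin(z, 2.5), -2.5)
  entries <- list()
  for (k in seq_len(n_per_group)) {
    base_seed <- as.integer(seed + 7919L * k)
    for (grp in c("control", "arthritis")) {
      s <- if (grp == "control") scl[k] else scl[n_per_group + k]
      sp <- lapply(size_params, function(v) v * s)
      ph <- make_ossicle(shape_kind, sp, voxel_size = voxel_size,
                         seed = base_seed, porosity = porosity)
      if (grp == "arthritis" && effect$target_bvtv_drop > 0) {
        es <- effect
        es$seed <- as.integer(effect$seed + 104729L + k)
        ph <- erode_phantom(ph, es)
      }
      entries[[length(entries) + 1L]] <-
        list(phantom = ph, group = grp,
             id = sprintf("%s_%02d", grp, k), class = class_tag)
    }
  }
  structure(entries, class = "ossicle_cohort")
}
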