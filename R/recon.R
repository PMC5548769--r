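#' Reconstructed volume container
#'
#' Floating-point reconstructed attenuation field (mm^-1) with isotropic
#' voxels equal to the detector pixel size, plus a provenance record.
#'
#' @param volume 3D numeric array
#' @param voxel_size voxel edge in micrometres
#' @param provenance list describing how the volume was produced
#' @return object of class `recon_volume`
#' @export
recon_volume <- function(volume, voxel_size, provenance = list()) {
  as_dim3(volume)
  if (!all(is.finite(volume))) stop("reconstructed volume contains non-finite values")
  structure(list(volume = volume, voxel_size = voxel_size,
                 provenance = provenance),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("<recon_volume> %s voxels @ %g um, range [%.4g, %.4g]\n",
              paste(dim(x$volume), collapse = "x"), x$voxel_size,
              min(x$volume), max(x$volume)))
  invisible(x)
}

#' Flat- and dark-field correction
#'
#' Normalizes raw projections to transmittance:
#' `(raw - mean dark) / (mean flat - mean dark)`, clipped below at `eps`.
#'
#' @param ps a `projection_set` with at least one flat and one dark
#' @param eps positive floor applied to the corrected transmittance
#' @return a corrected `projection_set` (flats become unity)
#' @export
flat_correct <- function(ps, eps = 1e-6) {
  stopifnot(inherits(ps, "projection_set"))
  if (ps$is_log) stop("projections are already log data")
  flat <- .mean_image(ps$flats)
  dark <- .mean_image(ps$darks)
  denom <- flat - dark
  nbad <- sum(denom <= 0)
  if (nbad > 0)
    stop(sprintf("mean flat <= mean dark at %d pixel(s); cannot flat-correct", nbad))
  out <- ps
  d <- dim(ps$projections)
  for (a in seq_len(d[3]))
    out$projections[, , a] <- pmax((ps$projections[, , a] - dark) / denom, eps)
  out$flats <- array(1, c(d[1], d[2], 1L))
  out$darks <- array(0, c(d[1], d[2], 1L))
  out$corrected <- TRUE
  out
}

#' Stitch a 360-degree extended-FOV set into 180-degree full-width data
#'
#' Pairs each projection at angle theta with the horizontally mirrored
#' projection at theta + 180 degrees, aligns both on the rotation axis and
#' blends the overlap band (width `2 * fov_offset_px` columns astride the
#' axis) with linear weights. Returns a 180-degree-equivalent full-width
#' projection set.
#'
#' @param ps an offset-detector `projection_set` from [split_extended_fov()]
#'   (or an equivalent acquisition), covering 360 degrees with an even
#'   number of projections
#' @return a stitched `projection_set` over 180 degrees
#' @export
stitch_360 <- function(ps) {
  stopifnot(inherits(ps, "projection_set"))
  g <- ps$geometry
  if (g$angular_range_deg != 360)
    stop("stitching requires a 360-degree acquisition")
  off <- g$fov_offset_px
  if (is.null(off) || is.na(off) || off < 0L)
    stop("projection set has no extended-FOV offset recorded")
  na <- dim(ps$projections)[3]
  if (na %% 2L != 0L)
    stop("no theta + 180 partner available: projection count is odd")
  half <- na %/% 2L
  # partner check: angles must be theta + 180 exactly (within tolerance)
  d180 <- ps$angles[half + seq_len(half)] - ps$angles[seq_len(half)]
  if (any(abs(d180 - 180) > 1e-6))
    stop("no theta + 180 partner within angular tolerance")
  W2 <- dim(ps$projections)[1]
  nv <- dim(ps$projections)[2]
  ov <- 2L * off
  W <- 2L * W2 - ov
  wl <- seq(1, 0, length.out = ov)  # weight of the mirrored (left) member
  stitch_one <- function(a, b) {
    # a: direct frame (axis at off + 0.5 from its left edge, covers right)
    # b: theta+180 partner, mirrored (covers left)
    m <- b[rev(seq_len(W2)), , drop = FALSE]
    out <- matrix(0, W, ncol(a))
    out[seq_len(W2 - ov), ] <- m[seq_len(W2 - ov), ]
    out[(W - W2 + ov + 1):W, ] <- a[(ov + 1):W2, , drop = FALSE]
    if (ov > 0) {
      band <- (W2 - ov + 1):W2
      out[band, ] <- wl * m[band, ] + (1 - wl) * a[seq_len(ov), , drop = FALSE]
    }
    out
  }
  proj <- array(0, c(W, nv, half))
  for (i in seq_len(half))
    proj[, , i] <- stitch_one(ps$projections[, , i], ps$projections[, , i + half])
  flats <- array(stitch_one(.mean_image(ps$flats), .mean_image(ps$flats)),
                 c(W, nv, 1L))
  darks <- array(stitch_one(.mean_image(ps$darks), .mean_image(ps$darks)),
                 c(W, nv, 1L))
  g$angular_range_deg <- 180
  g$n_projections <- half
  g$fov_offset_px <- 0L
  g$det_width_px <- W
  new_projection_set(proj, ps$angles[seq_len(half)], flats, darks, g,
                     delta_beta = ps$delta_beta, is_log = ps$is_log,
                     corrected = ps$corrected)
}

#' Single-distance phase retrieval
#'
#' For each flat-corrected projection: symmetric-extension padding, 2D FFT,
#' multiplication by the homogeneous-object retrieval filter
#' `H(u,v) = 1 / (1 + lambda * D * (delta/beta) / (4*pi) * (u^2 + v^2))`,
#' inverse FFT, then `-log` to obtain a thickness-proportional line-integral
#' map. With `delta_beta = 0` the filter is identity and the output is
#' exactly `-log` of the input.
#'
#' @param ps a flat-corrected `projection_set` with positive intensities
#' @param delta_beta retrieval delta/beta ratio (default 300)
#' @return a `projection_set` of line-integral (post-log) data
#' @export
phase_retrieve <- function(ps, delta_beta = 300) {
  stopifnot(inherits(ps, "projection_set"), delta_beta >= 0)
  if (ps$is_log) stop("projections are already log data")
  d <- dim(ps$projections)
  out <- ps
  out$delta_beta <- delta_beta
  if (delta_beta == 0 || ps$geometry$distance_cm == 0) {
    if (any(ps$projections <= 0))
      stop("nonpositive intensity encountered; apply flat_correct() (with a positive eps) first")
    out$projections <- -log(ps$projections)
  } else {
    H <- .retrieval_filter(2L * d[1], 2L * d[2], ps$geometry, delta_beta)
    for (a in seq_len(d[3])) {
      sm <- .filter_proj2d(ps$projections[, , a], H)
      if (any(sm <= 0))
        stop("nonpositive intensity after retrieval filtering; check flat correction")
      out$projections[, , a] <- -log(sm)
    }
  }
  out$is_log <- TRUE
  out
}

#' Filtered back projection reconstruction
#'
#' Standard slice-by-slice parallel-beam FBP: each sinogram row is
#' ramp-filtered in Fourier space (Ram-Lak, optional cosine apodization) and
#' back-projected with linear interpolation. The output is scaled so that a
#' phantom of attenuation mu (mm^-1) reconstructs to mu.
#'
#' @param ps a `projection_set` of line-integral (post-log) data covering at
#'   least 180 degrees
#' @param n_out output slice side length in voxels (default: detector width)
#' @param apodization `"none"` (Ram-Lak) or `"cosine"`
#' @return a [recon_volume()] in mm^-1
#' @export
fbp_reconstruct <- function(ps, n_out = NULL, apodization = c("none", "cosine")) {
  stopifnot(inherits(ps, "projection_set"))
  apodization <- match.arg(apodization)
  if (!ps$is_log)
    stop("fbp_reconstruct() expects line-integral data; run phase_retrieve() first")
  d <- dim(ps$projections)
  na <- d[3]
  if (na < 2L) stop("at least 2 projection angles are required")
  span <- ps$geometry$angular_range_deg
  if (span < 180) stop("projections must cover at least 180 degrees")
  nu <- d[1]; nz <- d[2]
  n_out <- as.integer(n_out %||% nu)
  ds_mm <- ps$geometry$pixel_size_um * 1e-3
  np <- next_pow2(2L * nu)
  # Ram-Lak ramp as the FFT of the band-limited spatial-domain kernel
  # (h0 = 1/(4 ds^2), odd taps -1/(pi n ds)^2): using the sampled-kernel
  # transform rather than |omega| removes the DC bias of the naive ramp.
  n_idx <- c(0:(np / 2), (-np / 2 + 1):-1)
  h <- numeric(np)
  h[1] <- 1 / (4 * ds_mm^2)
  odd <- which(n_idx %% 2 != 0)
  h[odd] <- -1 / (pi * n_idx[odd] * ds_mm)^2
  ramp <- Re(stats::fft(h)) * ds_mm   # cycles/mm scaling as for |omega|
  if (apodization == "cosine")
    ramp <- ramp * cos(pi * fftfreq(np))
  m <- matrix(0, np, nz * na)
  m[seq_len(nu), ] <- matrix(ps$projections, nu, nz * na)
  Fm <- stats::mvfft(m)
  filt <- Re(stats::mvfft(Fm * ramp, inverse = TRUE)) / np
  filt <- array(filt[seq_len(nu), ], c(nu, nz, na))
  vol <- cpp_backproject(filt, ps$angles * pi / 180, n_out)
  vol <- vol * (pi / na)
  recon_volume(vol, ps$geometry$pixel_size_um,
               provenance = list(n_projections = na,
                                 angular_range_deg = span,
                                 delta_beta = ps$delta_beta,
                                 filter = paste0("ram-lak",
                                   if (apodization == "cosine") "+cosine" else "")))
}
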