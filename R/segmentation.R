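#' 3D median filter
#'
#' Replaces each voxel by the median of the surrounding (2r+1)^3 cube,
#' with edge-replicated borders. Radius 0 is the identity.
#'
#' @param v a `recon_volume` or 3D numeric array
#' @param radius kernel radius in voxels (default 1, i.e. a 3^3 kernel)
#' @return filtered object of the same type
#' @export
median_filter_3d <- function(v, radius = 1L) {
  if (radius < 0) stop("radius must be >= 0")
  arr <- if (inherits(v, "recon_volume")) v$volume else v
  as_dim3(arr)
  out <- cpp_median3d(arr, as.integer(radius))
  if (inherits(v, "recon_volume")) {
    v$volume <- out
    v$provenance$median_radius <- as.integer(radius)
    v
  } else out
}

#' Otsu automatic threshold
#'
#' Builds an `n_bins` histogram of the intensity range and returns the
#' internal bin edge that maximizes the between-class variance
#' `sigma_b^2(t) = w0(t) * w1(t) * (mu0(t) - mu1(t))^2`, with class
#' statistics accumulated from the actual voxel values grouped by bin (so
#' the result matches an exhaustive value-based search over bin edges).
#' Ties are broken toward the lowest threshold.
#'
#' @param v a `recon_volume` or 3D numeric array with at least two distinct
#'   values
#' @param n_bins histogram bin count (default 256)
#' @return threshold intensity; voxels `>= threshold` are foreground
#' @export
otsu_threshold <- function(v, n_bins = 256L) {
  x <- as.vector(if (inherits(v, "recon_volume")) v$volume else v)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("cannot threshold a constant volume")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(x, edges, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  sums <- as.vector(tapply(x, factor(bin, levels = seq_len(n_bins)), sum))
  sums[is.na(sums)] <- 0
  n <- length(x); total <- sum(x)
  c0 <- cumsum(cnt)[-n_bins]       # counts below each internal edge
  s0 <- cumsum(sums)[-n_bins]
  w0 <- c0 / n; w1 <- 1 - w0
  valid <- c0 > 0 & c0 < n
  mu0 <- s0 / c0
  mu1 <- (total - s0) / (n - c0)
  sb <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  k <- which.max(sb)  # which.max returns the first (lowest) maximizer
  edges[k + 1L]
}

#' Label connected components
#'
#' 6-connected foreground components are labeled in decreasing size order;
#' components smaller than `min_voxels` are dropped.
#'
#' @param binary 3D logical array (or numeric, nonzero = foreground)
#' @param min_voxels minimum component size retained
#' @param voxel_size voxel edge in micrometres
#' @param threshold_used,filter_radius provenance passed to the result
#' @return a [labeled_volume()]
#' @export
label_components <- function(binary, min_voxels = 1L, voxel_size = 2,
                             threshold_used = NA_real_,
                             filter_radius = NA_integer_) {
  as_dim3(binary)
  mask <- array(as.logical(binary != 0), dim(binary))
  lab <- cpp_label6(mask, as.integer(min_voxels))
  labeled_volume(lab, voxel_size, threshold_used, filter_radius)
}

#' Median filter + Otsu threshold + labeling in one call
#'
#' The standard post-processing chain: median filter to reduce noise, global
#' Otsu threshold over the whole-volume histogram, 6-connected labeling.
#'
#' @param rv a `recon_volume`
#' @param median_radius median kernel radius (voxels)
#' @param n_bins Otsu histogram bins
#' @param min_voxels minimum component size retained
#' @return a [labeled_volume()]
#' @export
segment_volume <- function(rv, median_radius = 1L, n_bins = 256L,
                           min_voxels = 64L) {
  stopifnot(inherits(rv, "recon_volume"))
  f <- median_filter_3d(rv, median_radius)
  thr <- otsu_threshold(f, n_bins)
  label_components(f$volume >= thr, min_voxels = min_voxels,
                   voxel_size = rv$voxel_size, threshold_used = thr,
                   filter_radius = as.integer(median_radius))
}

#' Match segmented labels to ground-truth ossicles
#'
#' Replaces manual region-of-interest drawing: each segmented label is
#' assigned to the ground-truth ossicle with which it shares the largest
#' voxel overlap. An exact tie in overlap is an error (ambiguous
#' assignment); truth labels left without a match are reported.
#'
#' @param lv a `labeled_volume` (segmentation output)
#' @param truth a `phantom` or `labeled_volume` carrying ground-truth labels
#'   on the same grid
#' @return list with `mapping` (named integer vector, segmented -> truth
#'   label, 0 = background), `overlap_fraction` (fraction of each segmented
#'   label covered by its matched truth label), `unmatched_truth`,
#'   `unmatched_segmented`
#' @export
select_voi <- function(lv, truth) {
  seg <- .get_labels(lv)
  tru <- .get_labels(truth)
  if (!identical(dim(seg), dim(tru)))
    stop("segmentation and truth volumes differ in shape")
  seg_ids <- sort(setdiff(unique(as.vector(seg)), 0L))
  tru_ids <- sort(setdiff(unique(as.vector(tru)), 0L))
  mapping <- integer(0); ovfrac <- numeric(0)
  for (s in seg_ids) {
    sel <- seg == s
    counts <- tabulate(tru[sel] + 1L, nbins = max(tru_ids, 0L) + 1L)
    names(counts) <- 0:(length(counts) - 1L)
    ov <- counts[-1]  # overlap with each truth label
    if (length(ov) == 0L || all(ov == 0)) {
      mapping[as.character(s)] <- 0L
      ovfrac[as.character(s)] <- 0
      next
    }
    best <- max(ov)
    tied <- which(ov == best)
    if (length(tied) > 1L)
      stop(sprintf("ambiguous overlap tie for segmented label %d: truth labels %s",
                   s, paste(names(ov)[tied], collapse = ", ")))
    mapping[as.character(s)] <- as.integer(names(ov)[tied])
    ovfrac[as.character(s)] <- best / sum(sel)
  }
  list(mapping = mapping, overlap_fraction = ovfrac,
       unmatched_truth = setdiff(tru_ids, mapping),
       unmatched_segmented = as.integer(names(mapping)[mapping == 0L]))
}

#' Dice coefficient between a segmented label and a truth label
#'
#' @param lv segmentation `labeled_volume`
#' @param truth truth `phantom`/`labeled_volume`
#' @param seg_label,truth_label label ids to compare
#' @return Dice similarity in `[0, 1]`
#' @export
dice_coefficient <- function(lv, truth, seg_label = 1L, truth_label = 1L) {
  a <- .get_labels(lv) == seg_label
  b <- .get_labels(truth) == truth_label
  2 * sum(a & b) / (sum(a) + sum(b))
}
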