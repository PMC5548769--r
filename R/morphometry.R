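#' Labeled volume container
#'
#' Integer label field identifying each ossicle after segmentation
#' (0 = background). Every positive label is a single 6-connected component.
#'
#' @param labels 3D integer array of labels
#' @param voxel_size voxel edge length in micrometres
#' @param threshold_used intensity threshold that produced the binarization
#'   (NA when labels were not derived by thresholding)
#' @param filter_radius median-filter radius (voxels) applied before
#'   thresholding, if any
#' @return object of class `labeled_volume`
#' @export
labeled_volume <- function(labels, voxel_size, threshold_used = NA_real_,
                           filter_radius = NA_integer_) {
  as_dim3(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be nonnegative")
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be a positive length in micrometres")
  structure(list(labels = labels, voxel_size = voxel_size,
                 threshold_used = threshold_used,
                 filter_radius = filter_radius),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  n <- max(x$labels)
  cat(sprintf("<labeled_volume> %s voxels @ %g um, %d label(s)\n",
              paste(dim(x$labels), collapse = "x"), x$voxel_size, n))
  invisible(x)
}

.get_labels <- function(x) {
  if (inherits(x, c("labeled_volume", "phantom"))) x$labels
  else stop("expected a labeled_volume or phantom")
}

.check_label <- function(labels, label) {
  n <- sum(labels == label)
  if (label < 1L || n == 0L)
    stop(sprintf("label %d is absent from the volume", label))
  n
}

.vox_mm3 <- function(voxel_size) (voxel_size * 1e-3)^3
.vox_mm2 <- function(voxel_size) (voxel_size * 1e-3)^2

# Crop a logical mask to its bounding box plus `pad` background layers
# (clipped at the volume edge). Returns list(mask, touches_boundary).
.crop_mask <- function(mask, pad = 2L) {
  d <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  touches <- any(lo == 1L) || any(hi == d)
  lo2 <- pmax(lo - pad, 1L); hi2 <- pmin(hi + pad, d)
  list(mask = mask[lo2[1]:hi2[1], lo2[2]:hi2[2], lo2[3]:hi2[3], drop = FALSE],
       touches_boundary = touches)
}

#' Bone volume of one label
#'
#' BV is the volume of all voxels carrying the label: voxel count times the
#' voxel volume, reported in mm^3.
#'
#' @param lv a `labeled_volume` (or `phantom`)
#' @param label positive integer label id
#' @return bone volume in mm^3
#' @export
bone_volume <- function(lv, label = 1L) {
  labels <- .get_labels(lv)
  n <- .check_label(labels, label)
  n * .vox_mm3(lv$voxel_size)
}

#' Bone surface of one label
#'
#' BS is the area of a triangulated iso-surface of the label mask, in mm^2.
#' The binary mask is anti-aliased with a single 3^3 box mean before the
#' 0.5-level surface is extracted by marching tetrahedra; without this step
#' the staircase triangulation of a binary ball overestimates the true area
#' by roughly 9-28% depending on the triangulation scheme, while the
#' anti-aliased surface of a digitized ball is accurate to well under 1%.
#'
#' @inheritParams bone_volume
#' @return bone surface in mm^2
#' @export
bone_surface <- function(lv, label = 1L) {
  labels <- .get_labels(lv)
  .check_label(labels, label)
  cr <- .crop_mask(labels == label, pad = 2L)
  if (cr$touches_boundary)
    stop(sprintf("label %d touches the volume boundary; its surface would be clipped",
                 label))
  m <- array(as.numeric(cr$mask), dim(cr$mask))
  a_vox <- cpp_surface_area_mt(cpp_boxmean3(m), 0.5)
  a_vox * .vox_mm2(lv$voxel_size)
}

#' Total volume of one label
#'
#' TV is the label volume after filling holes: background cavities not
#' 26-connected to the volume border become part of the object. Surface
#' concavities open to the exterior are not holes and do not contribute.
#'
#' @inheritParams bone_volume
#' @return total volume in mm^3
#' @export
total_volume <- function(lv, label = 1L) {
  labels <- .get_labels(lv)
  .check_label(labels, label)
  cr <- .crop_mask(labels == label, pad = 1L)
  filled <- cpp_fill_holes(cr$mask)
  sum(filled) * .vox_mm3(lv$voxel_size)
}

#' Bone morphometry of every label
#'
#' Computes the minimum standard morphometric parameter set per ossicle:
#' bone volume fraction BV/TV, specific bone surface BS/BV (mm^-1), and bone
#' surface density BS/TV (mm^-1), alongside the raw BV, BS, TV.
#'
#' @param lv a `labeled_volume` (or `phantom`)
#' @param labels integer label ids (default: all present labels)
#' @return data.frame with one row per label and columns `label`, `BV_mm3`,
#'   `BS_mm2`, `TV_mm3`, `BV_TV`, `BS_BV`, `BS_TV`
#' @export
compute_morphometry <- function(lv, labels = NULL) {
  lab <- .get_labels(lv)
  present <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(present) == 0L) stop("volume contains no labels")
  labels <- labels %||% present
  rows <- lapply(labels, function(id) {
    bv <- bone_volume(lv, id)
    bs <- bone_surface(lv, id)
    tv <- total_volume(lv, id)
    data.frame(label = id, BV_mm3 = bv, BS_mm2 = bs, TV_mm3 = tv,
               BV_TV = bv / tv, BS_BV = bs / bv, BS_TV = bs / tv)
  })
  do.call(rbind, rows)
}
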