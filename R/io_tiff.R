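#' Write a 3D array as a multi-page TIFF stack
#'
#' Baseline little-endian TIFF, uncompressed, one strip per page; pages are
#' the third array dimension. Supported sample types: `uint8`, `uint16`
#' (integer data) and `float32`. An optional YAML sidecar
#' (`<path>.yaml`) carries metadata. Round-trips losslessly with
#' [read_tiff_stack()] (float data is stored at 32-bit precision).
#'
#' @param vol 3D array
#' @param path output file path
#' @param dtype `"uint8"`, `"uint16"` or `"float32"` (default chosen from
#'   the data: integer/logical arrays in range use the narrowest integer
#'   type, otherwise float32)
#' @param sidecar optional named list written as `<path>.yaml`
#' @return invisibly, `path`
#' @export
write_tiff_stack <- function(vol, path, dtype = NULL, sidecar = NULL) {
  d <- as_dim3(vol)
  x <- as.vector(vol)
  if (is.null(dtype)) {
    dtype <- if ((is.integer(x) || is.logical(x)) && !anyNA(x)) {
      if (max(x) <= 255L && min(x) >= 0L) "uint8"
      else if (max(x) <= 65535L && min(x) >= 0L) "uint16"
      else "float32"
    } else "float32"
  }
  if (!dtype %in% c("uint8", "uint16", "float32"))
    stop("dtype must be uint8, uint16 or float32")
  if (dtype %in% c("uint8", "uint16")) {
    if (anyNA(x) || any(x < 0) || any(x != round(x)))
      stop("integer TIFF output requires nonnegative integer data")
    lim <- if (dtype == "uint8") 255 else 65535
    if (any(x > lim)) stop(sprintf("data exceed %s range", dtype))
  }
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- if (dtype == "float32") 3L else 1L
  bpp <- bits %/% 8L
  w <- d[1]; h <- d[2]; npages <- d[3]
  pagebytes <- as.integer(w * h * bpp)
  n_entries <- 10L
  ifdsize <- 2L + 12L * n_entries + 4L
  data0 <- 8L
  ifd0 <- data0 + npages * pagebytes

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wb(42L, 2); wb(ifd0, 4)
  # pixel data
  for (k in seq_len(npages)) {
    page <- x[((k - 1) * w * h + 1):(k * w * h)]
    if (dtype == "float32") writeBin(as.numeric(page), con, size = 4, endian = "little")
    else {
      page <- as.integer(page)
      if (dtype == "uint16") page <- ifelse(page > 32767L, page - 65536L, page)
      suppressWarnings(writeBin(page, con, size = bpp, endian = "little"))
    }
  }
  entry <- function(tag, type, count, value) { wb(tag, 2); wb(type, 2); wb(count, 4); wb(value, 4) }
  entry_s <- function(tag, value) { # SHORT value left-justified in 4 bytes
    wb(tag, 2); wb(3L, 2); wb(1L, 4); wb(value, 2); wb(0L, 2)
  }
  for (k in seq_len(npages)) {
    wb(n_entries, 2)
    entry(256L, 4L, 1L, w)                         # ImageWidth
    entry(257L, 4L, 1L, h)                         # ImageLength
    entry_s(258L, bits)                            # BitsPerSample
    entry_s(259L, 1L)                              # Compression: none
    entry_s(262L, 1L)                              # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data0 + (k - 1L) * pagebytes)  # StripOffsets
    entry_s(277L, 1L)                              # SamplesPerPixel
    entry(278L, 4L, 1L, h)                         # RowsPerStrip
    entry(279L, 4L, 1L, pagebytes)                 # StripByteCounts
    entry_s(339L, fmt)                             # SampleFormat
    wb(if (k < npages) ifd0 + k * ifdsize else 0L, 4)  # next IFD
  }
  if (!is.null(sidecar))
    yaml::write_yaml(sidecar, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Reads the baseline uncompressed TIFFs produced by [write_tiff_stack()]
#' (little-endian, one strip per page). All pages must share shape and
#' sample type. If a `<path>.yaml` sidecar exists it is returned as the
#' `sidecar` attribute; a missing sidecar produces a warning and `NULL`
#' metadata.
#'
#' @param path TIFF file path
#' @param sidecar read the YAML sidecar if present (default `TRUE`)
#' @return 3D array (integer for uint8/uint16, double for float32) with
#'   attribute `sidecar`
#' @export
read_tiff_stack <- function(path, sidecar = TRUE) {
  fsize <- file.size(path)
  if (is.na(fsize)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rb <- function(n, size, signed = TRUE)
    readBin(con, "integer", n = n, size = size, signed = signed, endian = "little")
  need <- function(cond, what = "file is truncated or not a supported TIFF")
    if (!cond) stop(what, ": ", path)
  magic <- readChar(con, 2, useBytes = TRUE)
  need(identical(magic, "II"), "not a little-endian TIFF")
  need(identical(rb(1, 2), 42L), "bad TIFF magic number")
  offset <- rb(1, 4)
  pages <- list()
  dtype <- NULL
  while (offset != 0L) {
    need(offset + 2 <= fsize)
    seek(con, offset)
    n <- rb(1, 2, signed = FALSE)
    need(offset + 2 + 12 * n + 4 <= fsize)
    tags <- list()
    for (i in seq_len(n)) {
      tag <- rb(1, 2, signed = FALSE)
      type <- rb(1, 2, signed = FALSE)
      count <- rb(1, 4)
      value <- if (type == 3L) { v <- rb(1, 2, signed = FALSE); rb(1, 2); v }
               else rb(1, 4)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = value)
    }
    offset <- rb(1, 4)
    gettag <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else v$value
    }
    w <- gettag(256); h <- gettag(257)
    need(!is.null(w) && !is.null(h), "missing image dimensions")
    need(identical(gettag(259, 1L), 1L), "compressed TIFF not supported")
    need(identical(tags[["273"]]$count, 1L), "multi-strip TIFF not supported")
    bits <- gettag(258, 1L); fmt <- gettag(339, 1L)
    dt <- if (fmt == 3L) "float32" else if (bits == 16L) "uint16" else "uint8"
    if (is.null(dtype)) dtype <- dt
    else need(identical(dtype, dt), "mixed sample types across pages")
    if (length(pages) > 0)
      need(identical(dim(pages[[1]]), c(w, h)) || all(dim(pages[[1]]) == c(w, h)),
           "inconsistent page shapes")
    so <- gettag(273); sb <- gettag(279)
    need(so + sb <= fsize)
    seek(con, so)
    page <- if (dtype == "float32")
      readBin(con, "numeric", n = w * h, size = 4, endian = "little")
    else readBin(con, "integer", n = w * h, size = bits %/% 8,
                 signed = FALSE, endian = "little")
    need(length(page) == w * h)
    pages[[length(pages) + 1L]] <- matrix(page, w, h)
  }
  need(length(pages) > 0, "TIFF contains no pages")
  d1 <- dim(pages[[1]])
  out <- array(unlist(pages, use.names = FALSE), c(d1, length(pages)))
  meta <- NULL
  yml <- paste0(path, ".yaml")
  if (sidecar) {
    if (file.exists(yml)) meta <- yaml::read_yaml(yml)
    else warning("no YAML sidecar found for ", path, "; using defaults")
  }
  attr(out, "sidecar") <- meta
  out
}

#' Save / load a phantom as TIFF labels + YAML truth sidecar
#'
#' @param p a `phantom`
#' @param path TIFF path (sidecar written at `<path>.yaml`, truth CSV at
#'   `<path>.truth.csv`)
#' @return invisibly, `path`
#' @export
save_phantom <- function(p, path) {
  stopifnot(inherits(p, "phantom"))
  write_tiff_stack(p$labels, path, dtype = "uint8",
                   sidecar = list(kind = "phantom", voxel_size_um = p$voxel_size,
                                  seed = p$seed, shape = p$shape,
                                  truth = lapply(seq_len(nrow(p$truth)), function(i)
                                    as.list(p$truth[i, , drop = FALSE]))))
  write.csv(p$truth, paste0(path, ".truth.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname save_phantom
#' @export
load_phantom <- function(path) {
  arr <- read_tiff_stack(path)
  meta <- attr(arr, "sidecar")
  labels <- array(as.integer(arr), dim(arr))
  p <- structure(list(labels = labels,
                      voxel_size = meta$voxel_size_um %||% 2,
                      seed = meta$seed %||% NA_integer_,
                      shape = meta$shape %||% "unknown",
                      size_params = NULL, porosity = NA_real_, truth = NULL),
                 class = "phantom")
  tcsv <- paste0(path, ".truth.csv")
  p$truth <- if (file.exists(tcsv)) read.csv(tcsv) else compute_morphometry(p)
  p
}

#' Save / load a projection set (TIFF stacks + YAML geometry sidecar)
#'
#' Writes `<stem>.tif` (projections), `<stem>_flats.tif`, `<stem>_darks.tif`
#' and `<stem>.tif.yaml` with the geometry fields `pixel_size_um`,
#' `distance_cm`, `energy_keV`, `delta_beta`, `n_projections`,
#' `angular_range_deg`, `fov_offset_px`.
#'
#' @param ps a `projection_set`
#' @param stem path stem (no extension)
#' @return invisibly, the projection TIFF path
#' @export
save_projection_set <- function(ps, stem) {
  stopifnot(inherits(ps, "projection_set"))
  g <- ps$geometry
  write_tiff_stack(ps$projections, paste0(stem, ".tif"), dtype = "float32",
                   sidecar = list(kind = "projection_set",
                                  pixel_size_um = g$pixel_size_um,
                                  distance_cm = g$distance_cm,
                                  energy_keV = g$energy_keV,
                                  delta_beta = ps$delta_beta,
                                  n_projections = g$n_projections,
                                  angular_range_deg = g$angular_range_deg,
                                  fov_offset_px = g$fov_offset_px,
                                  is_log = ps$is_log, corrected = ps$corrected))
  write_tiff_stack(ps$flats, paste0(stem, "_flats.tif"), dtype = "float32")
  write_tiff_stack(ps$darks, paste0(stem, "_darks.tif"), dtype = "float32")
  invisible(paste0(stem, ".tif"))
}

#' @rdname save_projection_set
#' @export
load_projection_set <- function(stem) {
  proj <- read_tiff_stack(paste0(stem, ".tif"))
  meta <- attr(proj, "sidecar") %||% list()
  flats <- read_tiff_stack(paste0(stem, "_flats.tif"), sidecar = FALSE)
  darks <- read_tiff_stack(paste0(stem, "_darks.tif"), sidecar = FALSE)
  g <- geometry(pixel_size_um = meta$pixel_size_um %||% 2,
                distance_cm = meta$distance_cm %||% 15,
                energy_keV = meta$energy_keV %||% 25,
                n_projections = meta$n_projections %||% dim(proj)[3],
                angular_range_deg = meta$angular_range_deg %||% 360,
                fov_offset_px = meta$fov_offset_px %||% 0L,
                det_width_px = dim(proj)[1])
  ang <- .angles_deg(g)
  new_projection_set(array(as.numeric(proj), dim(proj)), ang,
                     array(as.numeric(flats), dim(flats)),
                     array(as.numeric(darks), dim(darks)), g,
                     delta_beta = meta$delta_beta %||% NA_real_,
                     is_log = isTRUE(meta$is_log),
                     corrected = isTRUE(meta$corrected))
}

#' Save / load a reconstructed volume (float32 TIFF + YAML sidecar)
#'
#' @param rv a `recon_volume`
#' @param path TIFF path
#' @return invisibly, `path`
#' @export
save_recon_volume <- function(rv, path) {
  stopifnot(inherits(rv, "recon_volume"))
  write_tiff_stack(rv$volume, path, dtype = "float32",
                   sidecar = c(list(kind = "recon_volume",
                                    voxel_size_um = rv$voxel_size),
                               rv$provenance))
  invisible(path)
}

#' @rdname save_recon_volume
#' @export
load_recon_volume <- function(path) {
  arr <- read_tiff_stack(path)
  meta <- attr(arr, "sidecar") %||% list()
  recon_volume(array(as.numeric(arr), dim(arr)),
               voxel_size = meta$voxel_size_um %||% 2,
               provenance = meta[setdiff(names(meta), c("kind", "voxel_size_um"))])
}
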