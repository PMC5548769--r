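#' Default pipeline configuration
#'
#' Nested configuration with the emulated acquisition's physics defaults:
#' 2 um pixels, 15 cm propagation distance, 25 keV, delta/beta 300.
#'
#' @return nested named list (`geometry`, `retrieval`, `segmentation`,
#'   `phantom`, `seed`)
#' @export
default_config <- function() {
  list(
    geometry = list(pixel_size_um = 2, distance_cm = 15, energy_keV = 25,
                    n_projections = 200L, angular_range_deg = 360,
                    fov_offset_px = 0L, exposure_ms = 600),
    retrieval = list(delta_beta = 300),
    segmentation = list(median_radius = 1L, n_bins = 256L, min_voxels = 64L),
    phantom = list(shape = "pyramid", base_um = 160, height_um = 140,
                   r_um = 80, porosity = 0.12,
                   erosion = list(target_bvtv_drop = 0.11,
                                  removal_prob = 0.05, max_iters = 400L),
                   n_per_group = 3L, between_animal_cv = 0.05),
    noise = list(mean_counts = 1e5),
    seed = 1L
  )
}

.validate_config <- function(cfg) {
  pos <- function(x, name) if (!is.numeric(x) || any(x <= 0))
    stop(sprintf("config field '%s' must be positive", name))
  pos(cfg$geometry$pixel_size_um, "geometry.pixel_size_um")
  pos(cfg$geometry$energy_keV, "geometry.energy_keV")
  pos(cfg$geometry$n_projections, "geometry.n_projections")
  if (cfg$geometry$distance_cm < 0)
    stop("config field 'geometry.distance_cm' must be >= 0")
  if (!cfg$geometry$angular_range_deg %in% c(180, 360))
    stop("config field 'geometry.angular_range_deg' must be 180 or 360")
  if (cfg$retrieval$delta_beta < 0)
    stop("config field 'retrieval.delta_beta' must be >= 0")
  if (cfg$segmentation$median_radius < 0)
    stop("config field 'segmentation.median_radius' must be >= 0")
  pos(cfg$segmentation$n_bins, "segmentation.n_bins")
  er <- cfg$phantom$erosion
  if (er$target_bvtv_drop < 0 || er$target_bvtv_drop >= 1)
    stop("config field 'phantom.erosion.target_bvtv_drop' must be in [0, 1)")
  pos(cfg$noise$mean_counts, "noise.mean_counts")
  invisible(cfg)
}

.merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults))
      stop("unknown config key: ", full)
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      .merge_config(defaults[[k]], user[[k]], full)
    else user[[k]]
  }
  defaults
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected (to catch typos); missing keys take the
#' defaults of [default_config()]. An empty file yields all defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults
#' @return validated configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user)) stop("config file must contain a YAML mapping")
      cfg <- .merge_config(cfg, user)
    }
  }
  .validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg configuration list
#' @param path output YAML path
#' @return invisibly, `path`
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
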