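# Example pipeline configuration. Omitted keys take the defaults of
# default_config(): 2 um pixels, 15 cm propagation, 25 keV, delta/beta 300.
geometry:
  pixel_size_um: 2
  distance_cm: 15
  energy_keV: 25
  n_projections: 200
  angular_range_deg: 360
retrieval:
  delta_beta: 300
segmentation:
  median_radius: 1
  n_bins: 256
  min_voxels: 64
phantom:
  shape: pyramid
  base_um: 160
  height_um: 140
  porosity: 0.12
  erosion:
    target_bvtv_drop: 0.11
  n_per_group: 3
  between_animal_cv: 0.05
noise:
  mean_counts: 100000
seed: 1
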