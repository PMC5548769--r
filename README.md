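# ossict

Synchrotron micro-CT simulation and bone morphometry of meniscal ossicles,
as a fully synthetic, end-to-end testable R pipeline.

## The problem

Early bone erosion is a central readout in preclinical arthritis studies.
Micro-CT bone morphometry can quantify it objectively, but only if the
volume of interest (VOI) is reproducible across animals. The meniscal
ossicles of the rodent knee — pyramid-shaped anteriorly, crescent-shaped
("lunulae") posteriorly — are anatomically self-delimiting and make a
natural VOI. The biomarker signature of arthritic erosion at the anterior
ossicles is a decrease in bone volume fraction with increases in surface
ratios:

- **BV/TV** — bone volume / total volume (volume after filling enclosed
  cavities), dimensionless;
- **BS/BV** — bone surface (triangulated) / bone volume, mm^-1;
- **BS/TV** — bone surface / total volume, mm^-1;

compared between groups with the unpaired **Welch two-sample t-test**
(t = (m1-m2)/sqrt(s1²/n1 + s2²/n2), Welch–Satterthwaite df, two-sided p).

No animal data ship with this package. Instead it provides an ossicle
**phantom generator** with analytically known ground truth and programmable
erosion, a **forward model** of the acquisition (parallel beam, 2 µm
pixels, 25 keV, 15 cm propagation distance, flat/dark fields, Poisson
noise, 360° extended field of view), **reconstruction** (flat-field
correction, sinogram stitching, single-distance phase retrieval at
δ/β = 300, filtered back projection), **segmentation** (3D median filter,
Otsu auto-threshold, 6-connected labeling, overlap-based VOI matching),
**morphometry**, and the **group statistics** — so the entire measurement
chain can be validated against known truth.

## Worked example

```r
library(ossict)

# an anterior-type ossicle: 160 um pyramid with marrow-space porosity
p <- make_ossicle("pyramid", list(base = 160, height = 140),
                  voxel_size = 2, seed = 2)
p$truth[, c("BV_mm3", "BS_mm2", "TV_mm3", "BV_TV", "BS_BV", "BS_TV")]
#>        BV_mm3     BS_mm2     TV_mm3     BV_TV    BS_BV    BS_TV
#> 1 0.001074784 0.09209833 0.00122668 0.8761731 85.69008 75.07934

# arthritic erosion programmed at an 11% BV/TV drop
pe <- erode_phantom(p, erosion_spec(target_bvtv_drop = 0.11, seed = 5))
pe$truth$BV_TV / p$truth$BV_TV
#> [1] 0.891367

# the full imaging chain on one phantom
g  <- geometry(pixel_size_um = 2, distance_cm = 15, energy_keV = 25,
               n_projections = 200)
ps <- project(p, g)                       # Beer-Lambert intensities
ps <- propagate(ps, delta_beta = 300)     # edge enhancement
ps <- add_noise(ps, mean_counts = 1e5, seed = 3)
ps <- flat_correct(ps)
ps <- phase_retrieve(ps, delta_beta = 300)
rv <- fbp_reconstruct(ps)                 # mm^-1 volume
lv <- segment_volume(rv)                  # median + Otsu + labels
compute_morphometry(lv, labels = 1L)[, c("BV_TV", "BS_BV", "BS_TV")]
#>       BV_TV   BS_BV    BS_TV
#> 1 0.8809158 83.0892 73.19459   # BV/TV recovered within ~0.6% of truth

# a three-per-group cohort study, mirroring the control/arthritis design
cohort <- make_cohort(3, erosion_spec(0.11, seed = 5),
                      between_animal_cv = 0.03, seed = 11)
study <- run_cohort_study(cohort, study_config(n_projections = 200), seed = 42)
study$summary[, c("parameter", "percent_change", "p")]
#>   parameter percent_change            p
#> 1     BV_TV       -8.93010 0.0001378254
#> 2     BS_BV       46.04426 0.0006403779
#> 3     BS_TV       32.99733 0.0003143002
```

The programmed −11% BV/TV effect is recovered at −8.9% through the full
imaging chain (partial-volume and blur attenuate it slightly), with the
surface ratios up and all three parameters significant at n = 3/group —
the directional signature the biomarker is designed to detect. An
uneroded ("posterior-class") cohort run the same way stays
non-significant.

## Command line

```sh
ossict phantom make --shape pyramid --out ph.tif --seed 3
ossict phantom erode --in ph.tif --out ph_eroded.tif --target 0.11
ossict acquire --in ph.tif --out acq --config config.yaml
ossict recon --projections acq --delta-beta 300 --output rec.tif
ossict segment --in rec.tif --out seg.tif
ossict morpho --in seg.tif --out morpho.csv
ossict study run --config config.yaml --seed 1 --out study_dir
```

(`ossict` is `inst/cli/ossict`; equivalently
`Rscript -e 'ossict::ossict_cli()' --args ...` or call `ossict_cli()`
directly.) Configs are YAML with the acquisition defaults baked in
(2 µm, 15 cm, 25 keV, δ/β = 300); see `inst/extdata/example_config.yaml`.
Every run writes a provenance YAML (command, seed, effective config,
package version).

## Package layout

- `R/phantom.R` — ossicle phantoms, programmable erosion, cohorts
- `R/forward_model.R` — geometry, projector, propagation, noise, extended FOV
- `R/recon.R` — flat/dark correction, stitching, phase retrieval, FBP
- `R/segmentation.R` — median filter, Otsu, labeling, VOI matching
- `R/morphometry.R` — BV, BS (marching tetrahedra), TV (hole filling)
- `R/stats.R` — Welch test, cohort study runner
- `R/io_tiff.R`, `R/config.R`, `R/cli.R` — TIFF/YAML/CSV I/O and the CLI
- `src/kernels.cpp` — compiled kernels (projector, backprojector, median,
  components, hole fill, surface triangulation, erosion)

The methods vignette (`vignettes/ossicle-morphometry.Rmd`) documents the
models, parameter choices, numerical decisions and limitations.
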