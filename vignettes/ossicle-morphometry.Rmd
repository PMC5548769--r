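---
title: "Quantifying bone erosion at meniscal ossicles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bone erosion at meniscal ossicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ossict)
```

## The problem

In rodent models of rheumatoid arthritis, early bone erosion is a key
readout for disease staging and drug evaluation. Quantitative micro-CT
morphometry of a well-defined anatomical volume of interest (VOI) makes
that readout objective, but the choice of VOI is the weakest link: freehand
regions are operator-dependent and hard to reproduce across animals. The
meniscal ossicles — small sesamoid bones inside the knee meniscus, pyramid
shaped anteriorly and crescent ("lunula") shaped posteriorly in the rat —
are topologically equivalent across animals and can serve as a
self-delimiting VOI. The biomarker hypothesis is that arthritic erosion
measurably shifts the standard bone-morphometric parameter triplet of the
anterior ossicles: bone volume fraction BV/TV down, specific bone surface
BS/BV and bone surface density BS/TV up.

This package implements the complete measurement chain as a tested,
synthetic-data-first pipeline: phantoms with known truth, a
propagation-based phase-contrast acquisition model, preprocessing and
filtered-back-projection (FBP) reconstruction, segmentation, morphometry,
and the Welch group comparison. Every stage is verifiable against analytic
or independently coded oracles, so a green test suite certifies the
*software*, not the biology.

## The measurement model

**Morphometry.** For a labeled ossicle: BV is the labeled voxel count times
the voxel volume; TV is the same after filling enclosed cavities
(background components not 26-connected to the image border); BS is the
area of a triangulated iso-surface. The reported triplet is BV/TV
(dimensionless), BS/BV and BS/TV (mm^-1), satisfying
(BV/TV)(BS/BV) = BS/TV identically.

Two numerical choices matter here:

* *Surface estimation.* We triangulate by marching tetrahedra (six
  tetrahedra per cell; table-free and correct by construction) at the 0.5
  level, after a single 3^3 box-mean anti-aliasing of the binary mask. On a
  raw binary mask any marching scheme inherits the voxel staircase and
  overestimates the area of a digitized ball by 9% or more; with the box
  prefilter the r = 25-voxel sphere comes out within 0.7% of 4 pi r^2.
  The triangulated mesh itself is not smoothed.
* *Hole filling for TV.* Foreground is 6-connected, background
  26-connected (the standard topological pairing). Surface concavities
  open to the exterior are not holes; only enclosed cavities count.

**Acquisition.** Parallel-beam synchrotron geometry at an effective energy
of 25 keV (monochromatic approximation of a Si-filtered white beam), 2 um
detector pixels, 15 cm propagation distance, 360-degree rotation, with
flat/dark fields and Poisson counting noise. The projector is pixel-driven
(each voxel splats onto the detector with linear weights), which conserves
sinogram mass exactly per angle — a property the tests assert at 1e-6 and
which a gather-interpolation projector would not have.

**Phase contrast and retrieval.** Single-distance phase retrieval for a
homogeneous object multiplies each projection spectrum by
H(u,v) = 1 / (1 + lambda D (delta/beta) / (4 pi) (u^2 + v^2)), with
delta/beta = 300. Propagation is modeled as the exact reciprocal 1/H so
that retrieval inverts it to machine precision — a deliberate choice that
makes correctness testable, at the price of physical fidelity at high
spatial frequencies (a true Fresnel propagator has bounded contrast
transfer). Both operations pad by whole-sample symmetric extension
(doubling each dimension); because H is real and even, filtering preserves
that symmetry and crop-then-re-extend is lossless, which is what makes the
inverse pair exact rather than approximate.

Two consequences of this model shaped the implementation:

* *Band-limited forward model.* A voxelized object carries spectral
  content to the grid Nyquist, and 1/H amplifies it by up to ~440x at
  these parameters, producing physically impossible negative intensities
  that destroy the chain after flat-field clipping. `project()` therefore
  band-limits the line integrals with a Gaussian anti-alias kernel
  (sigma = 1 px, FFT-based, mass-conserving). `aa_sigma_px = 0` restores
  exact voxel line integrals for the hand-computed oracles.
* *Resolution-aware phantoms.* The retrieval filter at delta/beta = 300,
  15 cm, 2 um smooths over ~13 um. Phantom features meant to survive the
  chain (marrow-space pores, erosion pits, cavity walls) are sized above
  that scale; see below.

**Reconstruction.** Standard slice-wise FBP: Ram-Lak ramp with linear
interpolation backprojection, rotation center exact by construction. The
ramp is realized as the FFT of the band-limited spatial-domain kernel
(h0 = 1/(4 ds^2), odd taps -1/(pi n ds)^2); the textbook |omega| sampling
has a DC bias that reconstructs a disk 4% low, while this form is accurate
to 0.05%. Output is scaled so attenuation reconstructs in mm^-1.

**Extended field of view.** The 360-degree offset-detector mode is modeled
by `split_extended_fov()` (keep one lateral half plus an overlap band) and
`stitch_360()` (mirror the theta + 180 partner, align on the rotation axis,
blend the 2 x offset overlap with linear weights). The split/stitch round
trip reproduces a directly simulated full-width sinogram to machine
precision for objects within the half field.

**Segmentation.** Median filter (radius 1 by default; the kernel size is a
declared choice, as is the 256-bin histogram), global Otsu threshold, and
6-connected labeling in decreasing size order. Otsu accumulates per-bin
value sums, so the maximizer matches an exhaustive value-based search over
bin edges exactly — that equivalence is asserted on randomized volumes.
Manual VOI drawing is replaced by `select_voi()`, which matches each
segmented label to the ground-truth ossicle of maximal overlap; this
removes the operator dependence that motivates the ossicle biomarker in
the first place.

**Statistics.** Welch's unpaired two-sample t-test, implemented from the
defining formulas (Welch-Satterthwaite degrees of freedom, two-sided p,
n-1 variances) and cross-checked against `stats::t.test` to 1e-10. The
percent change is reported as (arthritis - control)/control x 100. No
multiple-testing correction is applied across the three parameters and
two ossicle classes — the study design this mirrors reports raw p-values —
and the report says so in its footer.

## The synthetic world

`make_ossicle()` builds pyramid, lunula, or sphere phantoms at 2 um voxels
with ground truth computed *by the package's own morphometry operators*
(so truth and measurement share definitions), plus closed-form values for
solid spheres.

**Porosity.** Phantoms carry enclosed spherical pores (default 12% of TV
for pyramid/lunula; 0 for spheres so analytic checks stay exact). This is
not cosmetic: with TV defined by hole filling, eroding the outer surface
of a *solid* body removes the same voxels from BV and TV, so BV/TV stays
pinned at 1 and no surface erosion could ever produce the programmed
bone-volume-fraction drop. A removed surface voxel is always face-adjacent
to existing background, so erosion can also never create a new enclosed
cavity. Internal porosity — anatomically, marrow spaces — is therefore the
mechanism through which erosion moves BV/TV, which is also a statement
about what the biomarker measures: loss of bone relative to the enclosed
envelope. Pore radii are drawn between 0.18 and 0.28 of the object's
effective radius (>= 15 um here) behind >= 12 um walls, both above the
chain's ~13 um resolution.

**Erosion.** `erode_phantom()` removes exposed bone voxels (outer surface
and cavity linings) stochastically until BV/TV has dropped by the
programmed fraction (0.11 by default) within +-0.01. Removals happen as
hemispherical "bites" of 10 um radius around nucleation sites — the focal
pit morphology of marginal erosion — because single-voxel removal produces
sub-resolution roughness whose effect the imaging chain cannot recover.
Each removal passes a simple-point test (the (6,26) topological-number
criterion), so every ossicle remains one 6-connected body, and a
wall-protection rule (no removal whose 4-voxel neighborhood sees both
exterior and cavity background) keeps cavity walls >= 8 um so they neither
breach in truth nor blur open in reconstruction. Batch sizes are throttled
by the observed BV/TV sensitivity and capped at 0.5% of BV per iteration
to stay inside the tolerance band; BV and TV are tracked incrementally
(only exterior removals shrink TV), which the tests verify against fully
recomputed truth.

**Cohorts.** `make_cohort()` emulates the n = 3 per group design: control
phantoms with isotropic size jitter (default CV 5%, clamped at 2.5 sigma),
and an arthritis group built from the *same generation seeds* (same
animals) passed through erosion. With zero jitter and zero effect the
groups are bit-identical, the degenerate case the tests pin down.

**Attenuation.** mu_bone = 0.25 mm^-1 and mu_soft tissue = 0.05 mm^-1
(standard mass-attenuation values at 25 keV); the soft-tissue background
fills a centered cylinder, like the agarose tube the real samples sit in,
so its line integrals are rotation-invariant.

## What a green suite does and does not establish

The generator emulates: two-material contrast, propagation fringes, photon
noise, the offset-detector acquisition, partial-volume and blur effects on
morphometry, and a programmed group effect with realistic between-animal
scatter. It does **not** emulate trabecular microarchitecture, cartilage,
beam polychromaticity, detector PSF, ring artifacts, or rotation-center
error — so passing tests certify the measurement chain's correctness and
its ability to recover a programmed effect of the stated size at the
stated noise level, not the biology of any particular study, whose animal
data are not publicly deposited and whose printed effect sizes are
consequently not desk-reproducible.

Numerical acceptance anchors (all recomputed by `scripts/acceptance.R` and
the test suite):

* sphere (r = 25 voxels): BV within 2%, BS within 5%, BS/BV within 10% of
  closed forms; solid cube BV exact and BV/TV = 1; hollow shell
  (r1 = r2/2) BV/TV within 3% of 0.875;
* Otsu = exhaustive search; components = flood fill; Welch = textbook
  formulas at 1e-10; BS within 15% of face counts after the 3/2
  orientation correction;
* FBP disk interior within 2% of mu, error strictly decreasing over
  45/90/180/360 angles (180-degree span: over 360 degrees, 45 and 90
  equispaced angles alias to the same direction set and tie exactly);
* propagation/retrieval inverse pair at 1e-8; delta/beta = 0 reduces to
  -log; split/stitch round trip < 1% RMSE;
* end-to-end: programmed -11% BV/TV recovered within +-3 percentage
  points with p < 0.05 at 1e5 counts; surface ratios move up; the
  uneroded posterior class stays non-significant; null cohorts exceed
  p = 0.05 in >= 90% of 20 seeded runs.

## Known limitations

* The propagation model is the exact inverse of the retrieval filter, not
  Fresnel optics; edge-enhancement amplitudes at high frequency are
  unphysical, which is why the forward model is band-limited.
* Erosion reachability depends on porosity: a solid phantom cannot drop
  its BV/TV, and `erode_phantom()` reports the achieved drop when a target
  is unreachable rather than looping forever.
* The truth/measurement agreement for BS is definitional (same operator),
  not an independent calibration; the independent checks are the analytic
  sphere and the corrected face-count oracle.
* TIFF I/O implements the baseline uncompressed little-endian subset only
  — sufficient for the pipeline's own interchange, not a general reader.
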