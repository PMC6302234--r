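---
title: "Pixel-based quantification of multiplexed tissue images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-based quantification of multiplexed tissue images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sequential multiplex staining of one FFPE tissue section produces two
renditions of the same scene: a multiplex immunofluorescence (mIF) stack of
grayscale marker channels (here the myeloid/macrophage markers CD68, CD163,
CD206, CD11b, CD11c plus a DAPI counterstain, 16-bit, 0.3 µm/px) and, after
chromogenic restaining, a multiplex immunohistochemistry (mIHC) set
(hematoxylin, CD3, high- and low-molecular-weight cytokeratin, 8-bit,
0.5 µm/px). Macrophages are a poor fit for cell-centric image cytometry:
they are stellate, and their stained processes can lie many nuclear radii
away from the nucleus, so assigning marker signal to the nearest nucleus
miscounts them. `pixelplex` therefore quantifies *pixels*: binary marker
masks, their exclusive co-expression classes, and spatial statistics of
class pixels relative to tumor and T-cell compartments, with nucleus-based
phenotyping retained as a comparator and for compact cells.

## Marker masks and pixel classes

Each channel is binarized by a per-channel threshold (a fixed intensity, or
Otsu's method on a 256-level histogram); the comparison is strict
(`intensity > threshold`), so an image everywhere equal to the threshold is
empty. Thresholds in the original assay were adjusted visually per cohort;
both options are config-exposed. Otsu assumes a bimodal histogram — on a
channel with no stained structures it splits noise, so known-empty channels
should use a fixed threshold (the validation studies use the midpoint of
the simulator's two intensity levels).

Connected groups of fewer than 9 positive pixels are removed
(8-connectivity by default; 4-connectivity available). The filter is applied
once per antibody mask, after thresholding and before any mask algebra, so
all downstream counts are consistent; derived class masks are not
re-filtered.

The MC&M (myeloid cells and macrophages) reference mask is the union of the
CD68, CD163, CD11b and CD11c masks. CD206 is deliberately excluded from the
reference: it also stains vessel structures, so only CD206-positive pixels
*underneath* the MC&M mask are counted (`restrict_cd206()`). With CD206 in
the reference the vessel-exclusion rule would be circular.

`decompose_pixel_classes()` assigns every reference pixel its exact marker
set and reports exclusive single, double and triple classes, a residual
class for four or more colors, and the non-exclusive multicolor aggregate
(every pixel with at least two colors). The exclusive classes partition the
reference exactly — an integer identity the test suite checks against an
independent per-pixel pattern enumeration. `mask_class_breakdown()` applies
the same decomposition underneath one anchor marker's own mask (the
CD68-mask and CD163-mask views). Case summaries are unweighted means of
per-tile percentages with the sample (n−1) standard deviation; tiles whose
reference mask is empty have undefined percentages and are excluded, with
the per-class tile count decremented — percentages are never silently
coerced to zero.

## Nuclear phenotyping

Nuclei are segmented from DAPI or hematoxylin by Gaussian smoothing
(`smooth_sigma_px`, default 2), a global threshold (Otsu by default), hole
filling, a distance-transform watershed to split touching nuclei
(`watershed_tolerance`, default 1), and a minimum-area filter (default
20 px). The defaults favor noisy realistic images; clean synthetic disks
segment with exact areas at `smooth_sigma_px = 1`, and splitting two
same-size overlapping disks needs `watershed_tolerance = 0.5` because their
distance-map maxima are equal.

Each nucleus is expanded into a perinuclear doughnut of width
`round(1/3 × mean nuclear radius)` pixels (round half up), computed as a
Euclidean dilation (pixels within that distance of the nucleus), minus all
nucleus pixels, clipped at the tile border. A configured expansion that
rounds to zero raises an explicit degenerate-doughnut error rather than
silently producing empty rings. Doughnuts of neighboring cells may overlap —
classification is per cell and independent, so no ownership resolution is
attempted. A cell is positive for a marker when the fraction of
marker-positive doughnut pixels strictly exceeds `density_threshold`
(default 0.1, config-exposed; the original assay states only that a
predefined threshold was used). The call is monotone: growing a marker mask
can never turn a positive cell negative.

`correlate_counts()` reports the Pearson product-moment correlation between
per-tile positive-cell counts and positive-pixel counts. (The figure
legend of the source assay labels these values R², while its text quotes
them as r; this package reports r.)

## Co-registration and mask transfer

The chromogenic and fluorescent renditions of a tile are related by a 2-D
affine transform estimated from the nuclear counterstains (hematoxylin ↔
DAPI), the only structure imaged in both. Transforms act on physical (µm)
coordinates, mapping chromogenic-frame points to fluorescent-frame points;
the 0.5 → 0.3 µm pixel-size change is folded into the transform so each
mask is resampled exactly once. The coordinate convention, used everywhere:
0-based row/col indices, pixel centers at integer coordinates, row = y
increasing downward.

Estimation is deterministic: both images are smoothed, a fixed rotation
grid (±10° in 2.5° steps) is scanned with phase-correlation translation
initialization at each rotation, the best candidate by normalized
cross-correlation (NCC) seeds a Nelder-Mead refinement of all six affine
parameters, and the refinement is restarted once from its optimum (a fresh
simplex escapes the degenerate simplices Nelder-Mead can collapse into).
The objective is evaluated on a stride-2 subsample of the fluorescent grid.
If the final NCC falls below a configurable floor the registration *fails
loudly* — there is no silent fallback. Registration quality against a known
truth transform is summarized as the mean displacement of the four source
corners in µm.

Masks are transferred with nearest-neighbor sampling (binary preserved),
intensities with bilinear interpolation. Target pixels whose pull-back
falls outside the source field are negative and recorded in a coverage
mask; that co-registered area serves as the tissue region for density
analyses, so densities are never computed over unobserved tissue.
Registration can be estimated per tile or once per case and reused (the
original workflow established parameters once per case; both modes are
config-exposed).

## Spatial statistics

Densities are counting fractions: `|class ∩ region| / |region|`, for the
tumor mask, the stroma (tissue minus tumor — the subtraction definition),
and the CD3 T-cell mask. An empty region yields a missing value, not zero,
and a tumor:stroma ratio with an empty or class-free stroma is missing.
The identity `|class ∩ tumor| + |class ∩ stroma| = |class ∩ tissue|` holds
exactly by construction and is asserted in the tests.

Tumor-border nuclei are those whose centroid lies inside the tumor mask
within `band_width_um` (default 10 µm, config-exposed; the source assay
does not state its isometric-line offset) of the tumor edge, measured by
the inward Euclidean distance transform. The distance map is computed
within the tile only, so a tumor region cropped by the tile edge does not
acquire an artificial border there. From each border nucleus the distance
to the nearest class-positive pixel is read off the Euclidean distance
transform of the class mask's complement, sampled at the nucleus centroid
(the centroid, rather than the nuclear outline, is the reference point:
stable under segmentation noise). An empty class mask yields a missing
distance — never zero or infinity. Distances use the nucleus centroid
rounded to the nearest pixel center, which matches the exhaustive
brute-force oracle the tests compare against to 10⁻⁶ µm.

Distance histograms use a contact bin (exactly 0 µm) followed by half-open
upper-inclusive 20 µm bins (0, 20], (20, 40], …; a distance of exactly
20 µm falls in (0, 20]. Percentages are over measured distances and sum to
100 whenever anything was measured.

## The synthetic-tissue simulator

No image data accompany the original assay (archived clinical FFPE cases),
so validation rests on a seeded simulator that generates both renditions of
a tile with complete ground truth: the cell table, noise-free per-marker
masks, the tumor mask, and the acquisition transform. The same
configuration and seed give bit-identical tiles, and the caller's RNG state
is untouched.

* **Geometry.** Fluorescent grid at 0.3 µm/px (16-bit), chromogenic grid at
  0.5 µm/px (8-bit), matching the instruments the assay was built on. The
  chromogenic rendition is produced by inverse-mapping through a configured
  rigid/affine transform with bilinear interpolation, so hematoxylin
  depicts the same nuclei as DAPI, CD3 only T cells, and the cytokeratins
  only the tumor mask.
* **Cells.** Four types: compact CD3⁺ T cells; stellate macrophages;
  compact myeloid cells; and bare tumor nuclei inside the tumor epithelium.
  The tumor type extends the MC&M cell vocabulary because the border-nuclei
  distance procedure measures from tumor-cell nuclei, which requires nuclei
  inside the tumor mask. Marker positivity is drawn independently per
  marker from per-type co-expression probabilities.
* **Morphology.** Nuclei are disks with Gaussian-distributed radii. Marker
  signal for compact cells is a full perinuclear ring (default width
  1.2 µm). Stellate cells carry 3–6 processes (two-segment polylines,
  default lengths 10–40 µm, widths 1–2 px) and only a *patchy* perinuclear
  ring: arcs at the process roots covering a `ring_coverage` fraction of
  the circumference (default 0.1). That default places typical doughnut
  densities at the classifier's decision boundary, which is precisely the
  regime the assay documents for macrophages — nuclear counting breaks
  down when the stained signal sits on processes far from the nucleus. The
  assay gives no quantitative process morphology, so all of these are
  config-exposed placeholders, not calibrated values.
* **Placement.** Rejection sampling with a hard minimum centroid separation
  of 1.5 × the sum of nuclear radii (keeps nuclei disjoint, so nuclear
  segmentation remains testable; the count of connected DAPI components
  equals the cell count). Placement is per-type: uniform within a region
  (stroma, tumor, or anywhere), or biased toward the tumor border with
  acceptance probability exp(−d/L) for stroma-side distance d and decay
  length L. An infeasible packing raises an explicit placement error after
  a bounded number of attempts.
* **Noise.** Two-level (background/signal) images plus additive Gaussian
  noise, clipped and rounded to the dtype range — the simplest model that
  exercises thresholding. No PSF, no autofluorescence or bleed-through
  (the assay's filter cubes keep channels independent), no whole-slide
  mosaics.
* **Tumor regions.** Each region is a union of one main and four satellite
  disks; the configured area fraction is met approximately, not exactly.

What the simulator does *not* emulate — focal texture within stains,
uneven illumination, section artifacts, optically merged nuclei, spectral
bleed-through — bounds what a passing test shows about real data: the
pipeline's algebra, geometry and statistics are correct, and its behavior
under the modeled morphology contrast is as designed; threshold choice on
real stains remains an operator decision.

## Validation studies and their problem sizes

The package ships five seeded studies (`*_study()` functions) used by both
the test suite and `scripts/acceptance.R`:

* **Registration recovery** — 512² px tile pairs with ≥ 100 nuclei,
  rotations up to 10°, translations up to 20 fluorescent pixels; success is
  a mean corner displacement within one fluorescent pixel (0.3 µm).
* **Class-proportion recovery** — 80 compact CD68⁺ cells per 512² tile with
  CD163 co-expressed at probability 0.3, pooled over seeds; because each
  cell's markers share one footprint and footprints are disjoint, the
  expected double-class share equals the co-expression probability.
* **Morphology correlation** — 28 tiles of 384² px per condition with 13–17
  macrophages each (tiles from one specimen vary modestly in content);
  compact vs stellate morphology on matched layouts, process length
  15–20 µm ≈ 5 nuclear radii.
* **Spatial ordering** — two compact populations placed with border-decay
  lengths 10 µm vs 60 µm; mean border-nucleus distances must order
  accordingly. Compact morphology is used for both populations to isolate
  the placement effect from the morphology effect.
* **Uniform-placement ratio** — one population placed uniformly over the
  tile; pooled over seeds the tumor:stroma ratio has expectation 1. The
  placement margin that keeps nuclei whole slightly depletes the tile
  border, which sits in the stroma, so the pooled ratio runs marginally
  above 1; the effect is well inside the study's tolerance.

Problem sizes (tile sides, cell counts, numbers of seeds/pairs/runs) were
chosen so each study carries enough statistical resolution for its check
while the whole suite stays desk-scale.

## Known limitations

* Threshold selection is per-channel and global; no isotype-control-driven
  calibration and no spectral unmixing (the package consumes unmixed
  channels).
* The registration model is affine; no deformable registration, no
  whole-slide global alignment (per-tile or per-case only).
* Pixel classes treat marker positivity as binary; intensity gradations
  within a mask are not used.
* The quantitative results of the original assay's clinical cohort cannot
  be reproduced here — its tissue is not deposited — so validation is
  property-based on synthetic data by design.
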