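# pixelplex

Pixel-based quantification of sequentially multiplexed tissue images:
immunofluorescent (mIF) marker channels and the chromogenic (mIHC)
rendition of the same section, co-registered and analyzed as binary
pixel masks.

## Who this is for

Tissue-imaging groups quantifying myeloid cells and macrophages (MC&M:
CD68, CD163, CD206, CD11b, CD11c) in the tumor microenvironment.
Macrophages defeat cell-centric cytometry — their stained processes can lie
many nuclear radii from the nucleus — so this package counts *pixels*
instead of cells, while keeping nucleus-based phenotyping available as a
comparator.

## What it computes

For each tile of per-channel grayscale TIFFs (16-bit mIF at 0.3 µm/px,
8-bit unmixed mIHC at 0.5 µm/px):

1. **Marker masks** — per-channel thresholding (fixed or Otsu, strictly
   `intensity > t`), then removal of connected groups of fewer than 9
   pixels (8-connectivity by default).
2. **Pixel co-expression classes** — the MC&M mask is the union of the
   CD68/CD163/CD11b/CD11c masks (CD206 also stains vessels and is counted
   only underneath the MC&M mask). Each reference pixel is assigned its
   exact marker set, giving exclusive single/double/triple classes, a
   residual P4,5 class (≥ 4 colors), and the multicolor aggregate
   P2,3,4,5; classes partition the reference exactly:
   `percent = 100 · |class| / |reference|`.
3. **Nuclear phenotyping** — DAPI/hematoxylin segmentation
   (smooth → threshold → fill → watershed), a perinuclear doughnut of
   width ⅓ of the tile's mean nuclear radius, and a positivity call when
   the marker density in the doughnut exceeds a threshold; plus the
   Pearson r between per-tile positive-cell and positive-pixel counts.
4. **Co-registration** — a 2-D affine transform (µm coordinates,
   chromogenic → fluorescent) estimated from hematoxylin/DAPI by
   phase-correlation initialization and Nelder-Mead refinement of the
   normalized cross-correlation; tumor (cytokeratin) and T-cell (CD3)
   masks are transferred across pixel grids by nearest-neighbor sampling.
5. **Spatial statistics** — class densities inside/outside the tumor and
   under the T-cell mask, tumor:stroma ratios, tumor-border nuclei within
   an isometric band of the tumor edge, Euclidean-distance-transform
   distances from border nuclei to the nearest class pixel, and 20-µm
   distance histograms with a contact bin.

A seeded synthetic-tissue simulator (`generate_tile()`) produces both
renditions of a tile with full ground truth — cells, noise-free masks,
tumor regions, the acquisition transform — and backs the validation
studies; no real patient data ship with the package.

## Worked example

```r
library(pixelplex)

cfg  <- simulation_config(seed = 42)        # 512x512 IF px, 75 cells
tile <- generate_tile(cfg)

spec  <- threshold_spec(setNames(as.list(rep(10250, 5)), MCM_MARKERS))
masks <- lapply(MCM_MARKERS, function(mk)
  remove_small_groups(threshold_channel(tile$if_channels[[mk]], spec), spec))
names(masks) <- MCM_MARKERS
mcm          <- build_mcm_mask(masks)
masks$CD206  <- restrict_cd206(masks$CD206, mcm)

tab <- decompose_pixel_classes(masks, mcm)
subset(as.data.frame(tab), pixel_count > 0,
       c(class_label, n_colors, pixel_count, percent_of_reference))
#>         class_label n_colors pixel_count percent_of_reference
#> 1              CD68        1        2981               15.986
#> 2             CD163        1         979                5.250
#> 6        CD68/CD163        2        1899               10.183
#> 7        CD68/CD206        2        3247               17.412
#> 16 CD68/CD163/CD206        3         723                3.877
#> ...
attr(tab, "reference_pixel_count")
#> [1] 18648
```

16.0% of the MC&M-mask is CD68 single-positive, 10.2% CD68/CD163
double-positive, and so on; the exclusive rows sum to 100% of the 18,648
reference pixels. Continuing with phenotyping and co-registration:

```r
nset <- classify_cells(build_doughnuts(segment_nuclei(tile$if_channels$DAPI)),
                       masks$CD68)
c(nuclei = nrow(nset$table), cd68_cells = sum(nset$table$positive_CD68))
#> nuclei cd68_cells
#>     75         29

reg <- estimate_affine(tile$ihc_channels$hematoxylin, tile$if_channels$DAPI)
reg$quality$ncc
#> [1] 0.999
corner_displacement_um(reg$transform, tile$truth_transform,
                       dim(tile$ihc_channels$hematoxylin$pixels), 0.5)
#> [1] 0.002    # mean corner error, um (1 IF pixel = 0.3 um)
```

All 75 nuclei are recovered, 29 cells are called CD68⁺, and the estimated
chromogenic→fluorescent transform matches the simulator's ground truth to
0.002 µm at the tile corners.

## Command line

A thin CLI wraps the same functions
(`inst/cli/pixelplex.R`; after installation:
`system.file("cli", "pixelplex.R", package = "pixelplex")`):

```sh
Rscript pixelplex.R simulate   --out tiles --seed 5 --tiles 2
Rscript pixelplex.R run        --tiles tiles --out results --config pipe.yaml
Rscript pixelplex.R report     --out results
Rscript pixelplex.R coregister --fixed dapi.tif --moving hematoxylin.tif --out t.json
```

`run` writes per-tile masks (8-bit TIFF), class/cell/density/distance
tables (CSV), transforms (JSON) and a run manifest with output checksums;
`report` adds case-level pie-fraction tables, density summaries, distance
histograms and figures.

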