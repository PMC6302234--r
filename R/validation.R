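# Seeded validation studies: self-contained simulation experiments that
# exercise the full analysis chain against the simulator's ground truth.
# Both the test suite and scripts/acceptance.R run these.

#' Morphology-dependent correlation study
#'
#' Generates matched tile layouts (identical placement seeds and per-tile
#' cell counts) under two morphologies — compact cells whose marker signal
#' is a full perinuclear ring, and stellate cells whose signal sits on
#' 3-6 randomized processes about five nuclear radii long with only a patchy
#' perinuclear ring — then runs thresholding, nuclear segmentation and
#' doughnut classification on each tile and correlates per-tile positive-cell
#' counts with positive-pixel counts. Compact cells keep the two measures
#' tightly coupled; stellate cells decouple them because the doughnut misses
#' process-borne signal and picks up bystander nuclei.
#'
#' @param n_tiles number of tiles per condition (default 28).
#' @param seed base RNG seed.
#' @param count_range per-tile macrophage count range (default 13-17,
#'   emulating tiles drawn from one specimen with comparable content).
#' @param tile_px tile side in IF pixels.
#' @return List with `r_compact`, `r_stellate`, and the per-condition count
#'   series.
#' @export
morphology_correlation_study <- function(n_tiles = 28, seed = 500,
                                         count_range = c(13, 17),
                                         tile_px = 384) {
  counts <- with_seed(seed + 9999L,
                      sample(count_range[1]:count_range[2], n_tiles, replace = TRUE))
  run_condition <- function(stellate) {
    cell_counts <- integer(n_tiles)
    pixel_counts <- integer(n_tiles)
    for (i in seq_len(n_tiles)) {
      mac_morph <- list(nuclear_radius_um = c(mean = 3.5, sd = 0.4))
      if (stellate) {
        mac_morph <- c(mac_morph, list(
          process_count_range = c(3, 6),
          process_length_um_range = c(15, 20), # ~5x the 3.5 um nuclear radius
          process_width_px_range = c(1, 2),
          ring_coverage = 0.1
        ))
      }
      cfg <- simulation_config(
        tile_height_px = tile_px, tile_width_px = tile_px,
        n_tumor_regions = 0, tumor_area_fraction = 0,
        n_tcells = 8, n_macrophages = counts[i], n_myeloid = 0,
        n_tumor_nuclei = 0,
        coexpression = list(
          macrophage = c(CD68 = 1, CD163 = 0, CD206 = 0, CD11b = 0, CD11c = 0),
          myeloid = c(CD68 = 0, CD163 = 0, CD206 = 0, CD11b = 0, CD11c = 0)
        ),
        morphology = list(
          tcell = list(nuclear_radius_um = c(mean = 2.5, sd = 0.25)),
          macrophage = mac_morph,
          myeloid = list(nuclear_radius_um = c(mean = 3, sd = 0.3)),
          tumor = list(nuclear_radius_um = c(mean = 2.5, sd = 0.25))
        ),
        seed = seed + i
      )
      tile <- generate_tile(cfg)
      spec <- threshold_spec(list(CD68 = "otsu"))
      m <- remove_small_groups(threshold_channel(tile$if_channels$CD68, spec), spec)
      nset <- segment_nuclei(tile$if_channels$DAPI)
      nset <- build_doughnuts(nset)
      nset <- classify_cells(nset, m)
      cell_counts[i] <- sum(nset$table$positive_CD68)
      pixel_counts[i] <- positive_count(m)
    }
    list(cells = cell_counts, pixels = pixel_counts,
         r = correlate_counts(cell_counts, pixel_counts, "CD68")$pearson_r)
  }
  compact <- run_condition(FALSE)
  stellate <- run_condition(TRUE)
  list(
    r_compact = compact$r, r_stellate = stellate$r,
    compact = compact, stellate = stellate, n_tiles = n_tiles
  )
}

#' Co-expression class proportion recovery study
#'
#' Simulates compact myeloid cells that are all CD68+ with an independent
#' CD163 co-expression probability, runs the full mask pipeline (threshold,
#' small-group filter, MC&M mask, class decomposition) on each seeded tile,
#' and pools class pixel counts across seeds. Because each cell's markers
#' share one footprint and footprints of distinct cells are disjoint under
#' the non-overlap placement, the expected CD68/CD163 double-class share of
#' the MC&M mask equals the co-expression probability.
#'
#' @param n_seeds number of seeded tiles (default 10).
#' @param seed base RNG seed.
#' @param p_cd163 CD163 co-expression probability (default 0.3).
#' @param n_cells cells per tile (default 80).
#' @param tile_px tile side in IF pixels (default 512).
#' @return List with pooled `estimated_double_percent`,
#'   `estimated_single_percent`, the generative expectations, and per-seed
#'   values.
#' @export
class_proportion_study <- function(n_seeds = 10, seed = 700, p_cd163 = 0.3,
                                   n_cells = 80, tile_px = 512) {
  double_px <- 0; single_px <- 0; ref_px <- 0
  per_seed <- data.frame()
  for (i in seq_len(n_seeds)) {
    cfg <- simulation_config(
      tile_height_px = tile_px, tile_width_px = tile_px,
      n_tumor_regions = 0, tumor_area_fraction = 0,
      n_tcells = 0, n_macrophages = 0, n_myeloid = n_cells, n_tumor_nuclei = 0,
      coexpression = list(
        macrophage = c(CD68 = 1, CD163 = 0, CD206 = 0, CD11b = 0, CD11c = 0),
        myeloid = c(CD68 = 1, CD163 = p_cd163, CD206 = 0, CD11b = 0, CD11c = 0)
      ),
      seed = seed + i
    )
    tile <- generate_tile(cfg)
    # fixed midpoint threshold of the two-level noise model: robust on
    # channels with no positive cells, where Otsu would split pure noise
    thr <- (cfg$noise$if_background + cfg$noise$if_signal) / 2
    spec <- threshold_spec(setNames(as.list(rep(thr, 5)), MCM_MARKERS))
    masks <- lapply(MCM_MARKERS, function(mk) {
      remove_small_groups(threshold_channel(tile$if_channels[[mk]], spec), spec)
    })
    names(masks) <- MCM_MARKERS
    mcm <- build_mcm_mask(masks)
    masks$CD206 <- restrict_cd206(masks$CD206, mcm)
    tab <- decompose_pixel_classes(masks, mcm)
    dbl <- tab$pixel_count[tab$class_label == "CD68/CD163"]
    sgl <- tab$pixel_count[tab$class_label == "CD68"]
    ref <- attr(tab, "reference_pixel_count")
    double_px <- double_px + dbl; single_px <- single_px + sgl
    ref_px <- ref_px + ref
    per_seed <- rbind(per_seed, data.frame(
      seed = cfg$seed, double_percent = 100 * dbl / ref,
      single_percent = 100 * sgl / ref
    ))
  }
  list(
    estimated_double_percent = 100 * double_px / ref_px,
    estimated_single_percent = 100 * single_px / ref_px,
    expected_double_percent = 100 * p_cd163,
    expected_single_percent = 100 * (1 - p_cd163),
    per_seed = per_seed, n_cells_total = n_seeds * n_cells
  )
}

#' Affine registration recovery study
#'
#' Generates seeded tile pairs (0.3 um fluorescent / 0.5 um chromogenic
#' grids, at least 100 nuclei) under random rigid acquisition transforms
#' with rotations up to 10 degrees and translations up to 20 fluorescent
#' pixels, re-estimates the transform from the hematoxylin/DAPI pair, and
#' measures the mean corner displacement against the generating transform.
#'
#' @param n_pairs number of tile pairs (default 20).
#' @param seed base RNG seed.
#' @param tile_px tile side in IF pixels (default 512).
#' @return List with `errors_um` (per pair), `errors_if_px`, `ncc`, and the
#'   drawn transform parameters.
#' @export
registration_recovery_study <- function(n_pairs = 20, seed = 300,
                                        tile_px = 512) {
  params <- with_seed(seed + 4242L, data.frame(
    rotation_deg = runif(n_pairs, -10, 10),
    t_row_um = runif(n_pairs, -6, 6), # 20 IF px * 0.3 um
    t_col_um = runif(n_pairs, -6, 6)
  ))
  errors <- numeric(n_pairs)
  ncc <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    cfg <- simulation_config(
      tile_height_px = tile_px, tile_width_px = tile_px,
      n_tcells = 30, n_macrophages = 30, n_myeloid = 20, n_tumor_nuclei = 30,
      acquisition_transform = list(
        rotation_deg = params$rotation_deg[i],
        translation_um = c(params$t_row_um[i], params$t_col_um[i]),
        shear = 0, scale = 1
      ),
      seed = seed + i
    )
    tile <- generate_tile(cfg)
    reg <- estimate_affine(tile$ihc_channels$hematoxylin, tile$if_channels$DAPI)
    errors[i] <- corner_displacement_um(
      reg$transform, tile$truth_transform,
      dim(tile$ihc_channels$hematoxylin$pixels), cfg$ihc_pixel_size_um
    )
    ncc[i] <- reg$quality$ncc
  }
  list(
    errors_um = errors,
    errors_if_px = errors / 0.3,
    ncc = ncc,
    params = params,
    fraction_within_1px = mean(errors <= 0.3)
  )
}

#' Tumor-border spatial ordering study
#'
#' Places two compact marker populations in the stroma with different
#' border-decay lengths (CD68/CD163 cells hugging the tumor border,
#' CD11b/CD11c cells spread far from it), segments nuclei, selects
#' tumor-border nuclei, and measures the nearest-class distances per marker.
#' Returns per-run mean distances and the distance-histogram percent sums.
#'
#' @param n_runs number of seeded runs (default 20).
#' @param seed base RNG seed.
#' @param decay_near_um,decay_far_um placement decay lengths (defaults 10
#'   and 60 um).
#' @param tile_px tile side in IF pixels (default 512).
#' @return List with per-run `mean_near_um`, `mean_far_um`,
#'   `ordering_fraction` (runs with near < far) and `hist_percent_sums`.
#' @export
spatial_ordering_study <- function(n_runs = 20, seed = 900,
                                   decay_near_um = 10, decay_far_um = 60,
                                   tile_px = 512) {
  mean_near <- numeric(n_runs)
  mean_far <- numeric(n_runs)
  hist_sums <- numeric(0)
  for (i in seq_len(n_runs)) {
    cfg <- simulation_config(
      tile_height_px = tile_px, tile_width_px = tile_px,
      n_tumor_regions = 2, tumor_area_fraction = 0.25,
      n_tcells = 0, n_macrophages = 20, n_myeloid = 20, n_tumor_nuclei = 25,
      coexpression = list(
        macrophage = c(CD68 = 1, CD163 = 1, CD206 = 0, CD11b = 0, CD11c = 0),
        myeloid = c(CD68 = 0, CD163 = 0, CD206 = 0, CD11b = 1, CD11c = 1)
      ),
      morphology = list(
        tcell = list(nuclear_radius_um = c(mean = 2.5, sd = 0.25)),
        # compact morphology for both populations isolates the placement effect
        macrophage = list(nuclear_radius_um = c(mean = 3.5, sd = 0.4)),
        myeloid = list(nuclear_radius_um = c(mean = 3, sd = 0.3)),
        tumor = list(nuclear_radius_um = c(mean = 2.5, sd = 0.25))
      ),
      placement = list(
        tcell = list(model = "uniform", region = "stroma"),
        macrophage = list(model = "tumor_border", region = "stroma",
                          decay_um = decay_near_um),
        myeloid = list(model = "tumor_border", region = "stroma",
                       decay_um = decay_far_um),
        tumor = list(model = "uniform", region = "tumor")
      ),
      seed = seed + i
    )
    tile <- generate_tile(cfg)
    spec <- threshold_spec(setNames(as.list(rep("otsu", 5)), MCM_MARKERS))
    masks <- list()
    for (mk in c("CD68", "CD11b")) {
      masks[[mk]] <- remove_small_groups(
        threshold_channel(tile$if_channels[[mk]], spec), spec
      )
    }
    nset <- segment_nuclei(tile$if_channels$DAPI)
    border <- find_border_nuclei(nset, tile$truth_tumor_mask, border_band_spec(10))
    pts <- cbind(border$centroid_row, border$centroid_col)
    d_near <- nearest_class_distance(pts, masks$CD68)
    d_far <- nearest_class_distance(pts, masks$CD11b)
    mean_near[i] <- mean(d_near, na.rm = TRUE)
    mean_far[i] <- mean(d_far, na.rm = TRUE)
    for (d in list(d_near, d_far)) {
      h <- distance_histogram(d)
      if (h$n_measured > 0) hist_sums <- c(hist_sums, sum(h$bins$percent))
    }
  }
  list(
    mean_near_um = mean_near, mean_far_um = mean_far,
    ordering_fraction = mean(mean_near < mean_far),
    hist_percent_sums = hist_sums
  )
}

#' Uniform-placement tumor:stroma ratio study
#'
#' Places one compact marker population uniformly over the whole tile
#' (irrespective of the tumor mask) and pools class-in-tumor and
#' class-in-stroma pixel counts across seeds. Under uniform placement the
#' expected tumor and stroma densities are equal, so the pooled
#' tumor:stroma ratio has expectation 1.
#'
#' @param n_seeds number of seeded tiles (default 12).
#' @param seed base RNG seed.
#' @param n_cells cells per tile (default 150).
#' @param tile_px tile side in IF pixels (default 512).
#' @return List with the pooled `ratio`, pooled pixel counts, per-seed
#'   ratios, and the exact-bookkeeping check
#'   (`max |class&tumor| + |class&stroma| - |class&tissue|` over runs).
#' @export
uniform_ratio_study <- function(n_seeds = 12, seed = 1100, n_cells = 150,
                                tile_px = 512) {
  tumor_class <- 0; stroma_class <- 0
  tumor_area <- 0; stroma_area <- 0
  per_seed <- numeric(n_seeds)
  bookkeeping_error <- 0L
  total_class_px <- 0
  for (i in seq_len(n_seeds)) {
    cfg <- simulation_config(
      tile_height_px = tile_px, tile_width_px = tile_px,
      n_tumor_regions = 1, tumor_area_fraction = 0.3,
      n_tcells = 0, n_macrophages = 0, n_myeloid = n_cells, n_tumor_nuclei = 0,
      coexpression = list(
        macrophage = c(CD68 = 0, CD163 = 0, CD206 = 0, CD11b = 0, CD11c = 0),
        myeloid = c(CD68 = 1, CD163 = 0, CD206 = 0, CD11b = 0, CD11c = 0)
      ),
      morphology = list(
        tcell = list(nuclear_radius_um = c(mean = 2.5, sd = 0.25)),
        macrophage = list(nuclear_radius_um = c(mean = 3.5, sd = 0.4)),
        myeloid = list(nuclear_radius_um = c(mean = 1.5, sd = 0.15)),
        tumor = list(nuclear_radius_um = c(mean = 2.5, sd = 0.25))
      ),
      placement = list(
        tcell = list(model = "uniform", region = "any"),
        macrophage = list(model = "uniform", region = "any"),
        myeloid = list(model = "uniform", region = "any"),
        tumor = list(model = "uniform", region = "tumor")
      ),
      seed = seed + i
    )
    tile <- generate_tile(cfg)
    spec <- threshold_spec(list(CD68 = "otsu"))
    cls <- remove_small_groups(threshold_channel(tile$if_channels$CD68, spec), spec)
    tumor <- tile$truth_tumor_mask
    tissue <- marker_mask(matrix(TRUE, tile_px, tile_px),
                          cfg$if_pixel_size_um, "tissue", tile$tile_id)
    stroma_px <- tissue$pixels & !tumor$pixels
    ct <- sum(cls$pixels & tumor$pixels)
    cs <- sum(cls$pixels & stroma_px)
    call <- sum(cls$pixels & tissue$pixels)
    bookkeeping_error <- max(bookkeeping_error, abs(ct + cs - call))
    tumor_class <- tumor_class + ct; stroma_class <- stroma_class + cs
    tumor_area <- tumor_area + sum(tumor$pixels)
    stroma_area <- stroma_area + sum(stroma_px)
    total_class_px <- total_class_px + call
    rat <- tumor_stroma_ratio(cls, tumor, tissue)
    per_seed[i] <- rat$ratio
  }
  list(
    ratio = (tumor_class / tumor_area) / (stroma_class / stroma_area),
    per_seed_ratio = per_seed,
    total_class_px = total_class_px,
    bookkeeping_error = bookkeeping_error
  )
}
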