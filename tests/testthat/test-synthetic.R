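test_that("configuration invariants are enforced", {
  expect_error(simulation_config(tumor_area_fraction = 1.2), "tumor_area_fraction")
  expect_error(
    simulation_config(coexpression = list(
      macrophage = c(CD68 = 1.2, CD163 = 0, CD206 = 0, CD11b = 0, CD11c = 0),
      myeloid = c(CD68 = 0, CD163 = 0, CD206 = 0, CD11b = 0, CD11c = 0)
    )),
    "must lie in"
  )
  expect_error(
    simulation_config(coexpression = list(
      macrophage = c(CD68 = 1),
      myeloid = c(CD68 = 0, CD163 = 0, CD206 = 0, CD11b = 0, CD11c = 0)
    )),
    "must name all"
  )
})

test_that("the same configuration and seed give bit-identical tiles", {
  cfg <- small_sim_config(seed = 101)
  a <- generate_tile(cfg)
  b <- generate_tile(cfg)
  for (ch in names(a$if_channels)) {
    expect_identical(a$if_channels[[ch]]$pixels, b$if_channels[[ch]]$pixels)
  }
  for (ch in names(a$ihc_channels)) {
    expect_identical(a$ihc_channels[[ch]]$pixels, b$ihc_channels[[ch]]$pixels)
  }
  expect_identical(a$truth_cells, b$truth_cells)
  expect_identical(a$truth_transform$matrix, b$truth_transform$matrix)
  # a different seed gives different tiles
  cfg2 <- small_sim_config(seed = 102)
  expect_false(identical(generate_tile(cfg2)$if_channels$DAPI$pixels,
                         a$if_channels$DAPI$pixels))
})

test_that("cell-count bookkeeping and the co-expression draws are honest", {
  cfg <- simulation_config(
    tile_height_px = 512, tile_width_px = 512,
    n_tumor_regions = 0, tumor_area_fraction = 0,
    n_tcells = 0, n_macrophages = 50, n_myeloid = 0, n_tumor_nuclei = 0,
    coexpression = list(
      macrophage = c(CD68 = 1, CD163 = 0.3, CD206 = 0, CD11b = 0, CD11c = 0),
      myeloid = c(CD68 = 0, CD163 = 0, CD206 = 0, CD11b = 0, CD11c = 0)
    ),
    seed = 202
  )
  tile <- generate_tile(cfg)
  expect_equal(nrow(tile$truth_cells), 50)
  expect_true(all(tile$truth_cells$cell_type == "macrophage"))
  expect_true(all(tile$truth_cells$positive_CD68))
  # observed CD163 co-expression inside the two-sided 99% binomial interval
  n_cd163 <- sum(tile$truth_cells$positive_CD163)
  expect_gte(n_cd163, qbinom(0.005, 50, 0.3))
  expect_lte(n_cd163, qbinom(0.995, 50, 0.3))
})

test_that("noise-free channels equal the truth masks exactly", {
  cfg <- small_sim_config(
    seed = 103,
    noise = list(if_background = 500, if_signal = 20000, if_sd = 0,
                 ihc_background = 30, ihc_signal = 200, ihc_sd = 0)
  )
  tile <- generate_tile(cfg)
  expect_identical(tile$if_channels$DAPI$pixels > 500,
                   tile$truth_nuclear_mask$pixels)
  for (mk in MCM_MARKERS) {
    expect_identical(tile$if_channels[[mk]]$pixels > 500,
                     tile$truth_marker_masks[[mk]]$pixels)
  }
  # nuclei are disjoint: one connected DAPI component per cell
  lab <- EBImage::bwlabel(tile$truth_nuclear_mask$pixels)
  expect_equal(max(lab), nrow(tile$truth_cells))
})

test_that("macrophages carry processes and T cells do not", {
  cfg <- small_sim_config(seed = 104)
  tile <- generate_tile(cfg)
  types <- tile$truth_cells$cell_type
  expect_true(all(tile$truth_cells$n_processes[types == "macrophage"] >= 3))
  expect_true(all(tile$truth_cells$n_processes[types == "tcell"] == 0))
  expect_true(all(vapply(
    tile$truth_processes[types == "tcell"], length, integer(1)
  ) == 0))
  # T cells are CD3+ and MC&M-negative
  expect_true(all(tile$truth_cells$positive_CD3[types == "tcell"]))
  expect_false(any(tile$truth_cells$positive_CD68[types == "tcell"]))
})

test_that("an infeasible packing raises an explicit placement error", {
  cfg <- small_sim_config(seed = 105)
  cfg$tile_height_px <- 64L
  cfg$tile_width_px <- 64L
  cfg$n_macrophages <- 200L
  expect_error(generate_tile(cfg), "placement failure")
})

test_that("identity chromogenic rendering reproduces the nuclear field exactly", {
  cfg <- small_sim_config(
    seed = 106, ihc_pixel_size_um = 0.3,
    noise = list(if_background = 500, if_signal = 20000, if_sd = 0,
                 ihc_background = 30, ihc_signal = 200, ihc_sd = 0)
  )
  tile <- generate_tile(cfg)
  hema <- tile$ihc_channels$hematoxylin$pixels
  expect_equal(dim(hema), dim(tile$truth_nuclear_mask$pixels))
  expected <- matrix(30, nrow(hema), ncol(hema))
  expected[tile$truth_nuclear_mask$pixels] <- 200
  expect_identical(hema, expected)
  # CD3 only on T cells, cytokeratin only on the tumor mask
  expect_identical(tile$ihc_channels$CD3$pixels > 30, tile$truth_cd3_mask$pixels)
  expect_identical(tile$ihc_channels$HMW_CK$pixels > 30,
                   tile$truth_tumor_mask$pixels)
})

test_that("a pure translation displaces hematoxylin nuclei by the configured shift", {
  shift_px <- 10
  cfg <- small_sim_config(
    seed = 107, ihc_pixel_size_um = 0.3,
    noise = list(if_background = 500, if_signal = 20000, if_sd = 0,
                 ihc_background = 30, ihc_signal = 200, ihc_sd = 0),
    acquisition_transform = list(rotation_deg = 0,
                                 translation_um = c(shift_px * 0.3, 0),
                                 shear = 0, scale = 1)
  )
  tile <- generate_tile(cfg)
  hema <- tile$ihc_channels$hematoxylin$pixels > 30
  dapi <- tile$truth_nuclear_mask$pixels
  # a nucleus at IF row p appears in the chromogenic image at row p - 10
  centroid <- function(m, lab_id, lab) {
    idx <- which(lab == lab_id)
    c(mean((idx - 1) %% nrow(m)), mean((idx - 1) %/% nrow(m)))
  }
  lab_d <- EBImage::bwlabel(dapi)
  lab_h <- EBImage::bwlabel(hema)
  interior <- tile$truth_cells$centroid_row > 25 &
    tile$truth_cells$centroid_row < nrow(dapi) - 25
  matched <- 0
  for (i in which(interior)) {
    cd <- c(tile$truth_cells$centroid_row[i], tile$truth_cells$centroid_col[i])
    id_h <- lab_h[round(cd[1] - shift_px) + 1, round(cd[2]) + 1]
    if (id_h == 0) next
    ch <- centroid(hema, id_h, lab_h)
    expect_equal(ch[1], cd[1] - shift_px, tolerance = 0.5)
    expect_equal(ch[2], cd[2], tolerance = 0.5)
    matched <- matched + 1
  }
  expect_gt(matched, 5)
})

test_that("resampling 0.3 to 0.5 um shrinks a 20-px disk to 12 +/- 1 IHC px", {
  cfg <- simulation_config(
    tile_height_px = 128, tile_width_px = 128,
    n_tumor_regions = 0, tumor_area_fraction = 0,
    n_tcells = 0, n_macrophages = 0, n_myeloid = 1, n_tumor_nuclei = 0,
    morphology = list(
      tcell = list(nuclear_radius_um = c(mean = 2.5, sd = 0.25)),
      macrophage = list(nuclear_radius_um = c(mean = 3.5, sd = 0.4)),
      myeloid = list(nuclear_radius_um = c(mean = 3, sd = 0)), # 10 px radius
      tumor = list(nuclear_radius_um = c(mean = 2.5, sd = 0.25))
    ),
    noise = list(if_background = 500, if_signal = 20000, if_sd = 0,
                 ihc_background = 30, ihc_signal = 200, ihc_sd = 0),
    seed = 108
  )
  tile <- generate_tile(cfg)
  # IF nucleus spans ~20 rows (radius-10 disk rasterized at a random center)
  rows_if <- range(which(rowSums(tile$truth_nuclear_mask$pixels) > 0))
  expect_true((diff(rows_if) + 1) %in% c(20, 21))
  hema <- tile$ihc_channels$hematoxylin$pixels > 115 # midpoint of 30/200
  rows_ihc <- range(which(rowSums(hema) > 0))
  expect_lte(abs((diff(rows_ihc) + 1) - 12), 1)
  # chromogenic grid dimensions follow the pixel-size ratio
  expect_equal(dim(hema), round(c(128, 128) * 0.3 / 0.5))
})

test_that("tiles written to disk round-trip through the TIFF/CSV/JSON formats", {
  cfg <- small_sim_config(seed = 109)
  tile <- generate_tile(cfg, tile_id = "tile_007")
  dir <- file.path(tempdir(), "synthcase", "tile_007")
  write_synthetic_tile(tile, dir)
  cd68 <- read_channel_tiff(file.path(dir, "tile_007_CD68.tif"), 0.3, "CD68")
  expect_identical(cd68$pixels, tile$if_channels$CD68$pixels)
  hema <- read_channel_tiff(file.path(dir, "tile_007_hematoxylin.tif"), 0.5,
                            "hematoxylin")
  expect_identical(hema$pixels, tile$ihc_channels$hematoxylin$pixels)
  tumor <- read_mask_tiff(file.path(dir, "tile_007_truth_tumor.tif"), 0.3, "tumor")
  expect_identical(tumor$pixels, tile$truth_tumor_mask$pixels)
  tr <- read_transform_json(file.path(dir, "tile_007_truth_transform.json"))
  expect_equal(tr$matrix, tile$truth_transform$matrix, tolerance = 1e-12)
  cells <- read.csv(file.path(dir, "tile_007_truth_cells.csv"))
  expect_equal(nrow(cells), nrow(tile$truth_cells))
  unlink(file.path(tempdir(), "synthcase"), recursive = TRUE)
})
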