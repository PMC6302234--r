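# Seeded synthetic-tissue simulator: fluorescent and chromogenic renditions
# of one tile with full ground truth (cells, marker masks, tumor mask, and
# the acquisition transform between the two geometries).

#' Simulation configuration
#'
#' Defines one synthetic tile: geometry of the fluorescent (IF) and
#' chromogenic (IHC) grids, tumor regions, cell populations with their
#' marker co-expression probabilities and morphology, the placement model,
#' the two-level-plus-Gaussian noise model, and the affine acquisition
#' transform relating the two renditions. The same configuration and seed
#' always produce bit-identical tiles.
#'
#' Cell types: `tcell` (compact, CD3 only), `macrophage` (stellate, with
#' processes whose stained tips lie far from the nucleus), `myeloid`
#' (compact, MC&M co-expression), `tumor` (bare nuclei inside the tumor
#' epithelium). Co-expression probabilities are independent per marker.
#'
#' @param tile_height_px,tile_width_px IF grid dimensions in pixels.
#' @param if_pixel_size_um IF pixel size (default 0.3 um, 16-bit channels).
#' @param ihc_pixel_size_um IHC pixel size (default 0.5 um, 8-bit channels).
#' @param n_tumor_regions number of tumor-epithelium regions.
#' @param tumor_area_fraction approximate fraction of the tile covered by
#'   tumor (in `[0, 1]`).
#' @param n_tcells,n_macrophages,n_myeloid,n_tumor_nuclei cell counts.
#' @param coexpression named list (`macrophage`, `myeloid`) of per-marker
#'   positivity probabilities for the five MC&M markers.
#' @param morphology named list of per-type morphology parameters: nuclear
#'   radius mean/sd (um); for stellate cells the process count range, length
#'   range (um), width range (px) and the fraction of the perinuclear ring
#'   that is stained (`ring_coverage`).
#' @param marker_ring_width_um width of the stained perinuclear cytoplasm
#'   ring for compact cells (default 1.2 um).
#' @param placement named list of per-type placement models: `model`
#'   (`"uniform"` or `"tumor_border"`, the latter biased toward the tumor
#'   edge with decay length `decay_um`), and `region` (`"stroma"`, `"tumor"`
#'   or `"any"`).
#' @param min_separation_factor minimum centroid separation as a multiple of
#'   the sum of two nuclear radii (default 1.5; keeps nuclei disjoint).
#' @param noise two-level noise model: background and signal intensities
#'   plus additive Gaussian sd for the IF (16-bit) and IHC (8-bit) channels.
#' @param acquisition_transform affine parameters (rotation deg, translation
#'   um, shear, scale) producing the chromogenic rendition.
#' @param seed integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    tile_height_px = 512, tile_width_px = 512,
    if_pixel_size_um = 0.3, ihc_pixel_size_um = 0.5,
    n_tumor_regions = 2, tumor_area_fraction = 0.25,
    n_tcells = 20, n_macrophages = 25, n_myeloid = 0, n_tumor_nuclei = 30,
    coexpression = list(
      macrophage = c(CD68 = 0.9, CD163 = 0.6, CD206 = 0.3, CD11b = 0.3, CD11c = 0.2),
      myeloid = c(CD68 = 0.1, CD163 = 0.05, CD206 = 0, CD11b = 0.8, CD11c = 0.7)
    ),
    morphology = list(
      tcell = list(nuclear_radius_um = c(mean = 2.5, sd = 0.25)),
      macrophage = list(
        nuclear_radius_um = c(mean = 3.5, sd = 0.4),
        process_count_range = c(3, 6),
        process_length_um_range = c(10, 40),
        process_width_px_range = c(1, 2),
        ring_coverage = 0.1
      ),
      myeloid = list(nuclear_radius_um = c(mean = 3, sd = 0.3)),
      tumor = list(nuclear_radius_um = c(mean = 2.5, sd = 0.25))
    ),
    marker_ring_width_um = 1.2,
    placement = list(
      tcell = list(model = "uniform", region = "stroma"),
      macrophage = list(model = "uniform", region = "stroma", decay_um = 30),
      myeloid = list(model = "uniform", region = "stroma", decay_um = 30),
      tumor = list(model = "uniform", region = "tumor")
    ),
    min_separation_factor = 1.5,
    noise = list(
      if_background = 500, if_signal = 20000, if_sd = 300,
      ihc_background = 30, ihc_signal = 200, ihc_sd = 6
    ),
    acquisition_transform = list(
      rotation_deg = 0, translation_um = c(0, 0), shear = 0, scale = 1
    ),
    seed = 1L) {
  cfg <- list(
    tile_height_px = as.integer(tile_height_px),
    tile_width_px = as.integer(tile_width_px),
    if_pixel_size_um = if_pixel_size_um,
    ihc_pixel_size_um = ihc_pixel_size_um,
    n_tumor_regions = as.integer(n_tumor_regions),
    tumor_area_fraction = tumor_area_fraction,
    n_tcells = as.integer(n_tcells),
    n_macrophages = as.integer(n_macrophages),
    n_myeloid = as.integer(n_myeloid),
    n_tumor_nuclei = as.integer(n_tumor_nuclei),
    coexpression = coexpression,
    morphology = morphology,
    marker_ring_width_um = marker_ring_width_um,
    placement = placement,
    min_separation_factor = min_separation_factor,
    noise = noise,
    acquisition_transform = acquisition_transform,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(
    cfg$tile_height_px >= 16, cfg$tile_width_px >= 16,
    cfg$if_pixel_size_um > 0, cfg$ihc_pixel_size_um > 0,
    cfg$tumor_area_fraction >= 0, cfg$tumor_area_fraction <= 1,
    cfg$n_tumor_regions >= 0,
    cfg$n_tcells >= 0, cfg$n_macrophages >= 0, cfg$n_myeloid >= 0,
    cfg$n_tumor_nuclei >= 0,
    cfg$marker_ring_width_um > 0,
    cfg$min_separation_factor > 0
  )
  for (ty in names(cfg$coexpression)) {
    p <- cfg$coexpression[[ty]]
    if (any(p < 0 | p > 1)) {
      stop("co-expression probabilities for ", ty, " must lie in [0, 1]")
    }
    if (!all(MCM_MARKERS %in% names(p))) {
      stop("co-expression for ", ty, " must name all of: ",
           paste(MCM_MARKERS, collapse = ", "))
    }
  }
  for (ty in names(cfg$morphology)) {
    r <- cfg$morphology[[ty]]$nuclear_radius_um
    if (r[["mean"]] <= 0 || r[["sd"]] < 0) {
      stop("nuclear radius parameters for ", ty, " must be positive")
    }
  }
  invisible(cfg)
}

# Rasterization helpers (all return linear indices into an H x W matrix) ----

disk_indices <- function(H, W, cr0, cc0, r_px) {
  r0 <- max(1L, floor(cr0 - r_px) + 1L); r1 <- min(H, ceiling(cr0 + r_px) + 1L)
  c0 <- max(1L, floor(cc0 - r_px) + 1L); c1 <- min(W, ceiling(cc0 + r_px) + 1L)
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dr <- (rr - 1) - cr0
  dc <- (cc - 1) - cc0
  inside <- outer(dr^2, dc^2, `+`) <= r_px^2
  idx <- which(inside)
  rloc <- (idx - 1L) %% length(rr) + r0
  cloc <- (idx - 1L) %/% length(rr) + c0
  (cloc - 1L) * H + rloc
}

annulus_indices <- function(H, W, cr0, cc0, r_in, r_out,
                            arc_centers = NULL, arc_halfwidth = NULL) {
  r0 <- max(1L, floor(cr0 - r_out) + 1L); r1 <- min(H, ceiling(cr0 + r_out) + 1L)
  c0 <- max(1L, floor(cc0 - r_out) + 1L); c1 <- min(W, ceiling(cc0 + r_out) + 1L)
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dr <- (rr - 1) - cr0
  dc <- (cc - 1) - cc0
  d2 <- outer(dr^2, dc^2, `+`)
  inside <- d2 <= r_out^2 & d2 > r_in^2
  if (!is.null(arc_centers)) {
    ang <- atan2(
      base::matrix(rep(dc, each = length(dr)), length(dr)),
      base::matrix(rep(dr, times = length(dc)), length(dr))
    )
    in_arc <- Reduce(`|`, lapply(arc_centers, function(a) {
      d <- abs(((ang - a + pi) %% (2 * pi)) - pi)
      d <= arc_halfwidth
    }))
    inside <- inside & in_arc
  }
  idx <- which(inside)
  rloc <- (idx - 1L) %% length(rr) + r0
  cloc <- (idx - 1L) %/% length(rr) + c0
  (cloc - 1L) * H + rloc
}

polyline_indices <- function(H, W, pts_px, width_px) {
  # stamp disks of radius width/2 at sub-pixel steps along each segment
  rad <- max(width_px / 2, 0.5)
  samples <- list()
  for (s in seq_len(nrow(pts_px) - 1)) {
    a <- pts_px[s, ]; b <- pts_px[s + 1, ]
    len <- sqrt(sum((b - a)^2))
    nstep <- max(2L, ceiling(len / 0.4))
    tt <- seq(0, 1, length.out = nstep)
    samples[[s]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }
  P <- do.call(rbind, samples)
  off <- expand.grid(dr = -ceiling(rad):ceiling(rad), dc = -ceiling(rad):ceiling(rad))
  off <- off[off$dr^2 + off$dc^2 <= rad^2, , drop = FALSE]
  rr <- round(rep(P[, 1], each = nrow(off)) + off$dr) + 1L
  cc <- round(rep(P[, 2], each = nrow(off)) + off$dc) + 1L
  ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  unique((cc[ok] - 1L) * H + rr[ok])
}

# Tumor-epithelium regions: each region is a union of one main disk and four
# satellite disks, giving compact but irregular contiguous blobs whose total
# area approximates the configured fraction.
make_tumor_mask <- function(H, W, n_regions, fraction) {
  mask <- matrix(FALSE, H, W)
  if (n_regions == 0 || fraction <= 0) return(mask)
  R0 <- sqrt(fraction * H * W / (n_regions * pi))
  for (i in seq_len(n_regions)) {
    cr <- runif(1, R0, H - 1 - R0)
    cc <- runif(1, R0, W - 1 - R0)
    mask[disk_indices(H, W, cr, cc, 0.8 * R0)] <- TRUE
    for (k in 1:4) {
      a <- runif(1, 0, 2 * pi)
      d <- runif(1, 0.3, 0.6) * R0
      mask[disk_indices(H, W, cr + d * cos(a), cc + d * sin(a),
                        runif(1, 0.35, 0.55) * R0)] <- TRUE
    }
  }
  mask
}

# Rejection-sampling placement with a hard minimum centroid separation.
place_cells <- function(cfg, tumor) {
  H <- cfg$tile_height_px; W <- cfg$tile_width_px
  psz <- cfg$if_pixel_size_um
  counts <- c(
    tumor = cfg$n_tumor_nuclei, tcell = cfg$n_tcells,
    macrophage = cfg$n_macrophages, myeloid = cfg$n_myeloid
  )
  d_out_um <- NULL # stroma-side distance to tumor, for border-biased placement
  need_bias <- any(vapply(cfg$placement, function(p)
    identical(p$model, "tumor_border"), logical(1)))
  if (need_bias && any(tumor)) {
    d_out_um <- EBImage::distmap(!tumor) * psz
  }
  acc_r <- numeric(0); acc_c <- numeric(0); acc_rad <- numeric(0)
  rows <- list()
  for (ty in names(counts)) {
    n <- counts[[ty]]
    if (n == 0) next
    morph <- cfg$morphology[[ty]]
    plc <- cfg$placement[[ty]]
    if (is.null(plc)) plc <- list(model = "uniform", region = "any")
    rad_um <- pmax(
      rnorm(n, morph$nuclear_radius_um[["mean"]], morph$nuclear_radius_um[["sd"]]),
      0.4 * morph$nuclear_radius_um[["mean"]]
    )
    rad_px <- rad_um / psz
    for (i in seq_len(n)) {
      margin <- rad_px[i] + 2
      placed <- FALSE
      for (attempt in seq_len(20000)) {
        cr <- runif(1, margin, H - 1 - margin)
        cc <- runif(1, margin, W - 1 - margin)
        px <- c(round(cr) + 1, round(cc) + 1)
        in_tumor <- tumor[px[1], px[2]]
        if (identical(plc$region, "stroma") && in_tumor) next
        if (identical(plc$region, "tumor") && !in_tumor) next
        if (identical(plc$model, "tumor_border") && !is.null(d_out_um)) {
          d <- d_out_um[px[1], px[2]]
          if (runif(1) > exp(-d / plc$decay_um)) next
        }
        if (length(acc_r) > 0) {
          sep <- cfg$min_separation_factor * (acc_rad + rad_px[i])
          if (any((acc_r - cr)^2 + (acc_c - cc)^2 < sep^2)) next
        }
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(
          "placement failure: could not place %s %d/%d at non-overlap separation; reduce cell counts or separation",
          ty, i, n
        ))
      }
      acc_r <- c(acc_r, cr); acc_c <- c(acc_c, cc); acc_rad <- c(acc_rad, rad_px[i])
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ty, centroid_row = cr, centroid_col = cc,
        nuclear_radius_um = rad_um[i], nuclear_radius_px = rad_px[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      cell_id = integer(0), cell_type = character(0), centroid_row = numeric(0),
      centroid_col = numeric(0), nuclear_radius_um = numeric(0),
      nuclear_radius_px = numeric(0)
    ))
  }
  out <- do.call(rbind, rows)
  out <- cbind(cell_id = seq_len(nrow(out)), out)
  out
}

# Draw marker positivity and stellate processes for the placed cells.
annotate_cells <- function(cells, cfg) {
  n <- nrow(cells)
  for (mk in MCM_MARKERS) cells[[paste0("positive_", mk)]] <- FALSE
  cells$positive_CD3 <- cells$cell_type == "tcell"
  for (ty in names(cfg$coexpression)) {
    sel <- which(cells$cell_type == ty)
    for (mk in MCM_MARKERS) {
      p <- cfg$coexpression[[ty]][[mk]]
      cells[[paste0("positive_", mk)]][sel] <- runif(length(sel)) < p
    }
  }
  cells$n_processes <- 0L
  processes <- vector("list", n)
  psz <- cfg$if_pixel_size_um
  for (i in seq_len(n)) {
    morph <- cfg$morphology[[cells$cell_type[i]]]
    if (is.null(morph$process_count_range)) {
      processes[[i]] <- list()
      next
    }
    kr <- morph$process_count_range
    K <- sample(kr[1]:kr[2], 1)
    cells$n_processes[i] <- K
    base_angle <- runif(1, 0, 2 * pi)
    angles <- (base_angle + 2 * pi * (0:(K - 1)) / K + rnorm(K, 0, 0.25)) %% (2 * pi)
    pls <- vector("list", K)
    for (k in seq_len(K)) {
      len_px <- runif(1, morph$process_length_um_range[1],
                      morph$process_length_um_range[2]) / psz
      a <- angles[k]
      kink <- rnorm(1, 0, 0.35)
      r0 <- cells$nuclear_radius_px[i]
      p0 <- c(cells$centroid_row[i] + r0 * cos(a), cells$centroid_col[i] + r0 * sin(a))
      p1 <- p0 + (len_px / 2) * c(cos(a), sin(a))
      p2 <- p1 + (len_px / 2) * c(cos(a + kink), sin(a + kink))
      pls[[k]] <- list(
        pts = rbind(p0, p1, p2),
        width_px = sample(morph$process_width_px_range[1]:morph$process_width_px_range[2], 1),
        angle = a
      )
    }
    processes[[i]] <- pls
  }
  list(cells = cells, processes = processes)
}

# Footprint of one cell for its positive markers: compact cells carry a full
# perinuclear ring; stellate cells carry a patchy ring (arcs at the process
# roots covering `ring_coverage` of the circumference) plus the processes.
marker_footprint_indices <- function(cell, procs, cfg, H, W) {
  psz <- cfg$if_pixel_size_um
  ring_w <- cfg$marker_ring_width_um / psz
  morph <- cfg$morphology[[cell$cell_type]]
  r_in <- cell$nuclear_radius_px
  r_out <- r_in + ring_w
  if (length(procs) == 0) {
    return(annulus_indices(H, W, cell$centroid_row, cell$centroid_col, r_in, r_out))
  }
  cov <- morph$ring_coverage
  if (is.null(cov)) cov <- 1
  arc_centers <- vapply(procs, function(p) p$angle, numeric(1))
  arc_halfwidth <- cov * pi / length(procs)
  ring <- annulus_indices(H, W, cell$centroid_row, cell$centroid_col,
                          r_in, r_out, arc_centers, arc_halfwidth)
  proc_idx <- unlist(lapply(procs, function(p) {
    polyline_indices(H, W, p$pts, p$width_px)
  }))
  unique(c(ring, proc_idx))
}

#' Generate a synthetic tile
#'
#' Places tumor regions and cells, draws marker positivity from the
#' configured co-expression probabilities, rasterizes noise-free ground
#' truth (nuclear field, per-marker masks, CD3 footprints, tumor mask),
#' renders the fluorescent channels with the two-level-plus-Gaussian noise
#' model, and renders the chromogenic rendition through the acquisition
#' transform. All randomness derives from `config$seed`; the caller's RNG
#' state is untouched.
#'
#' @param config a [simulation_config()].
#' @param tile_id identifier used for all channels.
#' @return A `synthetic_tile`: list with `if_channels` (DAPI + 5 markers,
#'   16-bit scale), `ihc_channels` (hematoxylin, CD3, HMW_CK, LMW_CK, 8-bit
#'   scale), `truth_cells` (cell table), `truth_processes`, per-marker
#'   `truth_marker_masks` (noise-free, IF geometry), `truth_tumor_mask`,
#'   `truth_nuclear_mask`, `truth_cd3_mask`, `truth_transform` (IHC um to
#'   IF um) and `config`.
#' @export
generate_tile <- function(config, tile_id = "tile_001") {
  validate_simulation_config(config)
  H <- config$tile_height_px; W <- config$tile_width_px
  psz <- config$if_pixel_size_um
  tile <- with_seed(config$seed, {
    tumor <- make_tumor_mask(H, W, config$n_tumor_regions, config$tumor_area_fraction)
    cells <- place_cells(config, tumor)
    ann <- annotate_cells(cells, config)
    cells <- ann$cells
    processes <- ann$processes

    nuclear <- matrix(FALSE, H, W)
    for (i in seq_len(nrow(cells))) {
      nuclear[disk_indices(H, W, cells$centroid_row[i], cells$centroid_col[i],
                           cells$nuclear_radius_px[i])] <- TRUE
    }
    footprints <- lapply(seq_len(nrow(cells)), function(i) {
      if (cells$cell_type[i] %in% names(config$coexpression)) {
        marker_footprint_indices(cells[i, ], processes[[i]], config, H, W)
      } else {
        integer(0)
      }
    })
    marker_masks <- list()
    for (mk in MCM_MARKERS) {
      m <- matrix(FALSE, H, W)
      pos <- which(cells[[paste0("positive_", mk)]])
      for (i in pos) m[footprints[[i]]] <- TRUE
      marker_masks[[mk]] <- marker_mask(m, psz, mk, tile_id)
    }
    cd3 <- matrix(FALSE, H, W)
    ring_w <- config$marker_ring_width_um / psz
    for (i in which(cells$cell_type == "tcell")) {
      cd3[annulus_indices(H, W, cells$centroid_row[i], cells$centroid_col[i],
                          cells$nuclear_radius_px[i],
                          cells$nuclear_radius_px[i] + ring_w)] <- TRUE
    }

    render_if <- function(mask01) {
      nz <- config$noise
      img <- nz$if_background + (nz$if_signal - nz$if_background) * mask01
      if (nz$if_sd > 0) img <- img + rnorm(length(img), 0, nz$if_sd)
      base::matrix(pmin(pmax(round(img), 0), 65535), H, W)
    }
    if_channels <- list(DAPI = channel_image(render_if(nuclear * 1), psz, "DAPI", tile_id))
    for (mk in MCM_MARKERS) {
      if_channels[[mk]] <- channel_image(
        render_if(marker_masks[[mk]]$pixels * 1), psz, mk, tile_id
      )
    }

    cells$centroid_row_um <- cells$centroid_row * psz
    cells$centroid_col_um <- cells$centroid_col * psz

    dims_ihc <- c(
      max(2L, as.integer(round(H * psz / config$ihc_pixel_size_um))),
      max(2L, as.integer(round(W * psz / config$ihc_pixel_size_um)))
    )
    at <- config$acquisition_transform
    th <- at$rotation_deg * pi / 180
    A <- at$scale * base::matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
      base::matrix(c(1, 0, at$shear, 1), 2, 2)
    c_ihc <- (dims_ihc - 1) / 2 * config$ihc_pixel_size_um
    c_if <- (c(H, W) - 1) / 2 * psz
    truth_transform <- affine_transform(
      cbind(A, c_if + as.numeric(at$translation_um) - A %*% c_ihc),
      config$ihc_pixel_size_um, psz
    )

    structure(
      list(
        tile_id = tile_id,
        if_channels = if_channels,
        ihc_channels = NULL,
        truth_cells = cells,
        truth_processes = processes,
        truth_marker_masks = marker_masks,
        truth_tumor_mask = marker_mask(tumor, psz, "tumor", tile_id),
        truth_nuclear_mask = marker_mask(nuclear, psz, "nuclei", tile_id),
        truth_cd3_mask = marker_mask(cd3, psz, "CD3", tile_id),
        truth_transform = truth_transform,
        ihc_dim = dims_ihc,
        config = config
      ),
      class = "synthetic_tile"
    )
  })
  render_chromogenic_view(tile, config)
}

#' Render the chromogenic (IHC) rendition of a synthetic tile
#'
#' Fills `ihc_channels` by sampling the noise-free fluorescent-geometry
#' fields through the truth transform onto the chromogenic grid (inverse
#' mapping, bilinear for intensities): hematoxylin depicts the same nuclei
#' as DAPI, CD3 is rendered only on T cells, and the two cytokeratin
#' channels only on the tumor mask. Chromogenic noise is seeded from
#' `config$seed` so repeated rendering is deterministic.
#'
#' @param tile a `synthetic_tile` with `if_channels` populated.
#' @param config the tile's [simulation_config()].
#' @return The tile with `ihc_channels` filled (8-bit intensity scale).
#' @export
render_chromogenic_view <- function(tile, config = tile$config) {
  stopifnot(inherits(tile, "synthetic_tile"), !is.null(tile$if_channels))
  psz_if <- config$if_pixel_size_um
  psz_ihc <- config$ihc_pixel_size_um
  dims_ihc <- tile$ihc_dim
  pull <- tile$truth_transform$matrix # IHC um -> IF um, used as pull-back
  nz <- config$noise
  with_seed(config$seed + 1L, {
    render_ihc <- function(field01, signal_scale = 1) {
      rs <- pullback_resample(field01, psz_if, pull, dims_ihc, psz_ihc,
                              bilinear = TRUE)
      v <- rs$values
      v[is.na(v)] <- 0
      img <- nz$ihc_background +
        (nz$ihc_signal * signal_scale - nz$ihc_background) * v
      if (nz$ihc_sd > 0) img <- img + rnorm(length(img), 0, nz$ihc_sd)
      base::matrix(pmin(pmax(round(img), 0), 255), dims_ihc[1], dims_ihc[2])
    }
    tile$ihc_channels <- list(
      hematoxylin = channel_image(
        render_ihc(tile$truth_nuclear_mask$pixels * 1), psz_ihc,
        "hematoxylin", tile$tile_id
      ),
      CD3 = channel_image(
        render_ihc(tile$truth_cd3_mask$pixels * 1), psz_ihc, "CD3", tile$tile_id
      ),
      HMW_CK = channel_image(
        render_ihc(tile$truth_tumor_mask$pixels * 1), psz_ihc,
        "HMW_CK", tile$tile_id
      ),
      LMW_CK = channel_image(
        render_ihc(tile$truth_tumor_mask$pixels * 1, signal_scale = 0.8),
        psz_ihc, "LMW_CK", tile$tile_id
      )
    )
  })
  tile
}

#' @export
print.synthetic_tile <- function(x, ...) {
  cat(sprintf(
    "<synthetic_tile> %s: %d x %d IF px @ %g um, %d cells, tumor %.1f%%\n",
    x$tile_id, nrow(x$if_channels$DAPI$pixels), ncol(x$if_channels$DAPI$pixels),
    x$config$if_pixel_size_um, nrow(x$truth_cells),
    100 * mean(x$truth_tumor_mask$pixels)
  ))
  invisible(x)
}

#' Write a synthetic tile to disk
#'
#' Writes each channel as a single-channel TIFF named
#' `<tile>_<channel>.tif`, the truth cell table as CSV, the truth masks as
#' 8-bit TIFFs, and the truth transform plus a configuration echo as JSON.
#'
#' @param tile a `synthetic_tile`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_tile <- function(tile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tid <- tile$tile_id
  for (ch in names(tile$if_channels)) {
    write_channel_tiff(tile$if_channels[[ch]],
                       file.path(dir, sprintf("%s_%s.tif", tid, ch)), 16)
  }
  for (ch in names(tile$ihc_channels)) {
    write_channel_tiff(tile$ihc_channels[[ch]],
                       file.path(dir, sprintf("%s_%s.tif", tid, ch)), 8)
  }
  write.csv(tile$truth_cells, file.path(dir, sprintf("%s_truth_cells.csv", tid)),
            row.names = FALSE)
  for (mk in names(tile$truth_marker_masks)) {
    write_mask_tiff(tile$truth_marker_masks[[mk]],
                    file.path(dir, sprintf("%s_truth_%s.tif", tid, mk)))
  }
  write_mask_tiff(tile$truth_tumor_mask, file.path(dir, sprintf("%s_truth_tumor.tif", tid)))
  write_transform_json(tile$truth_transform,
                       file.path(dir, sprintf("%s_truth_transform.json", tid)))
  cfg <- tile$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, sprintf("%s_config.json", tid)),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}

#' Generate and write a multi-tile synthetic case
#'
#' Generates `n_tiles` tiles with per-tile seeds `config$seed + 0:(n-1)` and
#' writes each into its own subdirectory of `dir`.
#'
#' @param config a [simulation_config()].
#' @param n_tiles number of tiles.
#' @param dir case directory.
#' @return Character vector of tile directories, invisibly.
#' @export
write_synthetic_case <- function(config, n_tiles, dir) {
  dirs <- character(n_tiles)
  for (i in seq_len(n_tiles)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    tid <- sprintf("tile_%03d", i)
    tile <- generate_tile(cfg_i, tile_id = tid)
    dirs[i] <- file.path(dir, tid)
    write_synthetic_tile(tile, dirs[i])
  }
  invisible(dirs)
}
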