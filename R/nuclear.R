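# Nuclear segmentation, perinuclear doughnut construction and cell calls.

#' Nuclear segmentation parameters
#'
#' The recipe is the standard one for counterstain nuclei: Gaussian
#' smoothing, a global threshold, hole filling, a distance-transform
#' watershed to split touching nuclei, and a minimum-area filter.
#'
#' @param smooth_sigma_px Gaussian smoothing sigma in pixels (default 2).
#' @param threshold `"otsu"` or a numeric intensity in native units.
#' @param min_area_px nuclei smaller than this are discarded (default 20).
#' @param watershed_tolerance tolerance passed to [EBImage::watershed()].
#' @return An object of class `nucleus_spec`.
#' @export
nucleus_spec <- function(smooth_sigma_px = 2, threshold = "otsu",
                         min_area_px = 20, watershed_tolerance = 1) {
  stopifnot(smooth_sigma_px > 0, min_area_px >= 1)
  structure(
    list(
      smooth_sigma_px = smooth_sigma_px,
      threshold = threshold,
      min_area_px = as.integer(min_area_px),
      watershed_tolerance = watershed_tolerance
    ),
    class = "nucleus_spec"
  )
}

#' Doughnut (perinuclear ring) parameters
#'
#' The nuclear outline is expanded outward by a fixed length equal to
#' `expansion_fraction` of the tile's mean nuclear radius (default 1/3), and
#' a cell is called positive for a marker when the positive-pixel density in
#' that ring strictly exceeds `density_threshold`.
#'
#' @param expansion_fraction ring width as a fraction of the mean nuclear
#'   radius (default 1/3).
#' @param density_threshold positivity threshold on doughnut density,
#'   a fraction in `[0, 1]` (default 0.1).
#' @return An object of class `doughnut_spec`.
#' @export
doughnut_spec <- function(expansion_fraction = 1 / 3, density_threshold = 0.1) {
  stopifnot(
    expansion_fraction > 0,
    density_threshold >= 0, density_threshold <= 1
  )
  structure(
    list(
      expansion_fraction = expansion_fraction,
      density_threshold = density_threshold
    ),
    class = "doughnut_spec"
  )
}

#' Segment nuclei from a counterstain channel
#'
#' Applies smoothing, a global threshold, hole filling and a
#' distance-transform watershed to the DAPI or hematoxylin channel, then
#' filters nuclei below the minimum area. Centroids are reported 0-based
#' with pixel centers at integer coordinates.
#'
#' @param nuclear_image the counterstain [channel_image()].
#' @param spec a [nucleus_spec()].
#' @return A `nucleus_set`: list with `table` (data frame of `nucleus_id`,
#'   `centroid_row`, `centroid_col`, `area_px`, `equivalent_radius_px`),
#'   `labels` (integer label matrix), `mask` (the nuclear [marker_mask()]),
#'   `pixel_size_um`, `tile_id`, and `doughnuts` (`NULL` until
#'   [build_doughnuts()] is called).
#' @export
segment_nuclei <- function(nuclear_image, spec = nucleus_spec()) {
  stopifnot(inherits(nuclear_image, "channel_image"), inherits(spec, "nucleus_spec"))
  px <- nuclear_image$pixels
  empty_set <- function(labels) {
    structure(
      list(
        table = data.frame(
          nucleus_id = integer(0), centroid_row = numeric(0),
          centroid_col = numeric(0), area_px = integer(0),
          equivalent_radius_px = numeric(0)
        ),
        labels = labels,
        mask = marker_mask(labels > 0, nuclear_image$pixel_size_um,
                           "nuclei", nuclear_image$tile_id),
        pixel_size_um = nuclear_image$pixel_size_um,
        tile_id = nuclear_image$tile_id,
        doughnuts = NULL
      ),
      class = "nucleus_set"
    )
  }
  mx <- max(px)
  if (mx <= min(px)) {
    return(empty_set(matrix(0L, nrow(px), ncol(px))))
  }
  sm <- EBImage::gblur(px / mx, sigma = spec$smooth_sigma_px)
  thr <- if (identical(spec$threshold, "otsu")) {
    EBImage::otsu(sm, range = c(0, 1), levels = 256)
  } else {
    spec$threshold / mx
  }
  bin <- sm > thr
  bin <- EBImage::fillHull(bin)
  if (!any(bin)) {
    return(empty_set(matrix(0L, nrow(px), ncol(px))))
  }
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = spec$watershed_tolerance, ext = 1)
  lab <- as.matrix(EBImage::imageData(lab))
  storage.mode(lab) <- "integer"

  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= spec$min_area_px)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- relabel[lab[pos]]

  if (length(keep) == 0) {
    return(empty_set(lab))
  }
  idx <- which(lab > 0L)
  lv <- lab[idx]
  rows0 <- (idx - 1L) %% nrow(lab)       # 0-based row
  cols0 <- (idx - 1L) %/% nrow(lab)      # 0-based col
  area <- tabulate(lv)
  cr <- tapply(rows0, lv, mean)
  cc <- tapply(cols0, lv, mean)
  tab <- data.frame(
    nucleus_id = seq_along(area),
    centroid_row = as.numeric(cr),
    centroid_col = as.numeric(cc),
    area_px = as.integer(area),
    equivalent_radius_px = sqrt(area / pi)
  )
  structure(
    list(
      table = tab,
      labels = lab,
      mask = marker_mask(lab > 0L, nuclear_image$pixel_size_um,
                         "nuclei", nuclear_image$tile_id),
      pixel_size_um = nuclear_image$pixel_size_um,
      tile_id = nuclear_image$tile_id,
      doughnuts = NULL
    ),
    class = "nucleus_set"
  )
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf(
    "<nucleus_set> %s: %d nuclei, mean radius %.2f px%s\n",
    x$tile_id, nrow(x$table),
    if (nrow(x$table) > 0) mean(x$table$equivalent_radius_px) else NA,
    if (is.null(x$doughnuts)) "" else ", doughnuts built"
  ))
  invisible(x)
}

#' Build perinuclear doughnuts for all nuclei of a tile
#'
#' Each nucleus is dilated by a ring width of `round(expansion_fraction *
#' mean_radius)` pixels (round half up), where the mean radius is taken over
#' all nuclei in the tile; the nucleus's own pixels and the pixels of every
#' other nucleus are excluded from the ring, and rings are clipped at the
#' tile border. Rings of neighboring cells may overlap each other: each
#' cell is classified independently.
#'
#' @param nset a `nucleus_set` from [segment_nuclei()].
#' @param spec a [doughnut_spec()].
#' @return The `nucleus_set` with `doughnuts` set to a list of linear pixel
#'   index vectors (one per nucleus) and attribute `ring_width_px`.
#' @export
build_doughnuts <- function(nset, spec = doughnut_spec()) {
  stopifnot(inherits(nset, "nucleus_set"), inherits(spec, "doughnut_spec"))
  n <- nrow(nset$table)
  if (n == 0) {
    nset$doughnuts <- list()
    attr(nset, "ring_width_px") <- NA_integer_
    return(nset)
  }
  mean_radius <- mean(nset$table$equivalent_radius_px)
  w <- as.integer(round_half_up(spec$expansion_fraction * mean_radius))
  if (w < 1) {
    stop(sprintf(
      "degenerate doughnut: expansion %.3g x mean radius %.3g px rounds to 0",
      spec$expansion_fraction, mean_radius
    ))
  }
  H <- nrow(nset$labels)
  W <- ncol(nset$labels)
  any_nucleus <- nset$labels > 0L
  doughnuts <- vector("list", n)
  idx_all <- which(nset$labels > 0L)
  lv <- nset$labels[idx_all]
  by_nuc <- split(idx_all, lv)
  for (k in seq_len(n)) {
    idx <- by_nuc[[as.character(k)]]
    r <- (idx - 1L) %% H + 1L
    c <- (idx - 1L) %/% H + 1L
    r0 <- max(1L, min(r) - w); r1 <- min(H, max(r) + w)
    c0 <- max(1L, min(c) - w); c1 <- min(W, max(c) + w)
    crop <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    crop[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE
    # Euclidean dilation: ring pixels lie within distance w of the nucleus
    dil <- EBImage::distmap(!crop) <= w
    ring <- dil & !any_nucleus[r0:r1, c0:c1, drop = FALSE]
    ri <- which(ring)
    rr <- (ri - 1L) %% nrow(ring) + r0
    rc <- (ri - 1L) %/% nrow(ring) + c0
    doughnuts[[k]] <- (rc - 1L) * H + rr  # global linear indices
  }
  nset$doughnuts <- doughnuts
  attr(nset, "ring_width_px") <- w
  nset
}

#' Classify cells by marker density in the doughnut
#'
#' For each nucleus, `positive_density` is the fraction of doughnut pixels
#' positive in the marker mask, and the cell is called positive when that
#' density strictly exceeds the spec's threshold. Enlarging the marker mask
#' can therefore never flip a positive call to negative.
#'
#' @param nset a `nucleus_set` with doughnuts built.
#' @param marker_mask a [marker_mask()] in the same geometry.
#' @param spec a [doughnut_spec()].
#' @return The `nucleus_set` with columns `density_<marker>` and
#'   `positive_<marker>` appended to its `table`.
#' @export
classify_cells <- function(nset, marker_mask, spec = doughnut_spec()) {
  stopifnot(inherits(nset, "nucleus_set"), inherits(marker_mask, "marker_mask"))
  if (is.null(nset$doughnuts)) stop("build_doughnuts() must be called first")
  check_same_geometry(nset$mask, marker_mask, "nuclei and marker mask")
  n <- nrow(nset$table)
  dens <- numeric(n)
  for (k in seq_len(n)) {
    d <- nset$doughnuts[[k]]
    if (length(d) == 0) {
      stop("empty doughnut for nucleus ", k, "; cannot compute density")
    }
    dens[k] <- mean(marker_mask$pixels[d])
  }
  nset$table[[paste0("density_", marker_mask$label)]] <- dens
  nset$table[[paste0("positive_", marker_mask$label)]] <-
    dens > spec$density_threshold
  nset
}

#' Pearson correlation between cell-based and pixel-based counts
#'
#' Compares per-tile positive-cell counts against per-tile positive-pixel
#' counts for one marker using the Pearson product-moment coefficient. For
#' compact cells whose signal is perinuclear the two scale together; for
#' stellate cells whose stained processes lie far from the nucleus the
#' doughnut-based cell calls decouple from the pixel areas and the
#' correlation drops.
#'
#' @param cell_counts integer vector of positive-cell counts per tile.
#' @param pixel_counts integer vector of positive-pixel counts per tile.
#' @param marker marker label for the report.
#' @return A `tile_correlation_report`: list with `marker`, `n_tiles`,
#'   `pearson_r`.
#' @export
correlate_counts <- function(cell_counts, pixel_counts, marker = "marker") {
  if (length(cell_counts) != length(pixel_counts)) {
    stop("cell and pixel count series must have equal length")
  }
  n <- length(cell_counts)
  if (n < 3) stop("need at least 3 tiles for a correlation")
  if (stats::sd(cell_counts) == 0 || stats::sd(pixel_counts) == 0) {
    stop("undefined correlation: a count series is constant")
  }
  structure(
    list(
      marker = marker,
      n_tiles = n,
      pearson_r = stats::cor(cell_counts, pixel_counts)
    ),
    class = "tile_correlation_report"
  )
}

#' @export
print.tile_correlation_report <- function(x, ...) {
  cat(sprintf(
    "<tile_correlation_report> %s: r = %.3f over %d tiles\n",
    x$marker, x$pearson_r, x$n_tiles
  ))
  invisible(x)
}
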