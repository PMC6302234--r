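# Densities under region masks, tumor:stroma ratios, tumor-border nuclei,
# and Euclidean-distance-transform proximities.

#' Tumor border band specification
#'
#' Width of the inward band at the tumor edge (the "isometric line") whose
#' nuclei anchor the distance measurements.
#'
#' @param band_width_um band width in micrometers (default 10).
#' @return An object of class `border_band_spec`.
#' @export
border_band_spec <- function(band_width_um = 10) {
  stopifnot(band_width_um > 0)
  structure(list(band_width_um = band_width_um), class = "border_band_spec")
}

#' Density of a pixel class under a region mask
#'
#' The fraction of region pixels that are class-positive,
#' `|class & region| / |region|`. An empty region yields `NA` (undefined),
#' never zero.
#'
#' @param class_mask,region_mask [marker_mask()]s sharing geometry.
#' @return A fraction in `[0, 1]`, or `NA` for an empty region.
#' @export
density_under_mask <- function(class_mask, region_mask) {
  stopifnot(inherits(class_mask, "marker_mask"), inherits(region_mask, "marker_mask"))
  check_same_geometry(class_mask, region_mask, "class and region masks")
  n_region <- sum(region_mask$pixels)
  if (n_region == 0) return(NA_real_)
  sum(class_mask$pixels & region_mask$pixels) / n_region
}

#' Tumor to stroma density ratio for a pixel class
#'
#' Stroma is the tissue minus the tumor; the ratio is
#' `density(class, tumor) / density(class, stroma)`. It is `NA` (undefined)
#' when the stroma is empty or its class density is zero.
#'
#' @param class_mask the pixel-class [marker_mask()].
#' @param tumor_mask tumor region [marker_mask()]; must be contained in
#'   `tissue_mask`.
#' @param tissue_mask tissue region [marker_mask()].
#' @return A list with `ratio`, `tumor_density`, `stroma_density`.
#' @export
tumor_stroma_ratio <- function(class_mask, tumor_mask, tissue_mask) {
  check_same_geometry(tumor_mask, tissue_mask, "tumor and tissue masks")
  if (any(tumor_mask$pixels & !tissue_mask$pixels)) {
    stop("tumor mask extends outside the tissue mask")
  }
  stroma <- tissue_mask
  stroma$pixels <- tissue_mask$pixels & !tumor_mask$pixels
  stroma$label <- "stroma"
  dt <- density_under_mask(class_mask, tumor_mask)
  ds <- density_under_mask(class_mask, stroma)
  ratio <- if (is.na(ds) || is.na(dt) || ds == 0) NA_real_ else dt / ds
  list(ratio = ratio, tumor_density = dt, stroma_density = ds)
}

#' Select nuclei in the tumor border band
#'
#' Returns the nuclei whose centroid lies inside the tumor mask within
#' `band_width_um` of the tumor edge, measured by the inward Euclidean
#' distance from the boundary. The distance map is computed within the tile
#' only, so a tumor region cropped by the tile edge does not acquire an
#' artificial border there.
#'
#' @param nset a `nucleus_set` (see [segment_nuclei()]) in the same geometry
#'   as `tumor_mask`.
#' @param tumor_mask tumor [marker_mask()].
#' @param spec a [border_band_spec()].
#' @return The subset of `nset$table` rows in the band, with an added
#'   `border_distance_um` column.
#' @export
find_border_nuclei <- function(nset, tumor_mask, spec = border_band_spec()) {
  stopifnot(inherits(nset, "nucleus_set"), inherits(tumor_mask, "marker_mask"))
  check_same_geometry(nset$mask, tumor_mask, "nuclei and tumor mask")
  tab <- nset$table
  if (!any(tumor_mask$pixels) || nrow(tab) == 0) {
    out <- tab[integer(0), , drop = FALSE]
    out$border_distance_um <- numeric(0)
    return(out)
  }
  # inward distance: distance of tumor pixels to the nearest non-tumor pixel;
  # EBImage::distmap does not treat the image border as background
  d_in <- EBImage::distmap(tumor_mask$pixels) * tumor_mask$pixel_size_um
  ri <- pmin(pmax(round(tab$centroid_row) + 1, 1), nrow(d_in))
  ci <- pmin(pmax(round(tab$centroid_col) + 1, 1), ncol(d_in))
  inside <- tumor_mask$pixels[cbind(ri, ci)]
  dist_um <- d_in[cbind(ri, ci)]
  sel <- inside & dist_um <= spec$band_width_um
  out <- tab[sel, , drop = FALSE]
  out$border_distance_um <- dist_um[sel]
  rownames(out) <- NULL
  out
}

#' Distance from reference points to the nearest class-positive pixel
#'
#' Computes the Euclidean distance transform of the class mask's complement
#' and samples it at each reference point (rounded to the nearest pixel
#' center), returning distances in micrometers. A point on a positive pixel
#' has distance 0. An empty class mask yields `NA` (missing), never zero or
#' infinity.
#'
#' @param points Nx2 matrix of 0-based (row, col) pixel coordinates (e.g.
#'   nucleus centroids).
#' @param class_mask the pixel-class [marker_mask()].
#' @return Numeric vector of distances in um (NA if the mask is empty).
#' @export
nearest_class_distance <- function(points, class_mask) {
  stopifnot(inherits(class_mask, "marker_mask"))
  points <- base::matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  if (!any(class_mask$pixels)) return(rep(NA_real_, n))
  # distmap of the complement: at every pixel, distance to the nearest
  # positive pixel (0 on positives)
  d_px <- EBImage::distmap(!class_mask$pixels)
  ri <- pmin(pmax(round(points[, 1]) + 1, 1), nrow(d_px))
  ci <- pmin(pmax(round(points[, 2]) + 1, 1), ncol(d_px))
  as.numeric(d_px[cbind(ri, ci)]) * class_mask$pixel_size_um
}

#' Bin distances into the assay's 20-um histogram
#'
#' The first bin holds exact-contact distances (d = 0); subsequent bins are
#' half-open upper-inclusive intervals (0, 20], (20, 40], and so on, so a
#' distance of exactly 20 um falls in (0, 20]. Percentages are taken over
#' the measured (non-missing) distances and sum to 100 whenever any distance
#' was measured.
#'
#' @param distances_um numeric vector of distances in um; `NA`s are dropped
#'   and counted as missing.
#' @param bin_width_um bin width (default 20).
#' @param marker label for the histogram.
#' @return A `distance_histogram`: list with `marker`, `bins` (data frame of
#'   `bin_label`, `lower_um`, `upper_um`, `count`, `percent`), `n_measured`,
#'   `n_missing`, `mean_distance_um`.
#' @export
distance_histogram <- function(distances_um, bin_width_um = 20, marker = "class") {
  n_missing <- sum(is.na(distances_um))
  d <- distances_um[!is.na(distances_um)]
  if (any(d < 0)) stop("distances must be non-negative")
  n <- length(d)
  if (n == 0) {
    bins <- data.frame(
      bin_label = "0", lower_um = 0, upper_um = 0,
      count = 0L, percent = NA_real_
    )
    return(structure(
      list(marker = marker, bins = bins, n_measured = 0L,
           n_missing = n_missing, mean_distance_um = NA_real_,
           bin_width_um = bin_width_um),
      class = "distance_histogram"
    ))
  }
  contact <- d == 0
  k_max <- max(1, ceiling(max(d) / bin_width_um))
  k <- ceiling(d[!contact] / bin_width_um) # (0,w] -> 1, (w,2w] -> 2, ...
  counts <- c(sum(contact), tabulate(k, nbins = k_max))
  bins <- data.frame(
    bin_label = c("0", sprintf("(%g,%g]", (0:(k_max - 1)) * bin_width_um,
                               (1:k_max) * bin_width_um)),
    lower_um = c(0, (0:(k_max - 1)) * bin_width_um),
    upper_um = c(0, (1:k_max) * bin_width_um),
    count = as.integer(counts),
    percent = 100 * counts / n,
    stringsAsFactors = FALSE
  )
  structure(
    list(marker = marker, bins = bins, n_measured = n, n_missing = n_missing,
         mean_distance_um = mean(d), bin_width_um = bin_width_um),
    class = "distance_histogram"
  )
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf(
    "<distance_histogram> %s: n = %d (missing %d), mean %.1f um\n",
    x$marker, x$n_measured, x$n_missing, x$mean_distance_um
  ))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Per-tile density report for pixel classes over tumor / stroma / T cells
#'
#' Computes, for each marker mask, the density inside the tumor, in the
#' stroma (tissue minus tumor), underneath the T-cell mask, and the
#' tumor:stroma ratio.
#'
#' @param marker_masks named list of class [marker_mask()]s.
#' @param tumor_mask,tissue_mask region [marker_mask()]s; tumor must be
#'   contained in tissue.
#' @param tcell_mask optional CD3 [marker_mask()]; `NULL` skips the T-cell
#'   column.
#' @return A data frame with one row per marker: densities (fractions),
#'   region pixel counts and the ratio.
#' @export
density_report <- function(marker_masks, tumor_mask, tissue_mask,
                           tcell_mask = NULL) {
  stroma <- tissue_mask
  stroma$pixels <- tissue_mask$pixels & !tumor_mask$pixels
  rows <- lapply(names(marker_masks), function(mk) {
    m <- marker_masks[[mk]]
    rat <- tumor_stroma_ratio(m, tumor_mask, tissue_mask)
    data.frame(
      tile_id = m$tile_id,
      class_label = mk,
      tumor_density = rat$tumor_density,
      stroma_density = rat$stroma_density,
      tumor_stroma_ratio = rat$ratio,
      tcell_density = if (is.null(tcell_mask)) NA_real_ else
        density_under_mask(m, tcell_mask),
      tumor_px = sum(tumor_mask$pixels),
      stroma_px = sum(stroma$pixels),
      tcell_px = if (is.null(tcell_mask)) NA_integer_ else
        sum(tcell_mask$pixels),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
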