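# Thresholding, small-group filtering and pixel co-expression classes.

#' Thresholding and filtering specification
#'
#' Holds per-channel thresholds (a fixed intensity, or `"otsu"` for Otsu's
#' method), the minimum connected-group size, and the pixel connectivity used
#' by the small-group filter. The defaults implement the assay's rule that
#' pixel groups of fewer than 9 pixels are excluded; 8-connectivity is the
#' default because it matches the visual contiguity of thin stained
#' processes.
#'
#' @param thresholds named list mapping channel labels to a numeric intensity
#'   threshold or the string `"otsu"`.
#' @param min_group_size_px minimum connected-component size kept by
#'   [remove_small_groups()] (default 9).
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(thresholds = list(), min_group_size_px = 9,
                           connectivity = 8) {
  stopifnot(
    is.list(thresholds),
    min_group_size_px >= 1,
    connectivity %in% c(4, 8)
  )
  structure(
    list(
      thresholds = thresholds,
      min_group_size_px = as.integer(min_group_size_px),
      connectivity = as.integer(connectivity)
    ),
    class = "threshold_spec"
  )
}

# Resolve a threshold value for one channel. Otsu is computed on the image
# normalized to [0, 1] with a 256-level histogram and mapped back to native
# intensity units.
resolve_threshold <- function(image, spec, threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- spec$thresholds[[image$channel]]
    if (is.null(threshold)) {
      stop("no threshold configured for channel '", image$channel, "'")
    }
  }
  if (identical(threshold, "otsu")) {
    mx <- max(image$pixels)
    if (mx <= min(image$pixels)) {
      stop(
        "degenerate threshold: channel '", image$channel,
        "' is constant, Otsu's method is undefined"
      )
    }
    threshold <- EBImage::otsu(
      image$pixels / mx,
      range = c(0, 1), levels = 256
    ) * mx
  }
  if (!is.numeric(threshold) || length(threshold) != 1) {
    stop("threshold must be a single number or \"otsu\"")
  }
  threshold
}

#' Threshold a grayscale channel into a binary marker mask
#'
#' A pixel is positive iff its intensity is strictly greater than the
#' threshold, so an image everywhere equal to the threshold yields an empty
#' mask. Geometry and pixel size are preserved.
#'
#' @param image a [channel_image()].
#' @param spec a [threshold_spec()]; its entry for `image$channel` is used
#'   unless `threshold` is given.
#' @param threshold optional override: numeric intensity or `"otsu"`.
#' @return A [marker_mask()] labeled with the channel name.
#' @export
threshold_channel <- function(image, spec = threshold_spec(), threshold = NULL) {
  stopifnot(inherits(image, "channel_image"))
  thr <- resolve_threshold(image, spec, threshold)
  mask <- marker_mask(
    image$pixels > thr,
    image$pixel_size_um, image$channel, image$tile_id
  )
  attr(mask, "threshold") <- thr
  mask
}

#' Remove small connected pixel groups from a mask
#'
#' Clears every connected component (under the spec's connectivity) whose
#' size is below `min_group_size_px`; larger components are untouched. The
#' operation is idempotent and never increases the positive count.
#'
#' @param mask a [marker_mask()].
#' @param spec a [threshold_spec()] providing `min_group_size_px` and
#'   `connectivity`.
#' @return The filtered [marker_mask()].
#' @export
remove_small_groups <- function(mask, spec = threshold_spec()) {
  stopifnot(inherits(mask, "marker_mask"))
  if (!any(mask$pixels)) return(mask)
  lab <- .cc_label(mask$pixels, spec$connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes >= spec$min_group_size_px
  out <- matrix(FALSE, nrow(mask$pixels), ncol(mask$pixels))
  pos <- lab > 0L
  out[pos] <- keep[lab[pos]]
  mask$pixels <- out
  mask
}

#' Union of marker masks
#'
#' Logical OR of the input masks. The union of the CD68, CD163, CD11b and
#' CD11c masks is the MC&M mask, the reference area for pixel-class
#' percentages.
#'
#' @param masks list of [marker_mask()] objects sharing geometry.
#' @param label label for the result (default `"MCM_mask"`).
#' @return A [marker_mask()].
#' @export
union_masks <- function(masks, label = "MCM_mask") {
  stopifnot(is.list(masks), length(masks) >= 1)
  ref <- masks[[1]]
  acc <- matrix(FALSE, nrow(ref$pixels), ncol(ref$pixels))
  for (m in masks) {
    stopifnot(inherits(m, "marker_mask"))
    check_same_geometry(ref, m, "masks in union")
    acc <- acc | m$pixels
  }
  marker_mask(acc, ref$pixel_size_um, label, ref$tile_id)
}

#' Build the MC&M reference mask from per-marker masks
#'
#' @param marker_masks named list of [marker_mask()]s containing at least
#'   CD68, CD163, CD11b and CD11c. CD206 is deliberately excluded: it also
#'   stains vessels, so CD206 pixels are only counted after restriction to
#'   the MC&M mask.
#' @return The MC&M [marker_mask()].
#' @export
build_mcm_mask <- function(marker_masks) {
  missing <- setdiff(MCM_MASK_MARKERS, names(marker_masks))
  if (length(missing) > 0) {
    stop("missing marker masks for MC&M mask: ", paste(missing, collapse = ", "))
  }
  union_masks(marker_masks[MCM_MASK_MARKERS], label = "MCM_mask")
}

#' Restrict the CD206 mask to the MC&M mask
#'
#' CD206 also stains vessel structures outside the myeloid compartment; only
#' CD206-positive pixels underneath the MC&M mask are counted.
#'
#' @param cd206 the CD206 [marker_mask()].
#' @param mcm the MC&M reference [marker_mask()].
#' @return The intersected [marker_mask()] (label kept as `CD206`).
#' @export
restrict_cd206 <- function(cd206, mcm) {
  stopifnot(inherits(cd206, "marker_mask"), inherits(mcm, "marker_mask"))
  check_same_geometry(cd206, mcm, "CD206 and MC&M masks")
  cd206$pixels <- cd206$pixels & mcm$pixels
  cd206
}

# Pixel-class decomposition --------------------------------------------------

# Enumerate the canonical exclusive class labels for a marker set: all
# singles, pairs and triples (slash-joined in marker order), a residual
# "P4_5" for >= 4 colors, and "unlabeled" for reference pixels carrying no
# marker at all (possible when the reference is not the marker union).
class_schema <- function(markers) {
  labs <- character(0)
  ords <- integer(0)
  for (k in 1:min(3, length(markers))) {
    cmb <- utils::combn(markers, k)
    labs <- c(labs, apply(cmb, 2, paste, collapse = "/"))
    ords <- c(ords, rep(k, ncol(cmb)))
  }
  if (length(markers) >= 4) {
    labs <- c(labs, "P4_5")
    ords <- c(ords, 4L)
  }
  labs <- c(labs, "unlabeled")
  ords <- c(ords, 0L)
  data.frame(class_label = labs, n_colors = ords, stringsAsFactors = FALSE)
}

#' Decompose marker masks into exclusive pixel co-expression classes
#'
#' Every pixel of the reference mask is assigned the exact set of markers
#' that color it. The returned table reports exclusive single classes, the
#' pairwise double classes, the triple classes, a residual `P4_5` class
#' aggregating pixels with four or more colors, and an `unlabeled` row for
#' reference pixels with no marker (structurally empty when the reference is
#' the marker union). The exclusive classes partition the reference exactly.
#' A non-exclusive aggregate `P2_3_4_5` (all pixels with two or more colors)
#' is appended for multicolor reporting.
#'
#' @param marker_masks named list of [marker_mask()]s (typically the five
#'   MC&M markers, with CD206 already restricted via [restrict_cd206()]).
#' @param reference the reference [marker_mask()] (typically the MC&M mask).
#' @return A `pixel_class_table`: a data frame with columns `tile_id`,
#'   `reference_label`, `class_label`, `n_colors`, `exclusive`,
#'   `pixel_count`, `percent_of_reference`, and attribute
#'   `reference_pixel_count`. When the reference has zero positive pixels all
#'   percentages are `NA` (undefined, not zero).
#' @export
decompose_pixel_classes <- function(marker_masks, reference) {
  stopifnot(is.list(marker_masks), length(marker_masks) >= 1,
            !is.null(names(marker_masks)), inherits(reference, "marker_mask"))
  markers <- names(marker_masks)
  canon <- intersect(MCM_MARKERS, markers)
  markers <- c(canon, setdiff(markers, canon)) # canonical marker order first
  for (m in marker_masks) check_same_geometry(reference, m, "marker and reference masks")

  n_markers <- length(markers)
  if (n_markers > 16) stop("too many markers for bit-pattern decomposition")
  idx <- which(reference$pixels)
  code <- integer(length(idx))
  for (i in seq_len(n_markers)) {
    code <- code + bitwShiftL(1L, i - 1L) * as.integer(marker_masks[[markers[i]]]$pixels[idx])
  }
  pattern_counts <- tabulate(code + 1L, nbins = 2^n_markers)
  patterns <- 0:(2^n_markers - 1)
  popcount <- vapply(patterns, function(p) sum(bitwAnd(p, bitwShiftL(1L, 0:(n_markers - 1))) > 0), integer(1))
  pattern_label <- vapply(patterns, function(p) {
    paste(markers[bitwAnd(p, bitwShiftL(1L, 0:(n_markers - 1))) > 0], collapse = "/")
  }, character(1))

  schema <- class_schema(markers)
  count_for <- function(lab, ord) {
    if (lab == "P4_5") {
      sum(pattern_counts[popcount >= 4])
    } else if (lab == "unlabeled") {
      pattern_counts[1]
    } else {
      sum(pattern_counts[pattern_label == lab & popcount == ord])
    }
  }
  counts <- mapply(count_for, schema$class_label, schema$n_colors)
  ref_count <- length(idx)

  tab <- data.frame(
    tile_id = reference$tile_id,
    reference_label = reference$label,
    class_label = schema$class_label,
    n_colors = schema$n_colors,
    exclusive = TRUE,
    pixel_count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  # aggregate multicolor class (not part of the exclusive partition)
  tab <- rbind(tab, data.frame(
    tile_id = reference$tile_id,
    reference_label = reference$label,
    class_label = "P2_3_4_5",
    n_colors = NA_integer_,
    exclusive = FALSE,
    pixel_count = as.integer(sum(pattern_counts[popcount >= 2])),
    stringsAsFactors = FALSE
  ))
  tab$percent_of_reference <- if (ref_count > 0) {
    100 * tab$pixel_count / ref_count
  } else {
    NA_real_
  }
  attr(tab, "reference_pixel_count") <- ref_count
  attr(tab, "markers") <- markers
  class(tab) <- c("pixel_class_table", "data.frame")
  tab
}

#' Pixel-class breakdown underneath one anchor marker's mask
#'
#' Restricts the exclusive decomposition to the pixels of an anchor marker's
#' own mask (e.g. the classes underneath the CD68 mask or the CD163 mask):
#' the anchor single class, the anchor's pairs, the anchor's triples (such as
#' CD68/CD163/CD206), and the residual higher-order class, which together
#' partition the anchor mask.
#'
#' @param anchor anchor marker label (must be present in `marker_masks`).
#' @param marker_masks named list of [marker_mask()]s.
#' @return A `pixel_class_table` with reference = the anchor mask; classes
#'   not containing the anchor (structurally zero) are dropped.
#' @export
mask_class_breakdown <- function(anchor, marker_masks) {
  if (!anchor %in% names(marker_masks)) {
    stop("anchor marker '", anchor, "' not among marker masks")
  }
  ref <- marker_masks[[anchor]]
  ref$label <- paste0(anchor, "_mask")
  tab <- decompose_pixel_classes(marker_masks, ref)
  contains_anchor <- vapply(
    strsplit(tab$class_label, "/", fixed = TRUE),
    function(p) anchor %in% p, logical(1)
  )
  keep <- contains_anchor | tab$class_label %in% c("P4_5", "P2_3_4_5")
  out <- tab[keep, , drop = FALSE]
  attr(out, "reference_pixel_count") <- attr(tab, "reference_pixel_count")
  attr(out, "markers") <- attr(tab, "markers")
  class(out) <- class(tab)
  rownames(out) <- NULL
  out
}

#' Aggregate per-tile pixel-class tables into a case summary
#'
#' For each class label, the unweighted mean and the sample (n-1) standard
#' deviation of the per-tile percentages are computed across tiles. Tiles
#' with undefined percentages (empty reference mask) are excluded from the
#' mean and the per-class `n_tiles` is decremented accordingly.
#'
#' @param tables list of `pixel_class_table`s sharing a reference label and
#'   class schema.
#' @param case_id identifier for the aggregated case.
#' @return A `case_summary` data frame with columns `case_id`,
#'   `reference_label`, `class_label`, `mean_percent`, `sd_percent`,
#'   `n_tiles`.
#' @export
aggregate_case <- function(tables, case_id = "case") {
  if (!is.list(tables) || length(tables) == 0) {
    stop("aggregate_case: need at least one pixel_class_table")
  }
  ref_labels <- unique(vapply(tables, function(t) t$reference_label[1], character(1)))
  if (length(ref_labels) != 1) {
    stop("aggregate_case: tables mix reference labels: ",
         paste(ref_labels, collapse = ", "))
  }
  all_tab <- do.call(rbind, lapply(tables, as.data.frame))
  split_by <- split(all_tab, all_tab$class_label)
  out <- do.call(rbind, lapply(split_by, function(d) {
    v <- d$percent_of_reference[!is.na(d$percent_of_reference)]
    data.frame(
      case_id = case_id,
      reference_label = ref_labels,
      class_label = d$class_label[1],
      mean_percent = if (length(v) > 0) mean(v) else NA_real_,
      sd_percent = if (length(v) > 1) stats::sd(v) else if (length(v) == 1) 0 else NA_real_,
      n_tiles = length(v),
      stringsAsFactors = FALSE
    )
  }))
  # keep schema order of the first table
  out <- out[match(tables[[1]]$class_label, out$class_label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("case_summary", "data.frame")
  out
}
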