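# End-to-end orchestration: threshold -> filter -> pixel classes ->
# co-register -> transfer -> densities -> distances, over a case directory.

#' Pipeline configuration
#'
#' @param if_pixel_size_um,ihc_pixel_size_um pixel sizes of the fluorescent
#'   and chromogenic grids.
#' @param thresholds named list mapping channel labels to a numeric
#'   threshold or `"otsu"`; defaults to Otsu for every stained channel.
#' @param min_group_size_px,connectivity small-group filter parameters (see
#'   [threshold_spec()]).
#' @param nucleus a [nucleus_spec()].
#' @param doughnut a [doughnut_spec()].
#' @param border_band_um tumor border band width in um.
#' @param bin_width_um distance histogram bin width in um.
#' @param registration list: `per_case` (estimate one transform from the
#'   first tile and reuse it, the default) and `options`
#'   ([registration_options()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(
    if_pixel_size_um = 0.3, ihc_pixel_size_um = 0.5,
    thresholds = NULL,
    min_group_size_px = 9, connectivity = 8,
    nucleus = nucleus_spec(), doughnut = doughnut_spec(),
    border_band_um = 10, bin_width_um = 20,
    registration = list(per_case = TRUE, options = registration_options())) {
  if (is.null(thresholds)) {
    thresholds <- setNames(
      as.list(rep("otsu", length(CHANNEL_VOCABULARY))), CHANNEL_VOCABULARY
    )
  }
  bad <- setdiff(names(thresholds), CHANNEL_VOCABULARY)
  if (length(bad) > 0) {
    stop("unknown channel labels in thresholds: ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      if_pixel_size_um = if_pixel_size_um,
      ihc_pixel_size_um = ihc_pixel_size_um,
      thresholds = thresholds,
      min_group_size_px = min_group_size_px,
      connectivity = connectivity,
      nucleus = nucleus,
      doughnut = doughnut,
      border_band_um = border_band_um,
      bin_width_um = bin_width_um,
      registration = registration
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [pipeline_config()];
#' missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("if_pixel_size_um", "ihc_pixel_size_um", "thresholds",
              "min_group_size_px", "connectivity", "border_band_um",
              "bin_width_um")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$doughnut)) {
    args$doughnut <- do.call(doughnut_spec, y$doughnut)
  }
  if (!is.null(y$nucleus)) {
    args$nucleus <- do.call(nucleus_spec, y$nucleus)
  }
  if (!is.null(y$registration)) {
    reg <- list(per_case = isTRUE(y$registration$per_case),
                options = registration_options())
    args$registration <- reg
  }
  do.call(pipeline_config, args)
}

find_channel_file <- function(tile_dir, channel) {
  hits <- list.files(tile_dir, pattern = paste0("_", channel, "\\.tif$"),
                     full.names = TRUE)
  hits <- hits[!grepl("_truth_", basename(hits))]
  if (length(hits) == 0) return(NULL)
  sort(hits)[1]
}

# One tile: returns list(outputs, warnings) or signals an error.
process_tile <- function(tile_dir, out_dir, config, case_state) {
  tile_id <- basename(tile_dir)
  warnings <- character(0)
  tspec <- threshold_spec(config$thresholds, config$min_group_size_px,
                          config$connectivity)

  read_if <- function(channel) {
    f <- find_channel_file(tile_dir, channel)
    if (is.null(f)) return(NULL)
    read_channel_tiff(f, config$if_pixel_size_um, channel, tile_id)
  }
  read_ihc <- function(channel) {
    f <- find_channel_file(tile_dir, channel)
    if (is.null(f)) return(NULL)
    read_channel_tiff(f, config$ihc_pixel_size_um, channel, tile_id)
  }

  # --- marker masks -----------------------------------------------------
  masks <- list()
  for (mk in MCM_MARKERS) {
    ch <- read_if(mk)
    if (is.null(ch)) stop("missing required channel ", mk, " in ", tile_dir)
    masks[[mk]] <- remove_small_groups(threshold_channel(ch, tspec), tspec)
  }
  mcm <- build_mcm_mask(masks)
  masks$CD206 <- restrict_cd206(masks$CD206, mcm)

  tile_out <- file.path(out_dir, "tiles", tile_id)
  dir.create(tile_out, recursive = TRUE, showWarnings = FALSE)
  for (mk in MCM_MARKERS) {
    write_mask_tiff(masks[[mk]], file.path(tile_out, paste0(mk, "_mask.tif")))
  }
  write_mask_tiff(mcm, file.path(tile_out, "MCM_mask.tif"))

  classes <- decompose_pixel_classes(masks, mcm)
  write.csv(classes, file.path(tile_out, "pixel_classes_MCM.csv"), row.names = FALSE)
  breakdowns <- list()
  for (anchor in c("CD68", "CD163")) {
    breakdowns[[anchor]] <- mask_class_breakdown(anchor, masks)
    write.csv(breakdowns[[anchor]],
              file.path(tile_out, sprintf("pixel_classes_%s.csv", anchor)),
              row.names = FALSE)
  }

  # --- nuclear phenotyping ---------------------------------------------
  dapi <- read_if("DAPI")
  nset <- NULL
  if (is.null(dapi)) {
    warnings <- c(warnings, "missing DAPI channel; cell phenotyping skipped")
  } else {
    nset <- segment_nuclei(dapi, config$nucleus)
    if (nrow(nset$table) > 0) {
      nset <- build_doughnuts(nset, config$doughnut)
      for (mk in MCM_MARKERS) {
        nset <- classify_cells(nset, masks[[mk]], config$doughnut)
      }
    }
    write.csv(nset$table, file.path(tile_out, "cells.csv"), row.names = FALSE)
    write_mask_tiff(nset$mask, file.path(tile_out, "nuclear_mask.tif"))
  }

  # --- co-registration and region masks --------------------------------
  hema <- read_ihc("hematoxylin")
  region_results <- NULL
  if (is.null(hema) || is.null(dapi)) {
    warnings <- c(warnings,
                  "missing hematoxylin or DAPI; co-registration and region analyses skipped")
  } else {
    if (isTRUE(config$registration$per_case) && !is.null(case_state$transform)) {
      transform <- case_state$transform
      quality <- case_state$quality
    } else {
      reg <- estimate_affine(hema, dapi, config$registration$options)
      transform <- reg$transform
      quality <- reg$quality
      if (isTRUE(config$registration$per_case)) {
        case_state$transform <- transform
        case_state$quality <- quality
      }
    }
    write_transform_json(transform, file.path(tile_out, "transform.json"), quality)

    target_dim <- dim(dapi$pixels)
    ck_masks <- list()
    for (ck in c("HMW_CK", "LMW_CK")) {
      ch <- read_ihc(ck)
      if (!is.null(ch)) {
        ck_masks[[ck]] <- threshold_channel(ch, tspec)
      }
    }
    if (length(ck_masks) == 0) {
      warnings <- c(warnings, "missing cytokeratin channels; tumor analyses skipped")
    } else {
      tumor_ihc <- remove_small_groups(
        union_masks(ck_masks, label = "tumor"), tspec
      )
      tr <- transfer_mask(tumor_ihc, transform, target_dim)
      tumor_if <- tr$mask
      tissue_if <- tr$coverage # the co-registered area
      cd3_if <- NULL
      cd3_ch <- read_ihc("CD3")
      if (is.null(cd3_ch)) {
        warnings <- c(warnings, "missing CD3 channel; T-cell analyses skipped")
      } else {
        cd3_ihc <- remove_small_groups(threshold_channel(cd3_ch, tspec), tspec)
        cd3_if <- transfer_mask(cd3_ihc, transform, target_dim)$mask
      }
      write_mask_tiff(tumor_if, file.path(tile_out, "tumor_mask_if.tif"))
      if (!is.null(cd3_if)) {
        write_mask_tiff(cd3_if, file.path(tile_out, "tcell_mask_if.tif"))
      }

      class_masks4 <- masks[MCM_MASK_MARKERS]
      dens <- density_report(class_masks4, tumor_if, tissue_if, cd3_if)
      write.csv(dens, file.path(tile_out, "densities.csv"), row.names = FALSE)

      distances <- NULL
      if (!is.null(nset) && nrow(nset$table) > 0) {
        border <- find_border_nuclei(nset, tumor_if,
                                     border_band_spec(config$border_band_um))
        if (nrow(border) > 0) {
          pts <- cbind(border$centroid_row, border$centroid_col)
          distances <- data.frame(tile_id = tile_id,
                                  nucleus_id = border$nucleus_id)
          for (mk in MCM_MASK_MARKERS) {
            distances[[paste0("dist_", mk, "_um")]] <-
              nearest_class_distance(pts, masks[[mk]])
          }
        } else {
          warnings <- c(warnings, "no nuclei in the tumor border band")
        }
        if (!is.null(distances)) {
          write.csv(distances, file.path(tile_out, "border_distances.csv"),
                    row.names = FALSE)
        }
      }
      region_results <- list(densities = dens, distances = distances)
    }
  }

  list(
    tile_id = tile_id,
    classes = classes,
    breakdowns = breakdowns,
    region = region_results,
    warnings = warnings,
    out_dir = tile_out,
    case_state = case_state
  )
}

#' Run the full analysis pipeline over a case directory
#'
#' Processes every tile subdirectory of `tiles_dir` through the fixed stage
#' order (threshold, small-group filter, pixel classes, nuclear
#' phenotyping, co-registration, mask transfer, densities, border-nucleus
#' distances), writes per-tile and case-level CSV/TIFF/JSON outputs under
#' `out_dir`, and returns a run manifest. A tile failing a stage is excluded
#' downstream with a logged reason, never silently; the pipeline errors only
#' if no tile survives.
#'
#' @param tiles_dir directory containing one subdirectory per tile (as
#'   written by [write_synthetic_case()], or equivalently named real data:
#'   `<tile>_<channel>.tif`).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return The run manifest (also written to `manifest.json`): config echo,
#'   package version, per-tile status and warnings, output checksums.
#' @export
run_pipeline <- function(tiles_dir, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  tile_dirs <- sort(list.dirs(tiles_dir, recursive = FALSE))
  if (length(tile_dirs) == 0) {
    stop("pipeline error: no tile subdirectories under ", tiles_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  statuses <- list()
  class_tables <- list()
  breakdown_tables <- list(CD68 = list(), CD163 = list())
  density_tables <- list()
  distance_tables <- list()
  case_state <- list(transform = NULL, quality = NULL)

  for (td in tile_dirs) {
    tid <- basename(td)
    res <- tryCatch(
      process_tile(td, out_dir, config, case_state),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      statuses[[tid]] <- list(status = "failed", warnings = conditionMessage(res))
      next
    }
    case_state <- res$case_state
    statuses[[tid]] <- list(
      status = "complete",
      warnings = if (length(res$warnings)) res$warnings else character(0)
    )
    class_tables[[tid]] <- res$classes
    for (anchor in names(res$breakdowns)) {
      breakdown_tables[[anchor]][[tid]] <- res$breakdowns[[anchor]]
    }
    if (!is.null(res$region)) {
      density_tables[[tid]] <- res$region$densities
      if (!is.null(res$region$distances)) {
        distance_tables[[tid]] <- res$region$distances
      }
    }
  }
  ok <- vapply(statuses, function(s) s$status == "complete", logical(1))
  if (!any(ok)) {
    stop("pipeline error: zero tiles completed (",
         paste(vapply(statuses, function(s) s$warnings[1], character(1)),
               collapse = "; "), ")")
  }

  case_id <- basename(normalizePath(tiles_dir))
  case_dir <- file.path(out_dir, "case")
  dir.create(case_dir, showWarnings = FALSE)
  summ <- aggregate_case(class_tables, case_id)
  write.csv(summ, file.path(case_dir, "case_pixel_classes_MCM.csv"),
            row.names = FALSE)
  for (anchor in names(breakdown_tables)) {
    if (length(breakdown_tables[[anchor]]) > 0) {
      write.csv(
        aggregate_case(breakdown_tables[[anchor]], case_id),
        file.path(case_dir, sprintf("case_pixel_classes_%s.csv", anchor)),
        row.names = FALSE
      )
    }
  }
  if (length(density_tables) > 0) {
    all_dens <- do.call(rbind, density_tables)
    write.csv(all_dens, file.path(case_dir, "case_densities.csv"),
              row.names = FALSE)
  }
  if (length(distance_tables) > 0) {
    all_dist <- do.call(rbind, distance_tables)
    write.csv(all_dist, file.path(case_dir, "case_border_distances.csv"),
              row.names = FALSE)
    hist_rows <- list()
    for (mk in MCM_MASK_MARKERS) {
      h <- distance_histogram(all_dist[[paste0("dist_", mk, "_um")]],
                              config$bin_width_um, mk)
      if (h$n_measured > 0) {
        hb <- h$bins
        hb$marker <- mk
        hb$n_measured <- h$n_measured
        hb$mean_distance_um <- h$mean_distance_um
        hist_rows[[mk]] <- hb
      }
    }
    if (length(hist_rows) > 0) {
      write.csv(do.call(rbind, hist_rows),
                file.path(case_dir, "case_distance_histograms.csv"),
                row.names = FALSE)
    }
  }

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  checksums <- tools::md5sum(outputs)
  names(checksums) <- substring(outputs, nchar(out_dir) + 2) # paths relative to out_dir
  manifest <- list(
    package_version = as.character(utils::packageVersion("pixelplex")),
    case_id = case_id,
    config = unclass(config),
    tiles = statuses,
    checksums = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Build summary tables and figures from pipeline outputs
#'
#' Emits case-level pie-chart fraction tables for the MC&M pixel classes and
#' the CD68/CD163 breakdowns, a density/ratio bar table, the distance
#' histograms with mean distances, and ggplot figures (stacked class bars,
#' density bars, distance histograms). Missing stage outputs are listed as
#' absent rather than failing the report.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @param report_dir destination for report files (default
#'   `file.path(out_dir, "report")`).
#' @return Character vector of written files, invisibly.
#' @export
make_report <- function(out_dir, report_dir = file.path(out_dir, "report")) {
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
  case_dir <- file.path(out_dir, "case")
  written <- character(0)
  absent <- character(0)

  read_or_na <- function(name) {
    f <- file.path(case_dir, name)
    if (file.exists(f)) read.csv(f, stringsAsFactors = FALSE) else NULL
  }

  for (name in c("case_pixel_classes_MCM.csv", "case_pixel_classes_CD68.csv",
                 "case_pixel_classes_CD163.csv")) {
    tab <- read_or_na(name)
    if (is.null(tab)) {
      absent <- c(absent, name)
      next
    }
    pie <- tab[tab$class_label != "unlabeled" &
                 tab$class_label != "P2_3_4_5" &
                 !is.na(tab$mean_percent), ]
    out <- file.path(report_dir, sub("^case_", "pie_", name))
    write.csv(pie[, c("class_label", "mean_percent", "sd_percent", "n_tiles")],
              out, row.names = FALSE)
    written <- c(written, out)
    keep <- pie[pie$mean_percent > 0, ]
    if (nrow(keep) > 0) {
      p <- ggplot2::ggplot(keep, ggplot2::aes(
        x = "", y = mean_percent, fill = class_label
      )) +
        ggplot2::geom_col(width = 1) +
        ggplot2::coord_polar(theta = "y") +
        ggplot2::labs(title = sub("\\.csv$", "", sub("^case_", "", name)),
                      x = NULL, y = "mean percent of reference") +
        ggplot2::theme_minimal()
      fig <- sub("\\.csv$", ".png", out)
      ggplot2::ggsave(fig, p, width = 6, height = 5, dpi = 120)
      written <- c(written, fig)
    }
  }

  dens <- read_or_na("case_densities.csv")
  if (is.null(dens)) {
    absent <- c(absent, "case_densities.csv")
  } else {
    agg <- stats::aggregate(
      cbind(tumor_density, stroma_density, tumor_stroma_ratio) ~ class_label,
      data = dens, FUN = mean, na.rm = TRUE, na.action = stats::na.pass
    )
    out <- file.path(report_dir, "density_summary.csv")
    write.csv(agg, out, row.names = FALSE)
    written <- c(written, out)
    long <- data.frame(
      class_label = rep(agg$class_label, 2),
      region = rep(c("tumor", "stroma"), each = nrow(agg)),
      density = c(agg$tumor_density, agg$stroma_density)
    )
    p <- ggplot2::ggplot(long, ggplot2::aes(class_label, density, fill = region)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = "pixel density (fraction of region)", x = NULL) +
      ggplot2::theme_minimal()
    fig <- file.path(report_dir, "density_summary.png")
    ggplot2::ggsave(fig, p, width = 6, height = 4, dpi = 120)
    written <- c(written, fig)
  }

  hists <- read_or_na("case_distance_histograms.csv")
  if (is.null(hists)) {
    absent <- c(absent, "case_distance_histograms.csv")
  } else {
    out <- file.path(report_dir, "distance_histograms.csv")
    write.csv(hists, out, row.names = FALSE)
    mean_tab <- unique(hists[, c("marker", "n_measured", "mean_distance_um")])
    out2 <- file.path(report_dir, "mean_distances.csv")
    write.csv(mean_tab, out2, row.names = FALSE)
    hists$bin_label <- factor(hists$bin_label, levels = unique(hists$bin_label))
    p <- ggplot2::ggplot(hists, ggplot2::aes(bin_label, percent)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~marker) +
      ggplot2::labs(x = "distance bin (um)", y = "percent of measured nuclei") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    fig <- file.path(report_dir, "distance_histograms.png")
    ggplot2::ggsave(fig, p, width = 7, height = 5, dpi = 120)
    written <- c(written, out, out2, fig)
  }

  if (length(absent) > 0) {
    writeLines(absent, file.path(report_dir, "ABSENT_OUTPUTS.txt"))
  }
  invisible(written)
}
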