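# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (per-pixel enumeration, exhaustive minima, flood fill)
# and share no code with the implementation paths they check.

mk_mask <- function(m, psz = 0.3, label = "m", tile_id = "t") {
  marker_mask(m, psz, label, tile_id)
}

random_mask <- function(h = 64, w = 64, p = 0.2, psz = 0.3, label = "m") {
  marker_mask(matrix(runif(h * w) < p, h, w), psz, label, "t")
}

# mask with a rasterized disk (center 0-based, inclusion d <= r)
disk_matrix <- function(h, w, cr, cc, r) {
  rows <- matrix(0:(h - 1), h, w)
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}

# Oracle 1: pixel-class counts by explicit enumeration of all 2^k color
# patterns, intersecting masks pattern by pattern.
oracle_class_counts <- function(masks, reference) {
  k <- length(masks)
  markers <- names(masks)
  out <- list()
  for (code in 0:(2^k - 1)) {
    inset <- as.logical(bitwAnd(code, 2^(0:(k - 1))))
    sel <- reference$pixels
    for (j in seq_len(k)) {
      sel <- sel & (if (inset[j]) masks[[j]]$pixels else !masks[[j]]$pixels)
    }
    lab <- paste(markers[inset], collapse = "/")
    if (lab == "") lab <- "unlabeled"
    out[[lab]] <- sum(sel) + (out[[lab]] %||% 0)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Oracle 2: exhaustive nearest-positive-pixel distance from one point.
oracle_min_distance <- function(point, mask) {
  idx <- which(mask$pixels)
  if (length(idx) == 0) return(NA_real_)
  r0 <- (idx - 1) %% nrow(mask$pixels)
  c0 <- (idx - 1) %/% nrow(mask$pixels)
  min(sqrt((r0 - round(point[1]))^2 + (c0 - round(point[2]))^2)) *
    mask$pixel_size_um
}

# Oracle 3: connected-component sizes by queue-based flood fill.
oracle_component_sizes <- function(m, connectivity = 8) {
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  nbrs <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  sizes <- integer(0)
  for (start in which(m & !seen)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      ci <- (cur - 1) %% h + 1
      cj <- (cur - 1) %/% h + 1
      for (n in seq_len(nrow(nbrs))) {
        ni <- ci + nbrs[n, 1]; nj <- cj + nbrs[n, 2]
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            m[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue <- c(queue, (nj - 1) * h + ni)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# small compact-cell configuration used by several tests
small_sim_config <- function(seed = 11, ...) {
  simulation_config(
    tile_height_px = 192, tile_width_px = 192,
    n_tumor_regions = 1, tumor_area_fraction = 0.2,
    n_tcells = 5, n_macrophages = 8, n_myeloid = 0, n_tumor_nuclei = 6,
    seed = seed, ...
  )
}

# fixed midpoint thresholds for the simulator's two-level noise model
sim_threshold_spec <- function(cfg, channels = MCM_MARKERS) {
  thr <- (cfg$noise$if_background + cfg$noise$if_signal) / 2
  threshold_spec(setNames(as.list(rep(thr, length(channels))), channels))
}
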