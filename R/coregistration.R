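# Affine co-registration of chromogenic (IHC) and fluorescent (IF) tiles
# from nuclear counterstain intensities, and mask transfer across grids.
#
# Transforms act on physical (um) coordinates (row_um, col_um), mapping
# points in the source (chromogenic) frame to the target (fluorescent)
# frame. Pixel-size harmonization is folded into the transform.

#' 2-D affine transform between tile geometries
#'
#' @param matrix a 2x3 matrix `[A | t]` mapping source-frame physical
#'   coordinates (row_um, col_um) to target-frame coordinates:
#'   `p_target = A %*% p_source + t`.
#' @param source_pixel_size_um pixel size of the source (e.g. chromogenic)
#'   grid.
#' @param target_pixel_size_um pixel size of the target (e.g. fluorescent)
#'   grid.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, source_pixel_size_um, target_pixel_size_um) {
  matrix <- base::matrix(as.numeric(matrix), 2, 3)
  if (abs(det(matrix[, 1:2])) < 1e-12) {
    stop("degenerate affine transform: linear part is singular")
  }
  stopifnot(source_pixel_size_um > 0, target_pixel_size_um > 0)
  structure(
    list(
      matrix = matrix,
      source_pixel_size_um = source_pixel_size_um,
      target_pixel_size_um = target_pixel_size_um
    ),
    class = "affine_transform"
  )
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf(
    "<affine_transform> %g um/px -> %g um/px\n",
    x$source_pixel_size_um, x$target_pixel_size_um
  ))
  print(x$matrix)
  invisible(x)
}

#' Build a rigid (rotation + translation, optional scale) transform
#'
#' Rotation is about `center_um` in the source frame; `offset_um` shifts the
#' source center onto the target frame (so two fields of view with different
#' extents can be center-aligned), and `translation_um` is the residual
#' translation.
#'
#' @param rotation_deg rotation angle in degrees (positive rotates row
#'   toward col).
#' @param translation_um length-2 numeric, (row, col) translation in um.
#' @param center_um rotation center in source-frame um.
#' @param target_center_um point in the target frame that `center_um` maps
#'   to before translation (defaults to `center_um`).
#' @param scale isotropic scale factor (default 1).
#' @inheritParams affine_transform
#' @return An [affine_transform()].
#' @export
rigid_transform <- function(rotation_deg = 0, translation_um = c(0, 0),
                            center_um = c(0, 0), target_center_um = center_um,
                            scale = 1,
                            source_pixel_size_um = 1, target_pixel_size_um = 1) {
  th <- rotation_deg * pi / 180
  A <- scale * base::matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t <- as.numeric(target_center_um) + as.numeric(translation_um) -
    A %*% as.numeric(center_um)
  affine_transform(cbind(A, t), source_pixel_size_um, target_pixel_size_um)
}

#' Apply an affine transform to points
#' @param transform an [affine_transform()].
#' @param points Nx2 matrix of (row_um, col_um) source-frame points.
#' @return Nx2 matrix of target-frame points.
#' @export
apply_affine <- function(transform, points) {
  points <- base::matrix(as.numeric(points), ncol = 2)
  t(transform$matrix[, 1:2] %*% t(points) + transform$matrix[, 3])
}

#' Invert an affine transform
#' @param transform an [affine_transform()].
#' @return The inverse [affine_transform()] (pixel sizes swapped).
#' @export
invert_affine <- function(transform) {
  A <- transform$matrix[, 1:2]
  Ainv <- solve(A)
  affine_transform(
    cbind(Ainv, -Ainv %*% transform$matrix[, 3]),
    transform$target_pixel_size_um,
    transform$source_pixel_size_um
  )
}

# Sampling -------------------------------------------------------------------

# Sample a matrix at continuous 0-based pixel coordinates. Out-of-field
# points return NA. `bilinear = FALSE` gives nearest-neighbor sampling
# (binary masks are preserved).
sample_at <- function(img, r_px, c_px, bilinear = TRUE) {
  H <- nrow(img); W <- ncol(img)
  out <- rep(NA_real_, length(r_px))
  R <- r_px + 1; C <- c_px + 1
  valid <- R >= 1 & R <= H & C >= 1 & C <= W &
    is.finite(R) & is.finite(C)
  if (!any(valid)) return(out)
  R <- R[valid]; C <- C[valid]
  if (bilinear) {
    i0 <- pmin(pmax(floor(R), 1), max(H - 1, 1))
    j0 <- pmin(pmax(floor(C), 1), max(W - 1, 1))
    fi <- R - i0
    fj <- C - j0
    i1 <- pmin(i0 + 1, H)
    j1 <- pmin(j0 + 1, W)
    v <- img[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
      img[cbind(i1, j0)] * fi * (1 - fj) +
      img[cbind(i0, j1)] * (1 - fi) * fj +
      img[cbind(i1, j1)] * fi * fj
  } else {
    i0 <- pmin(pmax(round(R), 1), H)
    j0 <- pmin(pmax(round(C), 1), W)
    v <- img[cbind(i0, j0)]
  }
  out[valid] <- as.numeric(v)
  out
}

# Render a source image onto a target grid by pulling back target pixel
# centers through `pullback` (a 2x3 matrix mapping target um -> source um).
# Returns values (NA outside the source field) and a coverage matrix.
pullback_resample <- function(src, src_psz, pullback, target_dim, target_psz,
                              bilinear = TRUE, stride = 1) {
  H <- target_dim[1]; W <- target_dim[2]
  rows0 <- seq(0, H - 1, by = stride)
  cols0 <- seq(0, W - 1, by = stride)
  g <- expand.grid(r = rows0, c = cols0)
  p_um <- cbind(g$r * target_psz, g$c * target_psz)
  q_um <- t(pullback[, 1:2] %*% t(p_um) + pullback[, 3])
  v <- sample_at(src, q_um[, 1] / src_psz, q_um[, 2] / src_psz, bilinear)
  vals <- base::matrix(v, length(rows0), length(cols0))
  list(values = vals, covered = !is.na(vals), rows0 = rows0, cols0 = cols0)
}

#' Transfer a binary mask into a target geometry
#'
#' Resamples a mask from its source grid into a target grid through an
#' affine transform, using nearest-neighbor interpolation so the mask stays
#' binary. Target pixels whose pull-back falls outside the source field are
#' negative in the mask and marked in the returned `coverage` mask, which
#' delimits the co-registered area.
#'
#' @param mask a [marker_mask()] in the transform's source geometry.
#' @param transform an [affine_transform()] mapping source um to target um.
#' @param target_dim integer (rows, cols) of the target grid.
#' @param target_pixel_size_um pixel size of the target grid; defaults to
#'   the transform's `target_pixel_size_um`.
#' @return A list with `mask` (the transferred [marker_mask()]) and
#'   `coverage` (a [marker_mask()] of the co-registered area).
#' @export
transfer_mask <- function(mask, transform, target_dim,
                          target_pixel_size_um = transform$target_pixel_size_um) {
  stopifnot(inherits(mask, "marker_mask"), inherits(transform, "affine_transform"))
  pb <- invert_affine(transform)$matrix
  rs <- pullback_resample(
    mask$pixels * 1.0, mask$pixel_size_um, pb,
    target_dim, target_pixel_size_um, bilinear = FALSE
  )
  vals <- rs$values
  vals[is.na(vals)] <- 0
  list(
    mask = marker_mask(vals > 0, target_pixel_size_um, mask$label, mask$tile_id),
    coverage = marker_mask(rs$covered, target_pixel_size_um,
                           "coregistered_area", mask$tile_id)
  )
}

# Registration ---------------------------------------------------------------

# Integer-pixel translation between two equally sized matrices by phase
# correlation; returns (dr, dc) such that shifting `g` by (dr, dc) best
# aligns it with `f`.
phase_correlation_shift <- function(f, g) {
  Ff <- stats::fft(f)
  Fg <- stats::fft(g)
  R <- Ff * Conj(Fg)
  R <- R / (Mod(R) + 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE))
  k <- which.max(r)
  nr <- nrow(f); nc <- ncol(f)
  dr <- (k - 1) %% nr
  dc <- (k - 1) %/% nr
  if (dr > nr / 2) dr <- dr - nr
  if (dc > nc / 2) dc <- dc - nc
  c(dr, dc)
}

ncc_of <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 32) return(-1)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-1)
  stats::cor(a, b)
}

#' Registration options
#'
#' @param rotation_grid_deg rotations tried during deterministic multi-start
#'   initialization.
#' @param smooth_sigma_px Gaussian smoothing (fixed-grid pixels) applied to
#'   both counterstains before correlation.
#' @param stride subsampling stride of the fixed grid used in the objective
#'   (default 2; full resolution costs ~4x more).
#' @param ncc_floor minimum acceptable normalized cross-correlation at the
#'   optimum; below it the registration fails loudly rather than silently.
#' @param maxit Nelder-Mead iteration budget for the affine refinement.
#' @return A list of options for [estimate_affine()].
#' @export
registration_options <- function(rotation_grid_deg = seq(-10, 10, by = 2.5),
                                 smooth_sigma_px = 2, stride = 2,
                                 ncc_floor = 0.2, maxit = 250) {
  list(
    rotation_grid_deg = rotation_grid_deg,
    smooth_sigma_px = smooth_sigma_px,
    stride = as.integer(stride),
    ncc_floor = ncc_floor,
    maxit = as.integer(maxit)
  )
}

#' Estimate the affine transform between chromogenic and fluorescent tiles
#'
#' Registers the hematoxylin rendition of a tile (moving, chromogenic grid)
#' onto its DAPI rendition (fixed, fluorescent grid) by maximizing the
#' normalized cross-correlation of the smoothed nuclear intensities. The
#' procedure is deterministic: a fixed rotation grid is scanned, each
#' candidate's translation is initialized by phase correlation, and the best
#' candidate's six affine parameters are refined by Nelder-Mead.
#'
#' @param moving hematoxylin [channel_image()] (source / chromogenic grid).
#' @param fixed DAPI [channel_image()] (target / fluorescent grid).
#' @param options see [registration_options()].
#' @return A list with `transform` (an [affine_transform()] mapping moving
#'   um to fixed um) and `quality` (list with `ncc` at the optimum).
#' @export
estimate_affine <- function(moving, fixed, options = registration_options()) {
  stopifnot(inherits(moving, "channel_image"), inherits(fixed, "channel_image"))
  norm01 <- function(x) {
    mx <- max(x); mn <- min(x)
    if (mx <= mn) stop("registration failure: constant counterstain image")
    (x - mn) / (mx - mn)
  }
  psz_f <- fixed$pixel_size_um
  psz_m <- moving$pixel_size_um
  f <- EBImage::gblur(norm01(fixed$pixels), sigma = options$smooth_sigma_px)
  m <- EBImage::gblur(norm01(moving$pixels),
                      sigma = options$smooth_sigma_px * psz_f / psz_m)
  dim_f <- dim(f)
  c_f <- (dim_f - 1) / 2 * psz_f
  c_m <- (dim(m) - 1) / 2 * psz_m

  make_transform <- function(A, t) {
    affine_transform(cbind(A, c_f + t - A %*% c_m), psz_m, psz_f)
  }
  # strided fixed-grid sample points, shared by all NCC evaluations
  stride <- options$stride
  rows0 <- seq(0, dim_f[1] - 1, by = stride)
  cols0 <- seq(0, dim_f[2] - 1, by = stride)
  grid <- expand.grid(r = rows0, c = cols0)
  p_um <- cbind(grid$r * psz_f, grid$c * psz_f)
  f_sub <- as.numeric(f[cbind(grid$r + 1, grid$c + 1)])
  ncc_for <- function(A, t) {
    tr <- cbind(A, c_f + t - A %*% c_m)
    Ainv <- solve(tr[, 1:2])
    q_um <- t(Ainv %*% t(p_um) - as.numeric(Ainv %*% tr[, 3]))
    mv <- sample_at(m, q_um[, 1] / psz_m, q_um[, 2] / psz_m, bilinear = TRUE)
    ncc_of(f_sub, mv)
  }

  # deterministic multi-start: rotation grid + phase-correlation translation
  best <- NULL
  for (th in options$rotation_grid_deg) {
    rad <- th * pi / 180
    A0 <- base::matrix(c(cos(rad), sin(rad), -sin(rad), cos(rad)), 2, 2)
    pb <- invert_affine(make_transform(A0, c(0, 0)))$matrix
    rs <- pullback_resample(m, psz_m, pb, dim_f, psz_f, bilinear = TRUE)
    g <- rs$values
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    sh <- phase_correlation_shift(f, g) * psz_f
    v <- ncc_for(A0, sh)
    if (is.null(best) || v > best$ncc) best <- list(A = A0, t = sh, ncc = v)
  }

  # Nelder-Mead refinement of the six affine parameters
  par0 <- c(as.numeric(best$A), as.numeric(best$t))
  obj <- function(par) {
    A <- base::matrix(par[1:4], 2, 2)
    if (abs(det(A)) < 1e-6) return(2)
    -ncc_for(A, par[5:6])
  }
  nm_control <- list(
    maxit = options$maxit,
    parscale = c(rep(0.02, 4), rep(psz_f, 2)),
    reltol = 1e-9
  )
  fit <- stats::optim(par0, obj, method = "Nelder-Mead", control = nm_control)
  # restart once from the optimum: a fresh simplex escapes the degenerate
  # simplices Nelder-Mead can collapse into before full convergence
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead", control = nm_control)
  if (fit2$value < fit$value) fit <- fit2
  ncc <- -fit$value
  if (ncc < options$ncc_floor) {
    stop(sprintf(
      "registration failure: NCC %.3f below floor %.3f", ncc, options$ncc_floor
    ))
  }
  A <- base::matrix(fit$par[1:4], 2, 2)
  list(
    transform = make_transform(A, fit$par[5:6]),
    quality = list(ncc = ncc)
  )
}

#' Mean corner displacement between an estimated and a true transform
#'
#' Maps the four corners of the source field of view through both transforms
#' and returns the mean Euclidean displacement in micrometers.
#'
#' @param estimated,truth [affine_transform()]s with the same source frame.
#' @param source_dim integer (rows, cols) of the source image.
#' @param source_pixel_size_um source pixel size.
#' @return Mean corner displacement in um.
#' @export
corner_displacement_um <- function(estimated, truth, source_dim,
                                   source_pixel_size_um) {
  H <- (source_dim[1] - 1) * source_pixel_size_um
  W <- (source_dim[2] - 1) * source_pixel_size_um
  corners <- rbind(c(0, 0), c(0, W), c(H, 0), c(H, W))
  d <- apply_affine(estimated, corners) - apply_affine(truth, corners)
  mean(sqrt(rowSums(d^2)))
}

#' Write / read an affine transform as JSON
#' @param transform an [affine_transform()].
#' @param path JSON file path.
#' @param quality optional quality list stored alongside.
#' @return `path` invisibly (write); an [affine_transform()] (read).
#' @export
write_transform_json <- function(transform, path, quality = NULL) {
  obj <- list(
    # 2x3 matrix stored column-major: a11 a21 a12 a22 t1 t2
    matrix = as.numeric(transform$matrix),
    source_pixel_size_um = transform$source_pixel_size_um,
    target_pixel_size_um = transform$target_pixel_size_um
  )
  if (!is.null(quality)) obj$quality <- quality
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(
    base::matrix(unlist(obj$matrix), 2, 3),
    obj$source_pixel_size_um, obj$target_pixel_size_um
  )
}
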