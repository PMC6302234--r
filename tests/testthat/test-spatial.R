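test_that("densities under region masks follow the counting definition", {
  region <- matrix(FALSE, 20, 20)
  region[1:10, 1:20] <- TRUE # 200 px
  cls <- matrix(FALSE, 20, 20)
  cls[1:10, 1:2] <- TRUE # 20 px inside
  cls[11:20, 1] <- TRUE  # outside region
  cls[1, 3:11] <- TRUE   # 9 more inside -> 29 inside
  expect_equal(density_under_mask(mk_mask(cls), mk_mask(region)), 29 / 200)

  expect_equal(density_under_mask(mk_mask(matrix(FALSE, 4, 4)),
                                  mk_mask(matrix(TRUE, 4, 4))), 0)
  expect_equal(density_under_mask(mk_mask(matrix(TRUE, 4, 4)),
                                  mk_mask(matrix(TRUE, 4, 4))), 1)
  # empty region -> undefined, not zero
  expect_true(is.na(density_under_mask(mk_mask(matrix(TRUE, 4, 4)),
                                       mk_mask(matrix(FALSE, 4, 4)))))
})

test_that("tumor:stroma ratio follows the subtraction definition", {
  tissue <- mk_mask(matrix(TRUE, 20, 20))
  tumor <- matrix(FALSE, 20, 20)
  tumor[1:5, 1:20] <- TRUE # 100 px; stroma 300 px
  cls <- matrix(FALSE, 20, 20)
  cls[1:5, 1:2] <- TRUE    # 10 in tumor
  cls[6:20, 1] <- TRUE     # 15 in stroma
  out <- tumor_stroma_ratio(mk_mask(cls), mk_mask(tumor), tissue)
  expect_equal(out$tumor_density, 0.10)
  expect_equal(out$stroma_density, 0.05)
  expect_equal(out$ratio, 2.0)

  # identical densities -> ratio 1
  cls2 <- matrix(FALSE, 20, 20)
  cls2[, 1] <- TRUE
  out <- tumor_stroma_ratio(mk_mask(cls2), mk_mask(tumor), tissue)
  expect_equal(out$ratio, 1.0)

  # class entirely inside the tumor -> undefined ratio
  cls3 <- matrix(FALSE, 20, 20)
  cls3[1:3, 1:3] <- TRUE
  out <- tumor_stroma_ratio(mk_mask(cls3), mk_mask(tumor), tissue)
  expect_true(is.na(out$ratio))
  expect_equal(out$tumor_density, 9 / 100)

  # tumor outside tissue violates the precondition
  expect_error(
    tumor_stroma_ratio(mk_mask(cls), mk_mask(matrix(TRUE, 20, 20)),
                       mk_mask(tumor)),
    "outside the tissue"
  )
  # class in tumor + class in stroma = class in tissue, exactly
  set.seed(5)
  for (i in 1:20) {
    cls_r <- mk_mask(matrix(runif(400) < 0.3, 20, 20))
    n_t <- sum(cls_r$pixels & tumor)
    n_s <- sum(cls_r$pixels & tissue$pixels & !tumor)
    expect_identical(n_t + n_s, sum(cls_r$pixels & tissue$pixels))
  }
})

fake_nucleus_set <- function(centroids, h, w, psz = 0.3) {
  structure(
    list(
      table = data.frame(
        nucleus_id = seq_len(nrow(centroids)),
        centroid_row = centroids[, 1], centroid_col = centroids[, 2],
        area_px = 50, equivalent_radius_px = sqrt(50 / pi)
      ),
      labels = matrix(0L, h, w),
      mask = mk_mask(matrix(FALSE, h, w), psz = psz),
      pixel_size_um = psz, tile_id = "t", doughnuts = NULL
    ),
    class = "nucleus_set"
  )
}

test_that("border-band nuclei are selected by inward distance from the tumor edge", {
  # tumor disk of radius 100 px (30 um at 0.3 um/px), band 10 um
  h <- 256
  tumor <- mk_mask(disk_matrix(h, h, 128, 128, 100))
  centroids <- rbind(
    c(128, 128),   # center: 30 um inside -> excluded
    c(128, 128 + 50), # 15 um from center, 15 um inside edge -> excluded
    c(128, 128 + 83), # ~5 um inside the edge -> selected
    c(128 + 70, 128 + 70), # r ~ 99 px, ~0.3 um inside -> selected
    c(128, 240)    # outside the tumor -> excluded
  )
  nset <- fake_nucleus_set(centroids, h, h)
  sel <- find_border_nuclei(nset, tumor, border_band_spec(10))
  expect_setequal(sel$nucleus_id, c(3, 4))
  expect_true(all(sel$border_distance_um <= 10))

  # empty tumor mask -> empty selection
  empty <- find_border_nuclei(nset, mk_mask(matrix(FALSE, h, h)),
                              border_band_spec(10))
  expect_equal(nrow(empty), 0)
})

test_that("a tumor filling the whole tile has no border band inside it", {
  h <- 64
  nset <- fake_nucleus_set(rbind(c(10, 10), c(32, 32)), h, h)
  sel <- find_border_nuclei(nset, mk_mask(matrix(TRUE, h, h)),
                            border_band_spec(10))
  expect_equal(nrow(sel), 0)
})

test_that("nearest-class distances match the contact and axis-aligned cases", {
  m <- matrix(FALSE, 32, 32)
  m[11, 11] <- TRUE
  mask <- mk_mask(m, psz = 0.3)
  expect_equal(nearest_class_distance(rbind(c(10, 10)), mask), 0)
  expect_equal(nearest_class_distance(rbind(c(10, 20)), mask), 3.0) # 10 px x 0.3
  expect_true(is.na(nearest_class_distance(rbind(c(1, 1)),
                                           mk_mask(matrix(FALSE, 8, 8)))))
})

test_that("distance transform equals the exhaustive minimum on random masks", {
  set.seed(31)
  for (i in 1:10) {
    mask <- random_mask(64, 64, p = runif(1, 0.005, 0.1))
    pts <- cbind(sample(0:63, 5), sample(0:63, 5))
    d <- nearest_class_distance(pts, mask)
    for (j in 1:5) {
      expect_equal(d[j], oracle_min_distance(pts[j, ], mask), tolerance = 1e-6)
    }
  }
})

test_that("distance histograms use a contact bin and half-open 20-um bins", {
  h <- distance_histogram(c(0, 5, 15, 25))
  expect_equal(h$bins$percent[h$bins$bin_label == "0"], 25)
  expect_equal(h$bins$percent[h$bins$bin_label == "(0,20]"], 50)
  expect_equal(h$bins$percent[h$bins$bin_label == "(20,40]"], 25)
  expect_equal(sum(h$bins$percent), 100)
  expect_equal(h$mean_distance_um, mean(c(0, 5, 15, 25)))

  # everything in one bin
  h <- distance_histogram(c(1, 5, 19.9, 20)) # d = 20 falls in (0,20]
  expect_equal(h$bins$percent[h$bins$bin_label == "(0,20]"], 100)

  # missing values are dropped and counted
  h <- distance_histogram(c(NA, 10, NA))
  expect_equal(h$n_measured, 1)
  expect_equal(h$n_missing, 2)
  expect_equal(sum(h$bins$percent), 100)

  h <- distance_histogram(c(NA_real_, NA_real_))
  expect_equal(h$n_measured, 0)
  expect_true(is.na(h$mean_distance_um))
  expect_true(all(is.na(h$bins$percent)))

  expect_error(distance_histogram(c(-1, 3)), "non-negative")
})

test_that("histogram percents sum to 100 on random distance sets", {
  set.seed(77)
  for (i in 1:20) {
    d <- c(runif(sample(1:40, 1), 0, 120), rep(0, sample(0:3, 1)))
    h <- distance_histogram(d)
    expect_equal(sum(h$bins$percent), 100, tolerance = 1e-9)
  }
})

test_that("the per-tile density report carries ratios and region sizes", {
  tumor <- mk_mask(disk_matrix(64, 64, 32, 32, 15), label = "tumor")
  tissue <- mk_mask(matrix(TRUE, 64, 64), label = "tissue")
  set.seed(8)
  masks <- list(
    CD68 = random_mask(64, 64, 0.2, label = "CD68"),
    CD163 = random_mask(64, 64, 0.1, label = "CD163")
  )
  rep <- density_report(masks, tumor, tissue, tcell_mask = NULL)
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$tumor_density >= 0 & rep$tumor_density <= 1))
  expect_equal(rep$tumor_px + rep$stroma_px, rep(64 * 64, 2))
  expect_true(all(is.na(rep$tcell_density)))
})
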