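test_that("thresholding is strict and preserves geometry", {
  img <- channel_image(matrix(0, 4, 4), 0.3, "CD68")
  expect_equal(positive_count(threshold_channel(img, threshold = 10)), 0)

  img <- channel_image(matrix(100, 4, 4), 0.3, "CD68")
  expect_equal(positive_count(threshold_channel(img, threshold = 100)), 0)

  img <- channel_image(
    matrix(c(0, 200, 0, 50, 50, 0, 200, 0, 255), 3, 3), 0.3, "CD68"
  )
  m <- threshold_channel(img, threshold = 100)
  expect_equal(positive_count(m), 3)
  expect_equal(dim(m$pixels), c(3, 3))
  expect_equal(m$pixel_size_um, 0.3)
})

test_that("Otsu thresholding separates a two-level image and rejects a constant one", {
  img <- channel_image(
    matrix(c(rep(100, 60), rep(2000, 40)), 10, 10), 0.3, "CD68"
  )
  m <- threshold_channel(img, threshold_spec(list(CD68 = "otsu")))
  expect_equal(positive_count(m), 40)
  flat <- channel_image(matrix(7, 8, 8), 0.3, "CD68")
  expect_error(
    threshold_channel(flat, threshold_spec(list(CD68 = "otsu"))),
    "degenerate"
  )
  expect_error(
    threshold_channel(img, threshold_spec(list())),
    "no threshold configured"
  )
})

test_that("small-group filter removes components under 9 pixels and keeps the rest", {
  m <- matrix(FALSE, 20, 30)
  m[2:3, 2:5] <- TRUE       # 8 px -> removed
  m[10:12, 10:12] <- TRUE   # 9 px -> kept
  m[2:4, 20:23] <- TRUE     # 12 px -> kept
  mask <- mk_mask(m)
  out <- remove_small_groups(mask, threshold_spec())
  expect_equal(positive_count(out), 9 + 12)
  expect_false(any(out$pixels[2:3, 2:5]))
  expect_true(all(out$pixels[10:12, 10:12]))
  expect_true(all(out$pixels[2:4, 20:23]))

  expect_equal(positive_count(remove_small_groups(mk_mask(matrix(FALSE, 5, 5)))), 0)

  solid <- matrix(FALSE, 10, 10)
  solid[4:6, 4:6] <- TRUE
  for (conn in c(4, 8)) {
    out <- remove_small_groups(mk_mask(solid), threshold_spec(connectivity = conn))
    expect_equal(out$pixels, solid)
  }
})

test_that("connectivity changes which diagonal-touching groups survive", {
  # two 6-px blocks joined only at a corner: one 12-px component under
  # 8-connectivity, two 6-px components under 4-connectivity
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:3] <- TRUE
  m[5:7, 4:5] <- TRUE
  kept8 <- remove_small_groups(mk_mask(m), threshold_spec(connectivity = 8))
  kept4 <- remove_small_groups(mk_mask(m), threshold_spec(connectivity = 4))
  expect_equal(positive_count(kept8), 12)
  expect_equal(positive_count(kept4), 0)
})

test_that("small-group filter is idempotent and monotone, sizes match a flood-fill oracle", {
  set.seed(42)
  for (i in 1:30) {
    mask <- random_mask(48, 48, p = runif(1, 0.1, 0.4))
    for (conn in c(4, 8)) {
      spec <- threshold_spec(connectivity = conn)
      once <- remove_small_groups(mask, spec)
      twice <- remove_small_groups(once, spec)
      expect_identical(once$pixels, twice$pixels)
      expect_lte(positive_count(once), positive_count(mask))
      sizes <- oracle_component_sizes(once$pixels, conn)
      if (length(sizes) > 0) expect_true(all(sizes >= 9))
      removed <- sum(oracle_component_sizes(mask$pixels, conn)[
        oracle_component_sizes(mask$pixels, conn) >= 9
      ])
      expect_equal(positive_count(once), removed)
    }
  }
})

test_that("mask union is an OR with geometry checks", {
  a <- mk_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  b <- mk_mask(matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_equal(positive_count(union_masks(list(a, b))), 3)
  expect_equal(union_masks(list(a, a))$pixels, a$pixels)
  empty <- mk_mask(matrix(FALSE, 2, 2))
  expect_equal(positive_count(union_masks(list(empty, empty))), 0)
  wrong <- mk_mask(matrix(TRUE, 3, 2))
  expect_error(union_masks(list(a, wrong)), "geometry mismatch")
  wrong_psz <- mk_mask(matrix(TRUE, 2, 2), psz = 0.5)
  expect_error(union_masks(list(a, wrong_psz)), "pixel size mismatch")
})

test_that("CD206 restriction intersects with the MC&M mask", {
  cd206 <- mk_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2), label = "CD206")
  mcm <- mk_mask(matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2), label = "MCM_mask")
  out <- restrict_cd206(cd206, mcm)
  expect_equal(positive_count(out), 2)
  expect_false(any(out$pixels & !mcm$pixels))

  disjoint <- mk_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), label = "CD206")
  mcm2 <- mk_mask(matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2), label = "MCM_mask")
  expect_equal(positive_count(restrict_cd206(disjoint, mcm2)), 0)

  sub <- mk_mask(matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2), label = "CD206")
  expect_equal(restrict_cd206(sub, mcm)$pixels, sub$pixels)
})

make_five_masks <- function(mats, psz = 0.3) {
  out <- lapply(seq_along(MCM_MARKERS), function(i) {
    mk_mask(mats[[i]], psz = psz, label = MCM_MARKERS[i])
  })
  names(out) <- MCM_MARKERS
  out
}

test_that("pixel-class decomposition matches hand-enumerated examples", {
  z <- matrix(FALSE, 1, 4)
  A <- z; A[1, 1:2] <- TRUE          # {p1, p2}
  B <- z; B[1, 2:3] <- TRUE          # {p2, p3}
  C <- z; C[1, 3] <- TRUE            # {p3}
  masks <- make_five_masks(list(A, B, C, z, z))
  ref <- union_masks(masks)
  tab <- decompose_pixel_classes(masks, ref)
  expect_equal(attr(tab, "reference_pixel_count"), 3)
  get <- function(lab) tab$pixel_count[tab$class_label == lab]
  expect_equal(get("CD68"), 1)            # p1: A only
  expect_equal(get("CD68/CD163"), 1)      # p2: A and B
  expect_equal(get("CD163/CD206"), 1)     # p3: B and C
  expect_equal(sum(tab$pixel_count[tab$exclusive]), 3)
  expect_equal(tab$percent_of_reference[tab$class_label == "CD68"], 100 / 3)
  expect_equal(tab$percent_of_reference[tab$class_label == "P2_3_4_5"], 200 / 3)
})

test_that("full overlap, no overlap and empty reference are classified correctly", {
  on <- matrix(TRUE, 2, 2)
  off <- matrix(FALSE, 2, 2)
  # two identical marker masks, others empty -> 100% in their double class
  masks <- make_five_masks(list(on, on, off, off, off))
  tab <- decompose_pixel_classes(masks, union_masks(masks))
  expect_equal(tab$percent_of_reference[tab$class_label == "CD68/CD163"], 100)
  expect_equal(sum(tab$pixel_count[tab$exclusive & tab$n_colors == 1]), 0)

  # five disjoint masks -> singles sum to 100%, no multicolor pixels
  z <- matrix(FALSE, 1, 5)
  mats <- lapply(1:5, function(i) { m <- z; m[1, i] <- TRUE; m })
  masks <- make_five_masks(mats)
  tab <- decompose_pixel_classes(masks, union_masks(masks))
  expect_equal(tab$pixel_count[tab$class_label == "P2_3_4_5"], 0)
  expect_equal(sum(tab$percent_of_reference[tab$exclusive & tab$n_colors == 1]), 100)

  # zero-pixel reference -> undefined percentages, zero reference count
  masks <- make_five_masks(rep(list(off), 5))
  tab <- decompose_pixel_classes(masks, mk_mask(off))
  expect_equal(attr(tab, "reference_pixel_count"), 0)
  expect_true(all(is.na(tab$percent_of_reference)))
})

test_that("decomposition equals the per-pixel enumeration oracle on random masks", {
  set.seed(7)
  for (i in 1:25) {
    masks <- make_five_masks(lapply(1:5, function(j) {
      matrix(runif(32 * 32) < runif(1, 0.05, 0.4), 32, 32)
    }))
    ref <- union_masks(masks)
    tab <- decompose_pixel_classes(masks, ref)
    oracle <- oracle_class_counts(masks, ref)
    for (lab in tab$class_label[tab$exclusive & tab$n_colors %in% 1:3]) {
      expect_equal(tab$pixel_count[tab$class_label == lab], oracle[[lab]] %||% 0,
                   info = lab)
    }
    # residual and aggregate classes against summed oracle patterns
    n_colors <- vapply(strsplit(names(oracle), "/", fixed = TRUE), length, integer(1))
    n_colors[names(oracle) == "unlabeled"] <- 0L
    expect_equal(tab$pixel_count[tab$class_label == "P4_5"],
                 sum(unlist(oracle)[n_colors >= 4]))
    expect_equal(tab$pixel_count[tab$class_label == "P2_3_4_5"],
                 sum(unlist(oracle)[n_colors >= 2]))
    # symmetry: the pair class is order-free by construction of labels
    expect_equal(sum(tab$pixel_count[tab$exclusive]),
                 attr(tab, "reference_pixel_count"))
  }
})

test_that("anchor breakdown partitions the anchor mask", {
  z <- matrix(FALSE, 1, 2)
  cd68 <- z; cd68[1, 1:2] <- TRUE
  cd163 <- z; cd163[1, 2] <- TRUE
  masks <- make_five_masks(list(cd68, cd163, z, z, z))
  tab <- mask_class_breakdown("CD68", masks)
  expect_equal(tab$percent_of_reference[tab$class_label == "CD68"], 50)
  expect_equal(tab$percent_of_reference[tab$class_label == "CD68/CD163"], 50)
  expect_true(all(grepl("CD68", tab$class_label) |
                    tab$class_label %in% c("P4_5", "P2_3_4_5")))
  expect_equal(sum(tab$pixel_count[tab$exclusive]),
               attr(tab, "reference_pixel_count"))

  # empty anchor -> undefined percentages
  masks <- make_five_masks(rep(list(z), 5))
  tab <- mask_class_breakdown("CD68", masks)
  expect_true(all(is.na(tab$percent_of_reference)))

  # all five masks identical -> everything lands in the >=4-color residual
  on <- matrix(TRUE, 2, 3)
  masks <- make_five_masks(rep(list(on), 5))
  tab <- mask_class_breakdown("CD68", masks)
  expect_equal(tab$percent_of_reference[tab$class_label == "P4_5"], 100)
  expect_error(mask_class_breakdown("CD4", masks), "not among")
})

test_that("case aggregation averages tile percentages with sample sd", {
  z <- matrix(FALSE, 1, 10)
  mk_tab <- function(n_double, n_total) {
    cd68 <- z; cd68[1, seq_len(n_total)] <- TRUE
    cd163 <- z
    if (n_double > 0) cd163[1, seq_len(n_double)] <- TRUE
    masks <- make_five_masks(list(cd68, cd163, z, z, z))
    decompose_pixel_classes(masks, union_masks(masks))
  }
  one <- aggregate_case(list(mk_tab(2, 10)), "c1")
  expect_equal(one$sd_percent[one$class_label == "CD68/CD163"], 0)
  expect_equal(one$n_tiles[one$class_label == "CD68/CD163"], 1)
  expect_equal(one$mean_percent[one$class_label == "CD68/CD163"], 20)

  two <- aggregate_case(list(mk_tab(2, 10), mk_tab(4, 10)), "c1")
  row <- two[two$class_label == "CD68/CD163", ]
  expect_equal(row$mean_percent, 30)
  expect_equal(row$sd_percent, sqrt(200), tolerance = 1e-12) # sd of {20, 40}
  expect_equal(row$n_tiles, 2)

  # a tile with an empty reference is excluded, n_tiles decremented
  empty_tab <- decompose_pixel_classes(
    make_five_masks(rep(list(z), 5)), mk_mask(z, label = "MCM_mask")
  )
  three <- aggregate_case(list(mk_tab(2, 10), mk_tab(4, 10), empty_tab), "c1")
  row <- three[three$class_label == "CD68/CD163", ]
  expect_equal(row$mean_percent, 30)
  expect_equal(row$n_tiles, 2)

  expect_error(aggregate_case(list()), "at least one")
})
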