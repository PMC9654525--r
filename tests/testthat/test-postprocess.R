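# helper: rasterized disc mask
disc_mask <- function(h, w, cx, cy, r, cls = CLASS_TUMOR, base = CLASS_REMAINDER,
                      px = 0.44) {
  m <- matrix(base, h, w)
  X <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  Y <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  for (i in seq_along(cx))
    m[(X - cx[i])^2 + (Y - cy[i])^2 <= r[i]^2] <- cls
  class_mask(m, px)
}

test_that("specks below the area floor are removed; bounds validated", {
  m <- class_mask(matrix(CLASS_REMAINDER, 32, 32))
  mm <- unclass(m); mm[16, 16] <- CLASS_TUMOR
  m <- class_mask(mm)
  out <- refine_mask(m, min_area_um2 = 10, closing_radius_px = 0)
  expect_equal(sum(out == CLASS_TUMOR), 0)
  expect_error(refine_mask(m, min_area_um2 = 10, max_area_um2 = 5), "min_area")
})

test_that("a mask already satisfying the rules is unchanged (idempotence)", {
  m <- disc_mask(96, 96, c(25, 65), c(30, 60), c(9, 7))
  # pure area filtering leaves a compliant mask untouched
  r0 <- refine_mask(m, closing_radius_px = 0)
  expect_identical(unclass(r0), unclass(m))
  # with morphology, one application reaches the fixed point
  r1 <- refine_mask(m)
  r2 <- refine_mask(r1)
  expect_identical(unclass(r2), unclass(r1))
})

test_that("surviving components equal a brute-force area-filter oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 6
    m <- disc_mask(128, 128, runif(n, 12, 116), runif(n, 12, 116),
                   runif(n, 1, 8))
    lo <- 15; hi <- 120
    out <- refine_mask(m, min_area_um2 = lo, max_area_um2 = hi,
                       closing_radius_px = 0)
    # oracle: label components, filter by pixel area
    lab <- EBImage::bwlabel(EBImage::Image((unclass(m) == CLASS_TUMOR) * 1))
    areas <- tabulate(as.integer(EBImage::imageData(lab)))
    areas_um <- areas * 0.44^2
    expected_px <- sum(areas[areas_um >= lo & areas_um <= hi])
    expect_equal(sum(out == CLASS_TUMOR), expected_px)
  }
})

test_that("two overlapping discs split into two objects, one disc stays one", {
  two <- disc_mask(80, 80, c(30, 46), c(40, 40), c(10, 10))
  sp <- split_clusters(two, tolerance = 1)
  expect_equal(length(sp$class), 2)
  one <- disc_mask(64, 64, 32, 32, 12)
  sp1 <- split_clusters(one)
  expect_equal(length(sp1$class), 1)
  # partition property: foreground pixels unchanged
  expect_equal(sum(sp$labels > 0), sum(two == CLASS_TUMOR))
  expect_equal(length(sp$class), max(sp$labels))
})

test_that("non-touching simulated normal nuclei come out as exactly N objects", {
  cfg <- small_scene_config(seed = 17, tile = 192, n_tumor = 0, n_normal = 12,
                            cluster_prob = 0)
  sc <- generate_scene(cfg)
  m <- truth_masks(sc)
  sp <- split_clusters(m)
  expect_equal(sum(sp$class == CLASS_NORMAL), 12)
})

test_that("split object count is never below the connected-component count", {
  cfg <- small_scene_config(seed = 19, tile = 192, n_tumor = 10, n_normal = 10,
                            cluster_prob = 0.6)
  m <- truth_masks(generate_scene(cfg))
  ncc <- 0
  for (cls in c(CLASS_TUMOR, CLASS_NORMAL))
    ncc <- ncc + max(EBImage::bwlabel(EBImage::Image((unclass(m) == cls) * 1)))
  sp <- split_clusters(m)
  expect_gte(length(sp$class), ncc)
})

test_that("object records carry analytic areas and chromaticity measurements", {
  m <- disc_mask(96, 96, 50, 50, 10)
  sp <- split_clusters(m)
  # pure red tile
  tile <- array(0, dim = c(96, 96, 3)); tile[, , 1] <- 1
  ob <- extract_objects(sp, ihc = tile, basis = stain_basis("FastRed"))
  expect_equal(nrow(ob), 1)
  expect_equal(ob$area_um2, pi * (10 * 0.44)^2, tolerance = 0.1 * pi * 4.4^2)
  expect_equal(ob$mean_red_chromaticity, 1.0)
  expect_equal(ob$cx, 50, tolerance = 0.6)
  expect_equal(ob$cy, 50, tolerance = 0.6)
  # empty label image
  empty <- split_clusters(class_mask(matrix(CLASS_REMAINDER, 16, 16)))
  ob0 <- extract_objects(empty)
  expect_equal(nrow(ob0), 0)
  # shape mismatch
  expect_error(extract_objects(sp, ihc = array(1, dim = c(8, 8, 3))),
               "mismatch")
})
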