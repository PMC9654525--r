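test_that("tumor burden is a pure count ratio with the stated edge cases", {
  ob <- data.frame(class = rep(c("tumor-nucleus", "normal-nucleus"), c(70, 30)))
  expect_equal(tumor_burden(ob)$burden_pct, 70)
  expect_equal(tumor_burden(data.frame(class = rep("normal-nucleus", 50)))$burden_pct, 0)
  expect_error(tumor_burden(data.frame(class = character(0))), "undefined")
  # invariance under reindexing and count scaling
  ob2 <- ob[sample(nrow(ob)), , drop = FALSE]
  expect_equal(tumor_burden(ob2)$burden_pct, 70)
  ob3 <- rbind(ob, ob, ob)
  expect_equal(tumor_burden(ob3)$burden_pct, 70)
})

test_that("annotation rate divides labels by analyzed area", {
  ob <- disc_object_set(runif(150, 0, 100), runif(150, 0, 100), rep(3, 150))
  expect_equal(annotation_rate(ob, 0.15), 1000)
  empty <- ob[0, , drop = FALSE]
  expect_equal(annotation_rate(empty, 0.15), 0)
  expect_error(annotation_rate(ob, 0), "positive")
})

test_that("mean red chromaticity aggregates per-object means with a t CI", {
  ob <- data.frame(class = rep("tumor-nucleus", 2),
                   mean_red_chromaticity = c(1, 1))
  r <- mean_red_chromaticity(ob)
  expect_equal(r$mean, 1)
  expect_equal(diff(r$ci), 0)
  ob2 <- data.frame(class = rep("tumor-nucleus", 2),
                    mean_red_chromaticity = c(0.3, 0.5))
  expect_equal(mean_red_chromaticity(ob2)$mean, 0.4)
  expect_error(mean_red_chromaticity(data.frame(class = "normal-nucleus",
                                                mean_red_chromaticity = 1)),
               "no tumor objects")
})

test_that("lesion-level chromaticity decreases with the staining-strength knob", {
  mean_chrom <- function(intensity) {
    cfg <- small_scene_config(seed = 50, tile = 160, n_tumor = 8, n_normal = 4,
                              chromogen_intensity = intensity)
    s <- simulate_annotated_scene(cfg)
    mean_red_chromaticity(s$objects)$mean
  }
  hi <- mean_chrom(0.9); lo <- mean_chrom(0.45)
  expect_gt(hi, lo)
})

test_that("systematic-random fields: exact small case, determinism, coverage", {
  f <- 10
  roi <- cbind(c(0, 3 * f, 3 * f, 0), c(0, 0, f, f))
  plan <- sampling_plan(roi, 3, c(f, f), seed = 4)
  flds <- systematic_random_fields(plan)
  expect_equal(nrow(flds), 3)
  # non-overlapping
  expect_true(all(diff(sort(flds$x0)) >= f - 1e-9))
  expect_identical(flds, systematic_random_fields(plan))
  expect_error(sampling_plan(roi, 10, c(f, f)), "too small")

  # Monte-Carlo inclusion probability of a planted point, one field per plan:
  # cell area equals roi area, so P(cover) = field area / roi area
  roi2 <- cbind(c(0, 40, 40, 0), c(0, 0, 40, 40))
  pt <- c(17.3, 23.1)
  hits <- 0; n <- 2000
  for (s in seq_len(n)) {
    fl <- systematic_random_fields(sampling_plan(roi2, 1, c(12, 9), seed = s))
    hits <- hits + any(pt[1] >= fl$x0 & pt[1] <= fl$x0 + fl$w &
                       pt[2] >= fl$y0 & pt[2] <= fl$y0 + fl$h)
  }
  p_true <- (12 * 9) / (40 * 40)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(hits / n - p_true), 3 * se)
})

test_that("counting frame follows the Gundersen inclusion/forbidden rule", {
  px <- 0.44
  fr <- counting_frame(c(10.5, 10.5), width_um = 30, height_um = 25,
                       pixel_size_um = px)
  inside <- disc_object_set(fr$x0 + 20, fr$y0 + 20, 5)
  expect_equal(sum(counting_frame_count(inside, fr)), 1)
  # centers are offset from the frame lines so crossings are non-degenerate
  left <- disc_object_set(fr$x0 + 0.4, fr$y0 + 20, 5)   # crosses left edge
  expect_equal(sum(counting_frame_count(left, fr)), 0)
  bottom <- disc_object_set(fr$x0 + 20, fr$y1 - 0.4, 5) # crosses bottom edge
  expect_equal(sum(counting_frame_count(bottom, fr)), 0)
  top <- disc_object_set(fr$x0 + 20, fr$y0 + 0.4, 5)    # crosses top: inclusion
  expect_equal(sum(counting_frame_count(top, fr)), 1)
  right <- disc_object_set(fr$x1 - 0.4, fr$y0 + 20, 5)  # crosses right: inclusion
  expect_equal(sum(counting_frame_count(right, fr)), 1)
  # downward extension at the bottom-right corner is forbidden
  below_right <- disc_object_set(fr$x1 - 0.4, fr$y1 + 2, 5)
  expect_equal(sum(counting_frame_count(below_right, fr)), 0)
})

test_that("counting frames tiling the plane count every object exactly once", {
  set.seed(77)
  for (rep in 1:3) {
    n <- 60
    ob <- disc_object_set(runif(n, 30, 370), runif(n, 30, 370),
                          runif(n, 2, 12),
                          class = sample(c("tumor-nucleus", "normal-nucleus"),
                                         n, replace = TRUE))
    fw <- 41.7; fh <- 33.3
    ox <- runif(1, -fw, 0); oy <- runif(1, -fh, 0)
    tot <- 0L
    for (gx in 0:ceiling((400 - ox) / fw)) {
      for (gy in 0:ceiling((400 - oy) / fh)) {
        fr <- counting_frame(c(ox + gx * fw, oy + gy * fh),
                             width_um = fw * 0.44, height_um = fh * 0.44,
                             pixel_size_um = 0.44)
        tot <- tot + sum(counting_frame_count(ob, fr))
      }
    }
    expect_equal(tot, n)
  }
})

test_that("stereological burden approximates the object-set burden", {
  s <- simulate_annotated_scene(small_scene_config(seed = 23, tile = 256,
                                                   n_tumor = 14, n_normal = 10))
  roi <- cbind(c(4, 215, 215, 4), c(4, 4, 250, 250))
  st <- stereology_burden(s$objects, roi, n_frames = 10, seed = 3)
  tb <- tumor_burden(s$objects)
  expect_true(abs(st$burden_pct - tb$burden_pct) < 30)  # coarse at 10 frames
  expect_gt(st$n_frames, 5)
})
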