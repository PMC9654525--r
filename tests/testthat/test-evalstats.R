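test_that("the Wilson interval matches the score-test oracle and brackets p-hat", {
  for (n in c(5, 50, 376, 1444)) {
    for (k in unique(c(0, 1, round(n / 3), n - 1, n))) {
      w <- wilson_ci(k, n)
      expect_true(w[1] >= 0 && w[2] <= 1)
      expect_true(w[1] <= k / n + 1e-12 && w[2] >= k / n - 1e-12)
      # independent oracle: score interval from prop.test without correction
      o <- suppressWarnings(stats::prop.test(k, n, correct = FALSE))$conf.int
      expect_equal(unname(w), as.numeric(o), tolerance = 1e-6)
    }
  }
})

test_that("precision estimates reproduce printed reference cells", {
  p1 <- precision_ci(1298, 146)
  expect_equal(c(p1$percent, p1$percent_low, p1$percent_high),
               c(89.9, 88.2, 91.3))
  p2 <- precision_ci(5, 0)
  expect_equal(c(p2$percent, p2$percent_low, p2$percent_high),
               c(100, 56.6, 100))
  p3 <- precision_ci(5, 3)
  expect_equal(c(p3$percent, p3$percent_low, p3$percent_high),
               c(62.5, 30.6, 86.3))
  expect_error(precision_ci(0, 0), ">= 1")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(99.95, 1), 100)
})

test_that("two-proportion differences match reference values and symmetry", {
  d <- two_proportion_diff(1298, 1444, 2843, 2858)
  expect_equal(d$percent_diff, -9.6)
  expect_equal(d$percent_ci, c(-11.2, -8.0))
  expect_lt(d$p_value, 0.001)
  d2 <- two_proportion_diff(373, 376, 1113, 1222)
  expect_equal(d2$percent_diff, 8.1)
  same <- two_proportion_diff(30, 100, 30, 100)
  expect_equal(same$diff, 0)
  expect_equal(same$ci[1], -same$ci[2])
  expect_error(two_proportion_diff(1, 0, 1, 5), ">= 1")
})

test_that("object matching handles exact truth, spurious objects, and a brute-force oracle", {
  sc <- generate_scene(small_scene_config(seed = 61, tile = 160, n_tumor = 6,
                                          n_normal = 5))
  ent <- sc$entities
  nuc <- ent[ent$class %in% c("tumor-nucleus", "normal-nucleus"), ]
  exact <- data.frame(id = seq_len(nrow(nuc)), class = nuc$class,
                      cx = nuc$cx, cy = nuc$cy)
  mr <- match_objects(exact, sc)
  expect_equal(sum(mr$counts$tp), nrow(nuc))
  expect_equal(sum(mr$counts$fp), 0)
  expect_equal(sum(mr$counts$fn), 0)

  lone <- data.frame(id = 1, class = "tumor-nucleus", cx = 5, cy = 5)
  empty_scene <- generate_scene(scene_config(tile_size_px = 64,
                                             n_tumor_nuclei = 0,
                                             n_normal_nuclei = 0, seed = 1))
  mr2 <- match_objects(lone, empty_scene)
  expect_equal(mr2$counts$fp[mr2$counts$class == "tumor-nucleus"], 1)

  # greedy assignment attains the exhaustive maximum matching on small scenes
  set.seed(71)
  for (rep in 1:5) {
    sc <- generate_scene(small_scene_config(seed = 200 + rep, tile = 160,
                                            n_tumor = 5, n_normal = 4))
    ent <- sc$entities
    nuc <- ent[ent$class %in% c("tumor-nucleus", "normal-nucleus"), ]
    pred <- data.frame(id = seq_len(nrow(nuc)), class = nuc$class,
                       cx = nuc$cx + rnorm(nrow(nuc), 0, 2),
                       cy = nuc$cy + rnorm(nrow(nuc), 0, 2))
    mr <- match_objects(pred, sc)
    adj <- lapply(seq_len(nrow(pred)), function(i) {
      which(vapply(seq_len(nrow(nuc)), function(j) {
        nuc$class[j] == pred$class[i] &&
          dualstain:::.inside_entity(nuc[j, ], pred$cx[i], pred$cy[i])
      }, logical(1)))
    })
    expect_equal(sum(mr$counts$tp), max_matching_size(adj))
  }
})

test_that("confusion metrics match a hand-computed one-vs-rest oracle", {
  cm <- matrix(c(10, 0, 0, 0, 10, 0, 0, 0, 10), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  r <- confusion_metrics(cm)
  expect_true(all(abs(as.matrix(r$per_class[, 2:6]) - 1) < 1e-12))
  expect_true(all(abs(r$weighted - 1) < 1e-12))

  # class never predicted: precision reported 0 with a flag
  cm2 <- matrix(c(5, 3, 0, 0, 0, 0, 1, 2, 4), 3, 3, byrow = FALSE,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  r2 <- confusion_metrics(cm2)
  expect_equal(r2$per_class$precision[2], 0)
  expect_match(r2$flags, "class b")

  set.seed(5)
  cm3 <- matrix(sample(1:40, 9), 3, 3,
                dimnames = list(c("t", "n", "b"), c("t", "n", "b")))
  r3 <- confusion_metrics(cm3)
  tot <- sum(cm3)
  for (i in 1:3) {
    tp <- cm3[i, i]; fn <- sum(cm3[i, ]) - tp; fp <- sum(cm3[, i]) - tp
    tn <- tot - tp - fn - fp
    expect_equal(r3$per_class$sensitivity[i], tp / (tp + fn))
    expect_equal(r3$per_class$specificity[i], tn / (tn + fp))
    expect_equal(r3$per_class$accuracy[i], (tp + tn) / tot)
    expect_equal(r3$per_class$precision[i], tp / (tp + fp))
  }
  # weighted F1 equals the arithmetic mean when supports are equal
  cm4 <- matrix(c(8, 1, 1, 2, 7, 1, 1, 2, 7), 3, 3, byrow = TRUE)
  r4 <- confusion_metrics(cm4)
  expect_equal(unname(r4$weighted["f1"]), mean(r4$per_class$f1))
})

test_that("pixel confusion matrices merge remainder into background", {
  pred <- class_mask(matrix(c(1, 2, 3, 4), 2, 2))
  truth <- class_mask(matrix(c(1, 2, 4, 3), 2, 2))
  cm <- confusion_matrix3(pred, truth)
  expect_equal(sum(cm), 4)
  expect_equal(cm["background", "background"], 2L)
  expect_equal(unname(diag(cm)), c(1L, 1L, 2L))
})

test_that("Bland-Altman handles degenerate and antisymmetric inputs and covers", {
  ba <- bland_altman(c(11, 12, 13) + 4, c(11, 12, 13))
  expect_equal(ba$mean_diff, 4)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa, c(4, 4))
  ba2 <- bland_altman(c(-3, 3, -1, 1))
  expect_equal(ba2$mean_diff, 0)
  expect_error(bland_altman(1), "at least 2")
  expect_true(ba2$loa[1] <= ba2$mean_diff && ba2$mean_diff <= ba2$loa[2])

  # CI of the mean difference covers the true value ~95% of the time
  set.seed(99)
  n_rep <- 600; cover <- 0
  for (r in seq_len(n_rep)) {
    d <- rnorm(11, 6, 8)
    ci <- bland_altman(d)$ci_mean
    cover <- cover + (ci[1] <= 6 && 6 <= ci[2])
  }
  se <- sqrt(0.95 * 0.05 / n_rep)
  expect_lt(abs(cover / n_rep - 0.95), 3.5 * se)
})

test_that("mean comparisons use Welch/paired t with degenerate handling", {
  g <- c(1, 2, 3, 4)
  r <- mean_comparison(g, g)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  rd <- mean_comparison(c(1, 1, 1), c(1, 1, 1))
  expect_equal(rd$p_value, 1)
  expect_equal(rd$flag, "degenerate variance")
  # closed-form check of the paired t statistic
  x <- c(5.1, 4.8, 6.0, 5.5, 5.9); y <- c(4.9, 4.5, 5.2, 5.4, 5.1)
  rp <- mean_comparison(x, y, paired = TRUE)
  d <- x - y
  expect_equal(rp$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)

  # rejection rate tracks the analytic power of the two-sample t-test
  set.seed(123)
  s <- 0.04; n_rep <- 500; rej <- 0
  for (r in seq_len(n_rep)) {
    a <- rnorm(15, 0.37, s); b <- rnorm(15, 0.32, s)
    rej <- rej + (mean_comparison(a, b)$p_value < 0.05)
  }
  pow <- power.t.test(n = 15, delta = 0.05, sd = s)$power
  se <- sqrt(pow * (1 - pow) / n_rep)
  expect_lt(abs(rej / n_rep - pow), 4 * se)
})

test_that("bundled annotation counts load with printed precision columns", {
  tab <- example_annotation_counts()
  expect_equal(nrow(tab), 19)
  expect_true(all(c("fp", "tp", "precision_pct", "ci_fp", "ci_tp") %in%
                  names(tab)))
})
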