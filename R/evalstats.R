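# Validation statistics: object matching (TP/FP/FN), precision with Wilson
# score intervals, two-sample proportion differences, pixel confusion-matrix
# metrics with support-weighted averages, Bland-Altman agreement, and t-test
# wrappers. All proportions use z = 1.959964.

.Z95 <- 1.959964

#' Wilson score interval
#'
#' Closed-form score interval for a binomial proportion.
#'
#' @param k Successes.
#' @param n Trials.
#' @param z Normal quantile (default 1.959964 for 95%).
#' @return Numeric vector `c(low, high)` in \[0, 1\].
#' @export
wilson_ci <- function(k, n, z = .Z95) {
  if (n < 1) stop("n must be >= 1")
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Precision with Wilson interval
#'
#' Object-level precision TP / (TP + FP) with its Wilson 95% score interval.
#' Percentages are reported rounded half away from zero to one decimal;
#' full-precision values are kept alongside.
#'
#' @param tp,fp True-positive and false-positive counts.
#' @return Object of class `"proportion_estimate"`: `k`, `n`, `p_hat`,
#'   `wilson_low`, `wilson_high`, and rounded `percent`, `percent_low`,
#'   `percent_high`.
#' @export
#' @examples
#' precision_ci(2843, 15)$percent   # 99.5
precision_ci <- function(tp, fp) {
  n <- tp + fp
  if (n < 1) stop("tp + fp must be >= 1")
  ci <- wilson_ci(tp, n)
  structure(list(k = tp, n = n, p_hat = tp / n,
                 wilson_low = unname(ci[1]), wilson_high = unname(ci[2]),
                 percent = round_half_up(100 * tp / n, 1),
                 percent_low = unname(round_half_up(100 * ci[1], 1)),
                 percent_high = unname(round_half_up(100 * ci[2], 1))),
            class = "proportion_estimate")
}

#' Round half away from zero
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric (ties go away from zero, unlike [round()]).
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Difference of two proportions
#'
#' Difference `k1/n1 - k2/n2` with an unpooled Wald 95% confidence interval
#' and a pooled two-proportion z-test.
#'
#' @param k1,n1,k2,n2 Counts.
#' @param z Normal quantile for the interval.
#' @return List: `diff`, `ci` (length 2), `z` (test statistic), `p_value`;
#'   `percent` versions rounded to one decimal.
#' @export
#' @examples
#' two_proportion_diff(1298, 1444, 2843, 2858)$percent_diff   # -9.6
two_proportion_diff <- function(k1, n1, k2, n2, z = .Z95) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1")
  p1 <- k1 / n1; p2 <- k2 / n2
  d <- p1 - p2
  se_unpooled <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  ci <- c(d - z * se_unpooled, d + z * se_unpooled)
  pp <- (k1 + k2) / (n1 + n2)
  se_pooled <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  zstat <- if (se_pooled == 0) 0 else d / se_pooled
  list(diff = d, ci = ci, z = zstat,
       p_value = 2 * pnorm(-abs(zstat)),
       percent_diff = round_half_up(100 * d, 1),
       percent_ci = round_half_up(100 * ci, 1))
}

#' Pixel confusion matrix over tumor / normal / background
#'
#' Cross-tabulates truth rows against prediction columns for the three
#' evaluation classes. Remainder tissue and unstained background are merged
#' into a single background class, matching pixel-level evaluation where
#' "background" is everything that is not a nucleus.
#'
#' @param pred,truth Class masks (or integer matrices of class codes).
#' @param merge_remainder Merge remainder into background (default TRUE).
#' @return 3x3 integer matrix (rows = truth, cols = predicted) with
#'   dimnames tumor/normal/background.
#' @export
confusion_matrix3 <- function(pred, truth, merge_remainder = TRUE) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  map <- function(m) {
    m <- as.integer(m)
    if (merge_remainder) m[m == CLASS_REMAINDER] <- CLASS_BACKGROUND
    m
  }
  p <- map(pred); t_ <- map(truth)
  keep <- t_ %in% c(CLASS_TUMOR, CLASS_NORMAL, CLASS_BACKGROUND) &
    p %in% c(CLASS_TUMOR, CLASS_NORMAL, CLASS_BACKGROUND)
  lv <- c(CLASS_TUMOR, CLASS_NORMAL, CLASS_BACKGROUND)
  nm <- c("tumor", "normal", "background")
  tab <- table(factor(t_[keep], levels = lv, labels = nm),
               factor(p[keep], levels = lv, labels = nm))
  m <- matrix(as.integer(tab), 3, 3, dimnames = dimnames(tab))
  m
}

#' Confusion-matrix metrics
#'
#' One-vs-rest sensitivity (recall), specificity, accuracy, precision and
#' F1 per class, plus support-weighted averages. A class that is never
#' predicted has undefined precision; it is reported as 0 and flagged.
#'
#' @param cm Square confusion matrix (rows = truth, cols = predicted).
#' @return List: `per_class` data frame and `weighted` named vector
#'   (weights = true-class support), plus `flags`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  k <- nrow(cm)
  support <- rowSums(cm)
  res <- data.frame(class = rownames(cm) %||% as.character(seq_len(k)),
                    sensitivity = NA_real_, specificity = NA_real_,
                    accuracy = NA_real_, precision = NA_real_, f1 = NA_real_,
                    support = support, row.names = NULL)
  flags <- character(0)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fn <- support[i] - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    acc <- (tp + tn) / total
    if (tp + fp > 0) prec <- tp / (tp + fp)
    else { prec <- 0; flags <- c(flags, sprintf("precision undefined for class %s (no predictions); reported 0", res$class[i])) }
    f1 <- if (!is.na(sens) && (prec + sens) > 0) 2 * prec * sens / (prec + sens) else 0
    res[i, 2:6] <- c(sens, spec, acc, prec, f1)
  }
  w <- support / sum(support)
  weighted <- c(sensitivity = sum(w * res$sensitivity),
                specificity = sum(w * res$specificity),
                accuracy = sum(w * res$accuracy),
                precision = sum(w * res$precision),
                f1 = sum(w * res$f1))
  list(per_class = res, weighted = weighted, flags = flags)
}

#' Bland-Altman agreement
#'
#' Differences are taken as `method - reference`. Limits of agreement are
#' mean +/- 1.96 SD; the mean difference carries a t-based 95% CI and a
#' paired t-test p-value.
#'
#' @param method,reference Paired measurements, or `reference = NULL` and
#'   `method` already a vector of differences.
#' @return Object of class `"bland_altman"`: `mean_diff`, `sd_diff`,
#'   `loa` (length 2), `ci_mean` (length 2), `p_value`, `n`.
#' @export
bland_altman <- function(method, reference = NULL) {
  d <- if (is.null(reference)) method else method - reference
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  m <- mean(d); s <- sd(d)
  half <- qt(0.975, n - 1) * s / sqrt(n)
  tstat <- if (s == 0) Inf else m / (s / sqrt(n))
  p <- if (s == 0) as.numeric(m == 0) else 2 * pt(-abs(tstat), n - 1)
  structure(list(mean_diff = m, sd_diff = s,
                 loa = c(m - 1.96 * s, m + 1.96 * s),
                 ci_mean = c(m - half, m + half),
                 p_value = p, n = n),
            class = "bland_altman")
}

#' Compare group means by t-test
#'
#' Welch's t-test for unpaired groups, classic paired t-test for paired.
#' Degenerate zero-variance cases return `p = NaN` with a flag.
#'
#' @param g1,g2 Numeric vectors (same length when `paired`).
#' @param paired Paired comparison?
#' @return List: `t`, `df`, `p_value`, `ci`, `estimate`, `flag`.
#' @export
mean_comparison <- function(g1, g2, paired = FALSE) {
  if (length(g1) < 2 || length(g2) < 2) stop("group sizes must be >= 2")
  degenerate <- if (paired) sd(g1 - g2) == 0 else (sd(g1) == 0 && sd(g2) == 0)
  if (degenerate) {
    same <- if (paired) all(g1 == g2) else mean(g1) == mean(g2)
    return(list(t = if (same) 0 else Inf, df = NA_real_,
                p_value = if (same) 1 else NaN,
                ci = c(NA_real_, NA_real_),
                estimate = mean(g1) - mean(g2),
                flag = "degenerate variance"))
  }
  tt <- t.test(g1, g2, paired = paired, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, ci = as.numeric(tt$conf.int),
       estimate = if (paired) unname(tt$estimate) else
         unname(tt$estimate[1] - tt$estimate[2]),
       flag = NULL)
}

# --- object matching ---------------------------------------------------------

.truth_records <- function(truth) {
  if (inherits(truth, "gt_scene")) {
    keep <- truth$entities$class %in% c("tumor-nucleus", "normal-nucleus",
                                        "mitotic-figure")
    ent <- truth$entities[keep, , drop = FALSE]
    cls <- ifelse(ent$class == "mitotic-figure", "tumor-nucleus", ent$class)
    list(n = nrow(ent), class = cls, cx = ent$cx, cy = ent$cy,
         contains = function(i, x, y) .inside_entity(ent[i, ], x, y))
  } else {
    bounds <- attr(truth, "boundary")
    if (is.null(bounds)) stop("truth object set carries no boundaries")
    list(n = nrow(truth), class = truth$class, cx = truth$cx, cy = truth$cy,
         contains = function(i, x, y) point_in_polygon(x, y, bounds[[i]]))
  }
}

#' Match predicted objects against ground truth
#'
#' A predicted object is a true positive when its centroid lies inside a
#' same-class truth nucleus that no earlier (closer) prediction has claimed;
#' assignment is greedy by centroid distance. Unclaimed truth nuclei are
#' false negatives when the truth is complete.
#'
#' @param predicted An [extract_objects()] result.
#' @param truth A [generate_scene()] scene or a complete truth object set.
#' @param rule `"centroid"` (default). `"iou"` additionally requires
#'   intersection-over-union >= `iou_min` computed on bounding boxes of the
#'   boundary contours.
#' @param iou_min IoU threshold for `rule = "iou"`.
#' @param truth_complete Is the truth exhaustive (enables FN counts)?
#' @return Object of class `"match_result"`: data frame `counts` with one
#'   row per class (`tp`, `fp`, `fn`) and the matching `rule`.
#' @export
match_objects <- function(predicted, truth, rule = c("centroid", "iou"),
                          iou_min = 0.3, truth_complete = TRUE) {
  rule <- match.arg(rule)
  tr <- .truth_records(truth)
  np <- nrow(predicted)
  classes <- c("tumor-nucleus", "normal-nucleus")
  admissible <- list()
  for (i in seq_len(np)) {
    for (j in seq_len(tr$n)) {
      if (predicted$class[i] != tr$class[j]) next
      if (!tr$contains(j, predicted$cx[i], predicted$cy[i])) next
      if (rule == "iou") {
        bi <- attr(predicted, "boundary")[[i]]
        ov <- .bbox_iou(bi, tr, j)
        if (is.na(ov) || ov < iou_min) next
      }
      d <- sqrt((predicted$cx[i] - tr$cx[j])^2 + (predicted$cy[i] - tr$cy[j])^2)
      admissible[[length(admissible) + 1L]] <- c(i, j, d)
    }
  }
  used_p <- logical(np); used_t <- logical(tr$n)
  if (length(admissible)) {
    adm <- do.call(rbind, admissible)
    adm <- adm[order(adm[, 3]), , drop = FALSE]
    for (r in seq_len(nrow(adm))) {
      i <- adm[r, 1]; j <- adm[r, 2]
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE; used_t[j] <- TRUE
    }
  }
  counts <- data.frame(class = classes, tp = 0L, fp = 0L, fn = 0L)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    counts$tp[ci] <- sum(used_p & predicted$class == cl)
    counts$fp[ci] <- sum(!used_p & predicted$class == cl)
    counts$fn[ci] <- if (truth_complete) sum(!used_t & tr$class == cl) else NA_integer_
  }
  structure(list(counts = counts, rule = rule), class = "match_result")
}

.bbox_iou <- function(bound, tr, j) {
  if (is.null(bound)) return(NA_real_)
  # bounding boxes of prediction contour vs truth footprint (probed on a grid)
  bx <- range(bound[, 1]); by <- range(bound[, 2])
  xs <- seq(tr$cx[j] - 40, tr$cx[j] + 40, by = 2)
  ys <- seq(tr$cy[j] - 40, tr$cy[j] + 40, by = 2)
  g <- expand.grid(x = xs, y = ys)
  ins <- tr$contains(j, g$x, g$y)
  if (!any(ins)) return(NA_real_)
  tx <- range(g$x[ins]); ty <- range(g$y[ins])
  ix <- max(0, min(bx[2], tx[2]) - max(bx[1], tx[1]))
  iy <- max(0, min(by[2], ty[2]) - max(by[1], ty[1]))
  inter <- ix * iy
  a1 <- diff(bx) * diff(by); a2 <- diff(tx) * diff(ty)
  inter / (a1 + a2 - inter)
}

#' Precision of a matched class
#'
#' @param match A [match_objects()] result.
#' @param class Class name (`"tumor-nucleus"` or `"normal-nucleus"`).
#' @return A [precision_ci()] estimate, or NULL when no predictions exist.
#' @export
object_precision <- function(match, class = "tumor-nucleus") {
  row <- match$counts[match$counts$class == class, ]
  if (row$tp + row$fp == 0) return(NULL)
  precision_ci(row$tp, row$fp)
}
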