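# From raw class masks to individual nucleus objects: morphological cleanup
# and area filtering, distance-transform watershed with h-maxima style
# tolerance to split touching nuclei, a convexity-defect pass for residual
# merged blobs, and per-object feature extraction.

.ebi <- function(m) EBImage::Image(m * 1)

.label_matrix <- function(bin) {
  lab <- EBImage::bwlabel(.ebi(bin))
  matrix(as.integer(EBImage::imageData(lab)), nrow(bin), ncol(bin))
}

#' Morphological refinement and area filtering of a class mask
#'
#' Per nucleus class: morphological closing (then opening with the same
#' brush), followed by reclassification of connected components whose
#' calibrated area falls outside `[min_area_um2, max_area_um2]` to the
#' remainder class. An optional surround rule reassigns a surviving nucleus
#' component to the other nucleus class when that class clearly dominates
#' its dilated neighborhood.
#'
#' @param mask A [class_mask()].
#' @param min_area_um2,max_area_um2 Area bounds in square micrometers.
#' @param closing_radius_px Brush radius for closing/opening; 0 disables.
#' @param surround_rule Apply the neighborhood-majority reassignment.
#' @param surround_radius_px Dilation radius of the neighborhood ring.
#' @return A refined [class_mask()].
#' @export
refine_mask <- function(mask, min_area_um2 = 10, max_area_um2 = 600,
                        closing_radius_px = 1, surround_rule = FALSE,
                        surround_radius_px = 5) {
  if (min_area_um2 >= max_area_um2) stop("min_area_um2 must be < max_area_um2")
  px <- attr(mask, "pixel_size_um") %||% 0.44
  px_area <- px^2
  out <- unclass(mask)
  for (cls in c(CLASS_NORMAL, CLASS_TUMOR)) {
    bin <- out == cls
    out[bin] <- CLASS_REMAINDER
    if (closing_radius_px > 0) {
      brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L,
                                  shape = "disc")
      img <- EBImage::opening(EBImage::closing(.ebi(bin), brush), brush)
      bin <- EBImage::imageData(img) > 0.5
    }
    lab <- .label_matrix(bin)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0], max(lab)) * px_area
      ok <- areas >= min_area_um2 & areas <= max_area_um2
      keep <- lab > 0 & ok[pmax(lab, 1L)]
      out[keep] <- cls
    }
  }
  if (surround_rule) {
    brush <- EBImage::makeBrush(2L * as.integer(surround_radius_px) + 1L,
                                shape = "disc")
    for (cls in c(CLASS_TUMOR, CLASS_NORMAL)) {
      other <- if (cls == CLASS_TUMOR) CLASS_NORMAL else CLASS_TUMOR
      lab <- .label_matrix(out == cls)
      n <- max(lab)
      if (n == 0) next
      ring_all <- EBImage::imageData(EBImage::dilate(.ebi(lab > 0), brush)) > 0.5
      for (i in seq_len(n)) {
        comp <- lab == i
        ring <- EBImage::imageData(EBImage::dilate(.ebi(comp), brush)) > 0.5 & !comp
        nb <- out[ring]
        n_other <- sum(nb == other); n_same <- sum(nb == cls)
        if (n_other + n_same > 0 && n_other > 2 * n_same)
          out[comp] <- other
      }
    }
  }
  class_mask(out, px)
}

# max depth of convexity defects of a pixel point set (boundary samples)
.convexity_depth <- function(pts) {
  if (nrow(pts) < 4) return(0)
  hull <- pts[chull(pts), , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 3) return(0)
  hx1 <- hull[, 1]; hy1 <- hull[, 2]
  hx2 <- hull[c(2:nh, 1), 1]; hy2 <- hull[c(2:nh, 1), 2]
  ex <- hx2 - hx1; ey <- hy2 - hy1
  len2 <- pmax(ex^2 + ey^2, 1e-12)
  depth <- 0
  for (i in seq_len(nrow(pts))) {
    dx <- pts[i, 1] - hx1; dy <- pts[i, 2] - hy1
    t <- pmin(pmax((dx * ex + dy * ey) / len2, 0), 1)
    d2 <- (dx - t * ex)^2 + (dy - t * ey)^2
    depth <- max(depth, sqrt(min(d2)))
  }
  depth
}

.watershed_labels <- function(bin, tolerance) {
  if (!any(bin)) return(matrix(0L, nrow(bin), ncol(bin)))
  d <- EBImage::distmap(.ebi(bin))
  wt <- EBImage::watershed(d, tolerance = tolerance, ext = 1)
  matrix(as.integer(EBImage::imageData(wt)), nrow(bin), ncol(bin))
}

#' Split clusters of touching nuclei
#'
#' Distance-transform watershed (the `tolerance` plays the role of the
#' h-maxima depth) applied per nucleus class, followed by a convexity-defect
#' pass: blobs whose deepest boundary defect exceeds `min_defect_px` are
#' re-split with a finer watershed tolerance. Splitting never changes which
#' pixels are foreground.
#'
#' @param mask A [class_mask()] (typically after [refine_mask()]).
#' @param tolerance Watershed tolerance in distance units (px).
#' @param min_defect_px Convexity defect depth (px) that triggers re-splitting.
#' @return List of class `"object_labels"`: `labels` (integer matrix, 0 =
#'   background), `class` (integer vector, class code per label), and
#'   `pixel_size_um`.
#' @export
split_clusters <- function(mask, tolerance = 2, min_defect_px = 3) {
  px <- attr(mask, "pixel_size_um") %||% 0.44
  labels <- matrix(0L, nrow(mask), ncol(mask))
  cls_of <- integer(0)
  nxt <- 0L
  for (cls in c(CLASS_TUMOR, CLASS_NORMAL)) {
    bin <- unclass(mask) == cls
    if (!any(bin)) next
    lab <- .watershed_labels(bin, tolerance)
    # convexity-defect pass on each watershed object
    n0 <- max(lab)
    for (i in seq_len(n0)) {
      comp <- lab == i
      if (sum(comp) < 12) next
      cont <- EBImage::ocontour(.ebi(comp))[[1]]
      if (.convexity_depth(cont) > min_defect_px) {
        sub <- .watershed_labels(comp, tolerance / 2)
        if (max(sub) > 1) {
          lab[comp] <- 0L
          lab[sub > 0] <- max(lab) + sub[sub > 0]
        }
      }
    }
    ids <- sort(unique(lab[lab > 0]))
    relab <- integer(max(lab))
    relab[ids] <- nxt + seq_along(ids)
    labels[lab > 0] <- relab[lab[lab > 0]]
    cls_of <- c(cls_of, rep(cls, length(ids)))
    nxt <- nxt + length(ids)
  }
  structure(list(labels = labels, class = cls_of, pixel_size_um = px),
            class = "object_labels")
}

#' Extract per-nucleus object records
#'
#' One record per label: class, centroid (0-based px), calibrated area,
#' mean red chromaticity and mean chromogen concentration measured on the
#' IHC tile, and the object's boundary contour.
#'
#' @param objects An [split_clusters()] result (`"object_labels"`).
#' @param ihc Optional RGB IHC tile aligned with the label image.
#' @param basis Optional [stain_basis()] for chromogen concentrations.
#' @param analyzed_area_mm2 Analyzed tissue area; defaults to the full
#'   label-image area.
#' @param provenance Free-text tag of the producing annotator.
#' @return Object of class `"object_set"`: data frame with one row per
#'   object (columns `id`, `class`, `cx`, `cy`, `area_um2`,
#'   `mean_red_chromaticity`, `mean_chromogen`) plus a `boundary` attribute
#'   (list of contours) and `analyzed_area_mm2`, `pixel_size_um`,
#'   `provenance` attributes.
#' @export
extract_objects <- function(objects, ihc = NULL, basis = NULL,
                            analyzed_area_mm2 = NULL, provenance = "unknown") {
  stopifnot(inherits(objects, "object_labels"))
  lab <- objects$labels
  px <- objects$pixel_size_um
  if (!is.null(ihc)) {
    ihc <- .check_rgb_tile(ihc)
    if (!all(dim(ihc)[1:2] == dim(lab))) stop("label/tile shape mismatch")
  }
  n <- if (length(objects$class)) length(objects$class) else 0L
  if (is.null(analyzed_area_mm2))
    analyzed_area_mm2 <- prod(dim(lab)) * px^2 / 1e6
  if (n == 0L) {
    df <- data.frame(id = integer(0), class = character(0), cx = numeric(0),
                     cy = numeric(0), area_um2 = numeric(0),
                     mean_red_chromaticity = numeric(0),
                     mean_chromogen = numeric(0))
    return(structure(df, boundary = list(), analyzed_area_mm2 = analyzed_area_mm2,
                     pixel_size_um = px, provenance = provenance,
                     class = c("object_set", "data.frame")))
  }
  labv <- lab[lab > 0]
  rows <- row(lab)[lab > 0]; cols <- col(lab)[lab > 0]
  cnt <- tabulate(labv, n)
  cx <- rowsum(cols - 1, labv)[, 1] / cnt
  cy <- rowsum(rows - 1, labv)[, 1] / cnt
  area <- cnt * px^2
  mean_r <- rep(NA_real_, n); mean_c <- rep(NA_real_, n)
  if (!is.null(ihc)) {
    r_chr <- chromaticity(ihc)$r
    mean_r <- rowsum(r_chr[lab > 0], labv)[, 1] / cnt
    if (!is.null(basis)) {
      cmap <- chromogen_map(deconvolve(od_transform(ihc), basis))
      mean_c <- rowsum(cmap[lab > 0], labv)[, 1] / cnt
    }
  }
  bounds <- EBImage::ocontour(EBImage::Image(objects$labels))
  if (!is.null(names(bounds)))
    bounds <- bounds[order(as.integer(names(bounds)))]
  bounds <- lapply(bounds, function(ct) cbind(x = ct[, 2], y = ct[, 1]))
  df <- data.frame(id = seq_len(n),
                   class = class_code_to_name(objects$class),
                   cx = cx, cy = cy, area_um2 = area,
                   mean_red_chromaticity = mean_r, mean_chromogen = mean_c)
  structure(df, boundary = bounds, analyzed_area_mm2 = analyzed_area_mm2,
            pixel_size_um = px, provenance = provenance,
            class = c("object_set", "data.frame"))
}
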