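# Pipeline outputs: tumor burden (a number-based percentage of nuclei),
# annotation rate, per-lesion mean red chromaticity, systematic-random field
# sampling, and the stereological unbiased counting frame.

#' Tumor burden from nucleus objects
#'
#' Number-based percentage: tumor-cell nuclei divided by all nuclei.
#' Object counts only; areas play no role.
#'
#' @param objects An [extract_objects()] result, or a list/data frame with a
#'   `class` column using the names in [mask_classes()].
#' @return List of class `"tumor_burden"`: `n_tumor`, `n_normal`,
#'   `burden_pct`.
#' @export
#' @examples
#' ob <- data.frame(class = rep(c("tumor-nucleus", "normal-nucleus"), c(70, 30)))
#' tumor_burden(ob)$burden_pct
tumor_burden <- function(objects) {
  cls <- objects$class
  n_t <- sum(cls == "tumor-nucleus")
  n_n <- sum(cls == "normal-nucleus")
  if (n_t + n_n == 0) stop("tumor burden is undefined without nucleus objects")
  structure(list(n_tumor = n_t, n_normal = n_n,
                 burden_pct = 100 * n_t / (n_t + n_n)),
            class = "tumor_burden")
}

#' @export
print.tumor_burden <- function(x, ...) {
  cat(sprintf("tumor nuclei: %d, normal nuclei: %d -> burden %.1f%%\n",
              x$n_tumor, x$n_normal, x$burden_pct))
  invisible(x)
}

#' Annotation rate
#'
#' Accepted labels per square millimeter of analyzed tissue.
#'
#' @param objects An object set (rows are accepted labels).
#' @param analyzed_area_mm2 Analyzed area; defaults to the object set's
#'   attribute.
#' @return Labels per mm^2.
#' @export
annotation_rate <- function(objects, analyzed_area_mm2 = NULL) {
  if (is.null(analyzed_area_mm2))
    analyzed_area_mm2 <- attr(objects, "analyzed_area_mm2")
  if (is.null(analyzed_area_mm2) || analyzed_area_mm2 <= 0)
    stop("analyzed area must be positive")
  nrow(objects) / analyzed_area_mm2
}

#' Mean red chromaticity of tumor objects
#'
#' Mean of the per-object mean red chromaticity over tumor-class objects,
#' with a t-based 95% confidence interval (requires at least two objects).
#'
#' @param objects An [extract_objects()] result.
#' @param conf_level Confidence level.
#' @return List: `mean`, `ci` (length 2), `n`.
#' @export
mean_red_chromaticity <- function(objects, conf_level = 0.95) {
  v <- objects$mean_red_chromaticity[objects$class == "tumor-nucleus"]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no tumor objects with chromaticity measurements")
  m <- mean(v)
  if (length(v) == 1) return(list(mean = m, ci = c(NA_real_, NA_real_), n = 1L))
  half <- qt(1 - (1 - conf_level) / 2, length(v) - 1) * sd(v) / sqrt(length(v))
  list(mean = m, ci = c(m - half, m + half), n = length(v))
}

#' Systematic-random sampling plan
#'
#' @param roi Two-column polygon (same units as the field size).
#' @param n_fields Target number of fields.
#' @param field_size Numeric pair (width, height) of a field.
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return Object of class `"sampling_plan"`.
#' @export
sampling_plan <- function(roi, n_fields, field_size, seed = 1L) {
  if (length(field_size) == 1) field_size <- rep(field_size, 2)
  area <- polygon_area(roi)
  if (area < n_fields * prod(field_size))
    stop("roi too small for the requested number of fields")
  structure(list(roi = roi, n_fields = as.integer(n_fields),
                 field_size = field_size, seed = as.integer(seed)),
            class = "sampling_plan")
}

#' Systematic-random fields
#'
#' Uniform grid whose cell area is `roi_area / n_fields`, with one random
#' offset; a grid field belongs to the sample when its center lies inside
#' the ROI polygon. Deterministic for a fixed seed.
#'
#' @param plan A [sampling_plan()].
#' @return Data frame of field origins (`x0`, `y0`) and sizes (`w`, `h`).
#' @export
systematic_random_fields <- function(plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  roi <- plan$roi
  cell <- sqrt(polygon_area(roi) / plan$n_fields)
  with_seed(plan$seed, {
    off <- runif(2, 0, cell)
    xr <- range(roi[, 1]); yr <- range(roi[, 2])
    gx <- seq(floor((xr[1] - cell) / cell) * cell + off[1], xr[2] + cell, by = cell)
    gy <- seq(floor((yr[1] - cell) / cell) * cell + off[2], yr[2] + cell, by = cell)
    grid <- expand.grid(x0 = gx, y0 = gy)
    cxs <- grid$x0 + plan$field_size[1] / 2
    cys <- grid$y0 + plan$field_size[2] / 2
    keep <- point_in_polygon(cxs, cys, roi)
    data.frame(x0 = grid$x0[keep], y0 = grid$y0[keep],
               w = plan$field_size[1], h = plan$field_size[2])
  })
}

#' Unbiased counting frame
#'
#' Stereological counting frame with inclusion edges top and right and
#' forbidden edges left and bottom with their extensions (the forbidden
#' line runs from above the top-left corner down the left edge, along the
#' bottom edge, and down from the bottom-right corner). Defaults are a
#' 30 um x 25 um frame converted to pixels.
#'
#' @param origin Numeric pair: top-left corner (x0, y0) in pixel coordinates
#'   (y grows downward).
#' @param width_um,height_um Frame size in micrometers.
#' @param pixel_size_um Pixel calibration.
#' @return Object of class `"counting_frame"` with fields `x0`, `y0`, `x1`,
#'   `y1` in pixels.
#' @export
counting_frame <- function(origin, width_um = 30, height_um = 25,
                           pixel_size_um = 0.44) {
  structure(list(x0 = origin[1], y0 = origin[2],
                 x1 = origin[1] + width_um / pixel_size_um,
                 y1 = origin[2] + height_um / pixel_size_um),
            class = "counting_frame")
}

# does polygon P intersect the axis-aligned rectangle?
.poly_hits_rect <- function(P, x0, y0, x1, y1) {
  if (any(P[, 1] >= x0 & P[, 1] <= x1 & P[, 2] >= y0 & P[, 2] <= y1))
    return(TRUE)
  # rectangle corner inside polygon (object swallowing the frame)
  any(point_in_polygon(c(x0, x1, x0, x1), c(y0, y0, y1, y1), P))
}

# does polygon P touch the forbidden line of the frame?
.poly_hits_forbidden <- function(P, x0, y0, x1, y1) {
  n <- nrow(P)
  i2 <- c(2:n, 1)
  ax <- P[, 1]; ay <- P[, 2]
  bx <- P[i2, 1]; by <- P[i2, 2]
  # piece A: x = x0 for y <= y1 (left edge plus upward extension)
  if (.crosses_vline(ax, ay, bx, by, x0, -Inf, y1)) return(TRUE)
  # piece B: y = y1 for x0 <= x <= x1 (bottom edge)
  if (.crosses_hline(ax, ay, bx, by, y1, x0, x1)) return(TRUE)
  # piece C: x = x1 for y >= y1 (downward extension at bottom-right)
  if (.crosses_vline(ax, ay, bx, by, x1, y1, Inf)) return(TRUE)
  FALSE
}

#' Count objects in an unbiased counting frame
#'
#' Gundersen rule on object boundaries: an object is counted when it
#' intersects the frame (or its inclusion edges) and does not touch the
#' forbidden line. Frames tiling the plane therefore count every object
#' exactly once.
#'
#' @param objects An [extract_objects()] result (boundary contours are
#'   used), or a list with `class` and a `boundary` attribute.
#' @param frame A [counting_frame()].
#' @return Named integer vector of counts per class.
#' @export
counting_frame_count <- function(objects, frame) {
  bounds <- attr(objects, "boundary")
  if (is.null(bounds)) stop("objects carry no boundary contours")
  cls <- objects$class
  counted <- character(0)
  for (i in seq_along(bounds)) {
    P <- bounds[[i]]
    if (!.poly_hits_rect(P, frame$x0, frame$y0, frame$x1, frame$y1)) next
    if (.poly_hits_forbidden(P, frame$x0, frame$y0, frame$x1, frame$y1)) next
    counted <- c(counted, cls[i])
  }
  tab <- table(factor(counted, levels = unique(cls)))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Stereological tumor burden
#'
#' Samples counting-frame fields by systematic-random sampling over the ROI
#' and accumulates Gundersen-rule counts of tumor and normal nuclei.
#'
#' @param objects An [extract_objects()] result with boundaries.
#' @param roi Two-column polygon in pixel coordinates.
#' @param n_frames Number of frames to aim for.
#' @param frame_um Numeric pair: frame width and height in micrometers.
#' @param pixel_size_um Calibration.
#' @param seed Seed for the sampling plan.
#' @return List: `burden_pct`, `n_tumor`, `n_normal`, `n_frames`.
#' @export
stereology_burden <- function(objects, roi, n_frames = 200,
                              frame_um = c(30, 25), pixel_size_um = 0.44,
                              seed = 1L) {
  fs <- frame_um / pixel_size_um
  plan <- sampling_plan(roi, n_frames, fs, seed = seed)
  fields <- systematic_random_fields(plan)
  n_t <- 0L; n_n <- 0L
  for (i in seq_len(nrow(fields))) {
    fr <- counting_frame(c(fields$x0[i], fields$y0[i]),
                         width_um = frame_um[1], height_um = frame_um[2],
                         pixel_size_um = pixel_size_um)
    ct <- counting_frame_count(objects, fr)
    n_t <- n_t + sum(ct[names(ct) == "tumor-nucleus"])
    n_n <- n_n + sum(ct[names(ct) == "normal-nucleus"])
  }
  if (n_t + n_n == 0) stop("no nuclei counted in any frame")
  list(burden_pct = 100 * n_t / (n_t + n_n), n_tumor = n_t, n_normal = n_n,
       n_frames = nrow(fields))
}
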