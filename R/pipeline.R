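# End-to-end convenience wrappers: simulate -> annotate on IHC -> transfer
# to the H&E frame -> refine -> split -> objects.

#' Run the threshold annotation pipeline on an aligned pair
#'
#' Classifies IHC pixels, transfers labels into the H&E frame, applies
#' morphological refinement and cluster splitting, and extracts nucleus
#' objects with chromaticity/chromogen measurements.
#'
#' @param pair An `"aligned_pair"`.
#' @param basis A [stain_basis()] matching the staining.
#' @param params A [threshold_params()] with the same chromogen.
#' @param transform 2 x 3 affine (IHC -> H&E); defaults to the pair's own
#'   (use [estimate_transform()] when it is unknown).
#' @param roi Optional logical ROI matrix in the IHC frame.
#' @param min_area_um2,max_area_um2,closing_radius_px Passed to
#'   [refine_mask()].
#' @param tolerance,min_defect_px Passed to [split_clusters()].
#' @return An [extract_objects()] object set (provenance records the
#'   chromogen).
#' @export
annotate_pair <- function(pair, basis, params = threshold_params(),
                          transform = pair$transform, roi = NULL,
                          min_area_um2 = 12, max_area_um2 = 700,
                          closing_radius_px = 1, tolerance = 1,
                          min_defect_px = 3) {
  px <- pair$pixel_size_um %||% 0.44
  mask_ihc <- classify_pixels(pair$ihc, basis, params, roi = roi,
                              pixel_size_um = px)
  mask_he <- transfer_labels(mask_ihc, transform,
                             target_dim = dim(pair$he)[1:2])
  mask_he <- refine_mask(mask_he, min_area_um2 = min_area_um2,
                         max_area_um2 = max_area_um2,
                         closing_radius_px = closing_radius_px)
  labs <- split_clusters(mask_he, tolerance = tolerance,
                         min_defect_px = min_defect_px)
  # measurements are taken on the IHC tile warped into the H&E frame
  ihc_he <- .warp_rgb(pair$ihc, transform, dim(pair$he)[1:2])
  extract_objects(labs, ihc = ihc_he, basis = basis,
                  provenance = paste0("THR_", attr(basis, "chromogen")))
}

# nearest-neighbor warp of an RGB tile (shared with transfer_labels logic)
.warp_rgb <- function(tile, transform, target_dim) {
  if (inherits(transform, "stain_transform")) transform <- transform$transform
  inv <- .affine_invert(transform)
  h <- target_dim[1]; w <- target_dim[2]
  X <- rep(seq_len(w) - 1, each = h)
  Y <- rep(seq_len(h) - 1, times = w)
  sx <- inv[1, 1] * X + inv[1, 2] * Y + inv[1, 3]
  sy <- inv[2, 1] * X + inv[2, 2] * Y + inv[2, 3]
  ri <- round(sy) + 1L; ci <- round(sx) + 1L
  ok <- ri >= 1L & ri <= dim(tile)[1] & ci >= 1L & ci <= dim(tile)[2]
  out <- array(1, dim = c(h, w, 3))
  for (k in 1:3) {
    plane <- rep(1, h * w)
    src <- tile[, , k]
    plane[ok] <- src[cbind(ri[ok], ci[ok])]
    out[, , k] <- plane
  }
  out
}

#' Simulate and annotate one scene
#'
#' Convenience used throughout the tests: generates a scene, renders the
#' pair, runs the threshold pipeline, and returns everything including the
#' ground truth.
#'
#' @param config A [scene_config()].
#' @param params Optional [threshold_params()]; defaults to the scene's
#'   chromogen.
#' @param ... Passed to [annotate_pair()].
#' @return List: `scene`, `pair`, `truth` (mask), `objects`.
#' @export
simulate_annotated_scene <- function(config, params = NULL, ...) {
  scene <- generate_scene(config)
  pair <- render_pair(scene)
  basis <- stain_basis(config$chromogen)
  if (is.null(params)) params <- threshold_params(config$chromogen)
  objects <- annotate_pair(pair, basis, params, ...)
  list(scene = scene, pair = pair, truth = truth_masks(scene),
       objects = objects)
}
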