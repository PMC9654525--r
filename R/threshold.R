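# Handcrafted chromaticity/deconvolution threshold annotators (the THR_brown
# and THR_red style classifiers): pixel gates on the deconvolved chromogen
# and hematoxylin concentrations, blue chromaticity, and brightness.

#' Parameters of the threshold annotator
#'
#' Gates, in priority order: a pixel is a tumor-nucleus pixel if its
#' deconvolved chromogen concentration passes `chromogen_conc_min`;
#' otherwise a normal-nucleus pixel if hematoxylin concentration and blue
#' chromaticity pass their gates; otherwise background if bright and
#' unsaturated; otherwise remainder tissue. Any gate set to `NA` is replaced
#' per image by Otsu's threshold on the corresponding channel; the shipped
#' numeric defaults keep results reproducible.
#'
#' @param chromogen `"FastRed"` or `"DAB"`; must match the stain basis used.
#' @param chromogen_conc_min Tumor gate on chromogen concentration.
#' @param hematoxylin_conc_min Normal-nucleus gate on hematoxylin
#'   concentration.
#' @param blue_chromaticity_min Normal-nucleus gate on blue chromaticity.
#' @param background_lum_min Background gate on mean RGB brightness.
#' @param background_sat_max Background gate on saturation (max - min channel).
#' @param max_od_residual Normal-nucleus gate on the deconvolution
#'   reconstruction residual: pixels whose color is poorly explained by the
#'   stain basis (melanin pigment, foreign material) cannot be
#'   counterstained nuclei.
#' @param contrast_window_px Optional window (px) for local-contrast
#'   enhancement of the hematoxylin channel before thresholding.
#' @return Object of class `"threshold_params"`.
#' @export
threshold_params <- function(chromogen = c("FastRed", "DAB"),
                             chromogen_conc_min = 0.30,
                             hematoxylin_conc_min = 0.30,
                             blue_chromaticity_min = 0.36,
                             background_lum_min = 0.88,
                             background_sat_max = 0.08,
                             max_od_residual = 0.35,
                             contrast_window_px = NULL) {
  chromogen <- match.arg(chromogen)
  p <- list(chromogen = chromogen,
            chromogen_conc_min = chromogen_conc_min,
            hematoxylin_conc_min = hematoxylin_conc_min,
            blue_chromaticity_min = blue_chromaticity_min,
            background_lum_min = background_lum_min,
            background_sat_max = background_sat_max,
            max_od_residual = max_od_residual,
            contrast_window_px = contrast_window_px)
  num <- unlist(p[2:7])
  if (any(!is.na(num) & !is.finite(num))) stop("thresholds must be finite")
  structure(p, class = "threshold_params")
}

.box_mean <- function(m, radius) {
  if (radius <= 0) return(m)
  k <- 2L * as.integer(radius) + 1L
  f <- matrix(1 / (k * k), k, k)
  EBImage::filter2(m, f, boundary = "replicate")
}

.otsu_or <- function(value, channel) {
  if (!is.na(value)) return(value)
  rng <- range(channel)
  if (diff(rng) < 1e-9) return(rng[1] + 1e-6)
  EBImage::otsu(EBImage::Image((channel - rng[1]) / diff(rng)), levels = 256) *
    diff(rng) + rng[1]
}

#' Classify IHC pixels by thresholding
#'
#' The handcrafted annotator: deconvolves the IHC tile against the stain
#' basis and assigns each ROI pixel exactly one of the four classes with
#' priority tumor > normal > background > remainder.
#'
#' @param ihc RGB tile of the IHC rendering.
#' @param basis A [stain_basis()]; its chromogen must match `params`.
#' @param params A [threshold_params()].
#' @param roi Optional logical matrix marking analyzable pixels (default all).
#' @param pixel_size_um Pixel size carried into the returned mask.
#' @return A [class_mask()]; pixels outside `roi` are background.
#' @export
classify_pixels <- function(ihc, basis, params = threshold_params(),
                            roi = NULL, pixel_size_um = 0.44) {
  if (attr(basis, "chromogen") != params$chromogen)
    stop("stain basis and threshold parameters use different chromogens")
  ihc <- .check_rgb_tile(ihc)
  cm <- deconvolve(od_transform(ihc), basis)
  chrom <- chromogen_map(cm)
  hema <- cm$hematoxylin
  if (!is.null(params$contrast_window_px) && params$contrast_window_px > 0)
    hema <- hema - 0.5 * .box_mean(hema, params$contrast_window_px)
  ch <- chromaticity(ihc)
  lum <- (ihc[, , 1] + ihc[, , 2] + ihc[, , 3]) / 3
  sat <- pmax(ihc[, , 1], ihc[, , 2], ihc[, , 3]) -
    pmin(ihc[, , 1], ihc[, , 2], ihc[, , 3])

  t1 <- .otsu_or(params$chromogen_conc_min, chrom)
  t2 <- .otsu_or(params$hematoxylin_conc_min, hema)
  t3 <- .otsu_or(params$blue_chromaticity_min, ch$b)
  is_tumor <- chrom >= t1
  is_normal <- !is_tumor & hema >= t2 & ch$b >= t3 &
    cm$residual <= params$max_od_residual
  is_bg <- !is_tumor & !is_normal &
    lum >= params$background_lum_min & sat <= params$background_sat_max
  m <- matrix(CLASS_REMAINDER, nrow(lum), ncol(lum))
  m[is_bg] <- CLASS_BACKGROUND
  m[is_normal] <- CLASS_NORMAL
  m[is_tumor] <- CLASS_TUMOR
  if (!is.null(roi)) m[!roi] <- CLASS_BACKGROUND
  class_mask(m, pixel_size_um)
}
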