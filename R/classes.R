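# Pixel class codes shared by every stage of the pipeline.
# 0 is reserved for "unlabeled/ignore" (contributes nothing to training loss).
CLASS_IGNORE     <- 0L
CLASS_TUMOR      <- 1L
CLASS_NORMAL     <- 2L
CLASS_REMAINDER  <- 3L
CLASS_BACKGROUND <- 4L
CLASS_CLUSTER    <- 5L  # auxiliary "dilated normal cluster" training class

#' Pixel class codes
#'
#' The integer codes used in every class mask produced by the package:
#' tumor-cell nucleus (1), normal-cell nucleus (2), remainder tissue (3),
#' unstained background (4). Code 0 marks unlabeled pixels (ignored in
#' training) and code 5 the auxiliary dilated normal-cluster class used
#' only as a training label.
#'
#' @return Named integer vector of class codes.
#' @export
#' @examples
#' mask_classes()
mask_classes <- function() {
  c(ignore = CLASS_IGNORE, tumor = CLASS_TUMOR, normal = CLASS_NORMAL,
    remainder = CLASS_REMAINDER, background = CLASS_BACKGROUND,
    cluster = CLASS_CLUSTER)
}

#' Construct a class mask
#'
#' A class mask is an integer matrix of per-pixel class codes (see
#' [mask_classes()]) carrying the physical pixel size as an attribute.
#'
#' @param values Integer matrix of class codes.
#' @param pixel_size_um Side length of a pixel in micrometers.
#' @return An integer matrix of class `"class_mask"`.
#' @export
class_mask <- function(values, pixel_size_um = 0.44) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "integer"
  bad <- !(values %in% c(CLASS_IGNORE, CLASS_TUMOR, CLASS_NORMAL,
                         CLASS_REMAINDER, CLASS_BACKGROUND, CLASS_CLUSTER))
  if (any(bad)) stop("mask contains unknown class codes")
  structure(values, pixel_size_um = pixel_size_um, class = c("class_mask", "matrix", "array"))
}

# keep attributes when subassigning is not needed; helper to rewrap
.as_mask <- function(values, template) {
  class_mask(values, pixel_size_um = attr(template, "pixel_size_um") %||% 0.44)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.class_names <- c("tumor-nucleus", "normal-nucleus", "remainder", "background")

# map code (1..4) <-> name
class_code_to_name <- function(code) .class_names[code]
class_name_to_code <- function(name) match(name, .class_names)

#' @export
print.class_mask <- function(x, ...) {
  tab <- table(factor(as.vector(x), levels = 0:5,
                      labels = c("ignore", .class_names, "cluster")))
  cat(sprintf("<class_mask> %d x %d px, %.3g um/px\n", nrow(x), ncol(x),
              attr(x, "pixel_size_um")))
  print(tab[tab > 0])
  invisible(x)
}
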