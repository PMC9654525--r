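# Plain-text / standard-format input and output. TIFF/PNG writers are thin
# wrappers over the tiff and png packages (Suggests); object sets serialize
# to GeoJSON FeatureCollections and flat CSV.

#' Write an RGB tile to TIFF
#' @param tile H x W x 3 array in \[0, 1\].
#' @param path Output path.
#' @export
write_tile_tiff <- function(tile, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF files")
  tiff::writeTIFF(tile, path)
  invisible(path)
}

#' Read an RGB tile from TIFF or PNG
#' @param path Input path.
#' @return H x W x 3 array in \[0, 1\].
#' @export
read_tile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("'tiff' required")
      tiff::readTIFF(path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE)) stop("'png' required")
      png::readPNG(path)
    },
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

# fixed display palette for the 4+1 classes
.mask_palette <- matrix(c(
  0.85, 0.15, 0.15,   # tumor: red
  0.20, 0.60, 0.20,   # normal: green
  0.92, 0.86, 0.55,   # remainder: yellow-ish
  1.00, 1.00, 1.00,   # background: white
  0.55, 0.75, 0.95),  # cluster: light blue
  ncol = 3, byrow = TRUE)

#' Write a class mask as a paletted PNG
#' @param mask A [class_mask()].
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG files")
  m <- unclass(mask)
  img <- array(0, dim = c(nrow(m), ncol(m), 3))
  for (cls in 1:5) {
    sel <- m == cls
    for (k in 1:3) {
      plane <- img[, , k]; plane[sel] <- .mask_palette[cls, k]
      img[, , k] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Read a paletted class-mask PNG written by [write_mask_png()]
#' @param path Input path.
#' @param pixel_size_um Calibration to attach.
#' @return A [class_mask()].
#' @export
read_mask_png <- function(path, pixel_size_um = 0.44) {
  img <- read_tile(path)
  m <- matrix(CLASS_IGNORE, dim(img)[1], dim(img)[2])
  for (cls in 1:5) {
    d <- abs(img[, , 1] - .mask_palette[cls, 1]) +
      abs(img[, , 2] - .mask_palette[cls, 2]) +
      abs(img[, , 3] - .mask_palette[cls, 3])
    m[d < 0.02] <- cls
  }
  class_mask(m, pixel_size_um)
}

#' Serialize an object set to GeoJSON
#'
#' One Feature per object: polygon boundary (pixel coordinates) with
#' properties `class`, `area_um2`, `mean_red_chromaticity`.
#'
#' @param objects An [extract_objects()] result.
#' @param path Output path.
#' @export
write_objects_geojson <- function(objects, path) {
  bounds <- attr(objects, "boundary")
  feats <- lapply(seq_len(nrow(objects)), function(i) {
    ring <- bounds[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(r) c(ring[r, 1], ring[r, 2])))),
         properties = list(id = objects$id[i], class = objects$class[i],
                           area_um2 = objects$area_um2[i],
                           mean_red_chromaticity = objects$mean_red_chromaticity[i]))
  })
  fc <- list(type = "FeatureCollection", features = feats,
             properties = list(
               analyzed_area_mm2 = attr(objects, "analyzed_area_mm2"),
               pixel_size_um = attr(objects, "pixel_size_um"),
               provenance = attr(objects, "provenance")))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flat-CSV serialization of an object set
#' @param objects An [extract_objects()] result.
#' @param path Output path.
#' @export
write_objects_csv <- function(objects, path) {
  write.csv(as.data.frame(unclass(objects)[
    c("id", "class", "cx", "cy", "area_um2", "mean_red_chromaticity",
      "mean_chromogen")]), path, row.names = FALSE)
  invisible(path)
}
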