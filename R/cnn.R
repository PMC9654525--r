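# Desk-scale U-net harness: training-pair export (3-band IHC or 6-band
# H&E+IHC input), dilation of normal-cell labels into cluster annotations,
# training with Adam and checkpoint selection, and feature-map
# classification (mean filter + per-class thresholds).

#' U-net training configuration
#'
#' Canonical encoder/decoder topology scaled to desk size: `depth` pooling
#' levels and `base_channels` channels in the first block. The published
#' whole-slide regime used 512 px tiles and learning rates of 1e-6/1e-7;
#' the tiny default network trains with a correspondingly larger rate.
#'
#' @param input_bands 3 (IHC RGB) or 6 (H&E RGB + IHC RGB).
#' @param tile_px Tile side; must be divisible by `2^depth`.
#' @param learning_rate Adam learning rate.
#' @param iterations Training iterations (one batch each).
#' @param batch_size Tiles per iteration.
#' @param augment Random rot90/flip augmentation of image and labels jointly.
#' @param base_channels,depth Network width and number of pooling levels.
#' @param n_classes Number of output classes (default 4).
#' @param checkpoint_every Evaluate and possibly keep a checkpoint every so
#'   many iterations (selection by validation pixel accuracy, or training
#'   accuracy when no validation set is given); 0 keeps the final weights.
#' @param seed RNG seed for weight init, batch sampling and augmentation.
#' @return Object of class `"unet_config"`.
#' @export
unet_config <- function(input_bands = 6, tile_px = 128, learning_rate = 1e-3,
                        iterations = 200, batch_size = 2, augment = TRUE,
                        base_channels = 8, depth = 2, n_classes = 4,
                        checkpoint_every = 50, seed = 1L) {
  if (!input_bands %in% c(3, 6)) stop("input_bands must be 3 or 6")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (tile_px %% 2^depth != 0) stop("tile_px must be divisible by 2^depth")
  structure(list(input_bands = as.integer(input_bands),
                 tile_px = as.integer(tile_px),
                 learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 augment = isTRUE(augment),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 n_classes = as.integer(n_classes),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "unet_config")
}

# stack the input bands of one aligned pair: 3 = IHC RGB, 6 = H&E then IHC
.input_stack <- function(pair, input_bands) {
  if (input_bands == 3) return(pair$ihc)
  he <- pair$he; ihc <- pair$ihc
  out <- array(0, dim = c(dim(he)[1], dim(he)[2], 6))
  out[, , 1:3] <- he; out[, , 4:6] <- ihc
  out
}

#' Build an in-memory training dataset from aligned pairs and label masks
#'
#' Cuts non-overlapping tiles of `tile_px` from each pair/mask; masks must
#' already be in the H&E frame (after [transfer_labels()]). Unlabeled
#' pixels (class 0) are ignored by the loss; tiles without any labeled
#' pixel are skipped. The auxiliary cluster class (5) is merged into the
#' normal class for training.
#'
#' @param pairs List of `"aligned_pair"` objects.
#' @param masks List of [class_mask()]s in the H&E frame.
#' @param config A [unet_config()].
#' @return List of class `"unet_dataset"`: `images` (list of H x W x C
#'   arrays), `labels` (list of integer matrices), `manifest` (class pixel
#'   counts and tile bookkeeping).
#' @export
build_training_dataset <- function(pairs, masks, config) {
  if (length(pairs) != length(masks)) stop("pairs/masks length mismatch")
  tp <- config$tile_px
  images <- list(); labels <- list()
  n_skipped <- 0L
  for (i in seq_along(pairs)) {
    x <- .input_stack(pairs[[i]], config$input_bands)
    m <- unclass(masks[[i]])
    m[m == CLASS_CLUSTER] <- CLASS_NORMAL
    if (!all(dim(x)[1:2] == dim(m))) stop("pair/mask shape mismatch")
    nr <- ceiling(nrow(m) / tp); nc <- ceiling(ncol(m) / tp)
    for (bi in seq_len(nr)) {
      for (bj in seq_len(nc)) {
        r0 <- min((bi - 1) * tp + 1, nrow(m) - tp + 1)
        c0 <- min((bj - 1) * tp + 1, ncol(m) - tp + 1)
        if (r0 < 1 || c0 < 1) next  # image smaller than a tile
        lab <- m[r0:(r0 + tp - 1), c0:(c0 + tp - 1)]
        if (!any(lab > 0L)) { n_skipped <- n_skipped + 1L; next }
        images[[length(images) + 1L]] <- x[r0:(r0 + tp - 1), c0:(c0 + tp - 1), , drop = FALSE]
        labels[[length(labels) + 1L]] <- lab
      }
    }
  }
  counts <- integer(config$n_classes)
  for (lab in labels)
    counts <- counts + tabulate(lab[lab > 0L], config$n_classes)
  names(counts) <- .class_names[seq_len(config$n_classes)]
  structure(list(images = images, labels = labels,
                 manifest = list(n_tiles = length(images),
                                 n_skipped = n_skipped,
                                 tile_px = tp,
                                 input_bands = config$input_bands,
                                 class_pixel_counts = counts)),
            class = "unet_dataset")
}

#' Export training pairs to a dataset directory
#'
#' Writes `images/` (one CSV-encoded band stack per tile), `labels/`
#' (integer label tiles) and `manifest.json` with per-class pixel counts.
#' A plain-text serialization keeps the export portable; the in-memory
#' [build_training_dataset()] result is what [train_unet()] consumes.
#'
#' @param pairs,masks,config As in [build_training_dataset()].
#' @param dir Output directory (created if needed).
#' @param max_residual_px Pairs whose alignment residual attribute exceeds
#'   this limit are excluded from the export (misalignment guard).
#' @return The manifest, invisibly.
#' @export
export_training_pairs <- function(pairs, masks, config, dir,
                                  max_residual_px = 3) {
  keep <- vapply(pairs, function(p) {
    r <- attr(p, "residual") %||% p$residual %||% 0
    is.na(r) || r <= max_residual_px
  }, logical(1))
  ds <- build_training_dataset(pairs[keep], masks[keep], config)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$images)) {
    x <- ds$images[[i]]
    m <- matrix(x, nrow = dim(x)[1])  # bands unrolled column-blockwise
    write.csv(m, file.path(dir, "images", sprintf("tile_%04d.csv", i)),
              row.names = FALSE)
    write.csv(ds$labels[[i]],
              file.path(dir, "labels", sprintf("tile_%04d.csv", i)),
              row.names = FALSE)
  }
  manifest <- c(ds$manifest,
                list(n_pairs_excluded_by_residual = sum(!keep)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load an exported dataset directory
#'
#' @param dir Directory written by [export_training_pairs()].
#' @return A `"unet_dataset"` list.
#' @export
load_training_pairs <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ifs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  lfs <- sort(list.files(file.path(dir, "labels"), full.names = TRUE))
  tp <- manifest$tile_px; nb <- manifest$input_bands
  images <- lapply(ifs, function(f) {
    m <- as.matrix(read.csv(f))
    array(m, dim = c(tp, tp, nb))
  })
  labels <- lapply(lfs, function(f) {
    m <- as.matrix(read.csv(f)); storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  })
  structure(list(images = images, labels = labels, manifest = manifest),
            class = "unet_dataset")
}

#' Dilate normal-cell labels into cluster annotations
#'
#' Grows normal-nucleus labels by `radius_um` and marks the grown ring with
#' the auxiliary cluster class, which augments -- never overwrites -- tumor
#' labels (or any other existing label).
#'
#' @param mask A [class_mask()].
#' @param radius_um Dilation radius in micrometers; 0 returns the input.
#' @return A [class_mask()] with class 5 rings around normal nuclei.
#' @export
dilate_normal_labels <- function(mask, radius_um) {
  if (radius_um <= 0) return(mask)
  px <- attr(mask, "pixel_size_um") %||% 0.44
  r <- max(1L, round(radius_um / px))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  bin <- unclass(mask) == CLASS_NORMAL
  grown <- EBImage::imageData(EBImage::dilate(.ebi(bin), brush)) > 0.5
  out <- unclass(mask)
  ring <- grown & !bin & out != CLASS_TUMOR & out != CLASS_NORMAL
  out[ring] <- CLASS_CLUSTER
  class_mask(out, px)
}

#' Train the U-net
#'
#' Adam on softmax cross-entropy; label 0 pixels contribute zero loss.
#' The returned model holds the checkpoint with the best (validation or
#' training) pixel accuracy, mirroring selection of a mid-training
#' checkpoint by monitored accuracy.
#'
#' @param dataset A `"unet_dataset"`.
#' @param config A [unet_config()].
#' @param validation Optional `"unet_dataset"` used for checkpoint selection.
#' @return Object of class `"unet_model"`: `weights`, `config`, `loss`
#'   (per-iteration), `best_accuracy`, `best_iteration`.
#' @export
train_unet <- function(dataset, config, validation = NULL) {
  if (length(dataset$images) == 0) stop("empty training dataset")
  nb <- dim(dataset$images[[1]])[3]
  if (nb != config$input_bands)
    stop("dataset bands do not match config$input_bands")
  w0 <- cpp_unet_init(config$input_bands, config$n_classes,
                      config$base_channels, config$depth, config$seed)
  fit <- cpp_unet_train(w0, dataset$images, dataset$labels,
                        config$iterations, config$learning_rate,
                        config$batch_size, config$augment, config$seed,
                        config$checkpoint_every,
                        if (is.null(validation)) NULL else validation$images,
                        if (is.null(validation)) NULL else validation$labels)
  structure(list(weights = fit$weights, config = config, loss = fit$loss,
                 best_accuracy = fit$best_accuracy,
                 best_iteration = fit$best_iteration),
            class = "unet_model")
}

#' Per-class probability maps from a trained U-net
#'
#' @param model A [train_unet()] model.
#' @param pair An `"aligned_pair"` (bands are stacked according to the
#'   model's configuration), or an H x W x C array.
#' @return H x W x K array of softmax probabilities.
#' @export
predict_unet <- function(model, pair) {
  x <- if (is.array(pair)) pair else .input_stack(pair, model$config$input_bands)
  if (dim(x)[3] != model$config$input_bands) stop("band count mismatch")
  cpp_unet_predict(model$weights, x)
}

#' Training loss of a model on one labeled tile
#'
#' Mean softmax cross-entropy over labeled (non-ignore) pixels.
#'
#' @param model A [train_unet()] model.
#' @param image H x W x C array.
#' @param labels Integer matrix (0 = ignore).
#' @return Scalar loss.
#' @export
unet_loss <- function(model, image, labels) {
  storage.mode(labels) <- "integer"
  cpp_unet_loss(model$weights, image, labels)
}

#' Feature-map classifier
#'
#' @param mean_filter_radius Box mean-filter radius (px) applied to each
#'   probability map before thresholding.
#' @param thresholds Per-class probability thresholds in \[0, 1\].
#' @return Object of class `"feature_map_classifier"`.
#' @export
feature_map_classifier <- function(mean_filter_radius = 3,
                                   thresholds = c(0.5, 0.5, 0.5, 0.5)) {
  if (mean_filter_radius < 0) stop("radius must be >= 0")
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must be in [0, 1]")
  structure(list(mean_filter_radius = mean_filter_radius,
                 thresholds = thresholds),
            class = "feature_map_classifier")
}

#' Classify probability maps by mean filtering and thresholding
#'
#' Each class map is box-mean filtered, then gated by its threshold; the
#' pixel takes the argmax among passing classes, or remainder when no class
#' passes.
#'
#' @param probs H x W x K array of per-class maps in \[0, 1\].
#' @param fmc A [feature_map_classifier()]; its threshold count must match K.
#' @param pixel_size_um Calibration carried into the mask.
#' @return A [class_mask()].
#' @export
classify_feature_maps <- function(probs, fmc = feature_map_classifier(),
                                  pixel_size_um = 0.44) {
  K <- dim(probs)[3]
  if (length(fmc$thresholds) != K)
    stop("threshold count does not match the number of classes")
  h <- dim(probs)[1]; w <- dim(probs)[2]
  filt <- array(0, dim = dim(probs))
  for (k in seq_len(K))
    filt[, , k] <- .box_mean(probs[, , k], fmc$mean_filter_radius)
  pass <- sweep(filt, 3, fmc$thresholds, ">=")
  gated <- filt
  gated[!pass] <- -Inf
  best <- apply(gated, c(1, 2), which.max)
  none <- !apply(pass, c(1, 2), any)
  out <- matrix(as.integer(best), h, w)
  out[none] <- CLASS_REMAINDER
  class_mask(out, pixel_size_um)
}
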