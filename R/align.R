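# Superimposition of the two renderings: translation by phase correlation on
# luminance, optional affine refinement on matched blob centroids, and
# nearest-neighbor transfer of categorical label masks.

.luminance <- function(tile) {
  tile <- .check_rgb_tile(tile)
  0.299 * tile[, , 1] + 0.587 * tile[, , 2] + 0.114 * tile[, , 3]
}

# translation (dx, dy) maximizing correlation of b shifted onto a,
# i.e. a(x, y) ~ b(x - dx, y - dy); subpixel by parabolic peak fit
.phase_correlate <- function(a, b) {
  A <- fft(a - mean(a)); B <- fft(b - mean(b))
  R <- A * Conj(B)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(fft(R, inverse = TRUE)) / length(R)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  h <- nrow(r); w <- ncol(r)
  sub <- function(idx, n) {
    i0 <- idx
    im <- if (i0 == 1) n else i0 - 1
    ip <- if (i0 == n) 1 else i0 + 1
    num <- r_line[im] - r_line[ip]
    den <- 2 * (r_line[im] - 2 * r_line[i0] + r_line[ip])
    if (abs(den) < 1e-12) 0 else num / den
  }
  r_line <- r[, pk[2]]; dy <- unname(pk[1] - 1) + sub(pk[1], h)
  r_line <- r[pk[1], ]; dx <- unname(pk[2] - 1) + sub(pk[2], w)
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(dx = unname(dx), dy = unname(dy))
}

# centroids of dark blobs (nuclei) on a luminance image
.blob_centroids <- function(lum, min_px = 9) {
  rng <- range(lum)
  if (diff(rng) < 1e-6) return(matrix(numeric(0), ncol = 2))
  t <- EBImage::otsu(EBImage::Image((lum - rng[1]) / diff(rng)), levels = 256)
  bin <- (lum - rng[1]) / diff(rng) < t
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labv <- as.vector(EBImage::imageData(lab))
  n <- max(labv)
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  rows <- rep(seq_len(nrow(lum)), times = ncol(lum))
  cols <- rep(seq_len(ncol(lum)), each = nrow(lum))
  cnt <- tabulate(labv, n)
  sx <- rowsum(cols[labv > 0], labv[labv > 0])[, 1]
  sy <- rowsum(rows[labv > 0], labv[labv > 0])[, 1]
  keep <- cnt >= min_px
  cbind(x = (sx / cnt)[keep] - 1, y = (sy / cnt)[keep] - 1)
}

#' Estimate the transform relating the two renderings
#'
#' Translation is estimated by phase correlation on luminance; `"affine"`
#' adds a least-squares refinement on matched dark-blob centroids. The
#' returned 2 x 3 matrix maps IHC pixel coordinates to H&E pixel
#' coordinates; the reported residual is the RMS distance of matched blob
#' centroids after applying the transform (NA when fewer than 3 blobs
#' match).
#'
#' @param he,ihc RGB tiles of the same scene.
#' @param mode `"translation"` or `"affine"`.
#' @return List of class `"stain_transform"`: `transform` (2 x 3),
#'   `residual` (px), `mode`.
#' @export
estimate_transform <- function(he, ihc, mode = c("translation", "affine")) {
  mode <- match.arg(mode)
  la <- .luminance(he); lb <- .luminance(ihc)
  if (sd(la) < 1e-4 || sd(lb) < 1e-4)
    stop("degenerate (blank) image: cannot estimate a transform")
  d <- .phase_correlate(la, lb)
  tr <- cbind(diag(2), c(d["dx"], d["dy"]))
  ca <- .blob_centroids(la); cb <- .blob_centroids(lb)
  residual <- NA_real_
  if (nrow(ca) >= 3 && nrow(cb) >= 3) {
    cb_t <- sweep(cb, 2, -c(d["dx"], d["dy"]))
    nn <- apply(cb_t, 1, function(p)
      which.min((ca[, 1] - p[1])^2 + (ca[, 2] - p[2])^2))
    dist <- sqrt(rowSums((ca[nn, , drop = FALSE] - cb_t)^2))
    keep <- dist < 6
    if (sum(keep) >= 3) {
      src <- cb[keep, , drop = FALSE]
      dst <- ca[nn[keep], , drop = FALSE]
      if (mode == "affine") {
        Xd <- cbind(src, 1)
        beta <- qr.solve(Xd, dst)          # 3 x 2
        tr <- t(beta)                      # 2 x 3 rows: x', y'
        pred <- Xd %*% beta
        residual <- sqrt(mean(rowSums((dst - pred)^2)))
      } else {
        pred <- sweep(src, 2, -c(d["dx"], d["dy"]))
        residual <- sqrt(mean(rowSums((dst - pred)^2)))
      }
    }
  }
  structure(list(transform = unname(tr), residual = unname(residual),
                 mode = mode), class = "stain_transform")
}

.affine_invert <- function(tr) {
  A <- tr[, 1:2]; t <- tr[, 3]
  Ai <- solve(A)
  cbind(Ai, -Ai %*% t)
}

#' Transfer a categorical label mask through a transform
#'
#' Nearest-neighbor warp of a class mask from the IHC frame into the H&E
#' frame (labels are categorical; interpolation would invent classes).
#' Pixels mapping outside the source frame become background.
#'
#' @param mask A [class_mask()] in the source (IHC) frame.
#' @param transform 2 x 3 affine matrix mapping source to target
#'   coordinates, or a `"stain_transform"`.
#' @param target_dim Target (rows, cols); defaults to `dim(mask)`.
#' @return A [class_mask()] in the target frame.
#' @export
transfer_labels <- function(mask, transform, target_dim = dim(mask)) {
  if (inherits(transform, "stain_transform")) transform <- transform$transform
  inv <- .affine_invert(transform)
  h <- target_dim[1]; w <- target_dim[2]
  X <- rep(seq_len(w) - 1, each = h)
  Y <- rep(seq_len(h) - 1, times = w)
  sx <- inv[1, 1] * X + inv[1, 2] * Y + inv[1, 3]
  sy <- inv[2, 1] * X + inv[2, 2] * Y + inv[2, 3]
  ri <- round(sy) + 1L; ci <- round(sx) + 1L
  ok <- ri >= 1L & ri <= nrow(mask) & ci <= ncol(mask) & ci >= 1L
  out <- rep(CLASS_BACKGROUND, h * w)
  out[ok] <- mask[cbind(ri[ok], ci[ok])]
  class_mask(matrix(out, h, w), attr(mask, "pixel_size_um") %||% 0.44)
}
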