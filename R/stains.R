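# Stain color arithmetic: chromaticity maps, Beer-Lambert optical density,
# and color deconvolution for H&E + chromogen bases. The simulator renders
# through the same optical-density mixing model, so deconvolution is exactly
# invertible on noise-free pixels.

.unit3 <- function(v) v / sqrt(sum(v^2))

# Ruifrok-Johnston optical-density vectors for hematoxylin, eosin and DAB.
.OD_HEMATOXYLIN <- .unit3(c(0.650, 0.704, 0.286))
.OD_EOSIN       <- .unit3(c(0.070, 0.990, 0.110))
.OD_DAB         <- .unit3(c(0.270, 0.570, 0.780))
# Fast Red calibrated once from the simulator's pure chromogen color
# (RGB 0.91, 0.28, 0.58 at unit concentration).
.OD_FASTRED     <- .unit3(-log10(c(0.91, 0.28, 0.58)))
# Melanin: broad absorption, strongest in red; distinctly off the Fast-Red
# direction but close enough to DAB that brown pigment and DAB-stained nuclei
# unmix to similar DAB concentrations.
.OD_MELANIN     <- .unit3(c(0.70, 0.62, 0.55))

#' Stain basis for color deconvolution
#'
#' Returns the 3x3 optical-density basis used for unmixing: columns are unit
#' OD vectors for hematoxylin, eosin, and the chromogen (DAB or Fast Red).
#' The condition number of the basis matrix is attached as an attribute.
#'
#' @param chromogen `"DAB"` (brown) or `"FastRed"` (red).
#' @return A 3x3 matrix of class `"stain_basis"`; columns named
#'   `hematoxylin`, `eosin`, and the chromogen.
#' @export
#' @examples
#' b <- stain_basis("FastRed")
#' attr(b, "condition")
stain_basis <- function(chromogen = c("FastRed", "DAB")) {
  chromogen <- match.arg(chromogen)
  third <- switch(chromogen, DAB = .OD_DAB, FastRed = .OD_FASTRED)
  m <- cbind(hematoxylin = .OD_HEMATOXYLIN, eosin = .OD_EOSIN, chrom = third)
  colnames(m)[3] <- chromogen
  if (abs(det(m)) < 1e-8) stop("singular stain basis")
  structure(m, chromogen = chromogen, condition = kappa(m, exact = TRUE),
            class = c("stain_basis", "matrix", "array"))
}

#' Melanin optical-density direction
#'
#' Unit OD vector used by the simulator to render melanin pigment granules.
#' @return Numeric length-3 unit vector.
#' @export
melanin_od_vector <- function() .OD_MELANIN

.check_rgb_tile <- function(tile) {
  if (!(is.array(tile) && length(dim(tile)) == 3L && dim(tile)[3] == 3L))
    stop("expected an RGB tile (H x W x 3 array)")
  if (max(tile) > 1.5) tile <- tile / 255
  tile
}

#' Chromaticity maps
#'
#' Per-pixel normalized channels: each channel divided by the sum of the
#' three channels. Black pixels (zero sum) are defined as (1/3, 1/3, 1/3).
#' Red chromaticity is the intensity measure used for the red chromogen.
#'
#' @param tile RGB tile (H x W x 3, values in \[0, 1\] or 8-bit).
#' @return List of matrices `r`, `g`, `b` of class `"chromaticity_maps"`;
#'   the three values sum to 1 at every pixel.
#' @export
#' @examples
#' px <- array(c(1, 0, 0), dim = c(1, 1, 3))
#' chromaticity(px)$r
chromaticity <- function(tile) {
  tile <- .check_rgb_tile(tile)
  d <- dim(tile)
  ch <- function(k) matrix(tile[, , k], d[1], d[2])
  s <- ch(1) + ch(2) + ch(3)
  zero <- s <= 0
  s[zero] <- 1
  r <- ch(1) / s; g <- ch(2) / s; b <- ch(3) / s
  r[zero] <- 1 / 3; g[zero] <- 1 / 3; b[zero] <- 1 / 3
  structure(list(r = r, g = g, b = b), class = "chromaticity_maps")
}

#' Optical density transform
#'
#' Beer-Lambert transform `OD = -log10(I / I0)` per channel, with intensities
#' floored at one 8-bit step so that black pixels map to a finite OD.
#' White pixels map to OD 0.
#'
#' @param tile RGB tile in \[0, 1\] (8-bit input is rescaled).
#' @param I0 White reference level on the \[0, 1\] scale (default 1).
#' @return H x W x 3 array of optical densities.
#' @export
od_transform <- function(tile, I0 = 1) {
  tile <- .check_rgb_tile(tile)
  -log10(pmax(tile, 1 / 255) / I0)
}

#' Inverse of the optical density transform
#'
#' @param od H x W x 3 array of optical densities.
#' @param I0 White reference level.
#' @return RGB tile in \[0, 1\].
#' @export
od_to_rgb <- function(od, I0 = 1) {
  pmin(pmax(I0 * 10^(-od), 0), 1)
}

#' Mix stain concentrations into an optical-density tile
#'
#' Forward Beer-Lambert model: `OD = basis %*% concentrations` per pixel.
#' Used by the simulator and as the oracle for deconvolution round trips.
#'
#' @param conc H x W x 3 array of per-stain concentrations (basis order).
#' @param basis A [stain_basis()].
#' @return H x W x 3 OD array.
#' @export
mix_stains <- function(conc, basis) {
  d <- dim(conc)
  v <- matrix(aperm(conc, c(3, 1, 2)), nrow = 3)
  od <- unclass(basis) %*% v
  aperm(array(od, dim = c(3, d[1], d[2])), c(2, 3, 1))
}

# Exact nonnegative least squares for 3 columns by active-set enumeration:
# solve the unconstrained LS for each of the 8 column subsets, keep feasible
# candidates, pick the smallest residual. Fully vectorized over pixels.
.nnls3 <- function(M, V) {
  n <- ncol(V)
  subsets <- list(integer(0), 1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3)
  best_res <- colSums(V^2)
  best_x <- matrix(0, 3, n)
  for (s in subsets[-1]) {
    Ms <- M[, s, drop = FALSE]
    Xs <- solve(crossprod(Ms), t(Ms) %*% V)          # |s| x n
    feas <- colSums(Xs < -1e-10) == 0
    if (!any(feas)) next
    R <- V - Ms %*% Xs
    res <- colSums(R^2)
    upd <- feas & (res < best_res - 1e-12)
    if (any(upd)) {
      best_res[upd] <- res[upd]
      xfull <- matrix(0, 3, sum(upd))
      xfull[s, ] <- Xs[, upd, drop = FALSE]
      best_x[, upd] <- xfull
    }
  }
  list(x = best_x, res = best_res)
}

#' Color deconvolution
#'
#' Unmix a per-pixel optical-density tile into per-stain concentration maps.
#' The default method solves a nonnegative least-squares problem per pixel
#' (exact, by enumeration of the active sets of the 3-column basis), which
#' keeps off-basis colors such as melanin from bleeding into the chromogen
#' channel. `method = "inverse"` applies the basis inverse and clips
#' negative concentrations at zero.
#'
#' @param od H x W x 3 OD array (see [od_transform()]).
#' @param basis A [stain_basis()].
#' @param method `"nnls"` (default) or `"inverse"`.
#' @return Object of class `"concentration_maps"`: list with matrices
#'   `hematoxylin`, `eosin`, the chromogen (by its name), and `residual`
#'   (per-pixel L2 reconstruction residual in OD units).
#' @export
#' @examples
#' b <- stain_basis("DAB")
#' conc <- array(0, dim = c(2, 2, 3)); conc[, , 1] <- 0.8
#' cm <- deconvolve(mix_stains(conc, b), b)
#' cm$hematoxylin
deconvolve <- function(od, basis, method = c("nnls", "inverse")) {
  method <- match.arg(method)
  if (!(is.array(od) && length(dim(od)) == 3L && dim(od)[3] == 3L))
    stop("expected an H x W x 3 OD array")
  M <- unclass(basis)
  if (abs(det(M)) < 1e-8) stop("singular stain basis")
  d <- dim(od)
  V <- matrix(aperm(od, c(3, 1, 2)), nrow = 3)
  if (method == "inverse") {
    X <- pmax(solve(M, V), 0)
    res <- sqrt(colSums((V - M %*% X)^2))
  } else {
    fit <- .nnls3(M, V)
    X <- fit$x
    res <- sqrt(pmax(fit$res, 0))
  }
  shp <- d[1:2]
  out <- list(
    hematoxylin = matrix(X[1, ], shp[1], shp[2]),
    eosin       = matrix(X[2, ], shp[1], shp[2]),
    chrom       = matrix(X[3, ], shp[1], shp[2]),
    residual    = matrix(res, shp[1], shp[2])
  )
  names(out)[3] <- colnames(M)[3]
  structure(out, chromogen = attr(basis, "chromogen"), method = method,
            class = "concentration_maps")
}

# convenience: chromogen concentration map regardless of basis name
chromogen_map <- function(cm) cm[[attr(cm, "chromogen")]]
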