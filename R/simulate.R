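# Synthetic dual-stain scene simulator. A scene is a list of entities
# (nuclei and confounders) with exact geometry and staining attributes;
# render_pair() draws the same scene twice -- once as H&E, once as chromogenic
# IHC -- through the Beer-Lambert mixing model of the stains module, so the
# renderer and the deconvolution share one stain basis.

#' Scene configuration for the dual-stain simulator
#'
#' Defaults emulate a 0.05 mm^2 evaluation square of a melanocytic lesion:
#' 512 x 512 px at 0.44 um/px, large tumor nuclei (7 um mean radius) and
#' small normal nuclei (3 um), with confounders switched off. Densities are
#' per mm^2 of tile area; fractions are per tumor nucleus.
#'
#' @param tile_size_px Integer pair (width, height) in pixels.
#' @param pixel_size_um Pixel side length in micrometers.
#' @param n_tumor_nuclei,n_normal_nuclei Nucleus counts.
#' @param tumor_nucleus_radius_um,normal_nucleus_radius_um Numeric pair
#'   (mean, sd) of nucleus radius in micrometers.
#' @param sox10_negative_fraction Fraction of tumor nuclei rendered with no
#'   chromogen at all.
#' @param pale_fraction Fraction of tumor nuclei with weak chromogen.
#' @param pigment_density Melanin granules per mm^2.
#' @param red_dot_density Unspecific chromogen dots per mm^2 (IHC only).
#' @param mitotic_density,erythrocyte_density Confounder densities per mm^2.
#' @param cytoplasmic_reaction_prob Probability that a chromogen-positive
#'   tumor cell also shows a weak cytoplasmic chromogen ring (IHC only).
#' @param chromogen_intensity Mean optical-density intensity of the
#'   chromogen in positive tumor nuclei (the staining-strength knob).
#' @param cluster_prob Probability that a normal nucleus is planted touching
#'   an earlier normal nucleus (exercises cluster splitting).
#' @param misalignment List with `shift` (x, y displacement of the IHC
#'   rendering, px), `warp_amplitude` (px) and `warp_period` (px) for smooth
#'   local misalignment.
#' @param chromogen `"FastRed"` or `"DAB"`.
#' @param tissue_fraction Fraction of the tile width covered by tissue; the
#'   rest is unstained background.
#' @param noise_sd Multiplicative optical-density noise.
#' @param seed RNG seed (integer).
#' @return Object of class `"scene_config"`.
#' @export
scene_config <- function(tile_size_px = c(512L, 512L),
                         pixel_size_um = 0.44,
                         n_tumor_nuclei = 80L,
                         n_normal_nuclei = 20L,
                         tumor_nucleus_radius_um = c(7, 1.2),
                         normal_nucleus_radius_um = c(3, 0.45),
                         sox10_negative_fraction = 0,
                         pale_fraction = 0,
                         pigment_density = 0,
                         red_dot_density = 0,
                         mitotic_density = 0,
                         erythrocyte_density = 0,
                         cytoplasmic_reaction_prob = 0,
                         chromogen_intensity = 0.80,
                         cluster_prob = 0.15,
                         misalignment = list(shift = c(0, 0),
                                             warp_amplitude = 0,
                                             warp_period = 96),
                         chromogen = c("FastRed", "DAB"),
                         tissue_fraction = 0.88,
                         noise_sd = 0.02,
                         seed = 1L) {
  chromogen <- match.arg(chromogen)
  tile_size_px <- as.integer(tile_size_px)
  if (length(tile_size_px) == 1L) tile_size_px <- rep(tile_size_px, 2L)
  if (any(tile_size_px <= 0)) stop("tile size must be positive")
  if (pixel_size_um <= 0) stop("pixel size must be positive")
  fr <- c(sox10_negative_fraction, pale_fraction, cytoplasmic_reaction_prob,
          cluster_prob, tissue_fraction)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  if (any(c(pigment_density, red_dot_density, mitotic_density,
            erythrocyte_density) < 0)) stop("densities must be >= 0")
  if (n_tumor_nuclei < 0 || n_normal_nuclei < 0) stop("counts must be >= 0")
  mis <- misalignment
  mis$shift <- mis$shift %||% c(0, 0)
  mis$warp_amplitude <- mis$warp_amplitude %||% 0
  mis$warp_period <- mis$warp_period %||% 96
  cfg <- list(tile_size_px = tile_size_px, pixel_size_um = pixel_size_um,
              n_tumor_nuclei = as.integer(n_tumor_nuclei),
              n_normal_nuclei = as.integer(n_normal_nuclei),
              tumor_nucleus_radius_um = tumor_nucleus_radius_um,
              normal_nucleus_radius_um = normal_nucleus_radius_um,
              sox10_negative_fraction = sox10_negative_fraction,
              pale_fraction = pale_fraction,
              pigment_density = pigment_density,
              red_dot_density = red_dot_density,
              mitotic_density = mitotic_density,
              erythrocyte_density = erythrocyte_density,
              cytoplasmic_reaction_prob = cytoplasmic_reaction_prob,
              chromogen_intensity = chromogen_intensity,
              cluster_prob = cluster_prob,
              misalignment = mis,
              chromogen = chromogen,
              tissue_fraction = tissue_fraction,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  cfg$tile_area_mm2 <- prod(tile_size_px) * pixel_size_um^2 / 1e6
  structure(cfg, class = "scene_config")
}

# radial boundary model: ellipse (a, b, phi) with two low-order harmonics
.entity_row <- function(id, class, cx, cy, a, b, phi, chromogen_int, hema_int,
                        eosin_int = 0, sox10_negative = FALSE, pale = FALSE,
                        cyto_reaction = FALSE) {
  data.frame(id = id, class = class, cx = cx, cy = cy, a = a, b = b, phi = phi,
             eps2 = runif(1, 0, 0.06), psi2 = runif(1, 0, 2 * pi),
             eps3 = runif(1, 0, 0.05), psi3 = runif(1, 0, 2 * pi),
             chromogen_int = chromogen_int, hema_int = hema_int,
             eosin_int = eosin_int, sox10_negative = sox10_negative,
             pale = pale, cyto_reaction = cyto_reaction,
             stringsAsFactors = FALSE)
}

# tissue boundary: x position of the tissue/background border at row y (px)
.tissue_border_x <- function(y, w, h, tissue_fraction) {
  w * tissue_fraction + 0.03 * w * sin(2 * pi * 1.7 * y / h + 0.9)
}

.roi_polygon <- function(w, h, tissue_fraction) {
  ys <- seq(0, h - 1, length.out = 65)
  xs <- .tissue_border_x(ys, w, h, tissue_fraction)
  rbind(cbind(xs, ys), c(0, h - 1), c(0, 0))
}

#' Generate a synthetic dual-stain scene
#'
#' Draws the entity list (tumor/normal nuclei and confounders) for one tile.
#' The RNG consumption order is part of the reproducibility contract: the
#' first draws are, in order, binomial counts of SOX10-negative and pale
#' tumor nuclei, then Poisson counts of pigment granules, red dots, mitotic
#' figures and erythrocytes.
#'
#' @param config A [scene_config()].
#' @return Object of class `"gt_scene"`: list with `entities` (data frame),
#'   `roi` (tissue polygon, px coordinates), and `config`.
#' @export
#' @examples
#' sc <- generate_scene(scene_config(tile_size_px = 128, n_tumor_nuclei = 5,
#'                                   n_normal_nuclei = 3, seed = 7))
#' nrow(sc$entities)
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  w <- config$tile_size_px[1]; h <- config$tile_size_px[2]
  px <- config$pixel_size_um
  with_seed(config$seed, {
    n_tum <- config$n_tumor_nuclei
    n_sox_neg <- rbinom(1, n_tum, config$sox10_negative_fraction)
    n_pale <- rbinom(1, n_tum - n_sox_neg, config$pale_fraction)
    n_pig <- rpois(1, config$pigment_density * config$tile_area_mm2)
    n_dot <- rpois(1, config$red_dot_density * config$tile_area_mm2)
    n_mit <- rpois(1, config$mitotic_density * config$tile_area_mm2)
    n_ery <- rpois(1, config$erythrocyte_density * config$tile_area_mm2)

    ents <- list()
    placed <- matrix(numeric(0), ncol = 3)  # cx, cy, r (px) of placed nuclei
    place <- function(r_px, near = NULL) {
      for (try in seq_len(400)) {
        if (is.null(near)) {
          cx <- runif(1, r_px + 2, w - r_px - 3)
          cy <- runif(1, r_px + 2, h - r_px - 3)
        } else {
          ang <- runif(1, 0, 2 * pi)
          d <- (near[3] + r_px) * runif(1, 0.92, 1.05)
          cx <- near[1] + d * cos(ang); cy <- near[2] + d * sin(ang)
          if (cx < r_px + 2 || cx > w - r_px - 3 ||
              cy < r_px + 2 || cy > h - r_px - 3) next
        }
        if (cx + r_px > .tissue_border_x(cy, w, h, config$tissue_fraction) - 2) next
        if (nrow(placed) > 0) {
          dmin <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
          lim <- if (is.null(near)) 0.95 * (placed[, 3] + r_px) else
            0.80 * (placed[, 3] + r_px)
          if (any(dmin < lim)) next
        }
        return(c(cx, cy))
      }
      NULL
    }

    id <- 0L
    sox_flags <- rep(FALSE, n_tum); pale_flags <- rep(FALSE, n_tum)
    if (n_sox_neg > 0) sox_flags[sample.int(n_tum, n_sox_neg)] <- TRUE
    if (n_pale > 0) pale_flags[sample(which(!sox_flags), n_pale)] <- TRUE
    for (i in seq_len(n_tum)) {
      r_um <- max(1.5, rnorm(1, config$tumor_nucleus_radius_um[1],
                             config$tumor_nucleus_radius_um[2]))
      aspect <- runif(1, 0.75, 1)
      a <- r_um / px / sqrt(aspect); b <- r_um / px * sqrt(aspect)
      pos <- place(max(a, b))
      if (is.null(pos)) stop("cannot fit configured tumor nuclei into the tile")
      id <- id + 1L
      chrom <- if (sox_flags[i]) 0 else if (pale_flags[i])
        max(0.05, rnorm(1, 0.17, 0.04)) else
        min(1.2, rnorm(1, config$chromogen_intensity, 0.07))
      ents[[length(ents) + 1L]] <- .entity_row(
        id, "tumor-nucleus", pos[1], pos[2], a, b, runif(1, 0, pi),
        chromogen_int = chrom, hema_int = max(0.3, rnorm(1, 0.70, 0.08)),
        sox10_negative = sox_flags[i], pale = pale_flags[i],
        cyto_reaction = !sox_flags[i] &&
          runif(1) < config$cytoplasmic_reaction_prob)
      placed <- rbind(placed, c(pos, max(a, b)))
    }
    last_normal <- NULL
    for (i in seq_len(config$n_normal_nuclei)) {
      r_um <- max(1.0, rnorm(1, config$normal_nucleus_radius_um[1],
                             config$normal_nucleus_radius_um[2]))
      aspect <- runif(1, 0.85, 1)
      a <- r_um / px / sqrt(aspect); b <- r_um / px * sqrt(aspect)
      near <- if (!is.null(last_normal) && runif(1) < config$cluster_prob)
        last_normal else NULL
      pos <- place(max(a, b), near)
      if (is.null(pos)) stop("cannot fit configured normal nuclei into the tile")
      id <- id + 1L
      ents[[length(ents) + 1L]] <- .entity_row(
        id, "normal-nucleus", pos[1], pos[2], a, b, runif(1, 0, pi),
        chromogen_int = 0, hema_int = min(1.1, rnorm(1, 0.85, 0.08)))
      last_normal <- c(pos, max(a, b))
      placed <- rbind(placed, last_normal)
    }
    for (i in seq_len(n_mit)) {
      r_um <- runif(1, 3.2, 4.5)
      pos <- place(r_um / px)
      if (is.null(pos)) break
      id <- id + 1L
      e <- .entity_row(id, "mitotic-figure", pos[1], pos[2], r_um / px,
                       0.7 * r_um / px, runif(1, 0, pi),
                       chromogen_int = 0, hema_int = 1.25)
      e$eps2 <- runif(1, 0.15, 0.3); e$eps3 <- runif(1, 0.1, 0.25)
      ents[[length(ents) + 1L]] <- e
      placed <- rbind(placed, c(pos, r_um / px))
    }
    # pigment granules come in melanophage-like clumps
    if (n_pig > 0) {
      n_clump <- max(1L, round(n_pig / 6))
      ccx <- runif(n_clump, 8, w * config$tissue_fraction - 8)
      ccy <- runif(n_clump, 8, h - 8)
      for (i in seq_len(n_pig)) {
        k <- sample.int(n_clump, 1)
        r_px <- runif(1, 1.2, 2.2) / px
        cx <- ccx[k] + rnorm(1, 0, 6 / px); cy <- ccy[k] + rnorm(1, 0, 6 / px)
        cx <- min(max(cx, r_px + 1), w - r_px - 2)
        cy <- min(max(cy, r_px + 1), h - r_px - 2)
        if (cx + r_px > .tissue_border_x(cy, w, h, config$tissue_fraction) - 1)
          next
        id <- id + 1L
        ents[[length(ents) + 1L]] <- .entity_row(
          id, "pigment", cx, cy, r_px, r_px * runif(1, 0.8, 1), runif(1, 0, pi),
          chromogen_int = min(3, rnorm(1, 2.2, 0.3)), hema_int = 0)
      }
    }
    for (i in seq_len(n_dot)) {
      r_px <- runif(1, 1.0, 1.8) / px
      cx <- runif(1, r_px + 1, w * config$tissue_fraction - r_px - 2)
      cy <- runif(1, r_px + 1, h - r_px - 2)
      id <- id + 1L
      ents[[length(ents) + 1L]] <- .entity_row(
        id, "red-dot", cx, cy, r_px, r_px * runif(1, 0.85, 1), runif(1, 0, pi),
        chromogen_int = runif(1, 0.6, 0.95), hema_int = 0)
    }
    for (i in seq_len(n_ery)) {
      r_px <- runif(1, 2.8, 3.6) / px
      pos <- place(r_px)
      if (is.null(pos)) break
      id <- id + 1L
      ents[[length(ents) + 1L]] <- .entity_row(
        id, "erythrocyte", pos[1], pos[2], r_px, 0.85 * r_px, runif(1, 0, pi),
        chromogen_int = 0, hema_int = 0, eosin_int = runif(1, 0.8, 1.0))
    }
    entities <- if (length(ents)) do.call(rbind, ents) else
      .entity_row(0L, "tumor-nucleus", 0, 0, 1, 1, 0, 0, 0)[0, ]
    structure(list(entities = entities,
                   roi = .roi_polygon(w, h, config$tissue_fraction),
                   config = config),
              class = "gt_scene")
  })
}

# vectorized inside test for one entity over pixel-center coordinates
# (0-based x = column, y = row)
.inside_entity <- function(e, X, Y) {
  dx <- X - e$cx; dy <- Y - e$cy
  cph <- cos(e$phi); sph <- sin(e$phi)
  u <- (cph * dx + sph * dy) / e$a
  v <- (-sph * dx + cph * dy) / e$b
  t <- atan2(v, u)
  rho <- 1 + e$eps2 * cos(2 * t + e$psi2) + e$eps3 * cos(3 * t + e$psi3)
  u^2 + v^2 <= rho^2
}

# bounding-box pixel indices (1-based rows/cols) possibly covered by entity
.entity_bbox <- function(e, w, h) {
  r <- max(e$a, e$b) * 1.4 + 1
  cols <- max(1, floor(e$cx - r) + 1):min(w, ceiling(e$cx + r) + 1)
  rows <- max(1, floor(e$cy - r) + 1):min(h, ceiling(e$cy + r) + 1)
  list(rows = rows, cols = cols)
}

# rasterize entity -> (row, col) index matrix of covered pixels
.entity_pixels <- function(e, w, h, scale = 1) {
  es <- e; es$a <- e$a * scale; es$b <- e$b * scale
  bb <- .entity_bbox(es, w, h)
  X <- matrix(rep(bb$cols - 1, each = length(bb$rows)), nrow = length(bb$rows))
  Y <- matrix(rep(bb$rows - 1, times = length(bb$cols)), nrow = length(bb$rows))
  ins <- .inside_entity(es, X, Y)
  cbind(row = Y[ins] + 1L, col = X[ins] + 1L)
}

#' Boundary polygon of a scene entity
#'
#' @param e One row of a scene's `entities` data frame.
#' @param n Number of boundary vertices.
#' @return Two-column matrix of (x, y) pixel coordinates.
#' @export
entity_polygon <- function(e, n = 96) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rho <- 1 + e$eps2 * cos(2 * t + e$psi2) + e$eps3 * cos(3 * t + e$psi3)
  ux <- e$a * rho * cos(t); vy <- e$b * rho * sin(t)
  cph <- cos(e$phi); sph <- sin(e$phi)
  cbind(x = e$cx + cph * ux - sph * vy, y = e$cy + sph * ux + cph * vy)
}

# coarse smooth multiplicative texture field
.texture_field <- function(h, w, cell = 16, sdev = 0.25) {
  gh <- max(2, ceiling(h / cell) + 1); gw <- max(2, ceiling(w / cell) + 1)
  g <- matrix(rnorm(gh * gw, 0, sdev), gh, gw)
  ry <- seq(1, gh, length.out = h); rx <- seq(1, gw, length.out = w)
  i0 <- pmin(floor(ry), gh - 1); fx0 <- ry - i0
  j0 <- pmin(floor(rx), gw - 1); fy0 <- rx - j0
  a <- g[cbind(rep(i0, w), rep(j0, each = h))]
  b <- g[cbind(rep(i0 + 1, w), rep(j0, each = h))]
  cc <- g[cbind(rep(i0, w), rep(j0 + 1, each = h))]
  d <- g[cbind(rep(i0 + 1, w), rep(j0 + 1, each = h))]
  fx <- rep(fx0, w); fy <- rep(fy0, each = h)
  m <- a * (1 - fx) * (1 - fy) + b * fx * (1 - fy) + cc * (1 - fx) * fy +
    d * fx * fy
  matrix(pmax(1 + m, 0.2), h, w)
}

#' Render the H&E and IHC tiles of a scene
#'
#' Both renderings go through the optical-density mixing model: nuclei are
#' hematoxylin (plus eosin tissue wash) on the H&E tile; on the IHC tile
#' chromogen-positive tumor nuclei carry the configured chromogen with a
#' light hematoxylin counterstain, melanin pigment appears in both tiles,
#' and unspecific red dots / cytoplasmic reactions appear only in the IHC
#' tile. The IHC rendering is displaced by the configured misalignment and
#' the returned transform (IHC coordinates to H&E coordinates) is exactly
#' the inverse of the applied shift.
#'
#' @param scene A [generate_scene()] result.
#' @param config Optional [scene_config()]; defaults to the scene's own.
#' @return Object of class `"aligned_pair"`: list with RGB arrays `he` and
#'   `ihc` (values in \[0, 1\]), `transform` (2 x 3 affine, IHC -> H&E),
#'   `misalignment`, and `pixel_size_um`.
#' @export
render_pair <- function(scene, config = scene$config) {
  stopifnot(inherits(scene, "gt_scene"))
  w <- config$tile_size_px[1]; h <- config$tile_size_px[2]
  basis <- stain_basis(config$chromogen)
  V_h <- .OD_HEMATOXYLIN; V_e <- .OD_EOSIN
  V_c <- unclass(basis)[, 3]; V_m <- .OD_MELANIN
  mis <- config$misalignment
  warp <- function(cx, cy) {
    if (mis$warp_amplitude == 0) return(c(0, 0))
    mis$warp_amplitude * c(sin(2 * pi * cy / mis$warp_period + 0.7),
                           sin(2 * pi * cx / mis$warp_period + 2.1))
  }

  with_seed(config$seed + 101L, {
    he <- array(0, dim = c(h, w, 3))
    ihc <- array(0, dim = c(h, w, 3))
    # tissue wash: eosin-dominated cytoplasm on H&E, faint counterstain on IHC
    tex_he <- .texture_field(h, w); tex_ihc <- .texture_field(h, w)
    X <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
    Y <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
    tissue_he <- X < .tissue_border_x(Y, w, h, config$tissue_fraction)
    Xs <- X - mis$shift[1]; Ys <- Y - mis$shift[2]
    tissue_ihc <- Xs < .tissue_border_x(Ys, w, h, config$tissue_fraction)
    for (k in 1:3) {
      he[, , k] <- (0.16 * V_e[k] + 0.05 * V_h[k]) * tex_he * tissue_he
      ihc[, , k] <- 0.12 * V_h[k] * tex_ihc * tissue_ihc
    }
    add_od <- function(arr, idx, vec, amount, combine = "sum") {
      if (nrow(idx) == 0) return(arr)
      for (k in 1:3) {
        ii <- cbind(idx, k)
        arr[ii] <- if (combine == "max") pmax(arr[ii], amount * vec[k])
        else arr[ii] + amount * vec[k]
      }
      arr
    }
    for (i in seq_len(nrow(scene$entities))) {
      e <- scene$entities[i, ]
      idx_he <- .entity_pixels(e, w, h)
      es <- e
      wp <- warp(e$cx, e$cy)
      es$cx <- e$cx + mis$shift[1] + wp[1]
      es$cy <- e$cy + mis$shift[2] + wp[2]
      idx_ihc <- .entity_pixels(es, w, h)
      switch(e$class,
        "tumor-nucleus" = , "mitotic-figure" = {
          he <- add_od(he, idx_he, V_h, e$hema_int)
          if (e$chromogen_int > 0) {
            ihc <- add_od(ihc, idx_ihc, V_c, e$chromogen_int)
            ihc <- add_od(ihc, idx_ihc, V_h, 0.25 * e$hema_int)
            if (isTRUE(e$cyto_reaction)) {
              ring <- .entity_pixels(es, w, h, scale = 1.9)
              core <- paste(idx_ihc[, 1], idx_ihc[, 2])
              ring <- ring[!(paste(ring[, 1], ring[, 2]) %in% core), , drop = FALSE]
              ihc <- add_od(ihc, ring, V_c, 0.22)
            }
          } else {
            ihc <- add_od(ihc, idx_ihc, V_h, e$hema_int)
          }
        },
        "normal-nucleus" = {
          he <- add_od(he, idx_he, V_h, e$hema_int)
          ihc <- add_od(ihc, idx_ihc, V_h, e$hema_int)
        },
        "pigment" = {
          # overlapping granules saturate rather than sum: stacked melanin
          # would otherwise clip at the 8-bit floor and lose its color
          # direction
          he <- add_od(he, idx_he, V_m, e$chromogen_int, combine = "max")
          ihc <- add_od(ihc, idx_ihc, V_m, e$chromogen_int, combine = "max")
        },
        "red-dot" = {
          ihc <- add_od(ihc, idx_ihc, V_c, e$chromogen_int)
        },
        "erythrocyte" = {
          he <- add_od(he, idx_he, V_e, e$eosin_int)
          ihc <- add_od(ihc, idx_ihc, V_e, 0.6 * e$eosin_int)
        })
    }
    if (config$noise_sd > 0) {
      nz_he <- matrix(1 + rnorm(h * w, 0, config$noise_sd), h, w)
      nz_ihc <- matrix(1 + rnorm(h * w, 0, config$noise_sd), h, w)
      for (k in 1:3) {
        he[, , k] <- he[, , k] * nz_he
        ihc[, , k] <- ihc[, , k] * nz_ihc
      }
    }
    he <- round(255 * od_to_rgb(he)) / 255
    ihc <- round(255 * od_to_rgb(ihc)) / 255
    transform <- cbind(diag(2), -mis$shift)
    structure(list(he = he, ihc = ihc, transform = transform,
                   misalignment = mis, pixel_size_um = config$pixel_size_um),
              class = "aligned_pair")
  })
}

#' Ground-truth class mask of a scene
#'
#' Rasterizes the scene to the four-class per-pixel mask: tumor nuclei
#' (mitotic figures included), normal nuclei, remainder tissue, unstained
#' background. Pigment, red dots, and erythrocytes map to remainder.
#'
#' @param scene A [generate_scene()] result.
#' @return A [class_mask()].
#' @export
truth_masks <- function(scene) {
  cfg <- scene$config
  w <- cfg$tile_size_px[1]; h <- cfg$tile_size_px[2]
  X <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  Y <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  m <- matrix(CLASS_BACKGROUND, h, w)
  m[X < .tissue_border_x(Y, w, h, cfg$tissue_fraction)] <- CLASS_REMAINDER
  ents <- scene$entities
  for (i in which(ents$class == "normal-nucleus")) {
    idx <- .entity_pixels(ents[i, ], w, h)
    m[idx] <- CLASS_NORMAL
  }
  for (i in which(ents$class %in% c("tumor-nucleus", "mitotic-figure"))) {
    idx <- .entity_pixels(ents[i, ], w, h)
    m[idx] <- CLASS_TUMOR
  }
  class_mask(m, cfg$pixel_size_um)
}
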