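# Shared fixtures: small desk-scale scene configurations. Nucleus radii are
# slightly reduced at small tile sizes so the configured counts always fit.

small_scene_config <- function(seed, tile = 192, n_tumor = 10, n_normal = 8,
                               ...) {
  scene_config(tile_size_px = tile, n_tumor_nuclei = n_tumor,
               n_normal_nuclei = n_normal,
               tumor_nucleus_radius_um = c(5, 0.8), seed = seed, ...)
}

pigmented_scene_config <- function(seed, chromogen, tile = 256) {
  scene_config(tile_size_px = tile, n_tumor_nuclei = 18, n_normal_nuclei = 10,
               tumor_nucleus_radius_um = c(5.5, 0.8),
               pigment_density = 1500, chromogen = chromogen, seed = seed)
}

# object set built by hand from analytic disc polygons (no pipeline involved)
disc_object_set <- function(cx, cy, r, class = "tumor-nucleus", n_vert = 64) {
  n <- length(cx)
  if (length(class) == 1) class <- rep(class, n)
  bounds <- lapply(seq_len(n), function(i) {
    t <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
    cbind(x = cx[i] + r[i] * cos(t), y = cy[i] + r[i] * sin(t))
  })
  df <- data.frame(id = seq_len(n), class = class, cx = cx, cy = cy,
                   area_um2 = pi * r^2, mean_red_chromaticity = NA_real_,
                   mean_chromogen = NA_real_)
  structure(df, boundary = bounds, analyzed_area_mm2 = 1,
            pixel_size_um = 0.44, provenance = "synthetic",
            class = c("object_set", "data.frame"))
}

# exhaustive maximum bipartite matching size (oracle for match_objects)
max_matching_size <- function(adj) {
  # adj: list over predictions of admissible truth indices
  np <- length(adj)
  best <- 0L
  used <- integer(0)
  recurse <- function(i, used, size) {
    if (size + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, size); return() }
    for (j in adj[[i]]) {
      if (!(j %in% used)) recurse(i + 1L, c(used, j), size + 1L)
    }
    recurse(i + 1L, used, size)  # leave prediction i unmatched
  }
  recurse(1L, integer(0), 0L)
  best
}
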