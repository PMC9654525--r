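# Small geometry helpers shared by the simulator, sampling and stereology.

#' Point-in-polygon test
#'
#' Even-odd ray casting, vectorized over points.
#'
#' @param px,py Point coordinates.
#' @param poly Two-column matrix of polygon vertices (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + (yj == yi) * 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Polygon area (shoelace formula)
#' @param poly Two-column matrix of vertices.
#' @return Absolute area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# seed-preserving evaluation: run `expr` under set.seed(seed) without
# clobbering the caller's RNG stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# does segment (p1,p2) cross vertical line x = c with crossing ordinate in [ylo, yhi]?
.crosses_vline <- function(x1, y1, x2, y2, c, ylo = -Inf, yhi = Inf) {
  straddle <- (x1 - c) * (x2 - c) < 0
  if (!any(straddle)) return(FALSE)
  t <- (c - x1[straddle]) / (x2[straddle] - x1[straddle])
  yc <- y1[straddle] + t * (y2[straddle] - y1[straddle])
  any(yc >= ylo & yc <= yhi)
}

.crosses_hline <- function(x1, y1, x2, y2, c, xlo = -Inf, xhi = Inf) {
  straddle <- (y1 - c) * (y2 - c) < 0
  if (!any(straddle)) return(FALSE)
  t <- (c - y1[straddle]) / (y2[straddle] - y1[straddle])
  xc <- x1[straddle] + t * (x2[straddle] - x1[straddle])
  any(xc >= xlo & xc <= xhi)
}
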