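# planar polygon helpers for the synthetic landscape
#
# Polygons are tibbles with columns poly_id, x, y: one closed ring per id,
# vertices in order (either orientation). The generators emit convex rings,
# and the clipping below (Sutherland-Hodgman against a convex window) is
# exact for convex subjects, which is all the pipeline needs.

# signed shoelace area of one ring given as a 2-column matrix
ring_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# clip a ring by the half-plane a*x + b*y <= c
clip_halfplane <- function(xy, a, b, c) {
  n <- nrow(xy)
  if (is.null(n) || n == 0) return(xy)
  out_x <- numeric(0); out_y <- numeric(0)
  d <- a * xy[, 1] + b * xy[, 2] - c
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    din <- d[i] <= 1e-12; djn <- d[j] <= 1e-12
    if (din) { out_x <- c(out_x, xy[i, 1]); out_y <- c(out_y, xy[i, 2]) }
    if (xor(din, djn)) {
      t <- d[i] / (d[i] - d[j])
      out_x <- c(out_x, xy[i, 1] + t * (xy[j, 1] - xy[i, 1]))
      out_y <- c(out_y, xy[i, 2] + t * (xy[j, 2] - xy[i, 2]))
    }
  }
  cbind(out_x, out_y)
}

# intersection area of a ring with an axis-aligned rectangle
ring_rect_intersection_area <- function(xy, xmin, xmax, ymin, ymax) {
  p <- xy
  p <- clip_halfplane(p, -1, 0, -xmin)
  p <- clip_halfplane(p, 1, 0, xmax)
  p <- clip_halfplane(p, 0, -1, -ymin)
  p <- clip_halfplane(p, 0, 1, ymax)
  ring_area(p)
}

# minimum distance from points (px, py) to a closed ring (0 if inside)
dist_to_ring <- function(px, py, xy) {
  n <- nrow(xy)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- xy[i, 1]; ay <- xy[i, 2]
    bx <- xy[j, 1]; by <- xy[j, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
    dmin <- pmin(dmin, sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2))
  }
  inside <- point_in_ring(px, py, xy)
  dmin[inside] <- 0
  dmin
}

# even-odd point-in-polygon test, vectorised over points
point_in_ring <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + (yj == yi) * 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# split a polygon tibble into a named list of vertex matrices
polys_to_rings <- function(polys) {
  if (nrow(polys) == 0) return(list())
  idx <- split(seq_len(nrow(polys)), polys$poly_id)
  lapply(idx, function(i) cbind(polys$x[i], polys$y[i]))
}

# rectangle ring constructor
rect_ring <- function(xmin, xmax, ymin, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
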