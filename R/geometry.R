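# In-plane polygon geometry shared by the sampler, the phantoms and the
# delineation simulator. All polygons use implicit closure.

polygon_perimeter <- function(xy) {
  nxt <- xy[c(2:nrow(xy), 1), , drop = FALSE]
  sum(sqrt(rowSums((nxt - xy)^2)))
}

polygon_area_signed <- function(xy) {
  nxt <- xy[c(2:nrow(xy), 1), , drop = FALSE]
  sum(xy[, 1] * nxt[, 2] - nxt[, 1] * xy[, 2]) / 2
}

# force counter-clockwise orientation (positive signed area)
polygon_ccw <- function(xy) {
  if (polygon_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  else xy
}

# outward unit normal at each vertex of a CCW polygon: mean of the outward
# normals of the two incident edges, renormalized
polygon_vertex_normals <- function(xy) {
  n <- nrow(xy)
  nxt <- xy[c(2:n, 1), , drop = FALSE]
  e <- nxt - xy                        # edge i: vertex i -> i+1
  len <- sqrt(rowSums(e^2))
  en <- cbind(e[, 2], -e[, 1]) / len   # outward normal of edge i (CCW)
  prev <- en[c(n, 1:(n - 1)), , drop = FALSE]
  vn <- en + prev
  vl <- sqrt(rowSums(vn^2))
  bad <- vl < 1e-12
  if (any(bad)) vn[bad, ] <- en[bad, , drop = FALSE]
  vl[bad] <- 1
  vn / vl
}

# resample the closed perimeter at uniform arc length; returns >= n_vertex
# points with step <= spacing
polygon_resample <- function(xy, spacing) {
  per <- polygon_perimeter(xy)
  n <- nrow(xy)
  m <- max(ceiling(per / spacing), n)
  targets <- (seq_len(m) - 1) * per / m
  nxt <- xy[c(2:n, 1), , drop = FALSE]
  seg <- sqrt(rowSums((nxt - xy)^2))
  cum <- c(0, cumsum(seg))             # arc position of vertex i at cum[i]
  i <- findInterval(targets, cum, rightmost.closed = TRUE)
  i[i > n] <- n
  t <- (targets - cum[i]) / seg[i]
  xy[i, , drop = FALSE] + (nxt[i, , drop = FALSE] - xy[i, , drop = FALSE]) * t
}

# regular polygon approximating a circle
circle_polygon <- function(center, radius, max_arc = 0.5, n_min = 16) {
  n <- max(n_min, ceiling(2 * pi * radius / max_arc))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# ellipse polygon (axis-aligned), vertex arc spacing <= max_arc
ellipse_polygon <- function(center, a, b, max_arc = 0.5, n_min = 16) {
  h <- ((a - b) / (a + b))^2
  per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h))) # Ramanujan
  n <- max(n_min, ceiling(per / max_arc))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + a * cos(th), center[2] + b * sin(th))
}
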