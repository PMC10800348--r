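# Planar geometry engine.
#
# Everything works in one flat projected coordinate system in meters with the
# origin at the region corner (no geodesy). Polygons are n x 2 matrices of
# vertices without a repeated closing vertex. Landholdings are convex (Voronoi
# cells clipped to the region rectangle), deforestation patches are
# axis-aligned rectangles, so exact convex clipping covers every overlay the
# pipeline needs.

# Signed polygon area (shoelace); positive for counter-clockwise vertex order.
polygon_area_signed <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_area <- function(poly) abs(polygon_area_signed(poly))

# Area in hectares of a polygon with meter coordinates.
polygon_area_ha <- function(poly) polygon_area(poly) / 1e4

polygon_centroid <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x[j] + x) * cr) / (6 * a), sum((y[j] + y) * cr) / (6 * a))
}

# Sutherland-Hodgman step: clip polygon to half-plane a*x + b*y <= c.
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (is.null(n) || n == 0) return(matrix(numeric(0), 0, 2))
  d <- a * poly[, 1] + b * poly[, 2] - c
  keep <- d <= 0
  if (all(keep)) return(poly)
  if (!any(keep)) return(matrix(numeric(0), 0, 2))
  out <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i]) { k <- k + 1L; out[[k]] <- poly[i, ] }
    if (keep[i] != keep[j]) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1L
      out[[k]] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  do.call(rbind, out[seq_len(k)])
}

# Clip a polygon to a convex clip polygon (any vertex order).
clip_convex <- function(subject, clip) {
  if (polygon_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # keep points left of directed edge clip[i] -> clip[j]:
    # cross(p2-p1, q-p1) >= 0  <=>  -(dy) * qx + dx * qy <= dx*y1 - dy*x1 ... sign flip
    dx <- clip[j, 1] - clip[i, 1]; dy <- clip[j, 2] - clip[i, 2]
    # left: dx*(qy - y1) - dy*(qx - x1) >= 0  ->  dy*qx - dx*qy <= dy*x1 - dx*y1
    out <- clip_halfplane(out, dy, -dx, dy * clip[i, 1] - dx * clip[i, 2])
    if (nrow(out) == 0) break
  }
  out
}

rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# Point-in-polygon (ray casting, boundary counts as inside within fp noise),
# vectorized over points.
points_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Voronoi tessellation of seed points, clipped to [0,w] x [0,h].
# Returns a list of convex polygons, one per seed; O(n^2) half-plane clipping,
# fine for cadastre-scale n (hundreds).
voronoi_cells <- function(sx, sy, width, height) {
  n <- length(sx)
  cells <- vector("list", n)
  base <- rect_poly(0, 0, width, height)
  for (i in seq_len(n)) {
    poly <- base
    d2 <- (sx - sx[i])^2 + (sy - sy[i])^2
    for (j in order(d2)) {
      if (j == i) next
      # keep points closer to seed i than to seed j:
      a <- 2 * (sx[j] - sx[i]); b <- 2 * (sy[j] - sy[i])
      c <- sx[j]^2 + sy[j]^2 - sx[i]^2 - sy[i]^2
      poly <- clip_halfplane(poly, a, b, c)
      if (nrow(poly) == 0) break
    }
    cells[[i]] <- poly
  }
  cells
}

# Distance from points to one segment (a-b), vectorized over points.
point_seg_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
}

# Minimum distance from each point to a set of segments
# (segs: data.frame/matrix with columns ax, ay, bx, by).
min_dist_point_segs <- function(px, py, segs) {
  out <- rep(Inf, length(px))
  for (k in seq_len(nrow(segs))) {
    d <- point_seg_dist(px, py, segs[k, 1], segs[k, 2], segs[k, 3], segs[k, 4])
    out <- pmin(out, d)
  }
  out
}

seg_orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- seg_orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- seg_orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- seg_orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- seg_orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(ax, ay, bx, by, cx, cy)
    min(ax, bx) - 1e-9 <= cx && cx <= max(ax, bx) + 1e-9 &&
    min(ay, by) - 1e-9 <= cy && cy <= max(ay, by) + 1e-9
  (d1 == 0 && on_seg(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])) ||
  (d2 == 0 && on_seg(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])) ||
  (d3 == 0 && on_seg(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])) ||
  (d4 == 0 && on_seg(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2]))
}

# Distance between a segment and an axis-aligned rectangle
# rect = c(xmin, ymin, xmax, ymax). Zero when they intersect.
seg_rect_dist <- function(ax, ay, bx, by, rect) {
  xmin <- rect[1]; ymin <- rect[2]; xmax <- rect[3]; ymax <- rect[4]
  inside <- function(x, y) x >= xmin && x <= xmax && y >= ymin && y <= ymax
  if (inside(ax, ay) || inside(bx, by)) return(0)
  corners <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
  for (i in 1:4) {
    j <- if (i == 4) 1L else i + 1L
    if (segments_intersect(c(ax, ay), c(bx, by), corners[i, ], corners[j, ]))
      return(0)
  }
  # disjoint convex shapes: min over endpoint-to-rect and corner-to-segment
  pr <- function(px, py) {
    dx <- max(xmin - px, 0, px - xmax)
    dy <- max(ymin - py, 0, py - ymax)
    sqrt(dx * dx + dy * dy)
  }
  d <- min(pr(ax, ay), pr(bx, by))
  d2 <- point_seg_dist(corners[, 1], corners[, 2], ax, ay, bx, by)
  min(d, min(d2))
}

poly_bbox <- function(poly) {
  c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
}

bbox_overlap <- function(a, b) {
  a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
}
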