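# Planar polygon primitives used by the tessellation / overlay steps.
# All polygons are two-column matrices (x, y) of vertices in order, ring open
# (first vertex not repeated). Coordinates are projected metres; no geodesy.

#' Polygon area (shoelace formula)
#'
#' @param poly two-column numeric matrix of vertices (open ring).
#' @return Non-negative area. Orientation is ignored.
#' @keywords internal
poly_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

poly_centroid <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

poly_bbox <- function(poly) {
  c(min(poly[, 1]), max(poly[, 1]), min(poly[, 2]), max(poly[, 2]))
}

bbox_overlap <- function(b1, b2, tol = 0) {
  b1[1] <= b2[2] + tol && b2[1] <= b1[2] + tol &&
    b1[3] <= b2[4] + tol && b2[3] <= b1[4] + tol
}

# Sutherland-Hodgman: clip polygon `subject` by the convex polygon `clip`.
# Exact for convex-convex overlay; `clip` must be convex, `subject` may be
# any simple polygon. Returns a matrix (possibly with < 3 rows when the
# intersection is empty or degenerate).
clip_polygon_convex <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  # ensure counter-clockwise clip ring so "inside" is a consistent side
  if (ring_signed_area(clip) < 0) clip <- clip[n:1, , drop = FALSE]
  for (k in seq_len(n)) {
    if (is.null(nrow(out)) || nrow(out) == 0) return(out)
    a <- clip[k, ]
    b <- clip[if (k == n) 1L else k + 1L, ]
    out <- clip_halfplane(out, a, b)
  }
  out
}

ring_signed_area <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Keep the part of `poly` on the left of the directed line a -> b.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  side <- dx * (poly[, 2] - a[2]) - dy * (poly[, 1] - a[1])
  inside <- side >= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  xs <- numeric(2L * n); ys <- numeric(2L * n); m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      m <- m + 1L; xs[m] <- poly[i, 1]; ys[m] <- poly[i, 2]
    }
    if (inside[i] != inside[j]) {
      t <- side[i] / (side[i] - side[j])
      m <- m + 1L
      xs[m] <- poly[i, 1] + t * (poly[j, 1] - poly[i, 1])
      ys[m] <- poly[i, 2] + t * (poly[j, 2] - poly[i, 2])
    }
  }
  cbind(xs[seq_len(m)], ys[seq_len(m)])
}

# Area of intersection of a simple polygon with a convex polygon.
intersection_area <- function(subject, clip) {
  poly_area(clip_polygon_convex(subject, clip))
}

# Minimum Euclidean distance between two polygons' boundaries (vertex to
# segment, both directions). Zero when they touch or overlap on an edge;
# used for contiguity with a tolerance. Does not detect strict containment,
# which cannot occur between cells of one tessellation.
poly_min_distance <- function(p1, p2) {
  min(min_vert_seg(p1, p2), min_vert_seg(p2, p1))
}

min_vert_seg <- function(pts, poly) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- poly[j, 1]; by <- poly[j, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  len2[len2 == 0] <- 1
  best <- Inf
  for (i in seq_len(nrow(pts))) {
    t <- ((pts[i, 1] - ax) * dx + (pts[i, 2] - ay) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- (pts[i, 1] - qx)^2 + (pts[i, 2] - qy)^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# Point-in-polygon wrapper; boundary counts as inside.
point_in_poly <- function(x, y, poly) {
  sp::point.in.polygon(x, y, poly[, 1], poly[, 2]) > 0
}
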