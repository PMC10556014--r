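# Planar geometry primitives shared by masking, metrics and side detection.
# All coordinates in mm.

polygon_area_signed <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

polygon_area <- function(v) abs(polygon_area_signed(v))

# Ray casting with an explicit boundary test: points on an edge count as
# inside (the documented convention for the center_in coverage rule).
point_in_polygon <- function(px, py, v, tol = 1e-9) {
  n <- nrow(v)
  xs <- v[, 1]; ys <- v[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  # boundary check: distance from point to each edge segment
  dx <- xe - xs; dy <- ye - ys
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - xs) * dx + (py - ys) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  qx <- xs + t * dx; qy <- ys + t * dy
  if (min((px - qx)^2 + (py - qy)^2) <= tol^2) return(TRUE)
  # strict interior by crossing number
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

points_in_polygon <- function(px, py, v, tol = 1e-9) {
  vapply(seq_along(px), function(i) point_in_polygon(px[i], py[i], v, tol),
         logical(1))
}

segments_intersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
  d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
  d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
  (d1 * d2 < -eps) && (d3 * d4 < -eps)
}

# Simplicity check for small polygons: no pair of non-adjacent edges
# properly intersects.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(TRUE)
  idx <- function(i) (i - 1L) %% n + 1L
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the wrap-around
      if (segments_intersect(v[i, ], v[idx(i + 1L), ],
                             v[j, ], v[idx(j + 1L), ])) return(FALSE)
    }
  }
  TRUE
}

# Sutherland-Hodgman: clip polygon `subject` against CONVEX polygon `clip`
# (given counter-clockwise).  Returns the clipped vertex matrix (possibly
# with 0 rows).  Used for exact polygon/sensor-cell overlap areas.
clip_polygon_convex <- function(subject, clip) {
  if (polygon_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[k, ]; b <- clip[(k %% nc) + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inp <- out
    n <- nrow(inp)
    side <- ex * (inp[, 2] - a[2]) - ey * (inp[, 1] - a[1])  # >=0 is inside
    keep <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      j <- (i %% n) + 1L
      ci <- side[i] >= -1e-12; cj <- side[j] >= -1e-12
      if (ci) keep <- rbind(keep, inp[i, ])
      if (ci != cj) {
        t <- side[i] / (side[i] - side[j])
        keep <- rbind(keep, inp[i, ] + t * (inp[j, ] - inp[i, ]))
      }
    }
    out <- keep
  }
  out
}

# Overlap fraction of sensor cell polygon `cell` covered by mask polygon
# `poly` (cell assumed convex; mask polygon simple).
cell_coverage_fraction <- function(poly, cell) {
  inter <- clip_polygon_convex(poly, cell)
  if (nrow(inter) < 3L) return(0)
  polygon_area(inter) / polygon_area(cell)
}

# Perpendicular distance from point p to the infinite line through a, b,
# signed: positive on the side given by the left normal of (b - a).
point_line_signed_distance <- function(px, py, a, b) {
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("degenerate line")
  ((px - a[1]) * -dy + (py - a[2]) * dx) / len
}

convex_hull <- function(x, y) {
  idx <- grDevices::chull(x, y)
  cbind(x = x[idx], y = y[idx])
}

in_convex_hull <- function(px, py, hull, tol = 1e-7) {
  point_in_polygon(px, py, hull, tol = tol)
}

# Principal-axis alignment of a weighted point cloud.  Returns the rotation
# that maps the cloud into a frame whose second coordinate runs along the
# principal (long) axis; orientation of the axis is resolved by the caller.
principal_axis <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
  cxy <- sum(w * (x - mx) * (y - my))
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  list(center = c(mx, my), axis = e$vectors[, 1])  # unit vector, long axis
}
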