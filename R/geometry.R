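# Planar geometry primitives shared by the polarity metrics and the scene
# generator. All coordinates are in the mathematical frame used package-wide
# (see ?coordinate_conventions): x to the right, y upward, angles in radians
# counterclockwise from +x.

#' Wrap angles into (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles reduced modulo `2*pi` into the half-open interval `(-pi, pi]`.
#' @export
wrap_angle <- function(theta) {
  w <- theta - 2 * pi * floor(theta / (2 * pi) + 0.5)
  # floor() convention maps to [-pi, pi); move -pi to +pi
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Signed polygon area (shoelace formula)
#'
#' @param vertices two-column matrix of polygon vertices (not repeated at the
#'   end); orientation determines sign.
#' @return signed area; positive for counterclockwise orientation.
#' @export
polygon_area_signed <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

#' Polygon area (absolute)
#' @inheritParams polygon_area_signed
#' @return area >= 0.
#' @export
polygon_area <- function(vertices) abs(polygon_area_signed(vertices))

#' Polygon area centroid
#'
#' Area centroid of a simple polygon; may lie outside a concave polygon.
#'
#' @inheritParams polygon_area_signed
#' @return length-2 numeric (x, y).
#' @export
polygon_centroid <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n < 3) return(colMeans(v))
  j <- c(2:n, 1)
  cr <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(v))
  c(sum((v[, 1] + v[j, 1]) * cr), sum((v[, 2] + v[j, 2]) * cr)) / (6 * a)
}

# Do segments p1-p2 and p3-p4 properly intersect (cross at interior points)?
# `tol` is a relative tolerance: near-collinear configurations (shared edges
# of adjacent cells, up to float noise) do not count as crossings.
segments_cross <- function(p1, p2, p3, p4, tol = 0) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  scale <- max(abs(c(p1, p2, p3, p4)), 1)^2
  eps <- tol * scale
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
    ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))
}

#' Is a polygon simple (non-self-intersecting)?
#'
#' Checks all non-adjacent edge pairs for proper crossings (O(n^2); polygons
#' here are cell outlines with tens of vertices).
#'
#' @inheritParams polygon_area_signed
#' @return logical.
#' @export
polygon_is_simple <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n < 4) return(TRUE)
  j <- c(2:n, 1)
  for (a in seq_len(n - 2)) {
    for (b in (a + 1):n) {
      if (b == a || j[b] == a || j[a] == b) next
      if (segments_cross(v[a, ], v[j[a], ], v[b, ], v[j[b], ])) return(FALSE)
    }
  }
  TRUE
}

#' Point-in-polygon test (ray casting)
#'
#' Vectorized even-odd rule; points exactly on the boundary count as inside.
#'
#' @param x,y numeric vectors of point coordinates.
#' @param vertices two-column polygon vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- v[j[k], 1]; y1 <- v[j[k], 2]
    x2 <- v[k, 1];    y2 <- v[k, 2]
    crosses <- ((y1 > y) != (y2 > y))
    if (any(crosses)) {
      xi <- x1 + (y[crosses] - y1) * (x2 - x1) / (y2 - y1)
      flip <- rep(FALSE, length(x)); flip[crosses] <- x[crosses] < xi
      inside <- xor(inside, flip)
    }
    # boundary tolerance: collinear and within segment bbox
    dx <- x2 - x1; dy <- y2 - y1
    tcr <- abs(dx * (y - y1) - dy * (x - x1))
    len2 <- dx * dx + dy * dy
    tol <- sqrt(.Machine$double.eps) * max(1, sqrt(len2))
    within <- (x - x1) * dx + (y - y1) * dy
    on_edge <- on_edge | (tcr <= tol & within >= -tol & within <= len2 + tol)
  }
  inside | on_edge
}

#' First intersection of a ray with a polygon boundary
#'
#' Casts a ray from `origin` in direction `angle` and returns the nearest
#' boundary crossing with positive ray parameter.
#'
#' @param origin length-2 point (usually the cell centroid).
#' @param angle direction in radians (mathematical frame).
#' @param vertices two-column polygon vertex matrix.
#' @return list with `point` (x, y) and `distance` from origin; errors if the
#'   ray never meets the boundary (origin outside the polygon).
#' @export
ray_polygon_intersection <- function(origin, angle, vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  j <- c(2:n, 1)
  u <- c(cos(angle), sin(angle))
  best <- Inf
  for (k in seq_len(n)) {
    p <- v[k, ]; q <- v[j[k], ]
    e <- q - p
    den <- u[1] * (-e[2]) - u[2] * (-e[1])
    if (abs(den) < 1e-14) next  # parallel
    rhs <- p - origin
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den   # along ray
    s <- (u[1] * rhs[2] - u[2] * rhs[1]) / den         # along edge
    if (t > 1e-12 && s >= -1e-12 && s <= 1 + 1e-12 && t < best) best <- t
  }
  if (!is.finite(best)) {
    stop("ray from origin does not intersect the polygon boundary; ",
         "is the origin inside the polygon?")
  }
  list(point = origin + best * u, distance = best)
}

#' Convex hull area of a point set
#'
#' Convex hull by `grDevices::chull` followed by the shoelace formula.
#'
#' @param points two-column matrix of points.
#' @return hull area; 0 (with attribute `degenerate = TRUE`) for fewer than 3
#'   non-collinear points.
#' @export
convex_hull_area <- function(points) {
  p <- as.matrix(points)
  p <- p[stats::complete.cases(p), , drop = FALSE]
  if (nrow(p) < 3) return(structure(0, degenerate = TRUE))
  h <- grDevices::chull(p)
  if (length(h) < 3) return(structure(0, degenerate = TRUE))
  a <- polygon_area(p[h, , drop = FALSE])
  if (a == 0) structure(0, degenerate = TRUE) else a
}

# Clip a convex polygon by the half-plane {p : (p - a) . n <= 0}
# (Sutherland-Hodgman step). Used by the Voronoi mosaic builder.
clip_halfplane <- function(vertices, a, n_vec) {
  v <- as.matrix(vertices)
  m <- nrow(v)
  if (m == 0) return(v)
  sgn <- (v[, 1] - a[1]) * n_vec[1] + (v[, 2] - a[2]) * n_vec[2]
  out <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    in1 <- sgn[k] <= 1e-12; in2 <- sgn[k2] <= 1e-12
    if (in1) out <- rbind(out, v[k, ])
    if (in1 != in2) {
      t <- sgn[k] / (sgn[k] - sgn[k2])
      out <- rbind(out, v[k, ] + t * (v[k2, ] - v[k, ]))
    }
  }
  out
}

# Greedy globally-ordered one-to-one matching between two point sets:
# repeatedly accept the smallest remaining pairwise distance <= max_dist.
# Ties broken by lower row then lower column index (deterministic).
# Returns a two-column integer matrix (index_a, index_b).
greedy_match <- function(a, b, max_dist) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(integer(0), ncol = 2))
  d <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  d[d > max_dist^2] <- Inf
  out <- matrix(integer(0), ncol = 2)
  repeat {
    if (!any(is.finite(d))) break
    idx <- which(d == min(d), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    out <- rbind(out, idx)
    d[idx[1], ] <- Inf
    d[, idx[2]] <- Inf
  }
  unname(out)
}
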