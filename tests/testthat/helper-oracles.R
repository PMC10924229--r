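# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation.

# Convex hull area by gift wrapping (Jarvis march) + fan triangulation.
jarvis_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  h <- pts[hull, , drop = FALSE]
  if (nrow(h) < 3) return(0)
  # fan triangulation from the first hull vertex
  a <- 0
  for (i in 2:(nrow(h) - 1)) {
    a <- a + ((h[i, 1] - h[1, 1]) * (h[i + 1, 2] - h[1, 2]) -
                (h[i, 2] - h[1, 2]) * (h[i + 1, 1] - h[1, 1])) / 2
  }
  abs(a)
}

# Directionality oracle: densely sample the polygon boundary (n_pts points
# by arc length, image-frame coordinates), pick the boundary point whose
# math-frame direction from the centroid best matches the cluster
# direction, refine by local linear interpolation between neighbours.
boundary_sampling_directionality <- function(vertices, centroid, cluster,
                                             n_pts = 1e4) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  seg <- v[c(2:n, 1), ] - v
  len <- sqrt(rowSums(seg^2))
  s <- seq(0, sum(len), length.out = n_pts + 1)[-(n_pts + 1)]
  cum <- c(0, cumsum(len))
  idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE), n)
  frac <- (s - cum[idx]) / len[idx]
  pts <- v[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  target <- atan2(-(cluster[2] - centroid[2]), cluster[1] - centroid[1])
  ang <- atan2(-(pts[, 2] - centroid[2]), pts[, 1] - centroid[1])
  dd <- abs(wrap_angle(ang - target))
  i0 <- which.min(dd)
  # local refinement between the best point and its better neighbour
  nb <- c(if (i0 > 1) i0 - 1 else n_pts, if (i0 < n_pts) i0 + 1 else 1)
  i1 <- nb[which.min(dd[nb])]
  a0 <- wrap_angle(ang[i0] - target); a1 <- wrap_angle(ang[i1] - target)
  w <- if (abs(a0 - a1) < 1e-12) 0 else a0 / (a0 - a1)
  e_pt <- pts[i0, ] + w * (pts[i1, ] - pts[i0, ])
  sqrt(sum((cluster - centroid)^2)) / sqrt(sum((e_pt - centroid)^2))
}

# Random convex polygon (convex hull of uniform points in a disk of radius
# about `scale`), as a cell_outline.
random_convex_outline <- function(id, n_pts = 12, scale = 1, center = c(0, 0)) {
  repeat {
    p <- matrix(stats::rnorm(2 * n_pts, sd = scale), ncol = 2)
    h <- grDevices::chull(p)
    if (length(h) >= 4) break
  }
  cell_outline(id, sweep(p[h, ], 2, -center))
}

# Truth-labelled puncta tables of a scene, split by channel.
scene_truth_points <- function(scene) {
  tp <- scene$truth$puncta
  list(bb = data.frame(x_um = tp$x_um[tp$type == "bb"],
                       y_um = tp$y_um[tp$type == "bb"],
                       cell_true = tp$cell_id[tp$type == "bb"]),
       bf = data.frame(x_um = tp$x_um[tp$type == "bf"],
                       y_um = tp$y_um[tp$type == "bf"],
                       cell_true = tp$cell_id[tp$type == "bf"]))
}

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("%s within %g of %s",
                              paste(signif(object, 6), collapse = ","), tol,
                              paste(signif(expected, 6), collapse = ",")))
}
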