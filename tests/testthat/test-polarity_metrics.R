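# Per-cell and tissue-level polarity metrics.

unit_square <- function(id = 1, half = 1) {
  cell_outline(id, rbind(c(-half, -half), c(half, -half),
                         c(half, half), c(-half, half)))
}

test_that("rotational polarity matches closed forms and the min-pairs rule", {
  r <- rotational_polarity(rep(pi / 3, 12))
  expect_equal(r$rbar, 1)
  expect_equal(r$mean_angle_rad, pi / 3)
  expect_false(r$excluded)

  even <- rotational_polarity(2 * pi * (0:11) / 12 - pi)
  expect_lt(even$rbar, 1e-12)

  # ten at 0 and ten at pi/2: rbar = sqrt(2)/2, mean pi/4
  mix <- rotational_polarity(c(rep(0, 10), rep(pi / 2, 10)))
  expect_equal(mix$rbar, sqrt(2) / 2)
  expect_equal(mix$mean_angle_rad, pi / 4)

  few <- rotational_polarity(rep(0.2, 9), min_pairs = 10)
  expect_true(few$excluded)
  expect_true(is.na(few$rbar))
  expect_match(few$qc, "n_pairs")
  none <- rotational_polarity(numeric(0))
  expect_true(none$excluded)
})

test_that("cluster_center is the plain centroid", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(cluster_center(sq), c(0.5, 0.5))
  expect_equal(cluster_center(rbind(c(2, 3))), c(2, 3))
  set.seed(1)
  pts <- matrix(runif(200), ncol = 2)
  expect_equal(cluster_center(pts), colMeans(pts), tolerance = 1e-12)
  expect_true(all(is.na(cluster_center(matrix(numeric(0), ncol = 2)))))
})

test_that("translational angle uses the mathematical frame", {
  sq <- unit_square()
  # cluster up-right of the centroid in image coords (y down): (1,1)/sqrt2
  # at image-frame position (c + (0.5, -0.5)) is +pi/4
  expect_equal(translational_angle(sq, c(0.5, -0.5))$theta_rad, pi / 4)
  # cluster due image-up: +pi/2
  expect_equal(translational_angle(sq, c(0, -0.5))$theta_rad, pi / 2)
  und <- translational_angle(sq, sq$centroid + 1e-9)
  expect_true(is.na(und$theta_rad))
  expect_equal(und$qc, "undefined_angle")
})

test_that("theta is rotation equivariant", {
  set.seed(3)
  for (i in 1:20) {
    o <- random_convex_outline(1, scale = 2)
    cl <- o$centroid + runif(2, -0.2, 0.2)
    phi <- runif(1, -pi, pi)
    rot <- function(p) {
      # rotate by +phi in math frame, about the origin, image coords
      cbind(cos(phi) * p[, 1] + sin(phi) * p[, 2],
            -sin(phi) * p[, 1] + cos(phi) * p[, 2])
    }
    o2 <- cell_outline(1, rot(o$vertices))
    cl2 <- as.numeric(rot(rbind(cl)))
    t1 <- translational_angle(o, cl)$theta_rad
    t2 <- translational_angle(o2, cl2)$theta_rad
    expect_lt(abs(wrap_angle(t2 - t1 - phi)), 1e-9)
  }
})

test_that("bb_directionality: worked example and degenerate cases", {
  sq <- unit_square()  # [-1, 1]^2
  d <- bb_directionality(sq, c(0.5, 0))
  expect_equal(d$directionality, 0.5)
  expect_equal(d$edge_point, c(1, 0), tolerance = 1e-12)
  ctr <- bb_directionality(sq, c(0, 0))
  expect_equal(ctr$directionality, 0)
  expect_equal(ctr$qc, "cluster_at_centroid")
  expect_error(bb_directionality(sq, c(5, 5)), "outside")
})

test_that("bb_directionality matches the dense boundary-sampling oracle", {
  set.seed(8)
  for (i in 1:500) {
    o <- random_convex_outline(1, n_pts = sample(6:14, 1), scale = 1)
    # random interior cluster point (rejection from the bounding box)
    repeat {
      cl <- c(runif(1, min(o$vertices[, 1]), max(o$vertices[, 1])),
              runif(1, min(o$vertices[, 2]), max(o$vertices[, 2])))
      if (point_in_polygon(cl[1], cl[2], o$vertices) &&
          sum((cl - o$centroid)^2) > 1e-4) break
    }
    got <- bb_directionality(o, cl)$directionality
    oracle <- boundary_sampling_directionality(o$vertices, o$centroid, cl)
    expect_close(got, oracle, 1e-3)
  }
})

test_that("cluster_area equals the hull oracle; degenerate sets give 0", {
  corners <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(cluster_area(corners)$area_um2, 1)
  col <- cluster_area(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(col$area_um2, 0)
  expect_equal(col$qc, "degenerate_hull")
  set.seed(10)
  for (i in 1:20) {
    pts <- matrix(rnorm(100), ncol = 2)
    expect_equal(cluster_area(pts)$area_um2, jarvis_hull_area(pts),
                 tolerance = 1e-9)
  }
})

test_that("bb_count counts assigned puncta", {
  expect_equal(bb_count(matrix(numeric(0), ncol = 2)), 0L)
  sc <- generate_scene(scene_config(n_cells = 4, seed = 19))
  tp <- sc$truth$puncta
  for (o in sc$cells[1:2]) {
    expect_equal(bb_count(tp[tp$type == "bb" & tp$cell_id == o$cell_id,
                             c("x_um", "y_um")]),
                 sc$truth$cells$bb_count[o$cell_id])
  }
})

test_that("intensity_ratio behaves on flat and two-level images", {
  img <- matrix(1, 20, 20)
  m1 <- matrix(FALSE, 20, 20); m1[5:8, 5:8] <- TRUE
  m2 <- matrix(TRUE, 20, 20)
  expect_equal(intensity_ratio(img, m1, m2)$ratio, 1)
  img2 <- matrix(0.2, 20, 20); img2[m1] <- 0.4
  expect_equal(intensity_ratio(img2, m1, m2 & !m1)$ratio, 2)
  expect_equal(intensity_ratio(img, matrix(FALSE, 20, 20), m2)$qc,
               "empty_mask")
  expect_equal(intensity_ratio(img * 0, m1, m2)$qc, "zero_denominator")
})

test_that("tt_center finds a crescent and flags symmetric rings", {
  ps <- 0.1
  o <- cell_outline(1, rbind(c(0.5, 0.5), c(5.5, 0.5), c(5.5, 5.5),
                             c(0.5, 5.5)))
  img <- matrix(0.05, 60, 60)
  # uniform square blob of intensity 1 centred at (4, 3)
  img[26:35, 36:45] <- 1  # rows y 2.5..3.4, cols x 3.5..4.4
  tc <- tt_center(img, o, threshold = 0.5, pixel_size = ps)
  expect_equal(tc$center, c(3.95, 2.95), tolerance = 0.05)
  # symmetric ring: centroid degenerates to the cell centre
  img2 <- matrix(0.05, 60, 60)
  cx <- 30; cy <- 30
  for (r in seq_len(60)) for (c2 in seq_len(60)) {
    d <- sqrt((r - cy)^2 + (c2 - cx)^2)
    if (d >= 15 && d <= 18) img2[r, c2] <- 1
  }
  tc2 <- tt_center(img2, o, threshold = 0.5, pixel_size = ps)
  expect_equal(tc2$center, c((cx - 1) * ps, (cy - 1) * ps), tolerance = 0.1)
  # nothing above threshold
  expect_equal(tt_center(matrix(0.2, 60, 60), o, 0.5, ps)$qc, "no_signal")
})

test_that("corrected TT-BB distance follows its defining ratio", {
  expect_equal(corrected_tt_bb(c(0, 0), c(2, 0), c(2, 0))$ratio, 0)
  expect_equal(corrected_tt_bb(c(0, 0), c(0, 0), c(2, 0))$ratio, 1)
  expect_equal(corrected_tt_bb(c(0, 0), c(1, 0), c(2, 0))$ratio, 0.5)
  und <- corrected_tt_bb(c(0, 0), c(1, 0), c(0, 0))
  expect_true(is.na(und$ratio))
  expect_equal(und$qc, "tt_at_centroid")
})

test_that("tissue polarity delegates to circular statistics", {
  expect_equal(tissue_polarity(rep(1.2, 8))$rbar, 1)
  grid8 <- 2 * pi * (0:7) / 8 - pi
  expect_lt(tissue_polarity(grid8)$rbar, 1e-12)
  th <- withr::with_seed(6, rvonmises(200, 0.5, 2))
  A <- vm_mean_resultant(2)
  se <- sqrt((1 - A^2) / 200)
  tp <- tissue_polarity(c(th, NA, NA))
  expect_close(tp$rbar, A, 3 * se + 0.01)
  expect_equal(tp$n_excluded, 2)
  expect_equal(tp$circ_sd_rad, circ_sd(tp$rbar))
})

test_that("metrics are invariant under rigid translation and uniform scaling", {
  sc <- generate_scene(scene_config(n_cells = 4, seed = 23))
  stp <- scene_truth_points(sc)
  cfg <- analysis_config()
  res0 <- polarity_table(stp$bb[, 1:2], stp$bf[, 1:2], sc$cells, cfg)
  # translation
  sh <- c(3.21, -1.57)
  cells_t <- lapply(sc$cells, function(o)
    cell_outline(o$cell_id, sweep(o$vertices, 2, -sh)))
  bb_t <- data.frame(x_um = stp$bb$x_um + sh[1], y_um = stp$bb$y_um + sh[2])
  bf_t <- data.frame(x_um = stp$bf$x_um + sh[1], y_um = stp$bf$y_um + sh[2])
  res1 <- polarity_table(bb_t, bf_t, cells_t, cfg)
  for (col in c("rotational_rbar", "theta_trans_rad", "bb_directionality",
                "cluster_area_um2", "bb_count")) {
    expect_equal(res1$cells[[col]], res0$cells[[col]], tolerance = 1e-9)
  }
  # uniform scaling: ratios unchanged, areas scale by s^2
  s <- 2.5
  cells_s <- lapply(sc$cells, function(o)
    cell_outline(o$cell_id, o$vertices * s))
  res2 <- polarity_table(
    data.frame(x_um = stp$bb$x_um * s, y_um = stp$bb$y_um * s),
    data.frame(x_um = stp$bf$x_um * s, y_um = stp$bf$y_um * s),
    cells_s, analysis_config(pairing_max_dist_um = s * cfg$pairing_max_dist_um))
  expect_equal(res2$cells$bb_directionality, res0$cells$bb_directionality,
               tolerance = 1e-9)
  expect_equal(res2$cells$cluster_area_um2,
               s^2 * res0$cells$cluster_area_um2, tolerance = 1e-9)
  expect_equal(res2$cells$theta_trans_rad, res0$cells$theta_trans_rad,
               tolerance = 1e-9)
})

test_that("parameter recovery is monotone across a condition grid", {
  cfg <- analysis_config()
  med_dir <- c(); med_rbar <- c(); med_ratio <- c()
  for (cond in list(list(d = 0.15, k = 0.3, rho = 1.1),
                    list(d = 0.35, k = 2, rho = 1.5),
                    list(d = 0.55, k = 8, rho = 2))) {
    sc <- generate_scene(scene_config(n_cells = 9, cluster_offset = cond$d,
                                      kappa_rot = cond$k,
                                      enrichment = cond$rho, seed = 31))
    stp <- scene_truth_points(sc)
    res <- polarity_table(stp$bb[, 1:2], stp$bf[, 1:2], sc$cells, cfg,
                          actin = image_stack(sc$channels$actin,
                                              sc$pixel_size_um))
    med_dir <- c(med_dir, median(res$cells$bb_directionality, na.rm = TRUE))
    med_rbar <- c(med_rbar, median(res$cells$rotational_rbar, na.rm = TRUE))
    med_ratio <- c(med_ratio, median(res$cells$phalloidin_ratio, na.rm = TRUE))
  }
  expect_true(all(diff(med_dir) > 0))
  expect_true(all(diff(med_rbar) > 0))
  expect_true(all(diff(med_ratio) > 0))
  # directionality tracks the generating offset for convex cells
  expect_close(med_dir, c(0.15, 0.35, 0.55), 0.1)
})
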