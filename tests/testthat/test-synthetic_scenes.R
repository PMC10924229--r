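# The synthetic-scene, beat-trace, bead-track and kymograph generators:
# determinism, statistical calibration, geometric containment, rendering
# consistency.

small_cfg <- function(...) {
  args <- utils::modifyList(list(n_cells = 6, bb_count_mean = 25, seed = 3),
                            list(...))
  do.call(scene_config, args)
}

test_that("scene generation is deterministic for a fixed seed", {
  s1 <- generate_scene(small_cfg())
  s2 <- generate_scene(small_cfg())
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$channels, s2$channels)
  s3 <- generate_scene(small_cfg(seed = 4))
  expect_false(identical(s1$truth$puncta, s3$truth$puncta))
})

test_that("all basal bodies lie inside their cell; feet sit exactly r away", {
  sc <- generate_scene(small_cfg())
  tp <- sc$truth$puncta
  for (o in sc$cells) {
    bb <- tp[tp$type == "bb" & tp$cell_id == o$cell_id, ]
    expect_true(all(point_in_polygon(bb$x_um, bb$y_um, o$vertices)))
  }
  bb <- tp[tp$type == "bb", ]; bf <- tp[tp$type == "bf", ]
  d <- sqrt((bb$x_um - bf$x_um)^2 + (bb$y_um - bf$y_um)^2)
  expect_equal(d, rep(sc$config$bb_bf_dist_um, nrow(bb)), tolerance = 1e-9)
  # every basal foot has exactly one parent basal body
  expect_equal(nrow(bb), nrow(bf))
  # basal-foot angles follow the mathematical frame convention
  ang <- vector_angle(cbind(bb$x_um, bb$y_um), cbind(bf$x_um, bf$y_um))
  expect_lt(max(abs(wrap_angle(ang - bb$bf_angle_rad))), 1e-9)
})

test_that("degenerate limit: huge kappa_rot aligns every basal foot", {
  sc <- generate_scene(small_cfg(kappa_rot = 1e6, kappa_trans = 1e6))
  tp <- sc$truth$puncta
  bb <- tp[tp$type == "bb", ]
  err <- abs(wrap_angle(bb$bf_angle_rad - sc$config$mu_tissue))
  # per-cell direction and basal-foot angle each spread 1e-3 rad at
  # kappa = 1e6 (combined SD ~1.4e-3); the max over ~150 draws stays
  # within a few SD of the tissue direction
  expect_lt(max(err), 6e-3)
  expect_lt(median(err), 2e-3)
})

test_that("rotational spread matches the Bessel-ratio expectation", {
  # kappa = 2 over ~200 pairs: sample rbar within 3 SE of I1(2)/I0(2)
  sc <- generate_scene(scene_config(n_cells = 4, bb_count_mean = 50,
                                    kappa_rot = 2, seed = 12))
  ang <- sc$truth$puncta$bf_angle_rad[sc$truth$puncta$type == "bb"]
  theta <- sc$truth$cells$theta_cell_rad[sc$truth$puncta$cell_id[
    sc$truth$puncta$type == "bb"]]
  rel <- wrap_angle(ang - theta)  # remove per-cell mean direction
  A <- vm_mean_resultant(2)
  se <- sqrt((1 - A^2) / length(rel))
  expect_close(circ_mean_resultant(rel)$rbar, A, 3 * se + 0.01)
})

test_that("rendered noise-free spots sit on their generating points", {
  cfg <- scene_config(n_cells = 4, bb_count_mean = 6, bb_scatter_um = 2.5,
                      min_bb_sep_um = 1.5, seed = 6)
  sc <- generate_scene(cfg)
  tp <- sc$truth$puncta
  bb <- tp[tp$type == "bb", ]
  ps <- sc$pixel_size_um
  img <- sc$channels$bb
  for (k in seq_len(min(nrow(bb), 15))) {
    ci <- round(bb$x_um[k] / ps) + 1
    ri <- round(bb$y_um[k] / ps) + 1
    rows <- (ri - 3):(ri + 3); cols <- (ci - 3):(ci + 3)
    if (min(rows) < 1 || min(cols) < 1 ||
        max(rows) > nrow(img) || max(cols) > ncol(img)) next
    patch <- img[rows, cols] - cfg$background
    cx <- (sum(colSums(patch) * cols) / sum(patch) - 1) * ps
    cy <- (sum(rowSums(patch) * rows) / sum(patch) - 1) * ps
    # intensity-weighted centroid within 0.25 px of the generating point
    expect_lt(max(abs(c(cx - bb$x_um[k], cy - bb$y_um[k]))), 0.25 * ps)
  }
})

test_that("scene export writes the complete file set and reads back", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(small_cfg())
  paths <- export_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  mask <- read_label_mask(paths[["mask"]], sc$pixel_size_um)
  labs <- sort(unique(as.vector(mask$pixels)))
  expect_true(setequal(setdiff(labs, 0), seq_along(sc$cells)))
  pts <- read_points_csv(paths[["puncta"]])
  expect_equal(nrow(pts), nrow(sc$truth$puncta))
  outl <- read_outlines_csv(paths[["outlines"]])
  expect_length(outl, length(sc$cells))
  ch <- read_stack(paths[["bb"]], sc$pixel_size_um)
  expect_equal(ch$pixels, sc$channels$bb, tolerance = 1e-6)
})

test_that("beat traces honour immotile fraction, period and Nyquist guard", {
  trs <- generate_beat_traces(freq_hz = 20, fps = 190, duration_s = 2,
                              noise_sd = 0, immotile_fraction = 1,
                              n_traces = 5, seed = 1)
  expect_true(all(!vapply(trs, function(t) t$motile_truth, logical(1))))
  tr <- generate_beat_traces(freq_hz = 20, fps = 190, duration_s = 2,
                             noise_sd = 0, n_traces = 1, seed = 2)[[1]]
  x <- tr$displacement_um
  # exact 0.05 s period at 190 fps: samples repeat every 19 frames (two
  # full beats, the smallest integer number of samples)
  expect_equal(length(x), 380)
  expect_equal(x[1 + 19 * (0:19)], rep(x[1], 20), tolerance = 1e-6)
  expect_error(generate_beat_traces(freq_hz = 20, fps = 40), "Nyquist")
  t1 <- generate_beat_traces(n_traces = 3, seed = 7)
  t2 <- generate_beat_traces(n_traces = 3, seed = 7)
  expect_identical(t1, t2)
})

test_that("bead tracks are drift plus isotropic noise", {
  # diffusion 0: collinear, per-frame displacement = speed / fps
  tr <- generate_bead_tracks(speed_um_s = 2, direction_rad = pi / 4,
                             diffusion_sd_um = 0, fps = 10, duration_s = 2,
                             n_beads = 3, seed = 4)
  one <- tr[tr$bead_id == 1, ]
  dx <- diff(one$x_um); dy <- diff(one$y_um)
  expect_equal(sqrt(dx^2 + dy^2), rep(0.2, 19), tolerance = 1e-12)
  # mathematical frame: +pi/4 drifts right and image-up
  expect_true(all(dx > 0) && all(dy < 0))
  # speed 0: step directions are isotropic (Monte-Carlo check)
  rw <- generate_bead_tracks(speed_um_s = 0, diffusion_sd_um = 0.3,
                             fps = 10, duration_s = 40, n_beads = 10,
                             seed = 5)
  steps <- do.call(rbind, lapply(split(rw, rw$bead_id), function(b) {
    cbind(diff(b$x_um), diff(b$y_um))
  }))
  ang <- atan2(steps[, 2], steps[, 1])
  expect_lt(circ_mean_resultant(ang)$rbar, 3 / sqrt(nrow(steps)))
  expect_identical(generate_bead_tracks(seed = 6), generate_bead_tracks(seed = 6))
})

test_that("single-molecule kymograph geometry matches its parameters", {
  # pause probability 0: one run spanning all frames
  g <- generate_sm_kymograph(velocity_nm_s = 12.2, pause_prob = 0,
                             n_frames = 61, seed = 1)
  expect_equal(g$segments$kind, "run")
  expect_equal(g$segments$start_frame, 1L)
  expect_equal(g$segments$end_frame, 61L)
  # v = 12.2 nm/s at 3 s/frame for 3 min: total displacement ~ 2196 nm
  expect_equal((g$positions_um[61] - g$positions_um[1]) * 1000,
               12.2 * 3 * 60, tolerance = 1e-9)
  # velocity 0: vertical line (constant position)
  g0 <- generate_sm_kymograph(velocity_nm_s = 0, pause_prob = 0,
                              n_frames = 20, seed = 2)
  expect_equal(diff(range(g0$positions_um)), 0)
  expect_equal(which.max(g0$kymograph$matrix[1, ]),
               which.max(g0$kymograph$matrix[20, ]))
  expect_identical(generate_sm_kymograph(seed = 9, noise_sd = 0.05),
                   generate_sm_kymograph(seed = 9, noise_sd = 0.05))
})

test_that("reprojection keeps an aggressive cluster offset inside the cell", {
  sc <- generate_scene(scene_config(n_cells = 4, cluster_offset = 0.9,
                                    bb_scatter_um = 3, seed = 13))
  expect_gt(sc$n_reprojected, 0)
  tp <- sc$truth$puncta
  for (o in sc$cells) {
    bb <- tp[tp$type == "bb" & tp$cell_id == o$cell_id, ]
    expect_true(all(point_in_polygon(bb$x_um, bb$y_um, o$vertices)))
  }
})
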