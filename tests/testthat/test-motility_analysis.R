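# Kymographs, run/pause segmentation, velocities, beat frequency, bead
# tracking and time projections.

test_that("build_kymograph turns motion into sloped lines", {
  ps <- 0.1; nfr <- 20
  px <- array(0.02, c(nfr, 40, 60))
  # static spot at x = 3 um, y = 2 um
  for (t in 1:nfr) px[t, 21, 31] <- 1
  st <- image_stack(px, ps, frame_interval = 0.5)
  path <- rbind(c(0, 2), c(5.9, 2))
  ky <- build_kymograph(st, path, width_px = 3)
  expect_equal(nrow(ky$matrix), nfr)
  peaks <- apply(ky$matrix, 1, which.max)
  expect_equal(peaks, rep(31, nfr))
  # moving spot: 1 px/frame along the path -> unit-slope diagonal
  px2 <- array(0.02, c(nfr, 40, 60))
  for (t in 1:nfr) px2[t, 21, 10 + t] <- 1
  ky2 <- build_kymograph(image_stack(px2, ps, frame_interval = 0.5), path)
  expect_equal(apply(ky2$matrix, 1, which.max), 10 + 1:nfr)
  expect_error(build_kymograph(st, path, width_px = 2), "odd")
  expect_error(build_kymograph(st, rbind(c(0, 2), c(0.05, 2))), "2 pixels")
})

test_that("kymograph reconstruction correlates with the generator rendering", {
  g <- generate_sm_kymograph(velocity_nm_s = 12.2, pause_prob = 0.02,
                             n_frames = 60, noise_sd = 0, seed = 41)
  # re-render the particle into a movie and rebuild the kymograph
  ps_nm <- 100
  mat <- g$kymograph$matrix
  nfr <- nrow(mat); ncol_k <- ncol(mat)
  px <- array(0.05, c(nfr, 21, ncol_k))
  for (t in 1:nfr) {
    px[t, 11, ] <- mat[t, ]
  }
  st <- image_stack(px, ps_nm / 1000, frame_interval = 3)
  ky <- build_kymograph(st, rbind(c(0, 1), c((ncol_k - 1) * 0.1, 1)))
  m <- min(ncol(ky$matrix), ncol_k)
  expect_gt(cor(as.vector(ky$matrix[, 1:m]), as.vector(mat[, 1:m])), 0.99)
})

test_that("segmentation: constant-velocity and stationary traces", {
  v <- 12.2; dt <- 3
  pos <- (0:59) * v * dt / 1000
  seg <- segment_runs(pos, dt)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$kind, "run")
  expect_equal(seg$velocity_nm_s, v, tolerance = 1e-9)

  segp <- segment_runs(rep(1.5, 40), dt)
  expect_equal(nrow(segp), 1)
  expect_equal(segp$kind, "pause")

  short <- segment_runs(c(0, 0.01), dt)
  expect_true(attr(short, "flagged"))
})

test_that("run velocity and pause boundaries recover on noisy kymographs", {
  verr <- c(); bnd <- c()
  for (i in 1:25) {
    g <- generate_sm_kymograph(velocity_nm_s = 12.2, pause_prob = 0.03,
                               mean_pause_frames = 6, n_frames = 100,
                               noise_sd = 0.07, seed = 600 + i)  # SNR 10
    tr <- kymo_trace(g$kymograph)
    seg <- segment_runs(tr, 3)
    tru <- g$segments
    if (nrow(tru) > 1) {
      for (b in 2:nrow(tru)) {
        cand <- seg$start_frame[-1][seg$kind[-1] == tru$kind[b]]
        bnd <- c(bnd, if (length(cand))
          min(abs(cand - tru$start_frame[b])) else Inf)
      }
    }
    runs <- seg$kind == "run" & (seg$end_frame - seg$start_frame) >= 5
    verr <- c(verr, abs(seg$velocity_nm_s[runs] - 12.2))
  }
  expect_gte(mean(bnd <= 1), 0.9)
  expect_lte(mean(verr) / 12.2, 0.1)
})

test_that("run_velocity converts kymograph geometry to nm/s", {
  seg <- data.frame(start_frame = 1, end_frame = 11,
                    start_um = 0, end_um = 1)  # 10 columns x 100 nm
  expect_equal(run_velocity(seg, 3), 1000 / 30)  # 33.33 nm/s
  seg0 <- data.frame(start_frame = 1, end_frame = 5, start_um = 2, end_um = 2)
  expect_equal(run_velocity(seg0, 3), 0)
  bad <- data.frame(start_frame = 3, end_frame = 3, start_um = 0, end_um = 0)
  expect_error(run_velocity(bad, 3), "zero-duration")
})

test_that("velocity summaries equal sample moments", {
  s1 <- summarize_velocities(12.2)
  expect_equal(s1$sd, 0)
  expect_equal(s1$n, 1L)
  s2 <- summarize_velocities(c(10, 14))
  expect_equal(s2$mean, 12)
  expect_equal(s2$sd, sqrt(8))  # 2.828, sample SD
  v <- withr::with_seed(52, rnorm(143, 12.2, 2))
  s3 <- summarize_velocities(v)
  expect_close(s3$mean, 12.2, 3 * 2 / sqrt(143))
  expect_close(s3$sd, 2, 3 * 2 / sqrt(2 * 142))
  expect_equal(sum(s3$histogram$count), 143)
})

test_that("flat traces are scored immotile at 0 Hz", {
  flat <- withr::with_seed(1, rnorm(380, 0, 0.05))
  bf <- beat_frequency(flat, fps = 190)
  expect_equal(bf$freq_hz, 0)
  expect_false(bf$motile)
})

test_that("beat frequency recovers sinusoids including near Nyquist", {
  trs <- generate_beat_traces(freq_hz = 20, fps = 190, duration_s = 2,
                              noise_sd = 0, n_traces = 5, seed = 61)
  for (tr in trs) expect_close(beat_frequency(tr)$freq_hz, 20, 0.5)
  tr47 <- generate_beat_traces(freq_hz = 20, fps = 47, duration_s = 2,
                               noise_sd = 0, n_traces = 5, seed = 62)
  for (tr in tr47) expect_close(beat_frequency(tr)$freq_hz, 20, 1.0)
})

test_that("beat frequency is invariant to sign flip and offsets; 2-D traces project", {
  tr <- generate_beat_traces(freq_hz = 12, fps = 95, noise_sd = 0.1,
                             n_traces = 1, seed = 63)[[1]]
  f0 <- beat_frequency(tr)$freq_hz
  expect_equal(beat_frequency(-tr$displacement_um, fps = 95)$freq_hz, f0)
  expect_equal(beat_frequency(tr$displacement_um + 7.3, fps = 95)$freq_hz, f0)
  # 2-D tip positions along a slanted axis
  u <- c(cos(0.6), sin(0.6))
  xy <- outer(tr$displacement_um, u)
  expect_close(beat_frequency(xy, fps = 95)$freq_hz, f0, 0.2)
})

test_that("bead tracking links correctly and keeps identities apart", {
  tr <- generate_bead_tracks(speed_um_s = 3, diffusion_sd_um = 0,
                             n_beads = 1, duration_s = 5, seed = 71)
  tk <- track_beads(tr[, c("frame", "x_um", "y_um")], max_link_um = 1)
  expect_equal(length(unique(tk$track_id)), 1)
  expect_equal(nrow(tk), 50)
  # two distant beads never swap
  tr2 <- data.frame(frame = rep(1:10, 2),
                    x_um = c(1:10 * 0.3, 50 + 1:10 * 0.3),
                    y_um = rep(c(0, 0), each = 10))
  tk2 <- track_beads(tr2, max_link_um = 1)
  expect_equal(length(unique(tk2$track_id)), 2)
  sp <- split(tk2$x_um, tk2$track_id)
  expect_true(all(vapply(sp, function(x) diff(range(x)) < 5, logical(1))))
  expect_equal(nrow(track_beads(data.frame(frame = integer(0),
                                           x_um = numeric(0),
                                           y_um = numeric(0)), 1)), 0)
})

test_that("linking accuracy stays high at study-like bead density", {
  tr <- generate_bead_tracks(speed_um_s = 3.11, n_beads = 53,
                             diffusion_sd_um = 0.05, seed = 72)
  det <- tr[, c("frame", "x_um", "y_um")]
  tk <- track_beads(det, max_link_um = 1)
  key <- paste(tr$frame, round(tr$x_um, 9), round(tr$y_um, 9))
  lut <- tr$bead_id[match(paste(tk$frame, round(tk$x_um, 9),
                                round(tk$y_um, 9)), key)]
  ok <- unlist(lapply(split(seq_len(nrow(tk)), tk$track_id), function(ii) {
    ii <- ii[order(tk$frame[ii])]
    diff(lut[ii]) == 0
  }))
  expect_gte(mean(ok), 0.95)
})

test_that("pooled bead speeds: constants, accounting and provenance", {
  tr <- generate_bead_tracks(speed_um_s = 2.4, diffusion_sd_um = 0,
                             n_beads = 4, duration_s = 3, seed = 73)
  sp <- bead_speeds(tr, fps = 10)
  expect_equal(sp$per_frame$speed_um_s, rep(2.4, nrow(sp$per_frame)),
               tolerance = 1e-9)
  still <- data.frame(track_id = 1, frame = 1:20, x_um = 3, y_um = 4)
  expect_equal(bead_speeds(still, 10)$median, 0)
  # accounting identity: pooled rows = sum over tracks of (length - 1)
  tr2 <- generate_bead_tracks(n_beads = 20, seed = 74)
  sp2 <- bead_speeds(tr2, 10)
  expect_equal(sp2$n, sum(table(tr2$bead_id) - 1))
  expect_true(all(c("track_id", "frame") %in% names(sp2$per_frame)))
})

test_that("pooled median is invariant to relabeling and linear in drift", {
  tr <- generate_bead_tracks(n_beads = 10, seed = 75)
  sp0 <- bead_speeds(tr, 10)
  relab <- tr
  relab$bead_id <- match(relab$bead_id, sample(unique(relab$bead_id)))
  expect_equal(bead_speeds(relab, 10)$median, sp0$median)
  speeds <- c(1.67, 2.2, 2.7, 3.11, 4)
  meds <- vapply(speeds, function(v) {
    bead_speeds(generate_bead_tracks(speed_um_s = v, n_beads = 25,
                                     diffusion_sd_um = 0.05,
                                     seed = round(100 * v)), 10)$median
  }, numeric(1))
  expect_gt(summary(lm(meds ~ speeds))$r.squared, 0.99)
})

test_that("time projection is a pixel-wise running maximum", {
  px <- array(0.1, c(10, 8, 8))
  px[4, 3, 5] <- 0.9
  st <- image_stack(px, 0.2, frame_interval = 0.1)
  expect_equal(time_projection(st, 1)$pixels, px[1, , ])
  expect_equal(max(time_projection(st, 3)$pixels), 0.1)
  expect_equal(time_projection(st, 10)$pixels[3, 5], 0.9)
  # static scene: projection equals any single frame
  stat <- image_stack(array(rep(px[1, , ], each = 10), c(10, 8, 8)), 0.2,
                      frame_interval = 0.1)
  expect_equal(time_projection(stat)$pixels, px[1, , ])
  # moving spot leaves a streak of length ~ speed x duration / pixel
  ps <- 0.2
  mov <- array(0.02, c(20, 10, 40))
  for (t in 1:20) mov[t, 5, 5 + t] <- 1
  pr <- time_projection(image_stack(mov, ps, frame_interval = 0.1), 20)
  expect_equal(sum(pr$pixels[5, ] > 0.5), 20)
})
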