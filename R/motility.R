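# Time-domain analyses: kymograph construction and trace extraction,
# pause-segmented single-molecule velocities, ciliary beat frequency, bead
# tracking with pooled per-frame speeds, and time projections.

#' Construct a kymograph object
#'
#' @param matrix intensity matrix, rows = time frames, columns = positions
#'   along the sampling path; nonnegative.
#' @param pixel_size_um µm per column.
#' @param frame_interval_s seconds per row.
#' @param path optional source polyline (two-column matrix, µm).
#' @return object of class `kymograph`.
#' @export
kymograph <- function(matrix, pixel_size_um, frame_interval_s, path = NULL) {
  stopifnot(is.matrix(matrix), all(matrix >= 0), pixel_size_um > 0,
            frame_interval_s > 0)
  structure(list(matrix = matrix, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s, path = path),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d positions, %.4g um/col, %.4g s/row\n",
              nrow(x$matrix), ncol(x$matrix), x$pixel_size_um,
              x$frame_interval_s))
  invisible(x)
}

# Band-limited (sinc/FFT) upsampling of a uniformly sampled signal by an
# integer factor; exact for components below the original Nyquist limit.
sinc_upsample <- function(x, u = 8) {
  n <- length(x)
  if (n < 4 || u <= 1) return(x)
  m <- u * n
  X <- stats::fft(x)
  half <- floor(n / 2)
  Y <- complex(m)
  if (n %% 2 == 0) {
    Y[1:half] <- X[1:half]
    Y[half + 1] <- X[half + 1] / 2
    Y[m - half + 1] <- X[half + 1] / 2
    if (half > 1) Y[(m - half + 2):m] <- X[(half + 2):n]
  } else {
    Y[1:(half + 1)] <- X[1:(half + 1)]
    Y[(m - half + 1):m] <- X[(half + 2):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Bilinear intensity sampling at continuous pixel coordinates (1-based,
# image matrix row = y). Out-of-bounds positions clamp to the border.
sample_bilinear <- function(img, x_px, y_px) {
  ny <- nrow(img); nx <- ncol(img)
  x_px <- pmin(pmax(x_px, 1), nx); y_px <- pmin(pmax(y_px, 1), ny)
  x0 <- pmin(floor(x_px), nx - 1); y0 <- pmin(floor(y_px), ny - 1)
  fx <- x_px - x0; fy <- y_px - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Build a kymograph from a time-lapse stack along a path
#'
#' For each frame, intensity is sampled along the polyline at one-pixel
#' arc-length steps, taking the maximum across `width_px` perpendicular
#' offsets (the classic line-scan of width 3 drawn along a motor track).
#'
#' @param stack an [image_stack()] with a time axis.
#' @param path two-column matrix of polyline vertices (µm, image frame),
#'   total length at least 2 pixels.
#' @param width_px odd integer width of the sampling band.
#' @return a [kymograph()]; `pixel_size_um` equals the stack pixel size.
#' @export
build_kymograph <- function(stack, path, width_px = 3) {
  stopifnot(inherits(stack, "image_stack"), length(dim(stack$pixels)) == 3)
  if (width_px %% 2 != 1) stop("width_px must be odd")
  path <- as.matrix(path)
  ps <- stack$pixel_size
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  if (total < 2 * ps) stop("path must be at least 2 pixels long")
  s_steps <- seq(0, total, by = ps)
  cum <- c(0, cumsum(seg_len))
  idx <- pmin(findInterval(s_steps, cum, rightmost.closed = TRUE),
              nrow(path) - 1)
  frac <- (s_steps - cum[idx]) / seg_len[idx]
  pts <- path[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  tang <- seg[idx, , drop = FALSE] / seg_len[idx]
  norm <- cbind(-tang[, 2], tang[, 1])
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * ps
  n_frames <- dim(stack$pixels)[1]
  mat <- matrix(0, n_frames, length(s_steps))
  for (t in seq_len(n_frames)) {
    frame <- stack$pixels[t, , ]
    prof <- rep(-Inf, length(s_steps))
    for (o in offs) {
      q <- pts + o * norm
      prof <- pmax(prof, sample_bilinear(frame, q[, 1] / ps + 1,
                                         q[, 2] / ps + 1))
    }
    mat[t, ] <- prof
  }
  kymograph(mat, pixel_size_um = ps, frame_interval_s = stack$frame_interval,
            path = path)
}

#' Extract a particle trace from a kymograph
#'
#' Per-row sub-pixel position: each row (median-subtracted) is correlated
#' with a Gaussian template of width `sigma_px` (matched filter), the peak
#' is located within a tracking window centred on the previous frame's
#' position, and refined by parabolic interpolation of the correlation
#' around the peak.
#'
#' @param kym a [kymograph()].
#' @param start_col starting column (defaults to the brightest column of the
#'   first row).
#' @param window_px half-width of the tracking window in columns.
#' @param sigma_px Gaussian template sigma in columns (point-spread scale).
#' @return numeric vector of positions along the path, in µm, one per frame.
#' @export
kymo_trace <- function(kym, start_col = NULL, window_px = 6, sigma_px = 1.7) {
  mat <- kym$matrix
  n_frames <- nrow(mat); n_cols <- ncol(mat)
  if (is.null(start_col)) start_col <- which.max(mat[1, ])
  k <- gaussian_kernel_1d(sigma_px)
  r <- (length(k) - 1) / 2
  pos <- numeric(n_frames)
  cur <- start_col
  for (t in seq_len(n_frames)) {
    row <- mat[t, ] - stats::median(mat[t, ])
    cc <- as.numeric(stats::filter(row, k, sides = 2))
    cols <- max(r + 1, round(cur) - window_px):
      min(n_cols - r, round(cur) + window_px)
    pk <- cols[which.max(cc[cols])]
    den <- cc[pk - 1] - 2 * cc[pk] + cc[pk + 1]
    delta <- if (is.finite(den) && den != 0)
      0.5 * (cc[pk - 1] - cc[pk + 1]) / den else 0
    cur <- pk + max(-1, min(1, delta))
    pos[t] <- cur
  }
  (pos - 1) * kym$pixel_size_um
}

# O(1) segment fit residuals from prefix sums over positions p (frames
# a..b inclusive): constant fit for pauses, straight line for runs.
make_sse <- function(p) {
  t <- seq_along(p)
  c1 <- cumsum(p); c2 <- cumsum(p^2)
  ct <- cumsum(t); ctt <- cumsum(t^2); ctp <- cumsum(t * p)
  win <- function(cs, a, b) cs[b] - if (a > 1) cs[a - 1] else 0
  list(
    const = function(a, b) {
      nw <- b - a + 1
      max(0, win(c2, a, b) - win(c1, a, b)^2 / nw)
    },
    line = function(a, b) {
      nw <- b - a + 1
      if (nw < 3) return(0)
      sx <- win(ct, a, b); sy <- win(c1, a, b)
      sxx <- win(ctt, a, b) - sx^2 / nw
      sxy <- win(ctp, a, b) - sx * sy / nw
      syy <- win(c2, a, b) - sy^2 / nw
      if (sxx <= 0) return(max(0, syy))
      max(0, syy - sxy^2 / sxx)
    })
}

# Exact least-squares boundary placement for a fixed alternating run/pause
# structure: dynamic programme over (segment, end frame), pauses fitted as
# constants, runs as lines; adjacent segments share their boundary frame.
optimize_boundaries <- function(kinds, n, sse, min_pause) {
  m <- length(kinds)
  minlen <- ifelse(kinds == "pause", min_pause, 1L)
  if (sum(minlen) > n - 1) minlen <- rep(1L, m)  # infeasible: relax
  cost_seg <- function(i, a, b) {
    if (kinds[i] == "pause") sse$const(a, b) else sse$line(a, b)
  }
  f <- matrix(Inf, m, n)
  arg <- matrix(NA_integer_, m, n)
  for (b in (1 + minlen[1]):n) f[1, b] <- cost_seg(1, 1, b)
  if (m > 1) for (i in 2:m) {
    lo_a <- 1 + sum(minlen[seq_len(i - 1)])
    for (b in (lo_a + minlen[i]):n) {
      a_cand <- lo_a:(b - minlen[i])
      v <- f[i - 1, a_cand] + vapply(a_cand, function(a) cost_seg(i, a, b),
                                     numeric(1))
      j <- which.min(v)
      f[i, b] <- v[j]; arg[i, b] <- a_cand[j]
    }
  }
  bounds <- integer(m + 1); bounds[m + 1] <- n
  if (m > 1) for (i in m:2) bounds[i] <- arg[i, bounds[i + 1]]
  bounds[1] <- 1L
  list(bounds = bounds, sse = f[m, n])
}

#' Segment a kymograph trace into runs and pauses
#'
#' Three stages: (1) candidate pauses are frames whose speed over a sliding
#' window of `min_pause_frames` frames (on median-filtered positions) stays
#' below a threshold -- `pause_speed_nm_s`, raised adaptively towards half
#' the typical run speed so brief stops of fast motors are not missed;
#' (2) all boundaries are then placed exactly by a least-squares dynamic
#' programme in which pauses are constant and runs are straight lines;
#' (3) each candidate pause must beat the merged straight-line alternative
#' in a likelihood-ratio sense (noise estimated robustly from second
#' differences), otherwise it is pruned and the boundaries re-optimized.
#' Segment velocities are endpoint displacement over duration, in nm/s.
#'
#' @param positions_um per-frame positions along the path (µm), e.g. from
#'   [kymo_trace()].
#' @param frame_interval_s seconds per frame.
#' @param pause_speed_nm_s floor of the pause-speed threshold.
#' @param min_pause_frames minimum sustained frames for a pause call (also
#'   the speed-window length).
#' @return data.frame of segments: `kind` ("run"/"pause"), `start_frame`,
#'   `end_frame` (inclusive; adjacent segments share the boundary frame),
#'   `start_um`, `end_um`, `velocity_nm_s`, and attribute `flagged` = TRUE
#'   for traces shorter than 3 frames.
#' @export
segment_runs <- function(positions_um, frame_interval_s,
                         pause_speed_nm_s = 2, min_pause_frames = 3) {
  n <- length(positions_um)
  if (n < 3) {
    seg <- data.frame(kind = "run", start_frame = 1L, end_frame = n,
                      start_um = positions_um[1], end_um = positions_um[n],
                      velocity_nm_s = if (n == 2)
                        abs(diff(positions_um)) * 1000 / frame_interval_s
                      else 0)
    attr(seg, "flagged") <- TRUE
    return(seg)
  }
  k <- min(min_pause_frames, n - 1)
  p_s <- stats::runmed(positions_um, 3)
  wspeed <- abs(p_s[(1 + k):n] - p_s[1:(n - k)]) * 1000 /
    (k * frame_interval_s)
  v_run <- stats::median(wspeed[wspeed > stats::median(wspeed)])
  thr <- max(pause_speed_nm_s,
             if (is.finite(v_run)) 0.45 * v_run else 0)
  pause_step <- rep(FALSE, n - 1)
  for (t in which(wspeed < thr)) pause_step[t:(t + k - 1)] <- TRUE
  r <- rle(pause_step)
  kinds <- ifelse(r$values, "pause", "run")
  sse <- make_sse(positions_um)
  # robust noise level from second differences (variance of d2 = 6 sigma^2
  # for constant-velocity motion)
  d2 <- diff(diff(positions_um))
  sigma2 <- (stats::mad(d2) / sqrt(6))^2
  min_pause <- min(min_pause_frames, max(1L, n - 2L))
  repeat {
    opt <- optimize_boundaries(kinds, n, sse, min_pause)
    b <- opt$bounds
    m <- length(kinds)
    if (m == 1) break
    # likelihood-ratio pruning of the weakest unsupported pause
    worst_i <- 0L; worst_lr <- Inf
    for (i in which(kinds == "pause")) {
      a0 <- b[max(1, i - 1)]; b0 <- b[min(m, i + 1) + 1]
      sse_cur <- sum(vapply(max(1, i - 1):min(m, i + 1), function(j) {
        if (kinds[j] == "pause") sse$const(b[j], b[j + 1])
        else sse$line(b[j], b[j + 1])
      }, numeric(1)))
      sse_alt <- sse$line(a0, b0)
      dq <- if (i > 1 && i < m) 5 else 3  # params freed by the pause
      lr <- (sse_alt - sse_cur) / max(sigma2, 1e-12)
      if (lr < stats::qchisq(0.995, dq) && lr < worst_lr) {
        worst_lr <- lr; worst_i <- i
      }
    }
    if (worst_i == 0L) break
    # merge the pruned pause into its neighbouring run(s)
    drop <- if (worst_i > 1 && worst_i < m) c(worst_i, worst_i + 1)
    else worst_i
    kinds <- kinds[-drop]
    if (length(kinds) == 0) kinds <- "run"
  }
  b <- optimize_boundaries(kinds, n, sse, min_pause)$bounds
  seg <- data.frame(kind = kinds,
                    start_frame = b[seq_along(kinds)],
                    end_frame = b[seq_along(kinds) + 1])
  # segment endpoints read off the least-squares fit (line for runs,
  # constant for pauses), so a single noisy frame cannot skew the segment
  # displacement; velocity remains displacement / duration
  for (i in seq_len(nrow(seg))) {
    fr <- seg$start_frame[i]:seg$end_frame[i]
    p <- positions_um[fr]
    if (seg$kind[i] == "run" && length(fr) >= 3) {
      fit <- stats::lm.fit(cbind(1, fr), p)$coefficients
      seg$start_um[i] <- fit[1] + fit[2] * seg$start_frame[i]
      seg$end_um[i] <- fit[1] + fit[2] * seg$end_frame[i]
    } else if (seg$kind[i] == "pause") {
      seg$start_um[i] <- mean(p)
      seg$end_um[i] <- mean(p)
    } else {
      seg$start_um[i] <- p[1]
      seg$end_um[i] <- p[length(p)]
    }
  }
  seg$velocity_nm_s <- vapply(seq_len(nrow(seg)), function(i) {
    run_velocity(seg[i, ], frame_interval_s)
  }, numeric(1))
  attr(seg, "flagged") <- FALSE
  seg
}

#' Velocity of one kymograph segment
#'
#' Endpoint displacement (kymograph x-axis) divided by duration (y-axis),
#' converted to nm/s.
#'
#' @param segment one row of a [segment_runs()] data.frame (fields
#'   `start_frame`, `end_frame`, `start_um`, `end_um`).
#' @param frame_interval_s seconds per frame.
#' @return velocity in nm/s.
#' @export
run_velocity <- function(segment, frame_interval_s) {
  dt <- (segment$end_frame - segment$start_frame) * frame_interval_s
  if (dt <= 0) stop("zero-duration segment")
  abs(segment$end_um - segment$start_um) * 1000 / dt
}

#' Summarize a set of run velocities
#'
#' Sample mean and SD (the maximum-likelihood Gaussian location matches the
#' sample mean; SD reported with the usual n-1 denominator) plus histogram
#' bins for plotting the population.
#'
#' @param velocities numeric vector (nm/s).
#' @param bin_width_nm_s histogram bin width (default 1 nm/s).
#' @return list with `mean`, `sd` (0 for a single value), `n`, and
#'   `histogram` (data.frame of `bin_mid`, `count`).
#' @export
summarize_velocities <- function(velocities, bin_width_nm_s = 1) {
  v <- velocities[is.finite(velocities)]
  n <- length(v)
  if (n == 0) return(list(mean = NA_real_, sd = NA_real_, n = 0L,
                          histogram = data.frame(bin_mid = numeric(0),
                                                 count = integer(0))))
  br <- seq(floor(min(v) / bin_width_nm_s) * bin_width_nm_s,
            ceiling(max(v) / bin_width_nm_s + 1e-9) * bin_width_nm_s +
              bin_width_nm_s, by = bin_width_nm_s)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  list(mean = mean(v), sd = if (n > 1) stats::sd(v) else 0, n = n,
       histogram = data.frame(bin_mid = h$mids, count = h$counts))
}

#' Ciliary beat frequency of a tip trace
#'
#' The tip displacement (2-D motion is first projected onto its principal
#' axis) is scored for round-trips by a mean-level Schmitt trigger: one beat
#' per upward crossing of the mean, with hysteresis so noise cannot
#' double-count. Frequency is crossings per second; when a periodogram peak
#' (quadratically interpolated) agrees with the crossing count to within its
#' resolution, the peak refines the estimate (this rescues records sampled
#' near the Nyquist limit). Traces whose peak-to-peak amplitude stays below
#' `amplitude_threshold_um` are scored immotile: 0 Hz.
#'
#' @param trace a `beat_trace` from [generate_beat_traces()], a numeric
#'   displacement vector, or a two-column (x, y) position matrix.
#' @param fps frames per second (taken from a `beat_trace`).
#' @param amplitude_threshold_um peak-to-peak immotility threshold.
#' @return list with `freq_hz` (0 for immotile), `motile`, `n_beats`,
#'   `freq_crossing_hz`, `freq_fft_hz` (the periodogram cross-check).
#' @export
beat_frequency <- function(trace, fps = NULL, amplitude_threshold_um = 0.5) {
  if (inherits(trace, "beat_trace")) {
    fps <- trace$fps
    x <- trace$displacement_um
  } else if (is.matrix(trace) && ncol(trace) == 2) {
    ctr <- sweep(trace, 2, colMeans(trace))
    x <- ctr %*% svd(ctr, nu = 0, nv = 1)$v[, 1]
  } else {
    x <- as.numeric(trace)
  }
  if (length(x) < 2) stop("trace must have at least 2 frames")
  stopifnot(!is.null(fps), fps > 0)
  x <- x - mean(x)
  n <- length(x)
  duration <- n / fps
  ptp <- max(x) - min(x)
  if (ptp < amplitude_threshold_um) {
    return(list(freq_hz = 0, motile = FALSE, n_beats = 0L,
                freq_crossing_hz = 0, freq_fft_hz = 0))
  }
  # band-limited (sinc) 8x upsampling so that records sampled near the
  # Nyquist limit still show every round-trip to the trigger
  xu <- sinc_upsample(x, 8)
  a_rob <- (stats::quantile(xu, 0.95, names = FALSE) -
              stats::quantile(xu, 0.05, names = FALSE)) / 2
  h <- 0.4 * max(amplitude_threshold_um / 2, a_rob)
  state <- 0L  # 0 unknown, -1 low, +1 high
  n_beats <- 0L
  for (v in xu) {
    if (v <= -h) state <- -1L
    else if (v >= h) {
      if (state == -1L) n_beats <- n_beats + 1L
      state <- 1L
    }
  }
  f_cross <- n_beats / duration
  # periodogram refinement (zero-padded, parabolic peak interpolation)
  nfft <- 2^ceiling(log2(8 * n))
  sp <- Mod(stats::fft(c(x, rep(0, nfft - n))))^2
  half <- 2:(nfft %/% 2)
  pk <- half[which.max(sp[half])]
  num <- sp[pk - 1] - sp[pk + 1]
  den <- sp[pk - 1] - 2 * sp[pk] + sp[pk + 1]
  delta <- if (is.finite(den) && den != 0) 0.5 * num / den else 0
  f_fft <- (pk - 1 + delta) * fps / nfft
  freq <- if (n_beats >= 1 && abs(f_fft - f_cross) <= 3 / duration)
    f_fft else f_cross
  list(freq_hz = freq, motile = TRUE, n_beats = n_beats,
       freq_crossing_hz = f_cross, freq_fft_hz = f_fft)
}

#' Link per-frame detections into bead tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking: between consecutive
#' frames the globally smallest remaining displacement below `max_link_um`
#' is accepted repeatedly; unlinked detections start new tracks; tracks
#' shorter than `min_length` frames are dropped.
#'
#' @param detections data.frame with `frame`, `x_um`, `y_um`.
#' @param max_link_um maximum per-frame displacement.
#' @param min_length minimum track length in frames (default 3).
#' @return data.frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @export
track_beads <- function(detections, max_link_um, min_length = 3) {
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0))
  if (nrow(detections) == 0) return(empty)
  frames <- sort(unique(detections$frame))
  next_id <- 0L
  active <- data.frame(track_id = integer(0), x_um = numeric(0),
                       y_um = numeric(0))
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    det <- detections[detections$frame == frames[fi], c("x_um", "y_um")]
    linked_track <- rep(NA_integer_, nrow(det))
    if (nrow(active) > 0 && nrow(det) > 0 &&
        (fi > 1 && frames[fi] == frames[fi - 1] + 1)) {
      m <- greedy_match(as.matrix(active[, c("x_um", "y_um")]),
                        as.matrix(det), max_link_um)
      if (nrow(m) > 0) linked_track[m[, 2]] <- active$track_id[m[, 1]]
    }
    new <- is.na(linked_track)
    if (any(new)) {
      linked_track[new] <- next_id + seq_len(sum(new))
      next_id <- next_id + sum(new)
    }
    rows[[fi]] <- data.frame(track_id = linked_track, frame = frames[fi],
                             x_um = det$x_um, y_um = det$y_um)
    active <- data.frame(track_id = linked_track, x_um = det$x_um,
                         y_um = det$y_um)
  }
  out <- do.call(rbind, rows)
  keep <- names(which(table(out$track_id) >= min_length))
  out <- out[out$track_id %in% as.integer(keep), , drop = FALSE]
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Pooled per-frame bead speeds
#'
#' Per-frame speed is the displacement between consecutive linked positions
#' times the frame rate; the pooled list keeps (track, frame) provenance,
#' matching the frames-pooled-across-beads accounting used for cilia-driven
#' surface flow.
#'
#' @param tracks data.frame from [track_beads()] (or
#'   [generate_bead_tracks()] with `bead_id` renamed `track_id`).
#' @param fps frames per second.
#' @return list with `per_frame` (data.frame `track_id`, `frame`,
#'   `speed_um_s`), `per_track` (`track_id`, `n_frames`, `mean_speed_um_s`),
#'   `median`, `q25`, `q75`, `n` (pooled frame count; equals the sum of
#'   track lengths minus the number of tracks).
#' @export
bead_speeds <- function(tracks, fps) {
  if ("bead_id" %in% names(tracks) && !("track_id" %in% names(tracks))) {
    tracks$track_id <- tracks$bead_id
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  per <- lapply(split(tracks, tracks$track_id), function(tr) {
    if (nrow(tr) < 2) return(NULL)
    step_ok <- diff(tr$frame) == 1
    sp <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) * fps
    data.frame(track_id = tr$track_id[-1][step_ok],
               frame = tr$frame[-1][step_ok], speed_um_s = sp[step_ok])
  })
  per_frame <- do.call(rbind, per)
  if (is.null(per_frame)) {
    per_frame <- data.frame(track_id = integer(0), frame = integer(0),
                            speed_um_s = numeric(0))
  }
  rownames(per_frame) <- NULL
  agg <- if (nrow(per_frame) > 0) {
    stats::aggregate(speed_um_s ~ track_id, per_frame,
                     FUN = function(v) c(n = length(v), mean = mean(v)))
  } else NULL
  per_track <- if (is.null(agg)) {
    data.frame(track_id = integer(0), n_frames = integer(0),
               mean_speed_um_s = numeric(0))
  } else {
    data.frame(track_id = agg$track_id, n_frames = agg$speed_um_s[, "n"],
               mean_speed_um_s = agg$speed_um_s[, "mean"])
  }
  q <- if (nrow(per_frame) > 0)
    stats::quantile(per_frame$speed_um_s, c(0.25, 0.5, 0.75), names = FALSE)
  else rep(NA_real_, 3)
  list(per_frame = per_frame, per_track = per_track,
       median = q[2], q25 = q[1], q75 = q[3], n = nrow(per_frame))
}

#' Pixel-wise maximum time projection
#'
#' @param stack an [image_stack()] with a time axis (or a single frame,
#'   returned unchanged).
#' @param n_frames number of initial frames to project (default all; the
#'   flow assay uses the first 100).
#' @return an [image_stack()] holding the single projected frame.
#' @export
time_projection <- function(stack, n_frames = NULL) {
  px <- stack$pixels
  if (is.matrix(px)) return(stack)
  total <- dim(px)[1]
  if (is.null(n_frames)) n_frames <- total
  stopifnot(n_frames >= 1, n_frames <= total)
  proj <- apply(px[seq_len(n_frames), , , drop = FALSE], c(2, 3), max)
  image_stack(proj, pixel_size = stack$pixel_size,
              channel_names = stack$channel_names)
}
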