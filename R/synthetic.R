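# Ground-truthed synthetic inputs for every analysis stage: apical tissue
# scenes (cell mosaic, basal-body/basal-foot point sets, rendered channels),
# ciliary beat traces, bead tracks and single-molecule kymographs. Every
# generator is deterministic for a fixed seed, and every output carries its
# generating parameters so each pipeline stage can be validated by parameter
# recovery.

#' Synthetic scene configuration
#'
#' Parameters of the apical-tissue generator. Defaults emulate the
#' wild-type-like study conditions: about 50 basal bodies per cell, the
#' basal-body cluster offset halfway from the cell centre to the edge
#' (directionality 0.5), strongly aligned basal-foot vectors
#' (`kappa_rot = 8`), and a tissue-level translational concentration chosen
#' so the expected tissue R-bar is 0.714. A mutant-like tissue corresponds
#' to small `kappa_rot` (near-uniform basal-foot angles), small
#' `cluster_offset` and small `kappa_trans`.
#'
#' @param n_cells number of populated cells (>= 1).
#' @param cell_diameter_um typical cell diameter; sets the mosaic scale.
#' @param bb_count_mean mean basal-body count per cell (Poisson).
#' @param mu_tissue tissue polarity direction (radians, mathematical frame).
#' @param kappa_trans von Mises concentration of per-cell translational
#'   angles around `mu_tissue` (>= 0; 0 = unpolarized tissue).
#' @param cluster_offset fraction `d` in `[0, 1)` of the centroid-to-edge
#'   distance at which the basal-body cluster centre is placed.
#' @param kappa_rot von Mises concentration of basal-body to basal-foot
#'   angles around the cell's own direction (>= 0).
#' @param bb_bf_dist_um basal-body to basal-foot separation `r` (> 0;
#'   sub-micron, as seen by electron microscopy).
#' @param bb_scatter_um isotropic Gaussian SD of basal bodies around the
#'   cluster centre.
#' @param min_bb_sep_um hard-core minimum separation between basal bodies
#'   (centriole-scale exclusion; keeps the closest-dot pairing rule
#'   well-posed, as in real apical cortices where basal bodies cannot
#'   overlap).
#' @param enrichment actin-channel intensity enrichment `rho` at the
#'   basal-body disk region relative to the rest of the apical cortex.
#' @param psf_sigma_um Gaussian spot sigma for rendered puncta.
#' @param background background intensity (rendered channels live in [0, 1]).
#' @param spot_amplitude peak amplitude of one rendered spot.
#' @param gauss_noise_sd additive Gaussian noise SD (0 = noise-free).
#' @param poisson_photons if not `NULL`, apply Poisson noise with this many
#'   photons per intensity unit.
#' @param pixel_size_um rendering pixel size.
#' @param tt_sector_deg angular width of the tyrosinated-tubulin crescent.
#' @param tt_width_um radial width of the crescent band at the cell edge.
#' @param detect_noise_um localization noise added to exported point tables
#'   (0 = export true positions).
#' @param seed non-negative integer seed.
#' @return a validated list of class `scene_config`.
#' @export
scene_config <- function(n_cells = 30,
                         cell_diameter_um = 15,
                         bb_count_mean = 50,
                         mu_tissue = 0,
                         kappa_trans = vm_concentration(0.714),
                         cluster_offset = 0.5,
                         kappa_rot = 8,
                         bb_bf_dist_um = 0.25,
                         bb_scatter_um = 1.4,
                         min_bb_sep_um = 0.45,
                         enrichment = 1.5,
                         psf_sigma_um = 0.25,
                         background = 0.08,
                         spot_amplitude = 0.5,
                         gauss_noise_sd = 0,
                         poisson_photons = NULL,
                         pixel_size_um = 0.2,
                         tt_sector_deg = 100,
                         tt_width_um = 2.5,
                         detect_noise_um = 0,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_cells >= 1, cell_diameter_um > 0, bb_count_mean > 0,
            kappa_trans >= 0, kappa_rot >= 0,
            cluster_offset >= 0, cluster_offset < 1,
            bb_bf_dist_um > 0, bb_scatter_um >= 0, min_bb_sep_um >= 0,
            enrichment >= 0,
            psf_sigma_um > 0, pixel_size_um > 0, seed >= 0)
  cfg$n_cells <- as.integer(n_cells)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "scene_config")
}

# Voronoi mosaic of jittered grid seeds, clipped to the field rectangle.
# Half-plane clipping against every other seed (O(n^2), exact, convex cells).
voronoi_mosaic <- function(seeds, field_um) {
  n <- nrow(seeds)
  rect <- rbind(c(0, 0), c(field_um[1], 0), field_um, c(0, field_um[2]))
  lapply(seq_len(n), function(i) {
    v <- rect
    for (j in seq_len(n)) {
      if (j == i) next
      mid <- (seeds[i, ] + seeds[j, ]) / 2
      v <- clip_halfplane(v, mid, seeds[j, ] - seeds[i, ])
      if (nrow(v) < 3) break
    }
    v
  })
}

# Add Gaussian spots to an image matrix (image-frame um coordinates,
# pixel [1,1] centre at (0,0) um). Local windows of +-4 sigma.
render_spots <- function(img, xy_um, amplitude, sigma_um, pixel_size_um) {
  if (length(xy_um) == 0 || nrow(xy_um) == 0) return(img)
  ny <- nrow(img); nx <- ncol(img)
  w <- ceiling(4 * sigma_um / pixel_size_um)
  for (k in seq_len(nrow(xy_um))) {
    cx <- xy_um[k, 1] / pixel_size_um + 1
    cy <- xy_um[k, 2] / pixel_size_um + 1
    cols <- max(1, floor(cx) - w):min(nx, ceiling(cx) + w)
    rows <- max(1, floor(cy) - w):min(ny, ceiling(cy) + w)
    if (length(cols) == 0 || length(rows) == 0) next
    dx2 <- ((cols - cx) * pixel_size_um)^2
    dy2 <- ((rows - cy) * pixel_size_um)^2
    img[rows, cols] <- img[rows, cols] +
      amplitude * exp(-outer(dy2, dx2, "+") / (2 * sigma_um^2))
  }
  img
}

# Minimum distance from points to a polygon boundary (vectorized over points).
dist_to_boundary <- function(px, py, vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v); j <- c(2:n, 1)
  d2 <- rep(Inf, length(px))
  for (k in seq_len(n)) {
    ax <- v[k, 1]; ay <- v[k, 2]
    bx <- v[j[k], 1]; by <- v[j[k], 2]
    ex <- bx - ax; ey <- by - ay
    len2 <- ex^2 + ey^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * ex + (py - ay) * ey) / len2))
    d2 <- pmin(d2, (px - (ax + t * ex))^2 + (py - (ay + t * ey))^2)
  }
  sqrt(d2)
}

#' Generate a ground-truthed synthetic apical tissue scene
#'
#' Builds a Voronoi cell mosaic from jittered grid seeds; draws a
#' translational direction per cell from von Mises(`mu_tissue`,
#' `kappa_trans`); places the basal-body cluster centre at fraction
#' `cluster_offset` of the centroid-to-edge distance along that direction;
#' scatters basal bodies isotropically around the cluster centre (kept
#' inside the cell, re-projected towards the centroid when the scatter or
#' offset would leave the polygon); attaches each basal foot at exact
#' distance `bb_bf_dist_um` from its basal body at an angle drawn from von
#' Mises(cell direction, `kappa_rot`); and renders four channels (basal
#' body, basal foot, actin-like with `enrichment` at the cluster disks, and
#' a tyrosinated-tubulin-like crescent at the polarized cell edge) as
#' Gaussian spots over background, with optional Gaussian/Poisson noise.
#'
#' @param config a [scene_config()].
#' @return an object of class `scene`: list with `cells` (list of
#'   [cell_outline()]), `truth` (`$cells` and `$puncta` data.frames),
#'   `channels` (named list of image matrices in [0, 1]), `label_mask`
#'   (integer matrix), `pixel_size_um`, `field_um`, `n_reprojected`, and the
#'   `config` itself.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  local_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(cfg) {
  s <- cfg$cell_diameter_um
  nx <- ceiling(sqrt(cfg$n_cells))
  ny <- ceiling(cfg$n_cells / nx)
  field <- c(nx * s, ny * s)
  gx <- (rep(seq_len(nx), times = ny) - 0.5) * s
  gy <- (rep(seq_len(ny), each = nx) - 0.5) * s
  seeds <- cbind(gx + stats::runif(nx * ny, -0.3 * s, 0.3 * s),
                 gy + stats::runif(nx * ny, -0.3 * s, 0.3 * s))
  polys <- voronoi_mosaic(seeds, field)
  keep <- seq_len(cfg$n_cells)
  cells <- lapply(keep, function(i) cell_outline(i, polys[[i]]))

  margin <- cfg$bb_bf_dist_um + 0.15
  n_reproj <- 0L
  cell_rows <- list(); puncta_rows <- list()
  for (i in keep) {
    o <- cells[[i]]
    ctr <- o$centroid
    theta <- rvonmises(1, cfg$mu_tissue, cfg$kappa_trans)
    u_img <- c(cos(theta), -sin(theta))  # math angle -> image frame
    edge <- ray_polygon_intersection_img(ctr, theta, o$vertices)
    cluster_true <- ctr + cfg$cluster_offset * edge$distance * u_img
    n_bb <- max(1L, stats::rpois(1, cfg$bb_count_mean))
    bb <- matrix(NA_real_, n_bb, 2)
    for (k in seq_len(n_bb)) {
      # hard-core dart throwing: re-draw scatter proposals that fall within
      # min_bb_sep of an accepted basal body (basal bodies cannot overlap)
      p <- NULL
      for (try in 1:60) {
        q <- cluster_true + stats::rnorm(2, 0, cfg$bb_scatter_um)
        clear <- k == 1 || all((bb[seq_len(k - 1), 1] - q[1])^2 +
                                 (bb[seq_len(k - 1), 2] - q[2])^2 >=
                                 cfg$min_bb_sep_um^2)
        if (clear) { p <- q; break }
      }
      if (is.null(p)) p <- q  # crowded cell: accept the last proposal
      if (!point_in_polygon(p[1], p[2], o$vertices) ||
          dist_to_boundary(p[1], p[2], o$vertices) < margin) {
        # re-project towards the centroid, keeping the draw's direction
        n_reproj <- n_reproj + 1L
        d <- p - ctr
        len <- sqrt(sum(d^2))
        if (len < 1e-9) { p <- ctr } else {
          ang_img <- atan2(-d[2], d[1])
          e2 <- ray_polygon_intersection_img(ctr, ang_img, o$vertices)
          p <- ctr + d / len * max(0, min(len, e2$distance - margin))
        }
      }
      bb[k, ] <- p
    }
    bf_ang <- rvonmises(n_bb, theta, cfg$kappa_rot)
    bf <- bb + cfg$bb_bf_dist_um * cbind(cos(bf_ang), -sin(bf_ang))
    cell_rows[[i]] <- data.frame(
      cell_id = i, centroid_x_um = ctr[1], centroid_y_um = ctr[2],
      theta_cell_rad = theta, edge_dist_um = edge$distance,
      cluster_x_um = cluster_true[1], cluster_y_um = cluster_true[2],
      bb_count = n_bb)
    puncta_rows[[i]] <- rbind(
      data.frame(cell_id = i, type = "bb", index = seq_len(n_bb),
                 x_um = bb[, 1], y_um = bb[, 2], bf_angle_rad = bf_ang),
      data.frame(cell_id = i, type = "bf", index = seq_len(n_bb),
                 x_um = bf[, 1], y_um = bf[, 2], bf_angle_rad = bf_ang))
  }
  truth_cells <- do.call(rbind, cell_rows)
  truth_puncta <- do.call(rbind, puncta_rows)

  # label mask: nearest-seed labels (exact for a Voronoi mosaic)
  ps <- cfg$pixel_size_um
  npx <- ceiling(field[1] / ps); npy <- ceiling(field[2] / ps)
  pxs <- (seq_len(npx) - 1) * ps
  pys <- (seq_len(npy) - 1) * ps
  lab <- matrix(0L, npy, npx)
  d_best <- matrix(Inf, npy, npx)
  for (i in seq_len(nrow(seeds))) {
    d <- outer((pys - seeds[i, 2])^2, (pxs - seeds[i, 1])^2, "+")
    upd <- d < d_best
    lab[upd] <- if (i <= cfg$n_cells) i else 0L
    d_best[upd] <- d[upd]
  }

  # rendered channels
  blank <- matrix(cfg$background, npy, npx)
  is_bb <- truth_puncta$type == "bb"
  ch_bb <- render_spots(blank, as.matrix(truth_puncta[is_bb, c("x_um", "y_um")]),
                        cfg$spot_amplitude, cfg$psf_sigma_um, ps)
  ch_bf <- render_spots(blank, as.matrix(truth_puncta[!is_bb, c("x_um", "y_um")]),
                        cfg$spot_amplitude, cfg$psf_sigma_um, ps)
  # actin: uniform apical cortex, enriched rho-fold inside disks around BBs
  cortex_level <- 0.25
  ch_actin <- matrix(cfg$background, npy, npx)
  ch_actin[lab > 0] <- cortex_level
  pgx <- matrix(pxs, npy, npx, byrow = TRUE)
  pgy <- matrix(pys, npy, npx)
  disk_r <- 2 * cfg$psf_sigma_um  # per-dot disk radius, matching the metric
  in_disk <- matrix(FALSE, npy, npx)
  bbm <- as.matrix(truth_puncta[is_bb, c("x_um", "y_um")])
  wpx <- ceiling(disk_r / ps) + 1
  for (k in seq_len(nrow(bbm))) {
    cxi <- round(bbm[k, 1] / ps) + 1; cyi <- round(bbm[k, 2] / ps) + 1
    cols <- max(1, cxi - wpx):min(npx, cxi + wpx)
    rows <- max(1, cyi - wpx):min(npy, cyi + wpx)
    sub <- (pgx[rows, cols] - bbm[k, 1])^2 + (pgy[rows, cols] - bbm[k, 2])^2 <= disk_r^2
    in_disk[rows, cols] <- in_disk[rows, cols] | sub
  }
  enr <- in_disk & lab > 0
  ch_actin[enr] <- cortex_level * cfg$enrichment

  # tyrosinated-tubulin crescent: band at the cell boundary, centred on the
  # cell's own polarity direction
  ch_tt <- matrix(cfg$background, npy, npx)
  tt_xy <- matrix(NA_real_, length(keep), 2)
  half_sector <- cfg$tt_sector_deg * pi / 360
  for (i in keep) {
    o <- cells[[i]]
    idx <- which(lab == i)
    if (length(idx) == 0) next
    px <- pgx[idx]; py <- pgy[idx]
    ang <- atan2(-(py - o$centroid[2]), px - o$centroid[1])
    dtheta <- abs(wrap_angle(ang - truth_cells$theta_cell_rad[i]))
    db <- dist_to_boundary(px, py, o$vertices)
    sel <- dtheta <= half_sector & db <= cfg$tt_width_um
    if (!any(sel)) next
    ch_tt[idx[sel]] <- 0.6
    tt_xy[i, ] <- c(mean(px[sel]), mean(py[sel]))
  }
  truth_cells$tt_x_um <- tt_xy[, 1]
  truth_cells$tt_y_um <- tt_xy[, 2]

  channels <- list(bb = ch_bb, bf = ch_bf, actin = ch_actin, tt = ch_tt)
  channels <- lapply(channels, function(img) {
    if (!is.null(cfg$poisson_photons)) {
      img <- matrix(stats::rpois(length(img), img * cfg$poisson_photons) /
                      cfg$poisson_photons, nrow(img), ncol(img))
    }
    if (cfg$gauss_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, cfg$gauss_noise_sd)
    }
    pmin(pmax(img, 0), 1)
  })

  structure(list(cells = cells, truth = list(cells = truth_cells,
                                             puncta = truth_puncta),
                 channels = channels, label_mask = lab,
                 pixel_size_um = ps, field_um = field,
                 n_reprojected = n_reproj, config = cfg),
            class = "scene")
}

# Ray-polygon intersection for a mathematical-frame angle on image-frame
# polygon coordinates (y axis down): direction (cos a, -sin a).
ray_polygon_intersection_img <- function(origin, angle_math, vertices) {
  # flip y so the generic math-frame routine applies
  v <- cbind(vertices[, 1], -vertices[, 2])
  res <- ray_polygon_intersection(c(origin[1], -origin[2]), angle_math, v)
  list(point = c(res$point[1], -res$point[2]), distance = res$distance)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: %d cells, field %.0f x %.0f um, %d puncta per channel, seed %d\n",
              length(x$cells), x$field_um[1], x$field_um[2],
              sum(x$truth$puncta$type == "bb"), x$config$seed))
  invisible(x)
}

#' Export a scene to files
#'
#' Writes the four rendered channels and the label mask as TIFF, the cell
#' outlines and (optionally noisy) puncta point table as CSV, and the full
#' ground truth plus configuration as JSON -- the same schemas the reading
#' functions accept, so the whole pipeline can run from files.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
export_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- scene$pixel_size_um
  paths <- c(bb = file.path(dir, "channel_bb.tif"),
             bf = file.path(dir, "channel_bf.tif"),
             actin = file.path(dir, "channel_actin.tif"),
             tt = file.path(dir, "channel_tt.tif"),
             mask = file.path(dir, "label_mask.tif"),
             outlines = file.path(dir, "outlines.csv"),
             puncta = file.path(dir, "puncta.csv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "scene_config.json"))
  for (ch in names(scene$channels)) {
    write_stack(image_stack(scene$channels[[ch]], ps), paths[[ch]])
  }
  # labels stored as label/255 in float TIFF (exact for < 256 cells)
  write_stack(image_stack(scene$label_mask / 255, ps), paths[["mask"]])
  write_outlines_csv(scene$cells, paths[["outlines"]])
  tp <- scene$truth$puncta
  noise <- scene$config$detect_noise_um
  xy <- as.matrix(tp[, c("x_um", "y_um")])
  if (noise > 0) {
    xy <- xy + local_seed(scene$config$seed + 1L,
                          matrix(stats::rnorm(length(xy), 0, noise), ncol = 2))
  }
  write_points_csv(data.frame(cell_id = tp$cell_id, channel = tp$type,
                              x_um = xy[, 1], y_um = xy[, 2],
                              intensity = 1), paths[["puncta"]])
  jsonlite::write_json(list(cells = scene$truth$cells,
                            puncta = scene$truth$puncta,
                            n_reprojected = scene$n_reprojected),
                       paths[["truth"]], digits = NA, auto_unbox = TRUE)
  cfg <- scene$config
  jsonlite::write_json(unclass(cfg), paths[["config"]], digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(paths)
}

#' Read a label mask written by [export_scene()]
#' @param path TIFF path (labels stored as label/255).
#' @param pixel_size µm per pixel.
#' @return an [image_stack()] whose pixels are integer labels.
#' @export
read_label_mask <- function(path, pixel_size) {
  st <- read_stack(path, pixel_size)
  st$pixels <- round(st$pixels * 255)
  st
}

#' Generate synthetic ciliary-tip beat traces
#'
#' Motile traces are noisy sinusoidal tip displacements; immotile traces are
#' noise only. Refuses aliased ground truth (`fps <= 2 * freq_hz`).
#'
#' @param freq_hz true beat frequency of motile traces.
#' @param amplitude_um sinusoid amplitude (half peak-to-peak).
#' @param noise_sd_um additive Gaussian noise SD.
#' @param fps sampling rate (frames per second); records of 2 s at 47, 95 or
#'   190 fps match the acquisition this emulates.
#' @param duration_s record duration.
#' @param immotile_fraction fraction of traces that are immotile.
#' @param n_traces number of traces.
#' @param seed optional integer seed.
#' @return list of `beat_trace` objects: `displacement_um`, `fps`,
#'   `motile_truth`, `freq_truth_hz`.
#' @export
generate_beat_traces <- function(freq_hz = 19.9, amplitude_um = 1.25,
                                 noise_sd_um = 0.15, fps = 190,
                                 duration_s = 2, immotile_fraction = 0,
                                 n_traces = 1, seed = NULL) {
  stopifnot(freq_hz > 0, fps > 0, duration_s > 0,
            immotile_fraction >= 0, immotile_fraction <= 1)
  if (immotile_fraction < 1 && fps <= 2 * freq_hz) {
    stop("fps must exceed twice the beat frequency (Nyquist); got fps = ",
         fps, " for ", freq_hz, " Hz")
  }
  local_seed(seed, {
    n_im <- round(immotile_fraction * n_traces)
    motile <- c(rep(FALSE, n_im), rep(TRUE, n_traces - n_im))
    t_s <- (seq_len(floor(fps * duration_s)) - 1) / fps
    lapply(seq_len(n_traces), function(i) {
      x <- if (motile[i]) {
        phase <- stats::runif(1, 0, 2 * pi)
        amplitude_um * sin(2 * pi * freq_hz * t_s + phase)
      } else rep(0, length(t_s))
      x <- x + stats::rnorm(length(t_s), 0, noise_sd_um)
      structure(list(displacement_um = x, fps = fps,
                     motile_truth = motile[i],
                     freq_truth_hz = if (motile[i]) freq_hz else 0),
                class = "beat_trace")
    })
  })
}

#' Generate synthetic bead tracks (directed drift plus diffusion)
#'
#' Positions follow `x(t+1) = x(t) + v/fps * u(direction) + N(0, diffusion)`.
#' Defaults emulate the surface-flow assay this package quantifies: 10 fps
#' for 10 s, tens of beads in the field.
#'
#' @param speed_um_s drift speed (>= 0).
#' @param direction_rad drift direction (radians, mathematical frame).
#' @param diffusion_sd_um per-step isotropic Gaussian SD.
#' @param fps frames per second.
#' @param duration_s record duration.
#' @param n_beads number of beads.
#' @param field_um c(width, height) for uniform starting positions.
#' @param seed optional integer seed.
#' @return data.frame with `bead_id`, `frame`, `x_um`, `y_um` (image frame)
#'   and attribute `truth` (list of generating parameters).
#' @export
generate_bead_tracks <- function(speed_um_s = 3.11, direction_rad = 0,
                                 diffusion_sd_um = 0.05, fps = 10,
                                 duration_s = 10, n_beads = 53,
                                 field_um = c(200, 200), seed = NULL) {
  stopifnot(speed_um_s >= 0, diffusion_sd_um >= 0, fps > 0, n_beads >= 1)
  local_seed(seed, {
    n_frames <- floor(duration_s * fps)
    step <- speed_um_s / fps * c(cos(direction_rad), -sin(direction_rad))
    rows <- lapply(seq_len(n_beads), function(b) {
      p0 <- stats::runif(2) * field_um
      dx <- step[1] + stats::rnorm(n_frames - 1, 0, diffusion_sd_um)
      dy <- step[2] + stats::rnorm(n_frames - 1, 0, diffusion_sd_um)
      data.frame(bead_id = b, frame = seq_len(n_frames),
                 x_um = cumsum(c(p0[1], dx)), y_um = cumsum(c(p0[2], dy)))
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(speed_um_s = speed_um_s,
                               direction_rad = direction_rad,
                               diffusion_sd_um = diffusion_sd_um, fps = fps)
    out
  })
}

#' Generate a synthetic single-molecule kymograph
#'
#' One particle alternates constant-velocity runs and stationary pauses
#' (geometrically distributed pause lengths entered with per-frame
#' probability `pause_prob`), rendered into a distance-by-time intensity
#' matrix with Gaussian point-spread blur and optional noise. Defaults
#' emulate slow-motor imaging at one frame every 3 s.
#'
#' @param velocity_nm_s run velocity (>= 0).
#' @param pause_prob per-frame probability of entering a pause during a run.
#' @param mean_pause_frames mean pause duration in frames (>= 1).
#' @param min_pause_frames minimum pause duration in frames (pauses are
#'   sustained dwells, not single-frame hesitations; the remainder above the
#'   minimum is geometric with the requested mean).
#' @param pixel_size_nm nm per kymograph column.
#' @param frame_interval_s seconds per row.
#' @param n_frames number of frames (rows).
#' @param psf_sigma_nm Gaussian blur sigma.
#' @param amplitude,background,noise_sd rendering intensity parameters
#'   (peak amplitude over background; additive Gaussian noise SD, so
#'   amplitude / noise_sd is the SNR).
#' @param seed optional integer seed.
#' @return list with `kymograph` (a [kymograph()] object),
#'   `positions_um` (true particle position per frame, µm along the path),
#'   and `segments` (true run/pause table with frames, positions and
#'   velocity in nm/s).
#' @export
generate_sm_kymograph <- function(velocity_nm_s = 12.2, pause_prob = 0.02,
                                  mean_pause_frames = 6,
                                  min_pause_frames = 3, pixel_size_nm = 100,
                                  frame_interval_s = 3, n_frames = 60,
                                  psf_sigma_nm = 170, amplitude = 0.7,
                                  background = 0.05, noise_sd = 0,
                                  seed = NULL) {
  stopifnot(velocity_nm_s >= 0, pause_prob >= 0, pause_prob <= 1,
            mean_pause_frames >= min_pause_frames, min_pause_frames >= 1,
            n_frames >= 2)
  local_seed(seed, {
    n_steps <- n_frames - 1L       # state during interval t -> t+1
    state <- character(n_steps)
    pause_left <- 0L
    for (t in seq_len(n_steps)) {
      if (pause_left > 0) {
        state[t] <- "pause"; pause_left <- pause_left - 1L
      } else if (pause_prob > 0 && stats::runif(1) < pause_prob) {
        state[t] <- "pause"
        pause_left <- min_pause_frames - 1L +
          stats::rgeom(1, 1 / (mean_pause_frames - min_pause_frames + 1))
      } else state[t] <- "run"
    }
    step_nm <- ifelse(state == "run", velocity_nm_s * frame_interval_s, 0)
    pos_nm <- cumsum(c(0, step_nm))
    margin_px <- ceiling(4 * psf_sigma_nm / pixel_size_nm) + 2
    n_cols <- ceiling(max(pos_nm) / pixel_size_nm) + 2 * margin_px
    col_nm <- (seq_len(n_cols) - 1) * pixel_size_nm
    offset_nm <- margin_px * pixel_size_nm
    mat <- background +
      amplitude * exp(-(outer(pos_nm + offset_nm, col_nm, "-"))^2 /
                        (2 * psf_sigma_nm^2))
    if (noise_sd > 0) {
      mat <- mat + matrix(stats::rnorm(length(mat), 0, noise_sd),
                          nrow(mat), ncol(mat))
    }
    mat <- pmin(pmax(mat, 0), 1)
    seg <- rle(state)
    ends <- cumsum(seg$lengths)    # last step of each segment
    starts <- c(1L, utils::head(ends, -1) + 1L)
    segments <- data.frame(kind = seg$values, start_frame = starts,
                           end_frame = ends + 1L,
                           start_um = pos_nm[starts] / 1000,
                           end_um = pos_nm[ends + 1L] / 1000)
    segments$velocity_nm_s <- ifelse(segments$kind == "run", velocity_nm_s, 0)
    list(kymograph = kymograph(mat, pixel_size_um = pixel_size_nm / 1000,
                               frame_interval_s = frame_interval_s),
         positions_um = (pos_nm + offset_nm) / 1000,
         segments = segments)
  })
}
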