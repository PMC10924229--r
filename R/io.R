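# Reading and writing of every external artifact (TIFF stacks, point tables,
# outlines, label masks, config, result tables) and the unit/coordinate
# conventions shared by all modules.

#' Coordinate and unit conventions
#'
#' All file and in-memory point coordinates are in micrometres (µm) in the
#' *image frame*: origin at the image top-left, x increasing rightward,
#' y increasing downward, and the centre of pixel `[1, 1]` at (0, 0) µm
#' (continuous, sub-pixel coordinates). All *angles* are reported in the
#' *mathematical frame* obtained by negating y: 0 rad points along +x (image
#' right) and angles increase counterclockwise, so a structure one pixel
#' above another (smaller y) lies at +pi/2. Velocities are reported in nm/s
#' for single-molecule work and µm/s for bead flow; frequencies in Hz;
#' angles stored in radians (degrees only in exported tables where the
#' column name says so). No pixel-unit value escapes the package API:
#' calibration (`pixel_size`, `frame_interval`) is attached on read.
#'
#' @name coordinate_conventions
#' @keywords internal
NULL

#' Angle of the vector joining two image-frame points
#'
#' @param from,to two-column matrices (or length-2 vectors) of image-frame
#'   coordinates in µm.
#' @return angle(s) in radians in the mathematical frame (y negated),
#'   in `(-pi, pi]`.
#' @export
vector_angle <- function(from, to) {
  from <- rbind(from); to <- rbind(to)
  # wrap so the straight-left direction reports +pi, never -pi
  wrap_angle(atan2(-(to[, 2] - from[, 2]), to[, 1] - from[, 1]))
}

#' Construct a calibrated image stack
#'
#' @param pixels numeric matrix (y, x) for a single frame or 3-D array
#'   (time, y, x) for a time-lapse; all values finite and >= 0.
#' @param pixel_size pixel edge length in µm/pixel (> 0).
#' @param frame_interval seconds per frame (> 0); required when `pixels` has
#'   a time axis.
#' @param channel_names optional character label(s).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_size, frame_interval = NULL,
                        channel_names = NULL) {
  if (is.matrix(pixels)) {
    dims <- dim(pixels)
  } else if (is.array(pixels) && length(dim(pixels)) == 3) {
    dims <- dim(pixels)
    if (is.null(frame_interval)) {
      stop("frame_interval is required for a stack with a time axis")
    }
  } else {
    stop("pixels must be a (y, x) matrix or a (time, y, x) array")
  }
  if (any(dims == 0)) stop("zero-size image")
  if (!all(is.finite(pixels))) stop("all intensities must be finite")
  stopifnot(pixel_size > 0)
  if (!is.null(frame_interval)) stopifnot(frame_interval > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_names = channel_names),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  if (length(d) == 2) {
    cat(sprintf("image_stack: %d x %d px, %.4g um/px\n", d[1], d[2],
                x$pixel_size))
  } else {
    cat(sprintf("image_stack: %d frames of %d x %d px, %.4g um/px, %.4g s/frame\n",
                d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  }
  invisible(x)
}

#' Number of frames and total duration of a stack
#' @param stack an [image_stack()].
#' @return list with `n_frames` and `duration_s` (time between first and last
#'   frame; 0 for a single frame).
#' @export
stack_duration <- function(stack) {
  d <- dim(stack$pixels)
  n <- if (length(d) == 3) d[1] else 1L
  list(n_frames = n,
       duration_s = if (n > 1) (n - 1) * stack$frame_interval else 0)
}

#' Read a TIFF image or time-lapse stack
#'
#' Single-page files become single frames; multi-page files become
#' time-lapse stacks (time axis inferred from page count). The TIFF carries
#' no trusted calibration, so pixel size and frame interval are supplied by
#' the caller.
#'
#' @param path TIFF file path (8/16-bit or float).
#' @param pixel_size µm per pixel.
#' @param frame_interval seconds per frame (multi-page files only).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size, frame_interval = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) == 0) stop("no pages in TIFF: ", path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p  # first sample of RGB(A)
  })
  if (length(pages) == 1) {
    image_stack(pages[[1]], pixel_size = pixel_size)
  } else {
    if (is.null(frame_interval)) {
      stop("frame_interval is required for a multi-page TIFF")
    }
    px <- aperm(simplify2array(pages), c(3, 1, 2))
    image_stack(px, pixel_size = pixel_size, frame_interval = frame_interval)
  }
}

#' Write an image stack as (multi-page) float TIFF
#'
#' Values are stored as 32-bit float and must lie in `[0, 1]` (the renderer's
#' native range); round trips are exact to float precision (~1e-7 relative).
#'
#' @param stack an [image_stack()] with intensities in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  px <- stack$pixels
  if (min(px) < 0 || max(px) > 1) {
    stop("write_stack() stores float TIFF in [0, 1]; rescale first")
  }
  pages <- if (is.matrix(px)) list(px) else
    lapply(seq_len(dim(px)[1]), function(t) px[t, , ])
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
  invisible(path)
}

#' Construct a cell outline
#'
#' @param cell_id integer id.
#' @param vertices two-column matrix of polygon vertices in µm (image frame),
#'   ordered, not closed (first vertex not repeated).
#' @return object of class `cell_outline` with fields `cell_id`, `vertices`,
#'   `centroid` (area centroid), `area`, and `centroid_outside` flag (TRUE
#'   for concave cells whose area centroid falls outside the polygon).
#' @export
cell_outline <- function(cell_id, vertices) {
  v <- as.matrix(vertices)
  colnames(v) <- c("x_um", "y_um")
  if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3) stop("cell outline needs at least 3 vertices")
  if (!polygon_is_simple(v)) stop("cell ", cell_id, ": polygon self-intersects")
  a <- polygon_area(v)
  if (a <= 0) stop("cell ", cell_id, ": polygon area must be > 0")
  ctr <- polygon_centroid(v)
  structure(list(cell_id = as.integer(cell_id), vertices = v,
                 centroid = ctr, area = a,
                 centroid_outside = !point_in_polygon(ctr[1], ctr[2], v)),
            class = "cell_outline")
}

#' @export
print.cell_outline <- function(x, ...) {
  cat(sprintf("cell_outline %d: %d vertices, area %.3f um^2, centroid (%.2f, %.2f)\n",
              x$cell_id, nrow(x$vertices), x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

points_csv_cols <- c("cell_id", "channel", "x_um", "y_um", "intensity")

#' Read a puncta point table (CSV)
#'
#' Expected header: `cell_id, channel, x_um, y_um, intensity` (UTF-8, "."
#' decimal). `cell_id` may be empty/NA for unassigned puncta.
#'
#' @param path CSV path.
#' @return data.frame with the five columns, coordinates in µm.
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read points CSV: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(points_csv_cols, names(df))
  if (length(missing) > 0) {
    stop("points CSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("x_um", "y_um", "intensity")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad) > 0) {
        stop("points CSV ", path, ": non-numeric ", col, " at data row ",
             bad[1], " (file line ", bad[1] + 1, ")")
      }
      df[[col]] <- num
    }
  }
  df$cell_id <- suppressWarnings(as.integer(df$cell_id))
  df[, points_csv_cols]
}

#' Write a puncta point table (CSV)
#' @param puncta data.frame with columns `cell_id, channel, x_um, y_um,
#'   intensity`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(puncta, path) {
  missing <- setdiff(points_csv_cols, names(puncta))
  if (length(missing) > 0) stop("missing column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(puncta[, points_csv_cols], path, row.names = FALSE)
  invisible(path)
}

#' Read cell outlines from polygon CSV
#'
#' Expected header: `cell_id, vertex, x_um, y_um`; vertices ordered by
#' `vertex` within each cell.
#'
#' @param path CSV path.
#' @return list of [cell_outline()] objects, ordered by `cell_id`.
#' @export
read_outlines_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read outlines CSV: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "vertex", "x_um", "y_um")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("outlines CSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ids <- sort(unique(df$cell_id))
  lapply(ids, function(id) {
    sub <- df[df$cell_id == id, ]
    sub <- sub[order(sub$vertex), ]
    cell_outline(id, as.matrix(sub[, c("x_um", "y_um")]))
  })
}

#' Write cell outlines to polygon CSV
#' @param outlines list of [cell_outline()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_outlines_csv <- function(outlines, path) {
  rows <- do.call(rbind, lapply(outlines, function(o) {
    data.frame(cell_id = o$cell_id, vertex = seq_len(nrow(o$vertices)),
               x_um = o$vertices[, 1], y_um = o$vertices[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Convert an integer label mask to cell outlines
#'
#' Extracts, for each positive label, the longest 0.5-level contour of its
#' indicator image (marching-squares contours via
#' [grDevices::contourLines()]), accurate to about half a pixel. Cells whose
#' contour is degenerate are dropped with a warning.
#'
#' @param mask an [image_stack()] whose single frame holds integer labels
#'   (0 = background), or an integer matrix plus `pixel_size`.
#' @param pixel_size µm per pixel (taken from the stack when given one).
#' @return list of [cell_outline()] objects.
#' @export
label_mask_to_outlines <- function(mask, pixel_size = NULL) {
  if (inherits(mask, "image_stack")) {
    pixel_size <- mask$pixel_size
    mask <- mask$pixels
  }
  stopifnot(is.matrix(mask), !is.null(pixel_size))
  labels <- sort(unique(as.vector(mask)))
  labels <- labels[labels > 0]
  out <- list()
  for (lab in labels) {
    ind <- (mask == lab) * 1
    # pad so boundary cells produce closed contours; contourLines treats
    # x as rows -- build on pixel-centre coordinates then convert
    padded <- matrix(0, nrow(ind) + 2, ncol(ind) + 2)
    padded[2:(nrow(ind) + 1), 2:(ncol(ind) + 1)] <- ind
    cl <- grDevices::contourLines(x = seq_len(nrow(padded)),
                                  y = seq_len(ncol(padded)),
                                  z = padded, levels = 0.5)
    if (length(cl) == 0) next
    len <- vapply(cl, function(c0) length(c0$x), numeric(1))
    c0 <- cl[[which.max(len)]]
    # contour x follows rows (image y), y follows columns (image x);
    # remove padding offset of 1 and convert to 0-based pixel centres
    vx <- (c0$y - 2) * pixel_size
    vy <- (c0$x - 2) * pixel_size
    v <- cbind(vx, vy)
    if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
    o <- try(cell_outline(lab, v), silent = TRUE)
    if (inherits(o, "try-error")) {
      warning("label ", lab, ": degenerate contour dropped")
    } else {
      out <- c(out, list(o))
    }
  }
  out
}

#' Analysis configuration
#'
#' Bundles every tunable parameter with its default. Defaults follow the
#' measurement procedure the package implements: at least ten basal-body to
#' basal-foot vectors per cell before a rotational R-bar is reported, a 1 µm
#' pairing cutoff (the BB-BF separation is sub-micron), a 2 nm/s pause
#' threshold sustained for 3 frames in single-molecule kymographs, and a
#' 0.5 µm peak-to-peak amplitude floor below which a cilium is scored
#' immotile (0 Hz).
#'
#' @param pixel_size_um µm per pixel.
#' @param frame_interval_s seconds per frame for time-lapse input.
#' @param detect_sigma_um expected spot radius (Gaussian sigma) for puncta
#'   detection.
#' @param detect_threshold relative detection threshold in (0, 1], as a
#'   fraction of the image maximum after background subtraction.
#' @param pairing_max_dist_um maximum BB-BF pairing distance.
#' @param min_pairs_per_cell minimum number of BB-BF vectors for a per-cell
#'   rotational R-bar (>= 2).
#' @param immotile_amplitude_um peak-to-peak amplitude threshold below which
#'   a beat trace is scored 0 Hz.
#' @param pause_speed_nm_s instantaneous speed below which a motor is pausing.
#' @param min_pause_frames minimum sustained frames for a pause call.
#' @param disk_radius_um radius of the disks drawn around basal-body puncta
#'   when forming the "dots area" intensity mask (default 2 * detect_sigma).
#' @param max_link_um maximum per-frame displacement when linking bead
#'   detections into tracks.
#' @param n_permutations label permutations for the Watson U2 p-value.
#' @param seed non-negative integer RNG seed.
#' @param axis_convention free-text note mapping image axes to anatomical
#'   axes (e.g. "+x = anterior, +y(math) = dorsal"); carried into metadata.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(pixel_size_um = 0.2,
                            frame_interval_s = NULL,
                            detect_sigma_um = 0.25,
                            detect_threshold = 0.2,
                            pairing_max_dist_um = 1.0,
                            min_pairs_per_cell = 10,
                            immotile_amplitude_um = 0.5,
                            pause_speed_nm_s = 2,
                            min_pause_frames = 3,
                            disk_radius_um = NULL,
                            max_link_um = 1.0,
                            n_permutations = 9999,
                            seed = 1,
                            axis_convention = "+x anterior, +y (math frame) dorsal") {
  if (is.null(disk_radius_um)) disk_radius_um <- 2 * detect_sigma_um
  cfg <- list(pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
              detect_sigma_um = detect_sigma_um, detect_threshold = detect_threshold,
              pairing_max_dist_um = pairing_max_dist_um,
              min_pairs_per_cell = as.integer(min_pairs_per_cell),
              immotile_amplitude_um = immotile_amplitude_um,
              pause_speed_nm_s = pause_speed_nm_s,
              min_pause_frames = as.integer(min_pause_frames),
              disk_radius_um = disk_radius_um, max_link_um = max_link_um,
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed), axis_convention = axis_convention)
  for (nm in c("pixel_size_um", "detect_sigma_um", "detect_threshold",
               "pairing_max_dist_um", "immotile_amplitude_um",
               "pause_speed_nm_s", "disk_radius_um", "max_link_um")) {
    if (cfg[[nm]] <= 0) stop(nm, " must be > 0")
  }
  if (cfg$detect_threshold > 1) stop("detect_threshold must be in (0, 1]")
  if (cfg$min_pairs_per_cell < 2) stop("min_pairs_per_cell must be >= 2")
  if (cfg$seed < 0) stop("seed must be a non-negative integer")
  structure(cfg, class = "analysis_config")
}

#' Read / write an analysis configuration as JSON
#' @param path JSON file path.
#' @return for `read_config`, an [analysis_config()].
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- vals[names(vals) %in% names(formals(analysis_config))]
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @param config an [analysis_config()].
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a result table with a JSON sidecar
#'
#' Flat CSV (one row per cell/track/event, deterministic column order as
#' given) plus `<path>.json` recording the configuration and package
#' version.
#'
#' @param table data.frame of results.
#' @param path output CSV path.
#' @param config optional [analysis_config()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, config = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write results: no such directory ", dir)
  utils::write.csv(table, path, row.names = FALSE)
  side <- list(software = "ciliometry",
               version = as.character(utils::packageVersion("ciliometry")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               n_rows = nrow(table),
               config = if (is.null(config)) NULL else unclass(config))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("cannot read results: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
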