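# End-to-end orchestration: file-in/file-out commands with deterministic
# seeding and a machine-readable run manifest. A thin command-line wrapper
# over these functions ships in inst/cli/ciliometry.R.

# Stage-specific seed derived from a global seed (kept below 2^31).
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, detect = 211L, polarity = 307L,
            motility = 401L, compare = 503L)
  (as.integer(seed) * 7919L + offs[[stage]]) %% .Machine$integer.max
}

write_manifest <- function(dir, stage, inputs, seed, counts) {
  inputs <- inputs[file.exists(inputs)]
  man <- list(stage = stage,
              software = "ciliometry",
              version = as.character(utils::packageVersion("ciliometry")),
              seed = seed,
              inputs = lapply(inputs, function(p) {
                list(path = p, md5 = unname(tools::md5sum(p)))
              }),
              counts = counts)
  jsonlite::write_json(man, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

#' Simulate a scene and write every synthetic artifact
#'
#' Runs [generate_scene()] and [export_scene()]; identical (config, seed)
#' always produce identical files.
#'
#' @param out_dir output directory.
#' @param config a [scene_config()].
#' @param seed optional override of `config$seed`.
#' @return named vector of written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = scene_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  scene <- generate_scene(config)
  paths <- export_scene(scene, out_dir)
  write_manifest(out_dir, "simulate", character(0), config$seed,
                 list(n_cells = length(scene$cells),
                      n_puncta = nrow(scene$truth$puncta),
                      n_reprojected = scene$n_reprojected))
  invisible(paths)
}

#' Run the polarity pipeline from files
#'
#' Reads puncta (pre-detected CSV point table, or detects them from basal
#' body/foot channel TIFFs), reads cell outlines (polygon CSV or label-mask
#' TIFF), computes the full per-cell metric table and tissue summary, and
#' writes `cells.csv` (+ JSON sidecar), `pairs.csv` and `tissue.json`.
#'
#' @param out_dir output directory (created if needed).
#' @param config an [analysis_config()].
#' @param points_csv point table with `bb`/`bf` channels (used when given;
#'   otherwise both channel TIFFs are required).
#' @param outlines_csv polygon outlines CSV.
#' @param mask_tif label-mask TIFF (alternative to `outlines_csv`).
#' @param bb_tif,bf_tif channel TIFFs for detection.
#' @param actin_tif,tt_tif optional channels for the intensity ratio and
#'   corrected TT-BB distance.
#' @return the [polarity_table()] result, invisibly.
#' @export
cmd_polarity <- function(out_dir, config = analysis_config(),
                         points_csv = NULL, outlines_csv = NULL,
                         mask_tif = NULL, bb_tif = NULL, bf_tif = NULL,
                         actin_tif = NULL, tt_tif = NULL) {
  if (is.null(outlines_csv) && is.null(mask_tif)) {
    stop("cmd_polarity needs outlines_csv or mask_tif")
  }
  outlines <- if (!is.null(outlines_csv)) read_outlines_csv(outlines_csv)
  else label_mask_to_outlines(read_label_mask(mask_tif, config$pixel_size_um))
  if (!is.null(points_csv)) {
    pts <- read_points_csv(points_csv)
    bb <- pts[pts$channel == "bb", c("x_um", "y_um", "intensity")]
    bf <- pts[pts$channel == "bf", c("x_um", "y_um", "intensity")]
  } else {
    if (is.null(bb_tif) || is.null(bf_tif)) {
      stop("cmd_polarity needs points_csv or both bb_tif and bf_tif")
    }
    bb <- detect_puncta(read_stack(bb_tif, config$pixel_size_um),
                        config$detect_sigma_um, config$detect_threshold)
    bf <- detect_puncta(read_stack(bf_tif, config$pixel_size_um),
                        config$detect_sigma_um, config$detect_threshold)
  }
  actin <- if (!is.null(actin_tif)) read_stack(actin_tif, config$pixel_size_um)
  tt <- if (!is.null(tt_tif)) read_stack(tt_tif, config$pixel_size_um)
  res <- polarity_table(bb, bf, outlines, config, actin = actin, tt = tt)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results(res$cells, file.path(out_dir, "cells.csv"), config)
  write_pairs_csv(res$pairs, file.path(out_dir, "pairs.csv"))
  jsonlite::write_json(res$tissue, file.path(out_dir, "tissue.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_manifest(out_dir, "polarity",
                 c(points_csv, outlines_csv, mask_tif, bb_tif, bf_tif,
                   actin_tif, tt_tif),
                 config$seed,
                 list(n_cells = nrow(res$cells),
                      n_cells_excluded_min_pairs =
                        res$tissue$n_cells_excluded_min_pairs,
                      n_pairs = nrow(res$pairs),
                      n_puncta_bb = nrow(bb), n_puncta_bf = nrow(bf)))
  invisible(res)
}

#' Run a motility analysis from files
#'
#' Three modes: `"sm"` (single-molecule kymograph: trace extraction, pause
#' segmentation, per-run velocities -> `runs.csv` and `velocity.json`),
#' `"beat"` (tip-trace CSV with columns `trace_id`, `frame`,
#' `displacement_um` -> per-trace beat frequencies in `beat.csv`), and
#' `"beads"` (detection CSV with `frame`, `x_um`, `y_um` -> `tracks.csv` and
#' pooled `speeds.csv`).
#'
#' @param mode one of `"sm"`, `"beat"`, `"beads"`.
#' @param out_dir output directory.
#' @param config an [analysis_config()] (uses `pixel_size_um`,
#'   `frame_interval_s`, pause/link/immotility settings).
#' @param stack_tif time-lapse TIFF (sm mode).
#' @param path_csv polyline CSV (`x_um`, `y_um`) for the kymograph line
#'   (sm mode; defaults to a horizontal line through the brightest row).
#' @param traces_csv tip-trace CSV (beat mode).
#' @param detections_csv bead detection CSV (beads mode).
#' @param fps frames per second for beat/beads mode (defaults to
#'   `1 / config$frame_interval_s`).
#' @return invisibly, the mode-specific result list.
#' @export
cmd_motility <- function(mode = c("sm", "beat", "beads"), out_dir,
                         config = analysis_config(frame_interval_s = 3),
                         stack_tif = NULL, path_csv = NULL,
                         traces_csv = NULL, detections_csv = NULL,
                         fps = NULL) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(fps) && !is.null(config$frame_interval_s)) {
    fps <- 1 / config$frame_interval_s
  }
  if (mode == "sm") {
    stopifnot(!is.null(stack_tif))
    stack <- read_stack(stack_tif, config$pixel_size_um,
                        config$frame_interval_s)
    if (!is.null(path_csv)) {
      pth <- utils::read.csv(path_csv)
      kym <- build_kymograph(stack, as.matrix(pth[, c("x_um", "y_um")]))
    } else {
      proj <- time_projection(stack)
      row_best <- which.max(apply(proj$pixels, 1, max))
      y <- (row_best - 1) * config$pixel_size_um
      kym <- build_kymograph(stack, rbind(c(0, y),
                                          c((ncol(proj$pixels) - 1) *
                                              config$pixel_size_um, y)))
    }
    tr <- kymo_trace(kym)
    seg <- segment_runs(tr, config$frame_interval_s,
                        config$pause_speed_nm_s, config$min_pause_frames)
    runs <- seg[seg$kind == "run", , drop = FALSE]
    summ <- summarize_velocities(runs$velocity_nm_s)
    write_results(seg, file.path(out_dir, "runs.csv"), config)
    jsonlite::write_json(summ[c("mean", "sd", "n")],
                         file.path(out_dir, "velocity.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, "motility", c(stack_tif, path_csv), config$seed,
                   list(n_segments = nrow(seg), n_runs = nrow(runs)))
    return(invisible(list(kymograph = kym, trace = tr, segments = seg,
                          summary = summ)))
  }
  if (mode == "beat") {
    stopifnot(!is.null(traces_csv), !is.null(fps))
    df <- utils::read.csv(traces_csv)
    ids <- unique(df$trace_id)
    rows <- lapply(ids, function(id) {
      x <- df$displacement_um[df$trace_id == id][order(df$frame[df$trace_id == id])]
      bf <- beat_frequency(x, fps, config$immotile_amplitude_um)
      data.frame(trace_id = id, freq_hz = bf$freq_hz, motile = bf$motile,
                 n_beats = bf$n_beats)
    })
    beat <- do.call(rbind, rows)
    write_results(beat, file.path(out_dir, "beat.csv"), config)
    write_manifest(out_dir, "motility", traces_csv, config$seed,
                   list(n_traces = nrow(beat), n_motile = sum(beat$motile)))
    return(invisible(list(beat = beat)))
  }
  stopifnot(!is.null(detections_csv), !is.null(fps))
  det <- utils::read.csv(detections_csv)
  tracks <- track_beads(det, config$max_link_um)
  sp <- bead_speeds(tracks, fps)
  write_results(tracks, file.path(out_dir, "tracks.csv"), config)
  write_results(sp$per_frame, file.path(out_dir, "speeds.csv"), config)
  jsonlite::write_json(sp[c("median", "q25", "q75", "n")],
                       file.path(out_dir, "speed_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "motility", detections_csv, config$seed,
                 list(n_tracks = length(unique(tracks$track_id)),
                      n_pooled_frames = sp$n))
  invisible(list(tracks = tracks, speeds = sp))
}

#' Compare a metric column between two result files
#'
#' Routes angle columns (`*_rad`) to the Watson two-sample U2 test and
#' scalar columns to Welch's t-test or the Mann-Whitney U-test, writing the
#' result as JSON.
#'
#' @param csv_a,csv_b two `cells.csv`-style result files.
#' @param column column to compare.
#' @param test `"auto"`, `"watson"`, `"welch"` or `"mann_whitney"`.
#' @param out_json output JSON path (optional).
#' @param n_permutations,seed permutation settings for the Watson test.
#' @return the `htest` result, invisibly.
#' @export
cmd_compare <- function(csv_a, csv_b, column, test = "auto",
                        out_json = NULL, n_permutations = 9999, seed = 1) {
  a <- read_results(csv_a); b <- read_results(csv_b)
  for (nm in c(column)) {
    if (!(nm %in% names(a)) || !(nm %in% names(b))) {
      stop("column ", nm, " missing from inputs")
    }
  }
  x <- a[[column]]; y <- b[[column]]
  if (test == "auto") {
    test <- if (grepl("_rad$", column)) "watson" else "mann_whitney"
  }
  res <- if (test == "watson") {
    watson_u2(x[is.finite(x)], y[is.finite(y)],
              n_permutations = n_permutations, seed = seed)
  } else {
    compare_groups(x, y, method = test)
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(list(test = res$method, column = column,
                              statistic = unname(res$statistic),
                              p_value = res$p.value,
                              n_a = sum(is.finite(x)), n_b = sum(is.finite(y)),
                              n_permutations = if (test == "watson")
                                n_permutations else NULL,
                              seed = if (test == "watson") seed else NULL),
                         out_json, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(res)
}
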