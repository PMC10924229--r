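# Per-cell and tissue-level polarity metrics: rotational polarity (mean
# resultant length of basal-body to basal-foot vectors), translational
# polarity (angle and directionality of the basal-body cluster offset),
# distance of the cluster to the polarized tyrosinated-tubulin domain,
# cluster areas, counts and region-normalized intensity ratios.

#' Per-cell rotational polarity
#'
#' Averages the unit vectors of the BB-to-BF pair angles of one cell; R-bar
#' is the length of the mean vector (1 = all basal feet point the same way)
#' and the mean angle its direction. Cells with fewer than `min_pairs`
#' vectors are returned flagged and excluded from downstream summaries.
#'
#' @param pairs a [pair_bb_bf()] data.frame for one cell, or a numeric
#'   vector of pair angles in radians.
#' @param min_pairs minimum number of vectors required (default 10).
#' @return list with `rbar`, `mean_angle_rad`, `n_pairs`, `excluded`
#'   (logical) and `qc` (character, `""` when clean).
#' @export
rotational_polarity <- function(pairs, min_pairs = 10) {
  angles <- if (is.numeric(pairs)) pairs else pairs$angle_rad
  n <- length(angles)
  if (n < min_pairs) {
    return(list(rbar = NA_real_, mean_angle_rad = NA_real_, n_pairs = n,
                excluded = TRUE,
                qc = sprintf("n_pairs<%d", min_pairs)))
  }
  cm <- circ_mean_resultant(angles)
  list(rbar = cm$rbar, mean_angle_rad = cm$mean_angle, n_pairs = n,
       excluded = FALSE, qc = "")
}

#' Centre of a cell's basal-body cluster
#'
#' Unweighted centroid of the basal-body punctum positions (the centre of
#' the multicilia bundle base).
#'
#' @param points data.frame with `x_um`, `y_um`, or a two-column matrix.
#' @return length-2 numeric (x, y) in µm; `c(NA, NA)` for zero puncta.
#' @export
cluster_center <- function(points) {
  m <- if (is.data.frame(points)) as.matrix(points[, c("x_um", "y_um")]) else
    as.matrix(points)
  if (nrow(m) == 0) return(c(NA_real_, NA_real_))
  colMeans(m)
}

#' Translational polarity angle of one cell
#'
#' Angle (mathematical frame) of the vector from the cell centroid to the
#' basal-body cluster centre.
#'
#' @param outline a [cell_outline()].
#' @param cluster length-2 cluster centre (µm, image frame).
#' @param eps offsets below `eps` µm have no defined direction (default
#'   1e-6).
#' @return list with `theta_rad` (NA when undefined) and `qc`.
#' @export
translational_angle <- function(outline, cluster, eps = 1e-6) {
  d <- sqrt(sum((cluster - outline$centroid)^2))
  if (!is.finite(d) || d < eps) {
    return(list(theta_rad = NA_real_, qc = "undefined_angle"))
  }
  list(theta_rad = as.numeric(vector_angle(outline$centroid, cluster)),
       qc = "")
}

#' Basal-body cluster directionality of one cell
#'
#' Distance from the cell centroid to the cluster centre divided by the
#' distance from the centroid to the cell edge, where the edge point E is
#' the first intersection of the ray from the centroid through the cluster
#' with the polygon boundary. Lies in [0, 1]: 0 = cluster at the centre,
#' 1 = cluster at the edge.
#'
#' @inheritParams translational_angle
#' @return list with `directionality`, `edge_point` (x, y),
#'   `edge_dist_um`, and `qc` (`"cluster_at_centroid"` gives 0 by
#'   continuity).
#' @export
bb_directionality <- function(outline, cluster, eps = 1e-6) {
  if (!point_in_polygon(cluster[1], cluster[2], outline$vertices)) {
    stop("cluster centre lies outside cell ", outline$cell_id)
  }
  d <- sqrt(sum((cluster - outline$centroid)^2))
  if (d < eps) {
    return(list(directionality = 0, edge_point = c(NA_real_, NA_real_),
                edge_dist_um = NA_real_, qc = "cluster_at_centroid"))
  }
  ang <- as.numeric(vector_angle(outline$centroid, cluster))
  edge <- ray_polygon_intersection_img(outline$centroid, ang, outline$vertices)
  list(directionality = min(d / edge$distance, 1), edge_point = edge$point,
       edge_dist_um = edge$distance, qc = "")
}

#' Centre of the polarized tyrosinated-tubulin domain of one cell
#'
#' Pixels inside the cell whose background-subtracted intensity exceeds
#' `threshold` times the in-cell maximum form the polarized region; its
#' intensity-weighted centroid is returned. Background is the per-image
#' median.
#'
#' @param image an [image_stack()] frame or matrix (+ `pixel_size`).
#' @param outline a [cell_outline()].
#' @param threshold fraction of the in-cell maximum in (0, 1].
#' @param pixel_size µm per pixel (taken from an [image_stack()]).
#' @return list with `center` (x, y in µm; NA when no pixel passes),
#'   `n_pixels`, and `qc`.
#' @export
tt_center <- function(image, outline, threshold = 0.5, pixel_size = NULL) {
  if (inherits(image, "image_stack")) {
    pixel_size <- image$pixel_size
    image <- image$pixels
  }
  stopifnot(is.matrix(image), !is.null(pixel_size),
            threshold > 0, threshold <= 1)
  bgsub <- image - stats::median(image)
  bbx <- range(outline$vertices[, 1]); bby <- range(outline$vertices[, 2])
  cols <- max(1, floor(bbx[1] / pixel_size) + 1):
    min(ncol(image), ceiling(bbx[2] / pixel_size) + 1)
  rows <- max(1, floor(bby[1] / pixel_size) + 1):
    min(nrow(image), ceiling(bby[2] / pixel_size) + 1)
  px <- rep((cols - 1) * pixel_size, each = length(rows))
  py <- rep((rows - 1) * pixel_size, times = length(cols))
  inside <- point_in_polygon(px, py, outline$vertices)
  if (!any(inside)) {
    return(list(center = c(NA_real_, NA_real_), n_pixels = 0L,
                qc = "no_pixels_in_cell"))
  }
  vals <- as.vector(bgsub[rows, cols, drop = FALSE])[inside]
  vmax <- max(vals)
  if (vmax <= 0) {
    return(list(center = c(NA_real_, NA_real_), n_pixels = 0L,
                qc = "no_signal"))
  }
  sel <- vals >= threshold * vmax
  wx <- px[inside][sel]; wy <- py[inside][sel]; wv <- vals[sel]
  list(center = c(sum(wx * wv), sum(wy * wv)) / sum(wv),
       n_pixels = sum(sel), qc = "")
}

#' Corrected distance between basal-body cluster and polarized
#' tyrosinated-tubulin domain
#'
#' `|Cb - Ct| / |Cc - Ct|`: the cluster-to-domain distance normalized by the
#' centroid-to-domain distance. 0 when the cluster sits on the domain
#' centre, 1 when it sits at the cell centroid.
#'
#' @param centroid,cluster,tt_cen length-2 points in µm (image frame).
#' @param eps undefined when `|centroid - tt_cen| < eps`.
#' @return list with `ratio` (NA when undefined) and `qc`.
#' @export
corrected_tt_bb <- function(centroid, cluster, tt_cen, eps = 1e-6) {
  den <- sqrt(sum((centroid - tt_cen)^2))
  if (!is.finite(den) || den < eps) {
    return(list(ratio = NA_real_, qc = "tt_at_centroid"))
  }
  list(ratio = sqrt(sum((cluster - tt_cen)^2)) / den, qc = "")
}

#' Spreading area of a cell's basal-body cluster
#'
#' Area of the convex hull of the basal-body punctum positions.
#'
#' @inheritParams cluster_center
#' @return list with `area_um2` (0 for fewer than 3 non-collinear points)
#'   and `qc`.
#' @export
cluster_area <- function(points) {
  m <- if (is.data.frame(points)) as.matrix(points[, c("x_um", "y_um")]) else
    as.matrix(points)
  a <- convex_hull_area(m)
  qc <- if (isTRUE(attr(a, "degenerate"))) "degenerate_hull" else ""
  list(area_um2 = as.numeric(a), qc = qc)
}

#' Number of basal bodies assigned to a cell
#' @inheritParams cluster_center
#' @return integer count.
#' @export
bb_count <- function(points) {
  if (is.data.frame(points)) nrow(points) else nrow(as.matrix(points))
}

#' Region-normalized intensity ratio
#'
#' Mean intensity over the numerator mask divided by the mean intensity over
#' the denominator mask -- e.g. actin at the basal-body dots area over actin
#' at the whole apical cortex, or one cilium marker normalized against
#' another.
#'
#' @param image an [image_stack()] frame or numeric matrix.
#' @param numerator_mask,denominator_mask logical matrices of the image
#'   dimensions.
#' @return list with `ratio` (NA when a mask is empty or the denominator
#'   mean is not positive) and `qc`.
#' @export
intensity_ratio <- function(image, numerator_mask, denominator_mask) {
  if (inherits(image, "image_stack")) image <- image$pixels
  stopifnot(identical(dim(image), dim(numerator_mask)),
            identical(dim(image), dim(denominator_mask)))
  if (!any(numerator_mask) || !any(denominator_mask)) {
    return(list(ratio = NA_real_, qc = "empty_mask"))
  }
  den <- mean(image[denominator_mask])
  if (!is.finite(den) || den <= 0) {
    return(list(ratio = NA_real_, qc = "zero_denominator"))
  }
  list(ratio = mean(image[numerator_mask]) / den, qc = "")
}

#' Rasterize a cell outline into a logical mask
#' @param dim image dimensions `c(ny, nx)`.
#' @param outline a [cell_outline()].
#' @param pixel_size µm per pixel.
#' @return logical matrix, TRUE inside the polygon.
#' @export
outline_mask <- function(dim, outline, pixel_size) {
  ny <- dim[1]; nx <- dim[2]
  mask <- matrix(FALSE, ny, nx)
  bbx <- range(outline$vertices[, 1]); bby <- range(outline$vertices[, 2])
  cols <- max(1, floor(bbx[1] / pixel_size) + 1):
    min(nx, ceiling(bbx[2] / pixel_size) + 1)
  rows <- max(1, floor(bby[1] / pixel_size) + 1):
    min(ny, ceiling(bby[2] / pixel_size) + 1)
  px <- rep((cols - 1) * pixel_size, each = length(rows))
  py <- rep((rows - 1) * pixel_size, times = length(cols))
  inside <- point_in_polygon(px, py, outline$vertices)
  mask[cbind(rep(rows, times = length(cols))[inside],
             rep(cols, each = length(rows))[inside])] <- TRUE
  mask
}

#' Union-of-disks mask around puncta
#'
#' The "dots area" used as the numerator region of the actin intensity
#' ratio: disks of `radius_um` around each punctum.
#'
#' @param dim image dimensions `c(ny, nx)`.
#' @param points data.frame with `x_um`, `y_um` or two-column matrix.
#' @param radius_um disk radius.
#' @param pixel_size µm per pixel.
#' @return logical matrix.
#' @export
disk_mask <- function(dim, points, radius_um, pixel_size) {
  m <- if (is.data.frame(points)) as.matrix(points[, c("x_um", "y_um")]) else
    as.matrix(points)
  ny <- dim[1]; nx <- dim[2]
  mask <- matrix(FALSE, ny, nx)
  if (nrow(m) == 0) return(mask)
  w <- ceiling(radius_um / pixel_size) + 1
  for (k in seq_len(nrow(m))) {
    ci <- round(m[k, 1] / pixel_size) + 1
    ri <- round(m[k, 2] / pixel_size) + 1
    cols <- max(1, ci - w):min(nx, ci + w)
    rows <- max(1, ri - w):min(ny, ri + w)
    dx2 <- ((cols - 1) * pixel_size - m[k, 1])^2
    dy2 <- ((rows - 1) * pixel_size - m[k, 2])^2
    mask[rows, cols] <- mask[rows, cols] | (outer(dy2, dx2, "+") <= radius_um^2)
  }
  mask
}

#' Tissue-level translational polarity
#'
#' Circular summary of the per-cell translational angles: tissue R-bar,
#' mean direction and circular SD; cells with undefined angles are excluded
#' and counted.
#'
#' @param theta numeric vector of per-cell angles in radians (NA allowed).
#' @return list with `rbar`, `mean_angle_rad`, `circ_sd_rad`, `n`,
#'   `n_excluded`.
#' @export
tissue_polarity <- function(theta) {
  ok <- is.finite(theta)
  cm <- circ_mean_resultant(theta[ok])
  list(rbar = cm$rbar, mean_angle_rad = cm$mean_angle,
       circ_sd_rad = if (is.na(cm$rbar)) NA_real_ else circ_sd(cm$rbar),
       n = cm$n, n_excluded = sum(!ok))
}

#' Full per-cell polarity table
#'
#' Runs the complete per-cell metric set over assigned basal-body and
#' basal-foot puncta: BB-BF pairing, rotational R-bar, cluster centre,
#' translational angle, directionality, count, hull area, and (when the
#' corresponding channels are supplied) the actin intensity ratio and the
#' corrected TT-BB distance.
#'
#' @param bb,bf puncta data.frames (`x_um`, `y_um`, optional `cell_id`;
#'   assigned with [assign_to_cells()] when missing).
#' @param outlines list of [cell_outline()] objects.
#' @param config an [analysis_config()].
#' @param actin optional actin-like channel ([image_stack()]) for the
#'   intensity ratio.
#' @param tt optional tyrosinated-tubulin-like channel ([image_stack()]) for
#'   the corrected TT-BB distance.
#' @return list with `cells` (one row per cell; columns `cell_id`,
#'   `n_pairs`, `rotational_rbar`, `rotational_mean_rad`,
#'   `theta_trans_rad`, `bb_directionality`, `corrected_tt_bb`, `bb_count`,
#'   `cluster_area_um2`, `phalloidin_ratio`, `qc_flags`), `tissue` (the
#'   [tissue_polarity()] summary plus exclusion counts), and `pairs` (the
#'   paired-vector table).
#' @export
polarity_table <- function(bb, bf, outlines, config = analysis_config(),
                           actin = NULL, tt = NULL) {
  if (!("cell_id" %in% names(bb))) bb <- assign_to_cells(bb, outlines)
  if (!("cell_id" %in% names(bf))) bf <- assign_to_cells(bf, outlines)
  pairs <- pair_bb_bf(bb, bf, config$pairing_max_dist_um)
  rows <- lapply(outlines, function(o) {
    id <- o$cell_id
    cp <- pairs[!is.na(pairs$cell_id) & pairs$cell_id == id, , drop = FALSE]
    cbb <- bb[!is.na(bb$cell_id) & bb$cell_id == id, , drop = FALSE]
    qc <- character(0)
    rot <- rotational_polarity(cp, config$min_pairs_per_cell)
    if (nzchar(rot$qc)) qc <- c(qc, rot$qc)
    cc <- cluster_center(cbb)
    theta <- NA_real_; direc <- NA_real_
    area <- cluster_area(cbb)
    if (nzchar(area$qc)) qc <- c(qc, area$qc)
    if (!any(is.na(cc))) {
      ta <- translational_angle(o, cc)
      theta <- ta$theta_rad
      if (nzchar(ta$qc)) qc <- c(qc, ta$qc)
      bd <- bb_directionality(o, cc)
      direc <- bd$directionality
      if (nzchar(bd$qc)) qc <- c(qc, bd$qc)
    } else {
      qc <- c(qc, "no_bb_puncta")
    }
    phall <- NA_real_
    if (!is.null(actin) && nrow(cbb) > 0) {
      dims <- dim(if (inherits(actin, "image_stack")) actin$pixels else actin)
      cmask <- outline_mask(dims, o, config$pixel_size_um)
      dmask <- disk_mask(dims, cbb, config$disk_radius_um,
                         config$pixel_size_um) & cmask
      # reference cortex = the cell outside the dots area, so the ratio is
      # a pure enrichment contrast
      ir <- intensity_ratio(actin, dmask, cmask & !dmask)
      phall <- ir$ratio
      if (nzchar(ir$qc)) qc <- c(qc, ir$qc)
    }
    ttbb <- NA_real_
    if (!is.null(tt) && !any(is.na(cc))) {
      tc <- tt_center(tt, o, pixel_size = config$pixel_size_um)
      if (nzchar(tc$qc)) {
        qc <- c(qc, tc$qc)
      } else {
        ct <- corrected_tt_bb(o$centroid, cc, tc$center)
        ttbb <- ct$ratio
        if (nzchar(ct$qc)) qc <- c(qc, ct$qc)
      }
    }
    data.frame(cell_id = id, n_pairs = rot$n_pairs,
               rotational_rbar = rot$rbar,
               rotational_mean_rad = rot$mean_angle_rad,
               theta_trans_rad = theta, bb_directionality = direc,
               corrected_tt_bb = ttbb, bb_count = nrow(cbb),
               cluster_area_um2 = area$area_um2, phalloidin_ratio = phall,
               qc_flags = paste(qc, collapse = ";"))
  })
  cells <- do.call(rbind, rows)
  tissue <- tissue_polarity(cells$theta_trans_rad)
  tissue$n_cells_excluded_min_pairs <- sum(is.na(cells$rotational_rbar))
  list(cells = cells, tissue = tissue, pairs = pairs)
}
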