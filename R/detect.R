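# Fluorescent puncta detection, assignment of puncta to cells, and pairing
# of basal-body with basal-foot puncta by the closest-dot rule.

# 1-D Gaussian kernel, radius 3 sigma, normalized.
gaussian_kernel_1d <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable convolution with replicate edge padding.
conv_separable <- function(img, k) {
  r <- (length(k) - 1) / 2
  ny <- nrow(img); nx <- ncol(img)
  pad <- img[c(rep(1, r), seq_len(ny), rep(ny, r)), , drop = FALSE]
  out <- matrix(0, ny, nx)
  for (j in seq_along(k)) out <- out + k[j] * pad[(j - 1) + seq_len(ny), , drop = FALSE]
  pad <- out[, c(rep(1, r), seq_len(nx), rep(nx, r)), drop = FALSE]
  out <- matrix(0, ny, nx)
  for (j in seq_along(k)) out <- out + k[j] * pad[, (j - 1) + seq_len(nx), drop = FALSE]
  out
}

#' Detect fluorescent puncta in a 2-D channel
#'
#' Difference-of-Gaussians blob detection at scale `sigma_um` (the classic
#' Laplacian-of-Gaussian approximation), after robust background
#' subtraction (per-image median). Candidate maxima above
#' `threshold * max(response)` are kept, non-maximum suppressed within
#' `2 * sigma`, and localized to sub-pixel precision by the
#' intensity-weighted centroid of a `(2 * ceil(2 sigma) + 1)^2` pixel window
#' of the background-subtracted image.
#'
#' @param image an [image_stack()] single frame, or a numeric matrix with
#'   `pixel_size` given.
#' @param sigma_um expected spot sigma in µm (> 0, smaller than the image).
#' @param threshold relative threshold in (0, 1] of the maximum
#'   blob response after background subtraction.
#' @param pixel_size µm per pixel (ignored when `image` is an
#'   [image_stack()]).
#' @return data.frame with `x_um`, `y_um` (sub-pixel, image frame),
#'   `peak_intensity`, `integrated_intensity`; zero rows for a blank image.
#' @export
detect_puncta <- function(image, sigma_um, threshold = 0.2, pixel_size = NULL) {
  if (inherits(image, "image_stack")) {
    pixel_size <- image$pixel_size
    image <- image$pixels
  }
  stopifnot(is.matrix(image), !is.null(pixel_size), sigma_um > 0)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  sigma_px <- sigma_um / pixel_size
  if (6 * sigma_px >= min(dim(image))) {
    stop("sigma (", sigma_um, " um = ", round(sigma_px, 1),
         " px) is too large for a ", nrow(image), " x ", ncol(image), " image")
  }
  bgsub <- image - stats::median(image)
  if (max(bgsub) <= 0) return(empty_puncta())
  g1 <- conv_separable(bgsub, gaussian_kernel_1d(sigma_px))
  g2 <- conv_separable(bgsub, gaussian_kernel_1d(1.6 * sigma_px))
  resp <- g1 - g2
  rmax <- max(resp)
  if (rmax <= 0) return(empty_puncta())
  ny <- nrow(resp); nx <- ncol(resp)
  # strict 8-neighbour local maxima (interior pixels)
  core <- resp[2:(ny - 1), 2:(nx - 1)]
  ismax <- core >= threshold * rmax
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismax <- ismax & (core >= resp[2:(ny - 1) + dy, 2:(nx - 1) + dx])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_puncta())
  cand <- data.frame(row = idx[, 1] + 1, col = idx[, 2] + 1)
  cand$resp <- resp[cbind(cand$row, cand$col)]
  cand <- cand[order(-cand$resp, cand$row, cand$col), ]
  # non-maximum suppression within 2 sigma
  r2 <- (2 * sigma_px)^2
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (k == 1) { keep[1] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    keep[k] <- all((kept$row - cand$row[k])^2 + (kept$col - cand$col[k])^2 > r2)
  }
  cand <- cand[keep, , drop = FALSE]
  # sub-pixel localization: intensity-weighted centroid in a window of the
  # background-subtracted image (negatives clamped to zero)
  w <- ceiling(2 * sigma_px)
  out <- lapply(seq_len(nrow(cand)), function(k) {
    rows <- max(1, cand$row[k] - w):min(ny, cand$row[k] + w)
    cols <- max(1, cand$col[k] - w):min(nx, cand$col[k] + w)
    patch <- pmax(bgsub[rows, cols, drop = FALSE], 0)
    s <- sum(patch)
    if (s <= 0) return(NULL)
    cy <- sum(rowSums(patch) * rows) / s
    cx <- sum(colSums(patch) * cols) / s
    data.frame(x_um = (cx - 1) * pixel_size, y_um = (cy - 1) * pixel_size,
               peak_intensity = image[cand$row[k], cand$col[k]],
               integrated_intensity = s)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_puncta() else out
}

empty_puncta <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0),
             peak_intensity = numeric(0), integrated_intensity = numeric(0))
}

#' Assign puncta to cells by point-in-polygon
#'
#' Outlines must not overlap (shared Voronoi-style edges are fine); puncta
#' outside all cells get `cell_id = NA` and are excluded downstream. A
#' punctum on a shared boundary goes to the lower `cell_id` (deterministic).
#'
#' @param puncta data.frame with `x_um`, `y_um`.
#' @param outlines list of [cell_outline()] objects.
#' @return `puncta` with a `cell_id` column (NA = unassigned).
#' @export
assign_to_cells <- function(puncta, outlines) {
  validate_no_overlap(outlines)
  ids <- vapply(outlines, function(o) o$cell_id, integer(1))
  ord <- order(ids)
  cell_id <- rep(NA_integer_, nrow(puncta))
  for (o in outlines[ord]) {
    todo <- is.na(cell_id)
    if (!any(todo)) break
    inside <- point_in_polygon(puncta$x_um[todo], puncta$y_um[todo], o$vertices)
    cell_id[which(todo)[inside]] <- o$cell_id
  }
  puncta$cell_id <- cell_id
  puncta
}

# Error if any two outlines properly overlap (interior intersection).
validate_no_overlap <- function(outlines) {
  n <- length(outlines)
  if (n < 2) return(invisible(TRUE))
  bb <- t(vapply(outlines, function(o) {
    c(min(o$vertices[, 1]), max(o$vertices[, 1]),
      min(o$vertices[, 2]), max(o$vertices[, 2]))
  }, numeric(4)))
  bad <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bb[i, 2] < bb[j, 1] || bb[j, 2] < bb[i, 1] ||
        bb[i, 4] < bb[j, 3] || bb[j, 4] < bb[i, 3]) next
    oi <- outlines[[i]]; oj <- outlines[[j]]
    tol <- 1e-7  # um; vertices on a shared boundary are not "inside"
    vin <- function(a, b) {
      ins <- point_in_polygon(a$vertices[, 1], a$vertices[, 2], b$vertices)
      db <- dist_to_boundary(a$vertices[, 1], a$vertices[, 2], b$vertices)
      any(ins & db > tol)
    }
    cross <- FALSE
    vi <- oi$vertices; vj <- oj$vertices
    ni <- nrow(vi); nj <- nrow(vj)
    for (a in seq_len(ni)) {
      a2 <- if (a == ni) 1L else a + 1L
      for (b in seq_len(nj)) {
        b2 <- if (b == nj) 1L else b + 1L
        if (segments_cross(vi[a, ], vi[a2, ], vj[b, ], vj[b2, ], tol = 1e-9)) {
          cross <- TRUE; break
        }
      }
      if (cross) break
    }
    if (cross || vin(oi, oj) || vin(oj, oi)) {
      bad <- c(bad, paste0(oi$cell_id, "/", oj$cell_id))
    }
  }
  if (length(bad) > 0) {
    stop("overlapping cell outlines: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Pair basal-body puncta with their closest basal-foot puncta
#'
#' One-to-one matching by iteratively accepting the globally smallest
#' remaining BB-BF distance within `max_dist_um` (each basal body has
#' exactly one basal foot, so a basal-foot punctum may be claimed by at most
#' one basal body; equidistant candidates go to the lower punctum index).
#' Pairing is done within each cell when `cell_id` columns are present.
#'
#' @param bb,bf data.frames with `x_um`, `y_um` (and optionally `cell_id`).
#' @param max_dist_um maximum pairing distance in µm (> 0).
#' @return data.frame with one row per pair: `cell_id`, `bb_x_um`,
#'   `bb_y_um`, `bf_x_um`, `bf_y_um`, `angle_rad` (mathematical frame,
#'   BB to BF), `length_um`, `bb_index`, `bf_index` (row indices into the
#'   inputs).
#' @export
pair_bb_bf <- function(bb, bf, max_dist_um = 1.0) {
  if (max_dist_um <= 0) stop("max_dist_um must be > 0")
  empty <- data.frame(cell_id = integer(0), bb_x_um = numeric(0),
                      bb_y_um = numeric(0), bf_x_um = numeric(0),
                      bf_y_um = numeric(0), angle_rad = numeric(0),
                      length_um = numeric(0), bb_index = integer(0),
                      bf_index = integer(0))
  if (nrow(bb) == 0 || nrow(bf) == 0) return(empty)
  has_cells <- "cell_id" %in% names(bb) && "cell_id" %in% names(bf)
  groups <- if (has_cells) {
    ids <- sort(unique(stats::na.omit(c(bb$cell_id, bf$cell_id))))
    lapply(ids, function(id) {
      list(cell_id = id, bi = which(!is.na(bb$cell_id) & bb$cell_id == id),
           fi = which(!is.na(bf$cell_id) & bf$cell_id == id))
    })
  } else {
    list(list(cell_id = NA_integer_, bi = seq_len(nrow(bb)),
              fi = seq_len(nrow(bf))))
  }
  rows <- lapply(groups, function(g) {
    if (length(g$bi) == 0 || length(g$fi) == 0) return(NULL)
    m <- greedy_match(as.matrix(bb[g$bi, c("x_um", "y_um")]),
                      as.matrix(bf[g$fi, c("x_um", "y_um")]), max_dist_um)
    if (nrow(m) == 0) return(NULL)
    bi <- g$bi[m[, 1]]; fi <- g$fi[m[, 2]]
    dx <- bf$x_um[fi] - bb$x_um[bi]; dy <- bf$y_um[fi] - bb$y_um[bi]
    data.frame(cell_id = g$cell_id,
               bb_x_um = bb$x_um[bi], bb_y_um = bb$y_um[bi],
               bf_x_um = bf$x_um[fi], bf_y_um = bf$y_um[fi],
               angle_rad = wrap_angle(atan2(-dy, dx)),
               length_um = sqrt(dx^2 + dy^2),
               bb_index = bi, bf_index = fi)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) empty else rows
}

#' Export the paired-vector table as CSV
#' @param pairs output of [pair_bb_bf()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(pairs, path) {
  out <- data.frame(cell_id = pairs$cell_id,
                    bb_x = pairs$bb_x_um, bb_y = pairs$bb_y_um,
                    bf_x = pairs$bf_x_um, bf_y = pairs$bf_y_um,
                    angle_deg = pairs$angle_rad * 180 / pi,
                    length_um = pairs$length_um)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
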