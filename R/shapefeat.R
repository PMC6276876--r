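#' Reconstruct per-cell 3D shapes from a label volume
#'
#' Computes per-slice cross-sectional areas and centroids for every cell id
#' in a z-consistent label volume (ground truth from [make_tissue()] or the
#' output of [segment_volume()]) and derives the shape features used for
#' phenotyping invagination: apico-basal length (occupied slice count times
#' dz), apical and basal cap areas, the A/B ratio (apical cap volume over
#' basal cap volume; 1 = columnar, < 1 = apically constricted wedge), and
#' volume.
#'
#' Cells whose occupied slices contain a gap of more than one slice are
#' flagged `incomplete` and should be excluded from statistics (single-slice
#' gaps are tolerated as segmentation dropouts).
#'
#' @param labels integer label array `[y, x, z]`.
#' @param pixel_size um per pixel.
#' @param dz slice spacing, um.
#' @param cap_slices slices in the apical/basal caps (default 3, i.e. 3 um
#'   at unit spacing, mirroring the apical quantification window).
#' @param cap_mode `"mean"` (cap area = mean over cap slices, robust to
#'   segmentation noise) or `"extreme"` (single end slice).
#' @return data.frame of class `cell_shapes`: `cell_id, length, apical_area,
#'   basal_area, ab_ratio, volume, n_slices, incomplete` (um-based units),
#'   with per-cell slice profiles in `attr(, "profiles")` (list of
#'   data.frames `z, area, centroid_y, centroid_x`).
#' @export
reconstruct_cells <- function(labels, pixel_size, dz, cap_slices = 3,
                              cap_mode = c("mean", "extreme")) {
  cap_mode <- match.arg(cap_mode)
  d <- dim(labels)
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) stop("label volume contains no cells")
  pa <- pixel_size^2
  profiles <- vector("list", length(ids))
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    per_z <- lapply(seq_len(d[3]), function(z) {
      idx <- which(labels[, , z] == id, arr.ind = TRUE)
      if (!nrow(idx)) return(NULL)
      data.frame(z = (z - 1) * dz, area = nrow(idx) * pa,
                 centroid_y = mean(idx[, 1]) * pixel_size,
                 centroid_x = mean(idx[, 2]) * pixel_size)
    })
    occ <- which(!vapply(per_z, is.null, TRUE))
    prof <- do.call(rbind, per_z)
    profiles[[k]] <- prof
    gaps <- if (length(occ) > 1) max(diff(occ)) - 1L else 0L
    nocc <- length(occ)
    cs <- min(cap_slices, nocc)
    api <- prof$area[seq_len(cs)]
    bas <- prof$area[seq(nocc - cs + 1L, nocc)]
    a_ap <- if (cap_mode == "mean") mean(api) else api[1]
    a_ba <- if (cap_mode == "mean") mean(bas) else bas[cs]
    rows[[k]] <- data.frame(
      cell_id = id,
      length = nocc * dz,
      apical_area = a_ap,
      basal_area = a_ba,
      ab_ratio = sum(api) / sum(bas),
      volume = sum(prof$area) * dz,
      n_slices = nocc,
      incomplete = gaps > 1L)
  }
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- stats::setNames(profiles, ids)
  class(out) <- c("cell_shapes", "data.frame")
  out
}

#' Apical/basal cap-volume ratio of one cell
#'
#' Ratio of the volume of the most apical `cap_slices` slices to that of
#' the most basal ones. A ratio of 1 indicates a columnar cell, below 1 an
#' apically constricted (conic/wedge) cell, above 1 an inverted cone.
#'
#' @param areas per-slice cross-sectional areas, apical first (um^2), or a
#'   row of [reconstruct_cells()] profiles.
#' @param cap_slices cap size in slices, default 3.
#' @return numeric ratio.
#' @export
ab_ratio <- function(areas, cap_slices = 3) {
  areas <- as.numeric(areas)
  n <- length(areas)
  if (n < 2 * cap_slices)
    stop("cell spans fewer than 2 * cap_slices slices")
  sum(areas[seq_len(cap_slices)]) / sum(areas[seq(n - cap_slices + 1L, n)])
}

#' Filter cells with outlying volumes
#'
#' Retains cells whose volume lies within `cv * mean(volume)` of the mean
#' volume (single pass: the mean is computed once over all cells). The
#' default 25 percent coefficient-of-variation band removes mis-segmented
#' cells before shape statistics.
#'
#' @param shapes a `cell_shapes` data.frame (or any data.frame with a
#'   `volume` column), or a numeric vector of volumes.
#' @param cv half-width of the acceptance band relative to the mean.
#' @return the retained subset (same type as the input); for a vector
#'   input, the retained values with attribute `retained` (logical).
#' @export
filter_volume_outliers <- function(shapes, cv = 0.25) {
  v <- if (is.data.frame(shapes)) shapes$volume else as.numeric(shapes)
  if (!length(v)) stop("no cells supplied")
  m <- mean(v)
  ok <- abs(v - m) <= cv * m
  if (is.data.frame(shapes)) {
    out <- shapes[ok, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    structure(v[ok], retained = ok)
  }
}

#' Apical shape anisotropy
#'
#' Ratio of major to minor axis length of the second-moment ellipse of the
#' apical outline: 1 for an isotropic (circular or regular-polygonal)
#' apex, 2 for a 2:1 elongated apex. Accepts either a polygon (matrix of
#' `x, y` vertices, closed implicitly) whose moments are computed in closed
#' form, or a logical pixel mask.
#'
#' @param shape `n x 2` matrix of polygon vertices (um), or a logical mask.
#' @return numeric anisotropy (>= 1).
#' @export
anisotropy <- function(shape) {
  if (is.logical(shape) || (is.matrix(shape) && all(shape %in% c(0, 1)) &&
                            nrow(shape) > 2 && ncol(shape) > 2)) {
    idx <- which(shape > 0, arr.ind = TRUE)
    if (nrow(idx) < 3) stop("degenerate region")
    cv <- stats::cov(idx)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("degenerate region")
    return(sqrt(ev[1] / ev[2]))
  }
  p <- as.matrix(shape)
  if (ncol(p) != 2 || nrow(p) < 3) stop("polygon needs >= 3 x,y vertices")
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) stop("degenerate polygon (zero area)")
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  x <- x - cx; x2 <- x2 - cx; y <- y - cy; y2 <- y2 - cy
  cr <- x * y2 - x2 * y
  ixx <- sum(cr * (y^2 + y * y2 + y2^2)) / 12
  iyy <- sum(cr * (x^2 + x * x2 + x2^2)) / 12
  ixy <- sum(cr * (x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y)) / 24
  s <- sign(a)
  m <- matrix(c(iyy, -ixy, -ixy, ixx) * s, 2, 2)  # second-moment tensor
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("degenerate polygon")
  sqrt(ev[1] / ev[2])
}
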