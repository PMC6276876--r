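#' Segmentation and tracking parameters
#'
#' Defaults reproduce the stated settings of the original analysis:
#' bandpass thresholds of 2 and 10 um, minimum cell size of 2 um, and a
#' minimum spatial and/or temporal fractional overlap of 0.4.
#'
#' @param bandpass_low,bandpass_high feature-size band of the membrane
#'   bandpass filter, um (`0 < low < high`).
#' @param min_cell_size minimum equivalent diameter of a retained region, um.
#' @param max_cell_size maximum equivalent diameter of a retained region,
#'   um; basins larger than any plausible cell (e.g. the unstructured
#'   background of a field without a membrane lattice) are treated as
#'   background.
#' @param min_overlap minimum fractional overlap for linking a region
#'   across adjacent frames or z-slices (denominator = smaller region).
#' @param h watershed merging depth: adjacent basins separated by a
#'   membrane ridge shallower than `h` (intensity units of the filtered
#'   image) are merged, suppressing spurious minima.
#' @return list of class `seg_params`.
#' @export
seg_params <- function(bandpass_low = 2, bandpass_high = 10,
                       min_cell_size = 2, min_overlap = 0.4, h = 0.05,
                       max_cell_size = 30) {
  if (!(bandpass_low > 0 && bandpass_low < bandpass_high))
    stop("need 0 < bandpass_low < bandpass_high")
  if (min_overlap <= 0 || min_overlap > 1)
    stop("'min_overlap' must be in (0, 1]")
  if (min_cell_size >= max_cell_size)
    stop("need min_cell_size < max_cell_size")
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 min_cell_size = min_cell_size, min_overlap = min_overlap,
                 h = h, max_cell_size = max_cell_size),
            class = "seg_params")
}

#' Bandpass filter a membrane image
#'
#' Difference-of-Gaussians: features smaller than `bandpass_low` or larger
#' than `bandpass_high` (um) are attenuated. The response has zero mean on
#' constant input (DC is removed by the large-scale Gaussian).
#'
#' @param image 2D numeric matrix.
#' @param pixel_size um per pixel.
#' @param params a [seg_params()].
#' @return filtered matrix, same size.
#' @export
bandpass <- function(image, pixel_size, params = seg_params()) {
  if (params$bandpass_low < pixel_size)
    stop("bandpass_low is below one pixel; increase it or the sampling")
  fw <- 2 * sqrt(2 * log(2))
  s_lo <- params$bandpass_low / fw / pixel_size
  s_hi <- params$bandpass_high / fw / pixel_size
  gblur_pad(image, max(s_lo, 0.3)) - gblur_pad(image, s_hi)
}

# Gaussian blur with edge-replicating padding so the kernel may be larger
# than the image.
gblur_pad <- function(image, sigma) {
  pad <- 2L * as.integer(ceiling(3 * sigma)) + 2L
  n <- nrow(image); m <- ncol(image)
  ri <- c(rep(1L, pad), seq_len(n), rep(n, pad))
  ci <- c(rep(1L, pad), seq_len(m), rep(m, pad))
  big <- image[ri, ci]
  out <- as.matrix(EBImage::gblur(big, sigma = sigma))
  out[pad + seq_len(n), pad + seq_len(m)]
}

#' Segment one membrane slice into cells
#'
#' Watershed of the bandpassed membrane signal: basins of the inverted
#' filtered image are the cells, with basins separated by ridges shallower
#' than `params$h` merged (the watershed tolerance plays the role of an
#' h-minima marker depth). Regions with equivalent diameter below
#' `min_cell_size` are discarded (set to 0).
#'
#' @param filtered bandpassed 2D image (output of [bandpass()]).
#' @param pixel_size um per pixel.
#' @param params a [seg_params()].
#' @return integer label matrix (0 = discarded/background).
#' @export
segment_slice <- function(filtered, pixel_size, params = seg_params()) {
  rng <- range(filtered)
  if (diff(rng) < 1e-12) {
    warning("flat image: nothing to segment")
    return(matrix(0L, nrow(filtered), ncol(filtered)))
  }
  inv <- (rng[2] - filtered) / diff(rng)   # cells bright, membranes dark
  lab <- EBImage::watershed(inv, tolerance = params$h / diff(rng), ext = 1)
  lab <- matrix(as.integer(lab), nrow(filtered), ncol(filtered))
  # size filter on equivalent diameter (regions beyond max_cell_size are
  # unstructured background, not cells)
  cnt <- tabulate(lab)
  eqd <- 2 * sqrt(cnt / pi) * pixel_size
  drop <- which(eqd < params$min_cell_size | eqd > params$max_cell_size)
  if (length(drop)) lab[lab %in% drop] <- 0L
  # relabel compactly
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Link two label images by fractional overlap
#'
#' Regions i (in `labels_a`) and j (in `labels_b`) are candidate links when
#' `|i n j| / min(|i|, |j|) >= min_overlap`; links are made one-to-one
#' greedily by decreasing overlap fraction (ties broken by lower label id).
#' The same rule is used across time and across z.
#'
#' @param labels_a,labels_b integer label matrices of equal size.
#' @param params a [seg_params()] (only `min_overlap` is used).
#' @return data.frame `a, b, overlap` (one row per link).
#' @export
link_labels <- function(labels_a, labels_b, params = seg_params()) {
  if (!all(dim(labels_a) == dim(labels_b))) stop("label images differ in size")
  sel <- labels_a > 0L & labels_b > 0L
  empty <- data.frame(a = integer(), b = integer(), overlap = numeric())
  if (!any(sel)) return(empty)
  na <- tabulate(labels_a)
  nb <- tabulate(labels_b)
  tab <- table(a = labels_a[sel], b = labels_b[sel])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  df$a <- as.integer(df$a); df$b <- as.integer(df$b)
  df$overlap <- df$Freq / pmin(na[df$a], nb[df$b])
  df <- df[df$overlap >= params$min_overlap, ]
  if (!nrow(df)) return(empty)
  df <- df[order(-df$overlap, df$a, df$b), ]
  used_a <- used_b <- integer()
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!(df$a[i] %in% used_a) && !(df$b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, df$a[i]); used_b <- c(used_b, df$b[i])
    }
  }
  out <- df[keep, c("a", "b", "overlap")]
  rownames(out) <- NULL
  out
}

#' Track labels through a sequence of label images
#'
#' Chains [link_labels()] through consecutive images (frames in time, or
#' z-slices of one volume) and assigns persistent track ids. Unlinked
#' regions start new tracks.
#'
#' @param label_list list of integer label matrices.
#' @param params a [seg_params()].
#' @return list with `tracked` (list of relabeled matrices carrying track
#'   ids) and `table` (data.frame `track_id, index, label, area_px,
#'   centroid_y, centroid_x` in pixel units).
#' @export
track_labels <- function(label_list, params = seg_params()) {
  stopifnot(length(label_list) >= 1)
  n <- length(label_list)
  maps <- vector("list", n)            # local label -> track id
  next_id <- 0L
  ids0 <- sort(unique(label_list[[1]][label_list[[1]] > 0L]))
  maps[[1]] <- stats::setNames(seq_along(ids0), ids0)
  next_id <- length(ids0)
  if (n > 1) for (f in 2:n) {
    lk <- link_labels(label_list[[f - 1]], label_list[[f]], params)
    m <- integer(0)
    ids <- sort(unique(label_list[[f]][label_list[[f]] > 0L]))
    m <- stats::setNames(integer(length(ids)), ids)
    for (j in seq_along(ids)) {
      hit <- lk$a[lk$b == ids[j]]
      if (length(hit) == 1 && as.character(hit) %in% names(maps[[f - 1]])) {
        m[j] <- maps[[f - 1]][[as.character(hit)]]
      } else {
        next_id <- next_id + 1L
        m[j] <- next_id
      }
    }
    maps[[f]] <- m
  }
  tracked <- vector("list", n)
  rows <- list()
  for (f in seq_len(n)) {
    lab <- label_list[[f]]
    out <- matrix(0L, nrow(lab), ncol(lab))
    for (nm in names(maps[[f]])) {
      sel <- lab == as.integer(nm)
      tid <- maps[[f]][[nm]]
      out[sel] <- tid
      idx <- which(sel, arr.ind = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = tid, index = f, label = as.integer(nm),
        area_px = nrow(idx),
        centroid_y = mean(idx[, 1]), centroid_x = mean(idx[, 2]))
    }
    tracked[[f]] <- out
  }
  list(tracked = tracked, table = do.call(rbind, rows))
}

#' Segment and track a membrane volume
#'
#' Convenience wrapper: bandpass + watershed per z-slice, then overlap
#' linking across z so labels are consistent through the volume. Suitable
#' input for [reconstruct_cells()].
#'
#' @param stack membrane [image_stack()].
#' @param params a [seg_params()].
#' @return integer label array `[y, x, z]` with z-consistent cell ids.
#' @export
segment_volume <- function(stack, params = seg_params()) {
  d <- dim(stack$data)
  labs <- vector("list", d[3])
  for (z in seq_len(d[3])) {
    f <- bandpass(stack$data[, , z], stack$pixel_size, params)
    labs[[z]] <- segment_slice(f, stack$pixel_size, params)
  }
  tr <- track_labels(labs, params)
  arr <- array(0L, d)
  for (z in seq_len(d[3])) arr[, , z] <- tr$tracked[[z]]
  arr
}
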