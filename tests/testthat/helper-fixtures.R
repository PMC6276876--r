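# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# A noiseless Gaussian axial profile sampled at dz spacing.
gauss_profile <- function(center, fwhm, n_slices, dz = 1, amp = 1, offset = 0) {
  z <- (seq_len(n_slices) - 1) * dz
  s <- fwhm / (2 * sqrt(2 * log(2)))
  list(z = z, y = offset + amp * exp(-(z - center)^2 / (2 * s^2)))
}

# Label volume of identical square-footprint cells on a grid, each
# occupying `n_occ` slices out of `n_slices`, with per-slice pixel counts
# given by `area_px` (recycled over slices).
label_volume_grid <- function(n_cells_x = 4, n_cells_y = 4, side_px = 20,
                              gap_px = 4, n_occ = 10, n_slices = n_occ,
                              area_side_px = side_px) {
  pitch <- side_px + gap_px
  ny <- n_cells_y * pitch; nx <- n_cells_x * pitch
  arr <- array(0L, c(ny, nx, n_slices))
  id <- 0L
  for (gy in seq_len(n_cells_y)) for (gx in seq_len(n_cells_x)) {
    id <- id + 1L
    r0 <- (gy - 1) * pitch + 1L
    c0 <- (gx - 1) * pitch + 1L
    for (z in seq_len(n_occ)) {
      s <- if (length(area_side_px) > 1) area_side_px[z] else area_side_px
      arr[r0:(r0 + s - 1L), c0:(c0 + s - 1L), z] <- id
    }
  }
  arr
}

# Match ring detections to generator truth within `tol` um; returns
# per-truth-ring matched radius error (NA if unmatched) and the count of
# unmatched detections (false positives).
match_rings <- function(det, truth, tol = 1) {
  used <- rep(FALSE, nrow(det))
  rerr <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (!nrow(det)) break
    d <- sqrt((det$x - truth$x[i])^2 + (det$y - truth$y[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      rerr[i] <- abs(det$r[j] - truth$r[i])
    }
  }
  list(radius_err = rerr, n_unmatched_det = sum(!used),
       recall = mean(!is.na(rerr)),
       precision = if (nrow(det)) sum(used) / nrow(det) else NA_real_)
}

# Jaccard index of each ground-truth cell against its best-overlapping
# segmented region.
jaccard_per_cell <- function(seg, truth) {
  ids <- sort(unique(truth[truth > 0]))
  vapply(ids, function(id) {
    tm <- truth == id
    ov <- seg[tm]; ov <- ov[ov > 0]
    if (!length(ov)) return(0)
    best <- as.integer(names(sort(table(ov), decreasing = TRUE))[1])
    sm <- seg == best
    sum(tm & sm) / sum(tm | sm)
  }, 0)
}
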