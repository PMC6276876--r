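#' Detect apical-area pulses as prominent local maxima
#'
#' Local maxima of the area trace with topographic prominence at least
#' `min_prominence`; trace endpoints are never reported as peaks. The
#' default prominence is twice a robust estimate of the measurement noise
#' (MAD of first differences divided by sqrt(2)), so pure noise wiggles are
#' rejected while genuine pulses (several um^2) are kept.
#'
#' @param area numeric trace of apical areas, um^2 (>= 3 samples).
#' @param min_prominence minimum peak prominence, um^2 (default `2 *`
#'   estimated noise SD).
#' @return integer indices of the detected peaks (increasing).
#' @export
find_pulses <- function(area, min_prominence = NULL) {
  n <- length(area)
  if (n < 3) stop("trace must have at least 3 samples")
  if (is.null(min_prominence)) {
    noise <- stats::mad(diff(area)) / sqrt(2)
    min_prominence <- 2 * noise
  }
  # local maxima (plateaus collapse to their first sample), endpoints excluded
  i <- 2:(n - 1)
  is_max <- area[i] > area[i - 1] & area[i] >= area[i + 1]
  peaks <- i[is_max]
  if (!length(peaks)) return(integer())
  prom <- vapply(peaks, function(p) {
    lhs <- if (any(area[seq_len(p - 1)] > area[p])) {
      j <- max(which(area[seq_len(p - 1)] > area[p]))
      min(area[j:p])
    } else min(area[seq_len(p)])
    rhs <- if (any(area[(p + 1):n] > area[p])) {
      j <- p + min(which(area[(p + 1):n] > area[p]))
      min(area[p:j])
    } else min(area[p:n])
    area[p] - max(lhs, rhs)
  }, 0)
  peaks[prom >= min_prominence]
}

#' Mean pulsation period
#'
#' Mean temporal distance between consecutive detected peaks.
#'
#' @param t sample times, s.
#' @param peaks peak indices from [find_pulses()].
#' @return period in s, or `NA` (with a warning) when fewer than 2 peaks
#'   were detected.
#' @export
pulse_period <- function(t, peaks) {
  if (length(peaks) < 2) {
    warning("fewer than 2 peaks: period undefined")
    return(NA_real_)
  }
  mean(diff(t[peaks]))
}

#' Ratchet extent: mean area difference between consecutive peaks
#'
#' Mean of `area[peak k] - area[peak k+1]`: positive values mean the cell
#' locks in constriction between pulses (ratchet behavior), values near 0
#' mean the cell relaxes back to its pre-pulse area (non-ratchet).
#'
#' @param area area trace, um^2.
#' @param peaks peak indices from [find_pulses()].
#' @return mean area difference per pulse, um^2, or `NA` (with a warning)
#'   when fewer than 2 peaks were detected.
#' @export
ratchet_extent <- function(area, peaks) {
  if (length(peaks) < 2) {
    warning("fewer than 2 peaks: ratchet extent undefined")
    return(NA_real_)
  }
  mean(-diff(area[peaks]))
}

#' Classify a trace as constricting or non-constricting
#'
#' A cell is `constricting` when its final apical area is strictly smaller
#' than half of its initial area, `non_constricting` otherwise (boundary
#' cases count as non-constricting). To resist single-frame noise, initial
#' and final areas are the means of the first and last `edge_samples`
#' samples.
#'
#' @param area area trace, um^2 (>= 2 samples).
#' @param edge_samples samples averaged at each end (default 2; 1 = single
#'   frame).
#' @return `"constricting"` or `"non_constricting"`.
#' @export
classify_constriction <- function(area, edge_samples = 2) {
  n <- length(area)
  if (n < 2) stop("trace must have at least 2 samples")
  k <- min(edge_samples, floor(n / 2))
  a0 <- mean(area[seq_len(k)])
  a1 <- mean(area[seq(n - k + 1L, n)])
  if (!is.finite(a0) || a0 <= 0) stop("non-positive initial area")
  if (a1 < 0.5 * a0) "constricting" else "non_constricting"
}

#' Pulse statistics for a cohort of traces
#'
#' Runs peak detection, period, ratchet extent and constriction
#' classification on every trace of a long-format table.
#'
#' @param traces data.frame `cell_id, t, area`.
#' @param min_prominence forwarded to [find_pulses()].
#' @param edge_samples forwarded to [classify_constriction()].
#' @return object of class `pulse_stats`: list with
#'   \describe{
#'     \item{cells}{data.frame `cell_id, n_peaks, period, ratchet_extent,
#'       class`}
#'     \item{intervals}{pooled inter-peak intervals, s}
#'     \item{peak_diffs}{pooled between-peak area differences
#'       (positive = constriction), um^2}
#'   }
#' @export
analyze_pulses <- function(traces, min_prominence = NULL, edge_samples = 2) {
  stopifnot(all(c("cell_id", "t", "area") %in% names(traces)))
  ids <- unique(traces$cell_id)
  rows <- vector("list", length(ids))
  intervals <- list(); peak_diffs <- list()
  for (k in seq_along(ids)) {
    tr <- traces[traces$cell_id == ids[k], ]
    tr <- tr[order(tr$t), ]
    pk <- find_pulses(tr$area, min_prominence)
    per <- ext <- NA_real_
    if (length(pk) >= 2) {
      per <- mean(diff(tr$t[pk]))
      ext <- mean(-diff(tr$area[pk]))
      intervals[[length(intervals) + 1L]] <- diff(tr$t[pk])
      peak_diffs[[length(peak_diffs) + 1L]] <- -diff(tr$area[pk])
    }
    rows[[k]] <- data.frame(cell_id = ids[k], n_peaks = length(pk),
                            period = per, ratchet_extent = ext,
                            class = classify_constriction(tr$area, edge_samples))
  }
  structure(list(cells = do.call(rbind, rows),
                 intervals = unlist(intervals),
                 peak_diffs = unlist(peak_diffs)),
            class = "pulse_stats")
}

#' @export
print.pulse_stats <- function(x, ...) {
  cc <- x$cells
  cat(sprintf("pulse_stats: %d cells, %d pooled intervals\n",
              nrow(cc), length(x$intervals)))
  cat(sprintf("  pooled mean period: %.1f s (per-cell mean: %.1f s)\n",
              mean(x$intervals), mean(cc$period, na.rm = TRUE)))
  cat(sprintf("  mean ratchet extent: %.2f um^2\n",
              mean(cc$ratchet_extent, na.rm = TRUE)))
  cat(sprintf("  constricting: %d / %d\n",
              sum(cc$class == "constricting"), nrow(cc)))
  invisible(x)
}

#' @export
plot.pulse_stats <- function(x, ...) {
  graphics::hist(x$intervals, xlab = "inter-peak interval (s)",
                 main = "pulsation intervals", ...)
  invisible(x)
}
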