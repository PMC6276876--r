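#' Axial intensity profile with fitted basal Gaussian peak
#'
#' Computes the z-profile of the mean intensity in a region of interest,
#' subdividing the ROI into a grid of subregions that are processed
#' individually and averaged (weighted by pixel count, to accommodate the
#' uneven morphology of real embryos), and fits a Gaussian with constant
#' offset around the basal-side maximum by nonlinear least squares. The
#' full width at half maximum (FWHM = 2.355 sigma) of the fit quantifies
#' axial signal spreading ("z-spread").
#'
#' The fit is initialized at the argmax of the basal half of the profile
#' with sigma = 2 slices and amplitude = max - min, and the center is
#' bounded to the basal half so an apical peak cannot capture the fit.
#'
#' @param stack myosin [image_stack()].
#' @param roi_mask logical `[y, x]` mask (default: whole field).
#' @param subgrid integer c(rows, cols) of subregions, default `c(4, 4)`.
#' @param basal_from fraction of the axial range (from the apical end)
#'   beyond which the basal peak is sought; default 0.5 (basal half).
#' @return object of class `zprofile_peak`: list with `profile`, `z` (um),
#'   `peak_z` (um), `amplitude`, `fwhm` (um), `offset`, `fit_residual`.
#' @export
zprofile <- function(stack, roi_mask = NULL, subgrid = c(4, 4),
                     basal_from = 0.5) {
  d <- dim(stack$data)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, d[1], d[2])
  if (!any(roi_mask)) stop("ROI mask is empty")
  stopifnot(all(subgrid >= 1))
  idx <- which(roi_mask, arr.ind = TRUE)
  rsub <- ceiling(subgrid[1] * (idx[, 1] - min(idx[, 1]) + 0.5) /
                    (diff(range(idx[, 1])) + 1))
  csub <- ceiling(subgrid[2] * (idx[, 2] - min(idx[, 2]) + 0.5) /
                    (diff(range(idx[, 2])) + 1))
  tile <- (rsub - 1) * subgrid[2] + csub
  lin <- (idx[, 2] - 1) * d[1] + idx[, 1]
  nz <- d[3]
  prof_tiles <- matrix(0, nz, length(unique(tile)))
  tiles <- sort(unique(tile))
  wts <- numeric(length(tiles))
  for (k in seq_along(tiles)) {
    sel <- lin[tile == tiles[k]]
    wts[k] <- length(sel)
    for (z in seq_len(nz)) prof_tiles[z, k] <- mean(stack$data[, , z][sel])
  }
  profile <- as.numeric(prof_tiles %*% (wts / sum(wts)))
  z <- z_positions(stack)
  fit_zprofile(profile, z, basal_from = basal_from)
}

#' Fit a Gaussian basal peak to an axial profile
#'
#' Lower-level entry taking a precomputed profile; see [zprofile()].
#'
#' @param profile numeric vector of mean intensities per z-slice.
#' @param z axial positions, um.
#' @inheritParams zprofile
#' @return a `zprofile_peak` object.
#' @export
fit_zprofile <- function(profile, z, basal_from = 0.5) {
  stopifnot(length(profile) == length(z), length(z) >= 4)
  if (diff(range(profile)) < 1e-12) stop("flat profile: no basal peak found")
  zmin <- min(z); zspan <- diff(range(z))
  basal <- z >= zmin + basal_from * zspan
  pb <- profile[basal]
  # require a maximum on the basal side that is not just the tail of a
  # profile decreasing away from an apical peak
  imax <- which.max(pb)
  j <- which(basal)[imax]
  if (imax == 1 && j > 1 && profile[j - 1] >= profile[j])
    stop("no basal-side peak: profile decreases toward the base")
  dz <- stats::median(diff(z))
  start <- list(a = max(profile) - min(profile),
                mu = z[basal][imax],
                sigma = 2 * dz,
                c = min(profile))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c + a * exp(-(zz - mu)^2 / (2 * sigma^2)),
      data = data.frame(zz = z, y = profile),
      start = start,
      lower = c(a = 0, mu = zmin + basal_from * zspan, sigma = dz / 4, c = -Inf),
      upper = c(a = Inf, mu = max(z), sigma = zspan, c = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("basal peak fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(profile = profile, z = z,
                 peak_z = unname(cf["mu"]),
                 amplitude = unname(cf["a"]),
                 fwhm = unname(2 * sqrt(2 * log(2)) * cf["sigma"]),
                 offset = unname(cf["c"]),
                 fit_residual = sqrt(mean(stats::residuals(fit)^2))),
            class = "zprofile_peak")
}

#' @export
print.zprofile_peak <- function(x, ...) {
  cat(sprintf("zprofile_peak: basal peak at z = %.2f um, amplitude %.3g, FWHM %.2f um (rms resid %.3g)\n",
              x$peak_z, x$amplitude, x$fwhm, x$fit_residual))
  invisible(x)
}

#' @export
plot.zprofile_peak <- function(x, ...) {
  graphics::plot(x$z, x$profile, type = "b", xlab = "z (um, apical -> basal)",
                 ylab = "mean intensity", ...)
  zz <- seq(min(x$z), max(x$z), length.out = 200)
  s <- x$fwhm / (2 * sqrt(2 * log(2)))
  graphics::lines(zz, x$offset + x$amplitude * exp(-(zz - x$peak_z)^2 / (2 * s^2)),
                  col = "red")
  graphics::abline(v = x$peak_z, lty = 2, col = "red")
  invisible(x)
}

#' Basal myosin level in a window around the fitted peak
#'
#' Mean, over `window` consecutive slices centered at the basal peak, of
#' the integrated density per area of the ROI (by default per pixel of ROI
#' footprint, i.e. the mean ROI intensity of each slice; set
#' `per_um2 = TRUE` for um^-2 units). The default 5-slice window at 1 um
#' spacing reproduces the 5 um quantification window of the original
#' protocol.
#'
#' @param stack myosin [image_stack()].
#' @param peak a `zprofile_peak` (or a numeric basal peak position in um).
#' @param roi_mask logical mask (default whole field).
#' @param window odd number of slices, default 5.
#' @param per_um2 divide by the ROI area in um^2 instead of pixels.
#' @return object of class `myosin_level`: list with `level`, `window`,
#'   `slices` (indices used), `truncated` (TRUE if the window hit the stack
#'   border and was shortened, with a warning).
#' @export
basal_level <- function(stack, peak, roi_mask = NULL, window = 5,
                        per_um2 = FALSE) {
  if (window %% 2 != 1) stop("'window' must be odd")
  peak_z <- if (inherits(peak, "zprofile_peak")) peak$peak_z else peak
  d <- dim(stack$data)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, d[1], d[2])
  zc <- round(peak_z / stack$dz) + 1L
  half <- (window - 1L) / 2L
  lo <- zc - half; hi <- zc + half
  truncated <- FALSE
  if (lo < 1L || hi > d[3]) {
    warning("level window truncated at the stack border")
    truncated <- TRUE
    lo <- max(1L, lo); hi <- min(d[3], hi)
  }
  area <- if (per_um2) sum(roi_mask) * stack$pixel_size^2 else sum(roi_mask)
  per_slice <- vapply(lo:hi, function(z) sum(stack$data[, , z][roi_mask]) / area, 0)
  structure(list(level = mean(per_slice), window = window, slices = lo:hi,
                 truncated = truncated),
            class = "myosin_level")
}

#' @export
print.myosin_level <- function(x, ...) {
  cat(sprintf("myosin_level: %.4g (window %d slices%s)\n", x$level, x$window,
              if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' Fold-change between two myosin levels
#'
#' @param level_num,level_den `myosin_level` objects or plain numbers
#'   (numerator: e.g. activated region; denominator: e.g. non-activated).
#' @return numeric ratio.
#' @export
fold_change <- function(level_num, level_den) {
  a <- if (inherits(level_num, "myosin_level")) level_num$level else level_num
  b <- if (inherits(level_den, "myosin_level")) level_den$level else level_den
  if (!is.finite(b) || b == 0) stop("denominator level must be nonzero")
  a / b
}

#' Normalized basal z-projection
#'
#' Sums `window` slices centered at the basal peak and divides by the mean
#' of the summed image over the analyzed area, so the normalized projection
#' has mean 1 there. With separate activated/non-activated peaks, pass the
#' union of both windows via two calls or a shared peak.
#'
#' @inheritParams basal_level
#' @param analyzed_mask logical mask over which the normalization mean is
#'   taken (default: `roi_mask`, or the whole field).
#' @return normalized 2D matrix.
#' @export
basal_projection <- function(stack, peak, roi_mask = NULL, window = 5,
                             analyzed_mask = NULL) {
  if (window %% 2 != 1) stop("'window' must be odd")
  peak_z <- if (inherits(peak, "zprofile_peak")) peak$peak_z else peak
  d <- dim(stack$data)
  zc <- round(peak_z / stack$dz) + 1L
  half <- (window - 1L) / 2L
  lo <- zc - half; hi <- zc + half
  if (lo < 1L || hi > d[3]) {
    warning("projection window truncated at the stack border")
    lo <- max(1L, lo); hi <- min(d[3], hi)
  }
  proj <- matrix(0, d[1], d[2])
  for (z in lo:hi) proj <- proj + stack$data[, , z]
  if (is.null(analyzed_mask)) analyzed_mask <- roi_mask
  if (is.null(analyzed_mask)) analyzed_mask <- matrix(TRUE, d[1], d[2])
  m <- mean(proj[analyzed_mask])
  if (m == 0) stop("zero mean over the analyzed area; cannot normalize")
  proj / m
}

#' Per-cell apical myosin levels, population-normalized
#'
#' For each cell, integrates the myosin intensity over `window` slices
#' centered at the apical peak (found on the population z-profile of the
#' apical half of the stack) across the cell's pixels, then divides by the
#' mean integrated density per cell of the combined population, so the
#' population mean is 1.
#'
#' @param stack myosin [image_stack()].
#' @param labels integer label matrix (apical segmentation; cells = ids).
#' @param window odd number of slices, default 3.
#' @param regions optional named list of logical masks assigning cells to
#'   regions (a cell belongs to the region containing its centroid).
#' @return data.frame `cell_id, region, integrated, level` (`level` is the
#'   normalized value, population mean 1); cells absent from the apical
#'   slices get `NA` and are flagged in the `missing` column.
#' @export
apical_levels <- function(stack, labels, window = 3, regions = NULL) {
  if (window %% 2 != 1) stop("'window' must be odd")
  d <- dim(stack$data)
  if (!all(dim(labels) == d[1:2])) stop("labels do not cover the stack field")
  # apical peak on the population profile, restricted to the apical half
  prof <- vapply(seq_len(d[3]), function(z) mean(stack$data[, , z]), 0)
  napical <- max(2L, floor(d[3] / 2))
  zc <- which.max(prof[seq_len(napical)])
  half <- (window - 1L) / 2L
  lo <- max(1L, zc - half); hi <- min(d[3], zc + half)
  proj <- matrix(0, d[1], d[2])
  for (z in lo:hi) proj <- proj + stack$data[, , z]
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) stop("no cells in the label image")
  integrated <- vapply(ids, function(id) sum(proj[labels == id]), 0)
  region <- rep(NA_character_, length(ids))
  if (!is.null(regions)) {
    for (k in seq_along(ids)) {
      idx <- which(labels == ids[k], arr.ind = TRUE)
      cy <- round(mean(idx[, 1])); cx <- round(mean(idx[, 2]))
      for (rg in names(regions)) if (regions[[rg]][cy, cx]) { region[k] <- rg; break }
    }
  }
  data.frame(cell_id = ids, region = region, integrated = integrated,
             level = integrated / mean(integrated),
             missing = integrated == 0)
}

#' Polynomial fit of a level time-course
#'
#' Ordinary least-squares polynomial of the given degree, with
#' `r_squared = 1 - SSres / SStot`. For constant data (SStot = 0) the
#' convention `r_squared = 0` is used.
#'
#' @param t time points, s.
#' @param y levels.
#' @param degree polynomial degree.
#' @return object of class `fit_result`: `degree`, `coefficients`
#'   (intercept first), `r_squared`, `fitted`.
#' @export
fit_timecourse <- function(t, y, degree = 3) {
  stopifnot(length(t) == length(y))
  if (length(unique(t)) < degree + 1)
    stop("need at least degree + 1 distinct time points")
  fit <- stats::lm(y ~ stats::poly(t, degree, raw = TRUE))
  ssres <- sum(stats::residuals(fit)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot < 1e-300) 0 else max(0, 1 - ssres / sstot)
  structure(list(degree = degree,
                 coefficients = unname(stats::coef(fit)),
                 r_squared = r2,
                 fitted = unname(stats::fitted(fit))),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: degree-%d polynomial, r^2 = %.3f\n",
              x$degree, x$r_squared))
  cat("coefficients:", signif(x$coefficients, 4), "\n")
  invisible(x)
}
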