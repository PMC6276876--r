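# Zero-mean annulus matched filter for one radius (pixels). The kernel has
# a Gaussian cross-section of SD `width_px` around radius `r_px` and is
# normalized to unit L2 norm so scores are comparable across radii.
annulus_kernel <- function(r_px, width_px = 1.5) {
  h <- ceiling(r_px + 3 * width_px)
  n <- 2L * h + 1L
  d <- sqrt(outer((-h:h)^2, (-h:h)^2, `+`))
  k <- exp(-(d - r_px)^2 / (2 * width_px^2))
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

# Local maxima of a matrix above a threshold (8-neighbourhood, strict on
# right/down to collapse plateaus).
matrix_local_maxima <- function(m, thresh) {
  n <- nrow(m); p <- ncol(m)
  ok <- m >= thresh
  pad <- function(di, dj) {
    s <- matrix(-Inf, n, p)
    si <- seq_len(n) + di; sj <- seq_len(p) + dj
    vi <- si >= 1 & si <= n; vj <- sj >= 1 & sj <= p
    s[which(vi), which(vj)] <- m[si[vi], sj[vj]]
    s
  }
  res <- ok &
    m >= pad(-1, 0) & m > pad(1, 0) &
    m >= pad(0, -1) & m > pad(0, 1) &
    m >= pad(-1, -1) & m > pad(1, 1) &
    m >= pad(-1, 1) & m > pad(1, -1)
  which(res, arr.ind = TRUE)
}

# Parabolic sub-sample refinement of a peak at index i of vector v.
parabolic_peak <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(i)
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (abs(denom) < 1e-12) return(i)
  i + 0.5 * (v[i - 1] - v[i + 1]) / denom
}

# Intensity summary on a circle of radius r_px around (cy, cx) (pixel
# coords), by bilinear interpolation at `n_angles` points. `stat = "mean"`
# for radius refinement; `stat = "q10"` (lower decile over angles) as a
# uniformity-aware ring contrast: accumulator side-lobes touch bright
# structures only on short arcs and score near zero.
ring_profile_at <- function(img, cy, cx, r_px, n_angles = 64L, stat = "mean") {
  th <- seq(0, 2 * pi, length.out = n_angles + 1L)[-1]
  ys <- cy + r_px * sin(th); xs <- cx + r_px * cos(th)
  n <- nrow(img); p <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  ok <- y0 >= 1 & y0 < n & x0 >= 1 & x0 < p
  if (!any(ok)) return(NA_real_)
  y0 <- y0[ok]; x0 <- x0[ok]
  fy <- ys[ok] - y0; fx <- xs[ok] - x0
  v <- img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1L, x0)] * fy * (1 - fx) +
    img[cbind(y0, x0 + 1L)] * (1 - fy) * fx +
    img[cbind(y0 + 1L, x0 + 1L)] * fy * fx
  if (stat == "q10") stats::quantile(v, 0.1, names = FALSE) else mean(v)
}

#' Detect actomyosin rings by circular Hough transform
#'
#' Matched filtering with zero-mean annulus kernels over a radius range
#' (one-pixel radius steps, FFT convolution), followed by non-maximum
#' suppression with minimum center distance `rmin`, and sub-pixel
#' refinement of both center (parabolic interpolation of the score
#' surface) and radius (parabolic interpolation of the radial intensity
#' profile around the detected center).
#'
#' @param image 2D intensity matrix (basal myosin projection).
#' @param pixel_size um per pixel.
#' @param rmin,rmax radius search range, um (`rmin < rmax`).
#' @param threshold accumulator peak threshold as a fraction of the maximal
#'   score (default 0.5).
#' @param max_n optional cap on the number of detections.
#' @return object of class `ring_set`: data.frame `x, y, r, score` (um,
#'   sorted by decreasing score) with attributes `pixel_size`.
#' @export
detect_rings <- function(image, pixel_size, rmin, rmax, threshold = 0.5,
                         max_n = Inf) {
  if (rmin >= rmax) stop("need rmin < rmax")
  if (rmin <= 0) stop("'rmin' must be > 0")
  empty <- structure(data.frame(x = numeric(), y = numeric(), r = numeric(),
                                score = numeric()),
                     class = c("ring_set", "data.frame"),
                     pixel_size = pixel_size)
  if (diff(range(image)) < 1e-12) return(empty)
  radii_px <- seq(rmin / pixel_size, rmax / pixel_size, by = 1)
  layers <- vector("list", length(radii_px))
  cands <- vector("list", length(radii_px))
  smax <- -Inf
  for (k in seq_along(radii_px)) {
    sc <- as.matrix(EBImage::filter2(image, annulus_kernel(radii_px[k]),
                                     boundary = "replicate"))
    layers[[k]] <- sc
    smax <- max(smax, max(sc))
    m <- matrix_local_maxima(sc, 0.25 * max(sc))
    if (nrow(m))
      cands[[k]] <- data.frame(cy = m[, 1], cx = m[, 2], k = k,
                               r_px = radii_px[k], score = sc[m])
  }
  if (smax <= 0) return(empty)
  cand <- do.call(rbind, cands)
  cand <- cand[cand$score >= threshold * smax, , drop = FALSE]
  if (is.null(cand) || !nrow(cand)) return(empty)
  cand <- cand[order(-cand$score), , drop = FALSE]
  # greedy NMS jointly in center (min distance rmin) and radius: concentric
  # rings with clearly distinct radii are both kept
  min_d2 <- (rmin / pixel_size)^2
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (sum(keep) >= max_n) break
    ki <- which(keep)
    close <- length(ki) &&
      any((cand$cy[ki] - cand$cy[i])^2 + (cand$cx[ki] - cand$cx[i])^2 < min_d2 &
            abs(cand$r_px[ki] - cand$r_px[i]) <= 1.5)
    if (!close) keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  sc <- cand$score
  rr <- cand$r_px
  # sub-pixel center via parabolic fit on the score surface of each layer
  cy <- cand$cy; cx <- cand$cx
  cyr <- as.numeric(cy); cxr <- as.numeric(cx)
  for (i in seq_along(cy)) {
    lay <- layers[[cand$k[i]]]
    if (cy[i] > 1 && cy[i] < nrow(lay))
      cyr[i] <- parabolic_peak(lay[(cy[i] - 1):(cy[i] + 1), cx[i]], 2) + cy[i] - 2
    if (cx[i] > 1 && cx[i] < ncol(lay))
      cxr[i] <- parabolic_peak(lay[cy[i], (cx[i] - 1):(cx[i] + 1)], 2) + cx[i] - 2
  }
  # sub-pixel radius via the radial intensity profile
  rstep <- 0.1
  rfine <- rr
  for (i in seq_along(rr)) {
    rg <- seq(max(rr[i] - 1.5, 0.5), rr[i] + 1.5, by = rstep)
    prof <- vapply(rg, function(r) ring_profile_at(image, cyr[i], cxr[i], r), 0)
    if (anyNA(prof)) next
    j <- which.max(prof)
    rfine[i] <- rg[1] + (parabolic_peak(prof, j) - 1) * rstep
  }
  # verification: a genuine ring is bright along its whole refined circle;
  # accumulator side-lobes (e.g. between two concentric rings) are not
  contrast <- vapply(seq_along(sc), function(i)
    ring_profile_at(image, cyr[i], cxr[i], rfine[i], stat = "q10"), 0)
  ok <- is.finite(contrast) & contrast >= threshold * max(contrast, na.rm = TRUE)
  cyr <- cyr[ok]; cxr <- cxr[ok]; rfine <- rfine[ok]; sc <- sc[ok]
  if (!length(sc)) return(empty)
  # candidates from neighbouring radius layers refine to the same circle:
  # keep the highest-scoring one; genuinely concentric rings (refined radii
  # more than one pixel apart) both survive
  keep <- rep(TRUE, length(sc))
  for (i in seq_along(sc)[-1]) {
    ki <- which(keep[seq_len(i - 1)])
    if (any((cyr[ki] - cyr[i])^2 + (cxr[ki] - cxr[i])^2 < min_d2 &
              abs(rfine[ki] - rfine[i]) <= 1))
      keep[i] <- FALSE
  }
  out <- data.frame(x = (cxr[keep] - 0.5) * pixel_size,
                    y = (cyr[keep] - 0.5) * pixel_size,
                    r = rfine[keep] * pixel_size,
                    score = sc[keep])
  structure(out, class = c("ring_set", "data.frame"), pixel_size = pixel_size)
}

#' @export
print.ring_set <- function(x, ...) {
  cat(sprintf("ring_set: %d rings%s\n", nrow(x),
              if (nrow(x)) sprintf(", radii %.2f-%.2f um", min(x$r), max(x$r)) else ""))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Detect rings in every frame of a series
#'
#' @param images list of 2D matrices (frames).
#' @inheritParams detect_rings
#' @return data.frame `frame, x, y, r, score`.
#' @export
detect_rings_series <- function(images, pixel_size, rmin, rmax,
                                threshold = 0.5, max_n = Inf) {
  out <- lapply(seq_along(images), function(f) {
    d <- detect_rings(images[[f]], pixel_size, rmin, rmax, threshold, max_n)
    if (!nrow(d)) return(NULL)
    cbind(frame = f, as.data.frame(d))
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      r = numeric(), score = numeric())
  res
}

#' Ring constriction speed from normalized diameters
#'
#' Ring diameters are normalized to the mean diameter of the first frame
#' (population anchor) and an ordinary least-squares line is fitted; its
#' slope is the constriction speed (negative = constriction), in units of
#' normalized diameter per frame (and per second if `frame_interval` is
#' given).
#'
#' In `"pooled"` mode (default) all detections of each frame enter the fit;
#' in `"tracked"` mode rings are first matched across frames by nearest
#' center within `max_disp` um and only rings tracked from frame 1
#' contribute.
#'
#' @param detections data.frame `frame, x, y, r` (e.g. from
#'   [detect_rings_series()]).
#' @param frame_interval seconds between frames (optional).
#' @param mode `"pooled"` or `"tracked"`.
#' @param max_disp maximum center displacement per frame for tracking, um.
#' @return object of class `constriction_fit`: `slope` (per frame),
#'   `slope_per_s`, `intercept`, `r_squared`, `normalized` (data.frame
#'   `frame, d_norm`).
#' @export
constriction_speed <- function(detections, frame_interval = NA_real_,
                               mode = c("pooled", "tracked"),
                               max_disp = NULL) {
  mode <- match.arg(mode)
  frames <- sort(unique(detections$frame))
  if (length(frames) < 2) stop("need detections in at least 2 frames")
  if (mode == "tracked") {
    if (is.null(max_disp)) max_disp <- min(detections$r)
    d0 <- detections[detections$frame == frames[1], ]
    d0$ring_id <- seq_len(nrow(d0))
    tracked <- d0
    prev <- d0
    for (f in frames[-1]) {
      cur <- detections[detections$frame == f, ]
      if (!nrow(cur)) break
      cur$ring_id <- NA_integer_
      for (i in order(-prev$r)) {
        dd <- sqrt((cur$x - prev$x[i])^2 + (cur$y - prev$y[i])^2)
        dd[!is.na(cur$ring_id)] <- Inf
        j <- which.min(dd)
        if (length(j) && dd[j] <= max_disp) cur$ring_id[j] <- prev$ring_id[i]
      }
      cur <- cur[!is.na(cur$ring_id), ]
      tracked <- rbind(tracked, cur)
      prev <- cur
    }
    detections <- tracked
  }
  anchor <- mean(2 * detections$r[detections$frame == frames[1]])
  if (!is.finite(anchor) || anchor == 0) stop("no rings in the first frame")
  dn <- data.frame(frame = detections$frame,
                   d_norm = 2 * detections$r / anchor)
  fit <- stats::lm(d_norm ~ I(frame - frames[1]), data = dn)
  cf <- stats::coef(fit)
  sstot <- sum((dn$d_norm - mean(dn$d_norm))^2)
  r2 <- if (sstot < 1e-300) NA_real_
        else 1 - sum(stats::residuals(fit)^2) / sstot
  structure(list(slope = unname(cf[2]),
                 slope_per_s = unname(cf[2]) / frame_interval,
                 intercept = unname(cf[1]),
                 r_squared = r2,
                 normalized = dn,
                 mode = mode),
            class = "constriction_fit")
}

#' @export
print.constriction_fit <- function(x, ...) {
  cat(sprintf("constriction_fit (%s): slope %.4g per frame%s, r^2 = %.3f\n",
              x$mode, x$slope,
              if (is.finite(x$slope_per_s)) sprintf(" (%.4g /s)", x$slope_per_s) else "",
              x$r_squared))
  invisible(x)
}

#' Ring density in a region
#'
#' Number of detected ring centers inside the mask divided by the mask
#' area, in rings per um^2.
#'
#' @param detections data.frame with `x, y` in um (one frame).
#' @param mask logical region mask.
#' @param pixel_size um per pixel of the mask.
#' @return density, um^-2.
#' @export
ring_density <- function(detections, mask, pixel_size) {
  area <- sum(mask) * pixel_size^2
  if (area <= 0) stop("region mask has zero area")
  if (!nrow(detections)) return(0)
  ci <- pmin(pmax(ceiling(detections$y / pixel_size), 1L), nrow(mask))
  cj <- pmin(pmax(ceiling(detections$x / pixel_size), 1L), ncol(mask))
  sum(mask[cbind(ci, cj)]) / area
}
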