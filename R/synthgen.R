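# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Per-cell shape program
#'
#' Time-course of the idealized cell geometry used by [make_tissue()]: at
#' each time point every cell is a generalized frustum whose cross-sectional
#' area interpolates linearly from `apical_area` (z = 0) to `basal_area`
#' (z = length).
#'
#' @param times time points in seconds.
#' @param apical_area,basal_area cross-sectional areas in um^2 (recycled).
#' @param length apico-basal cell length in um (recycled).
#' @return data.frame with columns `t`, `apical_area`, `basal_area`, `length`.
#' @export
shape_program <- function(times, apical_area, basal_area, length) {
  data.frame(t = times,
             apical_area = rep_len(apical_area, base::length(times)),
             basal_area = rep_len(basal_area, base::length(times)),
             length = rep_len(length, base::length(times)))
}

#' Configuration of a synthetic epithelial tissue
#'
#' Describes a flat rectangular sheet of cells on a square grid, the
#' rendering calibration, and the time-course of the per-cell geometry.
#' When `constant_volume = TRUE` the cross-sectional areas of the shape
#' program are rescaled at every time point so the analytic per-cell volume
#' is time-invariant (well below 0.1 percent variation), emulating the
#' incompressibility of embryonic cells.
#'
#' @param grid_shape integer c(nx, ny), cells along x and y.
#' @param cell_footprint grid pitch in um (maximum cell width).
#' @param n_slices number of z-slices rendered (>= 2).
#' @param dz axial slice spacing, um.
#' @param pixel_size lateral pixel size, um.
#' @param membrane_width rendered membrane thickness, um.
#' @param psf_sigma Gaussian PSF sigma, um (lateral).
#' @param noise_sd additive Gaussian noise SD, relative to the unit membrane
#'   amplitude.
#' @param shape_program a [shape_program()] data.frame.
#' @param constant_volume logical; enforce per-cell volume conservation.
#' @param frame_interval time between frames, s (informational; the frame
#'   times are those of the shape program).
#' @param seed integer RNG seed (generation is deterministic given the seed).
#' @return list of class `tissue_config`.
#' @export
tissue_config <- function(grid_shape = c(5, 5), cell_footprint = 8,
                          n_slices = 12, dz = 1, pixel_size = 0.2,
                          membrane_width = 0.4, psf_sigma = 0.25,
                          noise_sd = 0,
                          shape_program = furrowquant::shape_program(
                            0, cell_footprint^2, cell_footprint^2, 10),
                          constant_volume = FALSE,
                          frame_interval = NA_real_, seed = 1L) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1))
  for (v in c(cell_footprint, n_slices, dz, pixel_size, membrane_width, psf_sigma))
    if (!is.numeric(v) || v <= 0) stop("all physical dimensions must be > 0")
  if (n_slices < 2) stop("'n_slices' must be >= 2")
  if (cell_footprint / pixel_size < 2)
    stop("cell footprint smaller than 2 pixels: increase 'cell_footprint' or decrease 'pixel_size'")
  if (any(shape_program$apical_area > cell_footprint^2 + 1e-9) ||
      any(shape_program$basal_area > cell_footprint^2 + 1e-9))
    stop("shape program areas exceed the cell footprint")
  if (any(shape_program$length > n_slices * dz + 1e-9))
    stop("shape program length exceeds the rendered axial range")
  if (constant_volume) {
    pr <- shape_program
    vol <- pr$length * (pr$apical_area + pr$basal_area) / 2
    fac <- vol[1] / vol
    pr$apical_area <- pr$apical_area * fac
    pr$basal_area <- pr$basal_area * fac
    if (any(pr$apical_area > cell_footprint^2 + 1e-9) ||
        any(pr$basal_area > cell_footprint^2 + 1e-9))
      stop("constant-volume rescaling pushes areas beyond the cell footprint")
    shape_program <- pr
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 cell_footprint = cell_footprint, n_slices = as.integer(n_slices),
                 dz = dz, pixel_size = pixel_size,
                 membrane_width = membrane_width, psf_sigma = psf_sigma,
                 noise_sd = noise_sd, shape_program = shape_program,
                 constant_volume = constant_volume,
                 frame_interval = frame_interval, seed = seed),
            class = "tissue_config")
}

# Rasterize an axis-aligned square of given area (um^2) centered at (cx, cy)
# um into label image `lab`, writing `id` into unclaimed pixels. Pixels are
# selected by fractional coverage, taking the round(area/px^2) best-covered
# free pixels so the rasterized area matches the analytic area to < 1 px^2.
rasterize_square <- function(lab, cx, cy, area, pixel_size, id) {
  h <- sqrt(area) / 2
  if (h <= 0) return(lab)
  p <- pixel_size
  cols <- max(1L, floor((cx - h) / p) + 1L):min(ncol(lab), ceiling((cx + h) / p))
  rows <- max(1L, floor((cy - h) / p) + 1L):min(nrow(lab), ceiling((cy + h) / p))
  wx <- pmax(0, pmin(cols * p, cx + h) - pmax((cols - 1) * p, cx - h)) / p
  wy <- pmax(0, pmin(rows * p, cy + h) - pmax((rows - 1) * p, cy - h)) / p
  cov <- outer(wy, wx)
  free <- lab[rows, cols] == 0L
  n_target <- round(area / p^2)
  ord <- order(cov * free, decreasing = TRUE)
  take <- ord[seq_len(min(n_target, sum(free & cov > 0)))]
  sub <- lab[rows, cols]
  sub[take] <- id
  lab[rows, cols] <- sub
  lab
}

# Boundary mask of a label image: pixels with a 4-neighbour of another value.
label_boundaries <- function(lab) {
  b <- matrix(FALSE, nrow(lab), ncol(lab))
  n <- nrow(lab); m <- ncol(lab)
  b[-1, ] <- b[-1, ] | (lab[-1, ] != lab[-n, ]) & lab[-1, ] > 0
  b[-n, ] <- b[-n, ] | (lab[-n, ] != lab[-1, ]) & lab[-n, ] > 0
  b[, -1] <- b[, -1] | (lab[, -1] != lab[, -m]) & lab[, -1] > 0
  b[, -m] <- b[, -m] | (lab[, -m] != lab[, -1]) & lab[, -m] > 0
  b
}

#' Generate a synthetic membrane tissue with ground truth
#'
#' Renders, for every time point of the shape program, a ground-truth label
#' volume of frustum-shaped cells on a square grid and the corresponding
#' membrane-channel image stack (cell boundaries, dilated to the configured
#' membrane width, blurred with a Gaussian PSF, plus additive Gaussian
#' noise). All geometry is also reported analytically in a truth table.
#'
#' @param cfg a [tissue_config()].
#' @return list with elements
#'   \describe{
#'     \item{membrane}{list over time of membrane [image_stack()]s}
#'     \item{labels}{list over time of integer label arrays `[y, x, z]`
#'       (0 = background; cell ids stable across z and t)}
#'     \item{truth}{data.frame `cell_id, t, frame, apical_area, basal_area,
#'       length, volume, ab_ratio, x, y` (analytic, physical units)}
#'     \item{cfg}{the configuration}
#'   }
#' @export
make_tissue <- function(cfg) {
  stopifnot(inherits(cfg, "tissue_config"))
  with_seed(cfg$seed, {
    nx <- cfg$grid_shape[1]; ny <- cfg$grid_shape[2]
    fp <- cfg$cell_footprint; p <- cfg$pixel_size
    npx <- round(nx * fp / p); npy <- round(ny * fp / p)
    centers <- expand.grid(gx = seq_len(nx), gy = seq_len(ny))
    centers$cell_id <- seq_len(nrow(centers))
    centers$cx <- (centers$gx - 0.5) * fp
    centers$cy <- (centers$gy - 0.5) * fp
    pr <- cfg$shape_program
    mw_px <- max(1L, round(cfg$membrane_width / p))
    brush <- if (mw_px > 2) EBImage::makeBrush(mw_px + (mw_px %% 2 == 0), "disc") else NULL

    labels <- vector("list", nrow(pr))
    membrane <- vector("list", nrow(pr))
    truth <- vector("list", nrow(pr))
    v_ref <- NA_real_
    for (f in seq_len(nrow(pr))) {
      Aa <- pr$apical_area[f]; Ab <- pr$basal_area[f]; L <- pr$length[f]
      nocc <- max(2L, round(L / cfg$dz))
      areas <- Aa + (Ab - Aa) * (seq_len(nocc) - 1) / (nocc - 1)
      if (cfg$constant_volume) {
        # correct the dz-rounding of the slice count so the discretized
        # volume is exactly time-invariant, not just the continuous one
        if (f == 1) v_ref <- sum(areas) * cfg$dz
        fac <- v_ref / (sum(areas) * cfg$dz)
        areas <- areas * fac
        Aa <- areas[1]; Ab <- areas[nocc]
      }
      lab3 <- array(0L, c(npy, npx, cfg$n_slices))
      mem3 <- array(0, c(npy, npx, cfg$n_slices))
      for (z in seq_len(cfg$n_slices)) {
        if (z > nocc) break
        lab <- matrix(0L, npy, npx)
        for (i in seq_len(nrow(centers)))
          lab <- rasterize_square(lab, centers$cx[i], centers$cy[i],
                                  areas[z], p, centers$cell_id[i])
        lab3[, , z] <- lab
        bmask <- label_boundaries(lab)
        mem <- matrix(as.numeric(bmask), npy, npx)
        if (!is.null(brush)) mem <- as.matrix(EBImage::dilate(mem, brush))
        mem <- as.matrix(EBImage::gblur(mem, sigma = max(cfg$psf_sigma / p, 0.3)))
        mem3[, , z] <- mem
      }
      if (cfg$noise_sd > 0)
        mem3 <- mem3 + array(stats::rnorm(length(mem3), 0, cfg$noise_sd), dim(mem3))
      labels[[f]] <- lab3
      membrane[[f]] <- image_stack(mem3, pixel_size = p, dz = cfg$dz,
                                   channel = "membrane", t = pr$t[f])
      truth[[f]] <- data.frame(
        cell_id = centers$cell_id, t = pr$t[f], frame = f,
        apical_area = Aa, basal_area = Ab, length = nocc * cfg$dz,
        volume = sum(areas) * cfg$dz,
        ab_ratio = Aa / Ab, x = centers$cx, y = centers$cy)
    }
    list(membrane = membrane, labels = labels,
         truth = do.call(rbind, truth), cfg = cfg)
  })
}

#' Amplitude time-courses for the myosin generator
#'
#' `amp_decay(fold, duration)` decays exponentially so the amplitude at
#' `t = duration` is `1/fold` of the initial value (the progressive loss of
#' basal myosin-II during invagination; ~5-fold in mesoderm, ~3-fold in
#' ectoderm). `amp_saturating(fold, t_sat, tau)` rises with saturation,
#' reaching exactly `fold` times the initial value at `t = t_sat`
#' (optogenetic recruitment, ~1.6-fold in 6 min). `amp_constant(a)` is flat.
#'
#' @param fold fold-change (> 0).
#' @param duration,t_sat time at which the fold-change is attained, s.
#' @param tau saturation time constant, s.
#' @param a constant amplitude.
#' @return function of time (s) returning the amplitude multiplier.
#' @name amplitude-courses
NULL

#' @rdname amplitude-courses
#' @export
amp_decay <- function(fold, duration) {
  stopifnot(fold > 0, duration > 0)
  function(t) fold^(-t / duration)
}

#' @rdname amplitude-courses
#' @export
amp_saturating <- function(fold, t_sat, tau = t_sat / 3) {
  stopifnot(fold > 0, t_sat > 0, tau > 0)
  function(t) 1 + (fold - 1) * (1 - exp(-t / tau)) / (1 - exp(-t_sat / tau))
}

#' @rdname amplitude-courses
#' @export
amp_constant <- function(a = 1) function(t) rep(a, length(t))

#' Configuration of synthetic myosin-II volumes
#'
#' The myosin channel is modeled as a basal intensity layer with a Gaussian
#' axial profile (configurable FWHM) riding on a constant background, plus
#' an optional apical layer. Per-region amplitude time-courses (e.g. an
#' activated region with saturating recruitment next to a non-activated
#' control region) are supplied as functions of time.
#'
#' @param basal_amplitude named list of per-region amplitude functions of
#'   time (see [amp_decay()] and friends), or a single function applied to
#'   the whole field.
#' @param basal_fwhm axial FWHM of the basal layer, um.
#' @param apical_amplitude as `basal_amplitude`, for the apical layer
#'   (default: none).
#' @param background constant background intensity.
#' @param noise_sd additive Gaussian noise SD (intensity units; the initial
#'   basal amplitude is 1).
#' @return list of class `myosin_config`.
#' @export
myosin_config <- function(basal_amplitude = amp_constant(1), basal_fwhm = 3,
                          apical_amplitude = NULL, background = 0.05,
                          noise_sd = 0) {
  if (is.function(basal_amplitude)) basal_amplitude <- list(all = basal_amplitude)
  if (is.function(apical_amplitude)) apical_amplitude <- list(all = apical_amplitude)
  if (basal_fwhm <= 0) stop("'basal_fwhm' must be > 0")
  if (background < 0 || noise_sd < 0) stop("amplitudes must be >= 0")
  structure(list(basal_amplitude = basal_amplitude, basal_fwhm = basal_fwhm,
                 apical_amplitude = apical_amplitude, background = background,
                 noise_sd = noise_sd),
            class = "myosin_config")
}

#' Generate synthetic myosin-II image stacks over a tissue
#'
#' For each time point of the tissue, renders a myosin stack whose axial
#' profile is `background + amplitude(t) * exp(-(z - z_basal)^2 / 2 sigma^2)`
#' within each region, with `sigma = basal_fwhm / 2.355` and `z_basal` the
#' cell length at that time. Region masks partition the field laterally;
#' the default splits it into an activated left half (`"AR"`) and
#' non-activated right half (`"NR"`).
#'
#' @param tissue output of [make_tissue()], or `NULL` to render a
#'   free-standing field (then `field_px`, `n_slices`, `pixel_size`, `dz`,
#'   `times` and `basal_z` must be given).
#' @param cfg a [myosin_config()].
#' @param region_masks named list of logical `[y, x]` masks; defaults to
#'   AR/NR halves. Names must match the names of the amplitude lists (a
#'   single unnamed amplitude function applies everywhere).
#' @param field_px,n_slices,pixel_size,dz,times,basal_z field geometry used
#'   when `tissue` is `NULL`: image size `c(ny, nx)` px, slice count,
#'   calibration, frame times (s) and basal peak position (um; recycled
#'   over time).
#' @param seed RNG seed for the noise (NULL = current stream).
#' @return list with `stacks` (list over time of myosin [image_stack()]s),
#'   `region_masks`, and `truth` (data.frame `t, frame, region, amplitude,
#'   basal_z, fwhm`).
#' @export
make_myosin <- function(tissue = NULL, cfg = myosin_config(),
                        region_masks = NULL,
                        field_px = c(64, 64), n_slices = 40, pixel_size = 0.2,
                        dz = 1, times = 0, basal_z = 30, seed = NULL) {
  if (!is.null(tissue)) {
    d <- dim(tissue$labels[[1]])
    field_px <- d[1:2]; n_slices <- d[3]
    pixel_size <- tissue$cfg$pixel_size; dz <- tissue$cfg$dz
    times <- tissue$cfg$shape_program$t
    basal_z <- vapply(seq_along(times), function(f)
      max(tissue$truth$length[tissue$truth$frame == f]), 0)
  }
  basal_z <- rep_len(basal_z, length(times))
  if (is.null(region_masks)) {
    m <- matrix(TRUE, field_px[1], field_px[2])
    left <- col(m) <= ncol(m) / 2
    region_masks <- list(AR = left, NR = !left)
  }
  for (msk in region_masks)
    if (!any(msk)) stop("region mask covers no pixels")
  amp_for <- function(lst, region) {
    if (is.null(lst)) return(NULL)
    lst[[region]] %||% lst[["all"]]
  }
  sigma <- cfg$basal_fwhm / (2 * sqrt(2 * log(2)))
  zpos <- (seq_len(n_slices) - 1) * dz
  with_seed(seed, {
    stacks <- vector("list", length(times))
    truth <- NULL
    for (f in seq_along(times)) {
      arr <- array(cfg$background, c(field_px[1], field_px[2], n_slices))
      for (rg in names(region_masks)) {
        bfun <- amp_for(cfg$basal_amplitude, rg)
        afun <- amp_for(cfg$apical_amplitude, rg)
        prof <- numeric(n_slices)
        bamp <- if (is.null(bfun)) 0 else bfun(times[f])
        if (!is.null(bfun))
          prof <- prof + bamp * exp(-(zpos - basal_z[f])^2 / (2 * sigma^2))
        if (!is.null(afun))
          prof <- prof + afun(times[f]) * exp(-zpos^2 / (2 * sigma^2))
        msk <- region_masks[[rg]]
        for (z in seq_len(n_slices))
          arr[, , z][msk] <- arr[, , z][msk] + prof[z]
        truth <- rbind(truth, data.frame(
          t = times[f], frame = f, region = rg, amplitude = bamp,
          basal_z = basal_z[f], fwhm = cfg$basal_fwhm))
      }
      if (cfg$noise_sd > 0)
        arr <- arr + array(stats::rnorm(length(arr), 0, cfg$noise_sd), dim(arr))
      stacks[[f]] <- image_stack(arr, pixel_size = pixel_size, dz = dz,
                                 channel = "myosin", t = times[f])
    }
    list(stacks = stacks, region_masks = region_masks, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration of a synthetic actomyosin ring field
#'
#' Rings (bright circles, as seen in basal projections of the
#' cellularization front) are placed on a jittered square grid. Ring
#' diameters change linearly over frames (`radius0 * (1 + slope * frame)`,
#' frames counted from 0), emulating ring constriction; coordinates inside
#' a designated region are contracted isotropically so the areal ring
#' density there increases by `compaction_factor`, emulating lateral tissue
#' compaction in the photo-activated area.
#'
#' @param n_rings number of rings.
#' @param radius0 initial ring radius, um.
#' @param slope fractional diameter change per frame (constriction < 0).
#' @param n_frames number of frames.
#' @param compaction_factor areal density increase inside the region (1 =
#'   none); applied at every frame.
#' @param region_fraction fraction of the field width (left side) forming
#'   the compacted region.
#' @param spacing grid pitch, um (default `3 * radius0`).
#' @param jitter_sd SD of the Gaussian jitter on grid positions, um.
#' @param pixel_size um per pixel.
#' @param ring_width Gaussian cross-section SD of the rendered ring line, um.
#' @param noise_sd additive Gaussian noise SD relative to ring amplitude 1.
#' @param max_overlap maximum tolerated fraction of ring pairs closer than
#'   one ring diameter before generation aborts.
#' @param seed RNG seed.
#' @return list of class `ring_field_config`.
#' @export
ring_field_config <- function(n_rings = 64, radius0 = 3, slope = -0.01,
                              n_frames = 5, compaction_factor = 1,
                              region_fraction = 0.5, spacing = 3 * radius0,
                              jitter_sd = 0.3, pixel_size = 0.2,
                              ring_width = 0.25, noise_sd = 0,
                              max_overlap = 0.05, seed = 1L) {
  if (radius0 <= 0) stop("'radius0' must be > 0")
  if (n_rings < 0) stop("'n_rings' must be >= 0")
  if (compaction_factor < 1) stop("'compaction_factor' must be >= 1")
  if (spacing <= 2 * radius0 / sqrt(compaction_factor) * 0.9)
    warning("grid spacing close to ring diameter after compaction; rings may overlap")
  structure(as.list(environment()), class = "ring_field_config")
}

#' Generate a synthetic actomyosin ring field
#'
#' @param cfg a [ring_field_config()].
#' @return list with
#'   \describe{
#'     \item{images}{list over frames of intensity matrices `[y, x]`}
#'     \item{truth}{data.frame `frame, ring_id, x, y, r, inside` (um; frame
#'       counted from 1, radii follow `radius0 * (1 + slope * (frame - 1))`)}
#'     \item{inside_mask,outside_mask}{logical masks of the compacted region
#'       extent and of the untouched region, for density measurements}
#'     \item{pixel_size}{calibration}
#'     \item{n_clipped}{number of rings partly outside the field}
#'   }
#' @export
make_ring_field <- function(cfg) {
  stopifnot(inherits(cfg, "ring_field_config"))
  with_seed(cfg$seed, {
    p <- cfg$pixel_size
    ngrid <- ceiling(sqrt(max(cfg$n_rings, 1)))
    extent <- ngrid * cfg$spacing + 2 * cfg$radius0
    npx <- round(extent / p)
    if (cfg$n_rings == 0) {
      img <- matrix(0, npx, npx)
      if (cfg$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
      return(list(images = rep(list(img), cfg$n_frames),
                  truth = data.frame(frame = integer(), ring_id = integer(),
                                     x = numeric(), y = numeric(),
                                     r = numeric(), inside = logical()),
                  inside_mask = matrix(FALSE, npx, npx),
                  outside_mask = matrix(TRUE, npx, npx),
                  pixel_size = p, n_clipped = 0L))
    }
    g <- expand.grid(gx = seq_len(ngrid), gy = seq_len(ngrid))
    g <- g[seq_len(cfg$n_rings), , drop = FALSE]
    x <- cfg$radius0 + (g$gx - 0.5) * cfg$spacing + stats::rnorm(cfg$n_rings, 0, cfg$jitter_sd)
    y <- cfg$radius0 + (g$gy - 0.5) * cfg$spacing + stats::rnorm(cfg$n_rings, 0, cfg$jitter_sd)
    # compacted region: left region_fraction of the field; contraction about
    # its center by 1/sqrt(factor) multiplies the areal density by `factor`
    xlim <- extent * cfg$region_fraction
    inside <- x < xlim
    s <- 1 / sqrt(cfg$compaction_factor)
    rcx <- xlim / 2; rcy <- extent / 2
    x[inside] <- rcx + (x[inside] - rcx) * s
    y[inside] <- rcy + (y[inside] - rcy) * s

    if (cfg$n_rings > 1) {
      dmin <- as.matrix(stats::dist(cbind(x, y)))
      diag(dmin) <- Inf
      frac_overlap <- mean(apply(dmin, 1, min) < 2 * cfg$radius0)
      if (frac_overlap > cfg$max_overlap)
        stop(sprintf("%.0f%% of rings overlap (> max_overlap)", 100 * frac_overlap))
    }

    radii <- cfg$radius0 * (1 + cfg$slope * (seq_len(cfg$n_frames) - 1))
    if (any(radii <= 0)) stop("slope drives ring radius to <= 0 within n_frames")
    sw <- cfg$ring_width
    n_clipped <- sum(x - radii[1] < 0 | x + radii[1] > extent |
                     y - radii[1] < 0 | y + radii[1] > extent)
    if (n_clipped > 0) warning(n_clipped, " rings clipped at the field border")

    images <- vector("list", cfg$n_frames)
    truth <- NULL
    for (f in seq_len(cfg$n_frames)) {
      img <- matrix(0, npx, npx)
      r <- radii[f]
      w_px <- ceiling((r + 4 * sw) / p)
      for (i in seq_len(cfg$n_rings)) {
        ci <- round(y[i] / p); cj <- round(x[i] / p)
        rows <- max(1L, ci - w_px):min(npx, ci + w_px)
        cols <- max(1L, cj - w_px):min(npx, cj + w_px)
        dy <- (rows - 0.5) * p - y[i]
        dx <- (cols - 0.5) * p - x[i]
        d <- sqrt(outer(dy^2, dx^2, `+`))
        img[rows, cols] <- img[rows, cols] + exp(-(d - r)^2 / (2 * sw^2))
      }
      if (cfg$noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
      images[[f]] <- img
      truth <- rbind(truth, data.frame(frame = f, ring_id = seq_len(cfg$n_rings),
                                       x = x, y = y, r = r, inside = inside))
    }
    # compacted extent: the image of the original region under the
    # contraction, so its area is exactly 1/factor of the region area
    zz <- matrix(0, npx, npx)
    pxc <- (col(zz) - 0.5) * p
    pyc <- (row(zz) - 0.5) * p
    inside_mask <- pxc > rcx * (1 - s) & pxc < rcx + (xlim - rcx) * s &
      pyc > rcy * (1 - s) & pyc < rcy + (extent - rcy) * s
    outside_mask <- pxc > xlim
    list(images = images, truth = truth, inside_mask = inside_mask,
         outside_mask = outside_mask, pixel_size = p, n_clipped = n_clipped)
  })
}

#' Configuration of synthetic apical-area pulse traces
#'
#' Apical cell areas oscillate with a configurable period. Within each
#' cycle the area falls by the pulse amplitude along a half-sine
#' (constriction phase) and then relaxes along a half-sine back up, either
#' fully (non-ratchet: the cell returns to its pre-pulse area) or only
#' partially, locking in `ratchet_lockin` um^2 per pulse (ratchet
#' constriction). Ratcheting cells stop pulsing once their area reaches
#' `floor_frac * baseline_area` (a fully constricted cell).
#'
#' @param n_traces number of traces (cells).
#' @param class_mix named fractions of `c(non_ratchet, ratchet)`, summing to 1.
#' @param baseline_area initial apical area, um^2.
#' @param period mean pulsation period, s.
#' @param period_jitter_sd SD of the per-cycle period, s.
#' @param pulse_amplitude peak-to-trough pulse depth, um^2.
#' @param ratchet_lockin area locked in per pulse for ratchet traces, um^2
#'   (must not exceed `pulse_amplitude`).
#' @param sampling_interval s (must be < period).
#' @param duration trace length, s (must cover >= 2 periods).
#' @param noise_sd additive measurement noise SD, um^2.
#' @param floor_frac minimum area as a fraction of baseline.
#' @param seed RNG seed.
#' @return list of class `pulse_config`.
#' @export
pulse_config <- function(n_traces = 100,
                         class_mix = c(non_ratchet = 0.85, ratchet = 0.15),
                         baseline_area = 40, period = 90, period_jitter_sd = 5,
                         pulse_amplitude = 10, ratchet_lockin = 6,
                         sampling_interval = 35, duration = 900,
                         noise_sd = 0.5, floor_frac = 0.1, seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("'class_mix' fractions must sum to 1")
  if (!all(names(class_mix) %in% c("non_ratchet", "ratchet")))
    stop("'class_mix' names must be 'non_ratchet' and 'ratchet'")
  if (sampling_interval >= period) stop("'sampling_interval' must be < period")
  if (duration < 2 * period) stop("'duration' must cover at least 2 periods")
  has_ratchet <- !is.na(class_mix["ratchet"]) && class_mix[["ratchet"]] > 0
  if (has_ratchet && ratchet_lockin > pulse_amplitude)
    stop("'ratchet_lockin' cannot exceed 'pulse_amplitude'")
  structure(as.list(environment()), class = "pulse_config")
}

#' Generate synthetic apical-area pulse traces
#'
#' @param cfg a [pulse_config()].
#' @return list with
#'   \describe{
#'     \item{traces}{long data.frame `cell_id, t, area`}
#'     \item{truth}{data.frame `cell_id, class, lockin`}
#'     \item{peaks}{data.frame `cell_id, peak_time, peak_area` of the true
#'       (noiseless) pulse onsets}
#'   }
#' @export
make_pulse_traces <- function(cfg) {
  stopifnot(inherits(cfg, "pulse_config"))
  with_seed(cfg$seed, {
    times <- seq(0, cfg$duration, by = cfg$sampling_interval)
    classes <- sample(names(cfg$class_mix), cfg$n_traces, replace = TRUE,
                      prob = cfg$class_mix)
    floor_area <- cfg$floor_frac * cfg$baseline_area
    traces <- vector("list", cfg$n_traces)
    peaks <- vector("list", cfg$n_traces)
    for (i in seq_len(cfg$n_traces)) {
      lockin <- if (classes[i] == "ratchet") cfg$ratchet_lockin else 0
      # cycle boundaries (pulse onsets = local area maxima of the truth)
      ptimes <- 0
      while (ptimes[length(ptimes)] < cfg$duration) {
        ptimes <- c(ptimes, ptimes[length(ptimes)] +
                      max(cfg$sampling_interval,
                          stats::rnorm(1, cfg$period, cfg$period_jitter_sd)))
      }
      levels <- pmax(floor_area, cfg$baseline_area - lockin * (seq_along(ptimes) - 1))
      area <- numeric(length(times))
      for (k in seq_len(length(ptimes) - 1)) {
        sel <- times >= ptimes[k] & times < ptimes[k + 1]
        if (!any(sel)) next
        lv <- levels[k]
        if (lv <= floor_area + 1e-12) { area[sel] <- floor_area; next }
        amp <- min(cfg$pulse_amplitude, lv - floor_area)
        drop <- lv - levels[k + 1]
        phase <- (times[sel] - ptimes[k]) / (ptimes[k + 1] - ptimes[k])
        a <- ifelse(phase <= 0.5,
                    lv - amp * sin(pi * phase),
                    lv - amp + (amp - drop) * sin(pi * (phase - 0.5)))
        area[sel] <- a
      }
      sel_end <- times >= ptimes[length(ptimes)]
      if (any(sel_end)) area[sel_end] <- levels[length(levels)]
      if (cfg$noise_sd > 0)
        area <- area + stats::rnorm(length(area), 0, cfg$noise_sd)
      traces[[i]] <- data.frame(cell_id = i, t = times, area = area)
      active <- levels > floor_area + 1e-12
      peaks[[i]] <- data.frame(cell_id = i,
                               peak_time = ptimes[active],
                               peak_area = levels[active])
    }
    list(traces = do.call(rbind, traces),
         truth = data.frame(cell_id = seq_len(cfg$n_traces), class = classes,
                            lockin = ifelse(classes == "ratchet",
                                            cfg$ratchet_lockin, 0)),
         peaks = do.call(rbind, peaks))
  })
}
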