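test_that("bandpass removes DC and peaks at the center of a band-sized ridge", {
  expect_true(all(abs(bandpass(matrix(5, 40, 40), 0.5)) < 1e-6))

  # 4 um ridge in a 2-10 um band: response maximal at the ridge center.
  # Oracle: direct 1D convolution with both Gaussian kernels (the image is
  # constant along rows, so the 2D DoG reduces to 1D).
  px <- 0.5
  n <- 120
  img <- matrix(0, 60, n)
  ridge <- 57:64   # 4 um wide, centered between cols 60 and 61
  img[, ridge] <- 1
  resp <- bandpass(img, px)
  mid <- resp[30, ]
  expect_true(which.max(mid) %in% 60:61)

  fw <- 2 * sqrt(2 * log(2))
  g <- function(s) { x <- -40:40; k <- exp(-x^2 / (2 * s^2)); k / sum(k) }
  prof <- as.numeric(img[30, ])
  conv1 <- function(k) {
    padded <- c(rep(prof[1], 40), prof, rep(prof[n], 40))
    vapply(seq_len(n), function(i) sum(padded[i:(i + 80)] * rev(k)), 0)
  }
  oracle <- conv1(g(2 / fw / px)) - conv1(g(10 / fw / px))
  expect_true(which.max(oracle) %in% 60:61)
  expect_gt(stats::cor(mid, oracle), 0.98)
})

test_that("degenerate bandpass limits are rejected", {
  expect_error(seg_params(bandpass_low = 10, bandpass_high = 2), "low")
  expect_error(bandpass(matrix(0, 5, 5), pixel_size = 5), "below one pixel")
})

test_that("watershed segmentation recovers a noiseless membrane grid", {
  tc <- tissue_config(grid_shape = c(5, 5), cell_footprint = 10, n_slices = 3,
                      dz = 1, pixel_size = 0.15, noise_sd = 0,
                      shape_program = shape_program(0, 100, 100, 3), seed = 3)
  ts <- make_tissue(tc)
  mem <- ts$membrane[[1]]$data[, , 1]
  f <- bandpass(mem, 0.15)
  seg <- segment_slice(f, 0.15)
  expect_equal(length(setdiff(unique(as.integer(seg)), 0L)), 25)
  jac <- jaccard_per_cell(seg, ts$labels[[1]][, , 1])
  expect_true(all(jac >= 0.9))
  # determinism
  expect_identical(seg, segment_slice(f, 0.15))
  # mean per-cell area error below 5%
  areas <- tabulate(seg)[tabulate(seg) > 0]
  expect_lt(mean(abs(areas * 0.15^2 - 100) / 100), 0.05)
})

test_that("a lone sub-threshold speck yields no cell regions", {
  img <- matrix(0, 250, 250)       # 50 x 50 um at 0.2 um/px
  img[124:128, 124:128] <- 1       # ~1 um speck
  f <- bandpass(img, 0.2)
  seg <- segment_slice(f, 0.2)
  expect_equal(max(seg), 0)
})

test_that("flat images segment to zero labels with a warning", {
  expect_warning(seg <- segment_slice(matrix(1, 30, 30), 0.2), "flat")
  expect_true(all(seg == 0))
})

test_that("overlap linking is thresholded, one-to-one, and symmetric", {
  a <- matrix(0L, 20, 40)
  a[5:14, 5:14] <- 1L; a[5:14, 25:34] <- 2L
  # identity
  lk <- link_labels(a, a)
  expect_equal(lk$a, lk$b)
  expect_true(all(lk$overlap == 1))
  # shift region 1 so the overlap fraction is 0.3 (30 of 100 px): no link
  b <- matrix(0L, 20, 40)
  b[5:14, 12:21] <- 1L            # columns 12:14 overlap region 1 -> 30 px
  lk2 <- link_labels(a, b)
  expect_false(any(lk2$a == 1 & lk2$b == 1))
  # at 0.4 the link appears
  b3 <- matrix(0L, 20, 40)
  b3[5:14, 11:20] <- 1L           # 40 px overlap
  lk3 <- link_labels(a, b3)
  expect_true(any(lk3$a == 1 & lk3$b == 1))
  # symmetry: the same pairs in both directions
  swap <- link_labels(b3, a)
  expect_equal(lk3[order(lk3$a), c("a", "b")],
               stats::setNames(swap[order(swap$b), c("b", "a")], c("a", "b")),
               ignore_attr = TRUE)
})

test_that("tracking preserves identity through a 1 px/frame drift", {
  base <- matrix(0L, 30, 60)
  base[8:17, 8:17] <- 1L; base[8:17, 30:39] <- 2L; base[20:29, 18:27] <- 3L
  shift <- function(m, dx) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[, (1 + dx):ncol(m)] <- m[, 1:(ncol(m) - dx)]
    out
  }
  frames <- list(base, shift(base, 1), shift(base, 2))
  tr <- track_labels(frames)
  tab <- tr$table
  # every original label keeps one track id across all 3 frames
  for (lab in 1:3) {
    tid <- unique(tab$track_id[tab$label == lab])
    expect_length(tid, 1)
    expect_equal(sum(tab$track_id == tid), 3)
  }
})

test_that("labels partition the foreground: no pixel carries two labels", {
  # trivially true for a single matrix; check the z-consistent volume path
  tc <- tissue_config(grid_shape = c(3, 3), cell_footprint = 10, n_slices = 4,
                      dz = 1, pixel_size = 0.2, noise_sd = 0,
                      shape_program = shape_program(0, 100, 100, 4), seed = 8)
  ts <- make_tissue(tc)
  vol <- suppressWarnings(segment_volume(ts$membrane[[1]]))
  expect_true(all(vol >= 0))
  expect_equal(length(unique(vol[, , 1][vol[, , 1] > 0])), 9)
  # ids consistent across z: every cell present in all 4 slices
  ids <- sort(unique(vol[vol > 0]))
  for (id in ids)
    expect_equal(sum(apply(vol == id, 3, any)), 4)
})
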