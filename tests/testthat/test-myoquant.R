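test_that("a noiseless Gaussian profile is fitted exactly", {
  gp <- gauss_profile(center = 30, fwhm = 4, n_slices = 45, dz = 1,
                      amp = 2, offset = 0.3)
  pk <- fit_zprofile(gp$y, gp$z)
  expect_equal(pk$peak_z, 30, tolerance = 1e-3)
  expect_equal(pk$fwhm, 4, tolerance = 0.05)
  expect_equal(pk$offset, 0.3, tolerance = 1e-3)
})

test_that("zprofile averages subregions and finds the basal peak of a stack", {
  myo <- make_myosin(NULL, myosin_config(basal_amplitude = amp_constant(1.5),
                                         basal_fwhm = 3, background = 0.1,
                                         noise_sd = 0),
                     field_px = c(32, 32), n_slices = 41, dz = 1,
                     times = 0, basal_z = 30)
  pk <- zprofile(myo$stacks[[1]], subgrid = c(4, 4))
  expect_equal(pk$peak_z, 30, tolerance = 0.05)
  expect_equal(pk$fwhm, 3, tolerance = 0.05)
})

test_that("the basal-side peak is returned even when the apical peak is larger", {
  z <- 0:40
  y <- 3 * exp(-(z - 2)^2 / 8) + 1 * exp(-(z - 32)^2 / 8) + 0.1
  pk <- fit_zprofile(y, z)
  # oracle: grid search restricted to the basal half
  grid <- expand.grid(mu = seq(20, 40, by = 0.1), sigma = seq(0.5, 6, by = 0.1))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    g <- exp(-(z - grid$mu[i])^2 / (2 * grid$sigma[i]^2))
    f <- stats::lm.fit(cbind(1, g), y)
    sum(f$residuals[z >= 20]^2)
  }, 0)
  best <- grid[which.min(sse), ]
  expect_equal(pk$peak_z, best$mu, tolerance = 0.2)
  expect_lt(abs(pk$peak_z - 32), 0.2)
})

test_that("flat and basal-decreasing profiles raise peak-not-found errors", {
  expect_error(fit_zprofile(rep(1, 20), 0:19), "flat")
  expect_error(fit_zprofile(exp(-(0:19)^2 / 4) + 0.1, 0:19), "basal")
})

test_that("Gaussian fit matches a dense grid-search oracle within 1% over FWHM 2-8 um", {
  for (fwhm in c(2, 3.5, 5, 8)) {
    gp <- gauss_profile(center = 28, fwhm = fwhm, n_slices = 41, dz = 1,
                        amp = 1, offset = 0.2)
    pk <- fit_zprofile(gp$y, gp$z)
    # oracle: dense grid-search least squares
    grid <- expand.grid(mu = seq(26, 30, by = 0.02),
                        sigma = seq(0.5, 4.5, by = 0.02))
    sse <- vapply(seq_len(nrow(grid)), function(i) {
      g <- exp(-(gp$z - grid$mu[i])^2 / (2 * grid$sigma[i]^2))
      sum(stats::lm.fit(cbind(1, g), gp$y)$residuals^2)
    }, 0)
    best <- grid[which.min(sse), ]
    expect_equal(pk$peak_z, best$mu, tolerance = 0.01 * best$mu)
    expect_equal(pk$fwhm, 2 * sqrt(2 * log(2)) * best$sigma,
                 tolerance = 0.01 * fwhm)
  }
})

test_that("basal level equals the windowed mean integrated density per area", {
  arr <- array(10, c(8, 8, 9))
  st <- image_stack(arr, pixel_size = 1, dz = 1, channel = "myosin")
  lv <- basal_level(st, peak = 4, window = 5)
  expect_equal(lv$level, 10)
  lv3 <- basal_level(st, peak = 4, window = 3)
  expect_equal(lv3$level, 10)

  arr2 <- array(0, c(4, 4, 9))
  arr2[, , 5] <- 5
  st2 <- image_stack(arr2, pixel_size = 1, dz = 1, channel = "myosin")
  expect_equal(basal_level(st2, peak = 4, window = 5)$level, 1)

  expect_error(basal_level(st, peak = 4, window = 4), "odd")
  expect_warning(basal_level(st, peak = 0, window = 5), "truncated")
})

test_that("doubling the basal amplitude doubles the recovered level", {
  mk <- function(amp) make_myosin(NULL, myosin_config(
    basal_amplitude = amp_constant(amp), basal_fwhm = 3, background = 0,
    noise_sd = 0), field_px = c(16, 16), n_slices = 31, dz = 1,
    times = 0, basal_z = 22)$stacks[[1]]
  s1 <- mk(1); s2 <- mk(2)
  pk1 <- zprofile(s1); pk2 <- zprofile(s2)
  r <- basal_level(s2, pk2)$level / basal_level(s1, pk1)$level
  # oracle: direct summation on the noiseless volumes
  direct <- sum(s2$data[, , 21:25]) / sum(s1$data[, , 21:25])
  expect_equal(r, direct, tolerance = 1e-6)
  expect_equal(r, 2, tolerance = 1e-6)
})

test_that("fold_change is a plain ratio with a guarded denominator", {
  expect_equal(fold_change(3.2, 2.0), 1.6)
  expect_equal(fold_change(7, 7), 1)
  expect_error(fold_change(1, 0), "nonzero")
})

test_that("saturating recruitment is recovered as ~1.6-fold through the level pipeline", {
  times <- seq(0, 380, by = 95)
  myo <- make_myosin(NULL, myosin_config(
    basal_amplitude = list(AR = amp_saturating(1.6, t_sat = 380),
                           NR = amp_constant(1)),
    basal_fwhm = 3, background = 0.05, noise_sd = 0.1),
    field_px = c(48, 96), n_slices = 41, dz = 1, times = times,
    basal_z = 30, seed = 11)
  lvl <- function(f, rg) {
    pk <- zprofile(myo$stacks[[f]], myo$region_masks[[rg]])
    basal_level(myo$stacks[[f]], pk, myo$region_masks[[rg]])$level
  }
  nf <- length(times)
  fold <- (lvl(nf, "AR") / lvl(1, "AR")) / (lvl(nf, "NR") / lvl(1, "NR"))
  expect_equal(fold, 1.6, tolerance = 0.1 / 1.6)
})

test_that("basal projections are normalized to unit mean over the analyzed area", {
  myo <- make_myosin(NULL, myosin_config(basal_amplitude = amp_constant(1),
                                         basal_fwhm = 3, background = 0.05,
                                         noise_sd = 0.05),
                     field_px = c(24, 24), n_slices = 31, dz = 1, times = 0,
                     basal_z = 22, seed = 2)
  pk <- zprofile(myo$stacks[[1]])
  proj <- basal_projection(myo$stacks[[1]], pk)
  expect_equal(mean(proj), 1, tolerance = 1e-12)

  ones <- image_stack(array(1, c(6, 6, 7)), 1, 1, channel = "myosin")
  p1 <- basal_projection(ones, peak = 3, window = 5)
  expect_true(all(abs(p1 - 1) < 1e-12))
})

test_that("apical levels are population-normalized with mean 1", {
  labels <- matrix(0L, 10, 20)
  labels[3:8, 3:8] <- 1L; labels[3:8, 13:18] <- 2L
  arr <- array(0, c(10, 20, 6))
  arr[, , 1:3] <- 1   # uniform apical signal
  st <- image_stack(arr, 1, 1, channel = "myosin")
  lev <- apical_levels(st, labels, window = 3)
  expect_equal(lev$level, c(1, 1))

  # cells with 2:1 true apical amounts -> normalized 4/3 and 2/3
  arr2 <- array(0, c(10, 20, 6))
  arr2[3:8, 3:8, 1:3] <- 2
  arr2[3:8, 13:18, 1:3] <- 1
  st2 <- image_stack(arr2, 1, 1, channel = "myosin")
  lev2 <- apical_levels(st2, labels, window = 3)
  expect_equal(sort(lev2$level), c(2 / 3, 4 / 3))
})

test_that("equal AR/NR apical signal is non-significant in at least 90% of runs", {
  # t-test size under the null, on the normalized per-cell levels
  labels <- matrix(0L, 12, 24)
  id <- 0L
  for (gy in 0:1) for (gx in 0:3) {
    id <- id + 1L
    labels[(gy * 6 + 2):(gy * 6 + 5), (gx * 6 + 2):(gx * 6 + 5)] <- id
  }
  regions <- list(AR = col(labels) <= 12, NR = col(labels) > 12)
  set.seed(42)
  nonsig <- 0L
  for (rep in 1:100) {
    arr <- array(stats::rnorm(12 * 24 * 4, mean = 1, sd = 0.2), c(12, 24, 4))
    st <- image_stack(arr, 1, 1, channel = "myosin")
    lev <- apical_levels(st, labels, window = 3, regions = regions)
    tt <- ttest2(lev$level[lev$region == "AR"], lev$level[lev$region == "NR"])
    if (tt$p_value > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 90)
})

test_that("z-spread estimates stay below 4 um for sub-threshold basal layers", {
  n_ok <- 0L
  for (s in 1:20) {
    myo <- make_myosin(NULL, myosin_config(basal_amplitude = amp_constant(1),
                                           basal_fwhm = 3.4, background = 0.05,
                                           noise_sd = 0.05),
                       field_px = c(16, 16), n_slices = 41, dz = 1,
                       times = 0, basal_z = 30, seed = 100 + s)
    pk <- zprofile(myo$stacks[[1]])
    if (pk$fwhm <= 4) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 19)
})

test_that("polynomial time-course fits report r-squared with the documented conventions", {
  t <- 0:8
  y <- 1 + 2 * t - 0.3 * t^2
  expect_equal(fit_timecourse(t, y, degree = 2)$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit_timecourse(t, rep(2, 9), degree = 1)$r_squared, 0)
  expect_error(fit_timecourse(rep(1, 5), rnorm(5), degree = 2), "distinct")
  # noiseless 5-fold exponential decay, 10 samples, cubic fit
  td <- seq(0, 600, length.out = 10)
  yd <- 5^(-td / 600)
  expect_gte(fit_timecourse(td, yd, degree = 3)$r_squared, 0.95)
})
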