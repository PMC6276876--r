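test_that("constant-volume tissues conserve per-cell truth volume during elongation", {
  # cells elongate 25 -> 40 um while apical/basal areas shrink to compensate
  pr <- shape_program(times = c(0, 300, 600),
                      apical_area = 60, basal_area = 60,
                      length = c(25, 32, 40))
  tc <- tissue_config(grid_shape = c(2, 2), cell_footprint = 8, n_slices = 40,
                      dz = 1, pixel_size = 0.25, noise_sd = 0,
                      shape_program = pr, constant_volume = TRUE, seed = 1)
  ts <- make_tissue(tc)
  cv <- tapply(ts$truth$volume, ts$truth$cell_id,
               function(v) stats::sd(v) / mean(v))
  expect_true(all(cv < 1e-3))
  expect_equal(sort(unique(ts$truth$length)), c(25, 32, 40))
})

test_that("cylinder shape programs give truth A/B ratio 1 for all cells", {
  tc <- tissue_config(grid_shape = c(3, 3), cell_footprint = 6, n_slices = 8,
                      dz = 1, pixel_size = 0.25,
                      shape_program = shape_program(0, 30, 30, 8), seed = 1)
  ts <- make_tissue(tc)
  expect_true(all(ts$truth$ab_ratio == 1))
})

test_that("tissue generation is deterministic given the seed", {
  tc <- tissue_config(grid_shape = c(2, 2), cell_footprint = 5, n_slices = 4,
                      dz = 1, pixel_size = 0.25, noise_sd = 0.1,
                      shape_program = shape_program(0, 20, 20, 4), seed = 99)
  a <- make_tissue(tc)
  b <- make_tissue(tc)
  expect_identical(a$membrane[[1]]$data, b$membrane[[1]]$data)
  expect_identical(a$labels, b$labels)
})

test_that("measuring truth labels reproduces truth-table volumes within 2%", {
  pr <- shape_program(0, apical_area = 20, basal_area = 55, length = 10)
  tc <- tissue_config(grid_shape = c(3, 3), cell_footprint = 8, n_slices = 12,
                      dz = 1, pixel_size = 0.2, shape_program = pr, seed = 2)
  ts <- make_tissue(tc)
  sh <- reconstruct_cells(ts$labels[[1]], 0.2, 1)
  rel <- abs(sh$volume - ts$truth$volume[match(sh$cell_id, ts$truth$cell_id)]) /
    ts$truth$volume[match(sh$cell_id, ts$truth$cell_id)]
  expect_true(all(rel < 0.02))
})

test_that("sub-footprint cell footprints are rejected", {
  expect_error(tissue_config(cell_footprint = 0.3, pixel_size = 0.2),
               "2 pixels")
  expect_error(tissue_config(n_slices = 1), "n_slices")
})

test_that("myosin decay and saturating recruitment follow the configured folds", {
  # 5-fold decay: last/first basal amplitude = 0.2 by construction
  dec <- amp_decay(fold = 5, duration = 600)
  expect_equal(dec(600) / dec(0), 0.2)
  # ~1.6-fold saturating rise at 6 min
  sat <- amp_saturating(fold = 1.6, t_sat = 360)
  expect_equal(sat(360) / sat(0), 1.6)
  # rendered noiseless stacks carry the fold in their basal amplitudes
  myo <- make_myosin(NULL, myosin_config(
    basal_amplitude = list(all = dec), basal_fwhm = 3, background = 0,
    noise_sd = 0), field_px = c(8, 8), n_slices = 20, dz = 1,
    times = c(0, 600), basal_z = 12)
  peak0 <- max(myo$stacks[[1]]$data)
  peak1 <- max(myo$stacks[[2]]$data)
  expect_equal(peak1 / peak0, 0.2, tolerance = 1e-6)
})

test_that("rendered basal layer has the configured axial FWHM (half-max oracle)", {
  # oracle: dense axial rendering (dz = 0.02 um) and direct half-maximum
  # crossing, independent of any Gaussian fitting
  myo <- make_myosin(NULL, myosin_config(basal_amplitude = amp_constant(1),
                                         basal_fwhm = 3.4, background = 0,
                                         noise_sd = 0),
                     field_px = c(4, 4), n_slices = 601, dz = 0.02,
                     times = 0, basal_z = 6)
  prof <- vapply(seq_len(601), function(z) mean(myo$stacks[[1]]$data[, , z]), 0)
  zz <- (seq_len(601) - 1) * 0.02
  half <- max(prof) / 2
  above <- range(zz[prof >= half])
  expect_equal(diff(above), 3.4, tolerance = 0.1)
})

test_that("myosin generation rejects empty region masks", {
  expect_error(make_myosin(NULL, myosin_config(),
                           region_masks = list(AR = matrix(FALSE, 4, 4)),
                           field_px = c(4, 4)),
               "no pixels")
})

test_that("ring-field truth follows the configured linear constriction", {
  cfg <- ring_field_config(n_rings = 9, radius0 = 3, slope = -0.01,
                           n_frames = 5, pixel_size = 0.25, seed = 1)
  rf <- make_ring_field(cfg)
  r_by_frame <- tapply(rf$truth$r, rf$truth$frame, unique)
  expect_equal(unname(r_by_frame[["5"]]) / unname(r_by_frame[["1"]]), 0.96)
})

test_that("compaction raises truth ring density inside the region by the areal factor", {
  cfg <- ring_field_config(n_rings = 100, radius0 = 3, slope = 0, n_frames = 1,
                           compaction_factor = 1.35, jitter_sd = 0.2,
                           pixel_size = 0.25, seed = 3)
  rf <- make_ring_field(cfg)
  tr <- rf$truth
  p2 <- cfg$pixel_size^2
  dens_in <- sum(tr$inside) / (sum(rf$inside_mask) * p2)
  dens_out <- sum(!tr$inside) / (sum(rf$outside_mask) * p2)
  expect_equal(dens_in / dens_out, 1.35, tolerance = 0.03)
})

test_that("an empty ring field yields empty truth and a blank image", {
  cfg <- ring_field_config(n_rings = 0, radius0 = 3, n_frames = 2,
                           pixel_size = 0.5, seed = 1)
  rf <- make_ring_field(cfg)
  expect_equal(nrow(rf$truth), 0)
  expect_true(all(rf$images[[1]] == 0))
})

test_that("noiseless non-ratchet traces return to baseline at every true peak", {
  cfg <- pulse_config(n_traces = 5, class_mix = c(non_ratchet = 1, ratchet = 0),
                      baseline_area = 40, noise_sd = 0, period_jitter_sd = 0,
                      sampling_interval = 30, period = 90, duration = 450,
                      seed = 1)
  pt <- make_pulse_traces(cfg)
  expect_true(all(pt$peaks$peak_area == 40))
  # sampled areas at the true peak times equal baseline (times align on the
  # sampling grid when jitter is 0 and period is a multiple of the interval)
  tr1 <- pt$traces[pt$traces$cell_id == 1, ]
  at_peaks <- tr1$area[tr1$t %in% pt$peaks$peak_time[pt$peaks$cell_id == 1]]
  expect_true(all(abs(at_peaks - 40) < 1e-9))
})

test_that("ratchet lock-in lowers successive true peak areas by the configured step", {
  cfg <- pulse_config(n_traces = 3, class_mix = c(non_ratchet = 0, ratchet = 1),
                      ratchet_lockin = 6, pulse_amplitude = 10, noise_sd = 0,
                      duration = 400, seed = 2)
  pt <- make_pulse_traces(cfg)
  pk1 <- pt$peaks$peak_area[pt$peaks$cell_id == 1]
  expect_true(all(abs(diff(pk1) + 6) < 1e-9))
})

test_that("realized class counts of a 85/15 mixture fall in the binomial 99% interval", {
  cfg <- pulse_config(n_traces = 407,
                      class_mix = c(non_ratchet = 0.85, ratchet = 0.15),
                      seed = 7)
  pt <- make_pulse_traces(cfg)
  n_nr <- sum(pt$truth$class == "non_ratchet")
  ci <- stats::qbinom(c(0.005, 0.995), 407, 0.85)   # oracle: binomial quantiles
  expect_gte(n_nr, ci[1])
  expect_lte(n_nr, ci[2])
})

test_that("pulse generation rejects impossible sampling configurations", {
  expect_error(pulse_config(duration = 100, period = 90), "2 periods")
  expect_error(pulse_config(sampling_interval = 95, period = 90), "sampling_interval")
  expect_error(pulse_config(class_mix = c(non_ratchet = 0.5, ratchet = 0.2)),
               "sum to 1")
})
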