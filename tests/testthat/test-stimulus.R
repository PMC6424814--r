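test_that("trajectory steps are quantized, reproducible, and have the expected statistics", {
  tr <- generate_trajectory(seed = 1, n_frames = 30000)
  expect_equal(dim(tr$steps), c(30000L, 2L))
  expect_true(all(tr$steps %% 7.5 == 0))
  expect_identical(tr$steps, generate_trajectory(1, 30000)$steps)
  expect_false(identical(tr$steps,
                         generate_trajectory(2, 30000)$steps))

  # rounding inflates the per-component SD to sqrt(sigma^2 + q^2/12)
  sd_eff <- sqrt(22.5^2 + 7.5^2 / 12)
  sds <- apply(tr$steps, 2, sd)
  expect_true(all(sds > 22.5 & sds < 22.5 * 1.05))
  expect_equal(mean(sds), sd_eff, tolerance = 0.02)

  # x and y streams are independent draws
  expect_lt(abs(cor(tr$steps[, 1], tr$steps[, 2])), 3 / sqrt(30000))
})

test_that("mean 1-s displacement matches the analytic Rayleigh oracle", {
  tr <- generate_trajectory(seed = 3, n_frames = 60000)
  # 2D Gaussian random walk: E|disp| over n steps = sigma_eff sqrt(n pi / 2)
  oracle <- sqrt(22.5^2 + 7.5^2 / 12) * sqrt(30) * sqrt(pi / 2)
  expect_equal(mean_window_displacement(tr), oracle, tolerance = 0.02)
  # empty trajectory edge case
  expect_equal(mean_window_displacement(generate_trajectory(1, 0)), 0)
  expect_error(generate_trajectory(1, 10, step_sd = -1), "positive")
})

test_that("flipping preserves step magnitudes and negates both components", {
  tr <- generate_trajectory(4, 500)
  fl <- flip_trajectory(tr)
  expect_identical(abs(fl$steps), abs(tr$steps))
  expect_identical(fl$steps, -tr$steps)
})

test_that("smoothed texture is clipped, mean-accurate, and deterministic", {
  tex <- generate_smoothed_texture(1, extent = c(3000, 3000))
  expect_true(all(tex$luminance >= 0 & tex$luminance <= 1))
  # x1.5 contrast scaling drives the extremes into clipping
  expect_true(min(tex$luminance) == 0 || max(tex$luminance) == 1)
  expect_lt(abs(tex$mean - 0.5), 0.01)  # within 2% of the target mean
  expect_identical(tex$luminance, generate_smoothed_texture(1, c(3000, 3000))$luminance)
  # zero-contrast limit
  flat <- generate_smoothed_texture(1, c(600, 600), contrast_scale = 0)
  expect_true(all(flat$luminance == 0.5))
  expect_error(generate_smoothed_texture(1, extent = c(10, 10)), "square")
})

test_that("pink texture has a 1/f amplitude spectrum matched to the standard texture", {
  ref <- generate_smoothed_texture(2, c(3000, 3000))
  pk <- generate_pink_texture(2, c(3000, 3000))
  expect_equal(amplitude_spectrum_slope(pk), -1, tolerance = 0.1)
  expect_lt(abs(pk$mean - ref$mean) / ref$mean, 0.02)
  expect_lt(abs(pk$sd - ref$sd) / ref$sd, 0.02)
  expect_identical(pk$luminance, generate_pink_texture(2, c(3000, 3000))$luminance)
})

test_that("rendered movies translate the texture per the cumulative trajectory", {
  tex <- generate_smoothed_texture(5, c(1500, 1500))
  zero <- structure(list(steps = matrix(0, 3, 2), step_sd = 22.5,
                         quantum = 7.5, n_frames = 3L, seed = 0L),
                    class = "motion_trajectory")
  mv <- render_moving_texture(tex, zero, window = c(300, 300))
  expect_equal(dim(mv), c(4, 40, 40))
  for (t in 2:4) expect_identical(mv[t, , ], mv[1, , ])

  one <- zero; one$steps <- matrix(c(7.5, 0, 0, 0, 0, 0), 3, 2)
  mv1 <- render_moving_texture(tex, one, window = c(300, 300))
  # +x step shifts the window content one pixel: pixel p shows texture p - d
  expect_identical(mv1[2, , 2:40], mv1[1, , 1:39])

  tr <- generate_trajectory(6, 50)
  m_fl <- render_moving_texture(tex, flip_trajectory(tr), window = c(300, 300))
  fl2 <- tr; fl2$steps <- -tr$steps
  expect_identical(m_fl, render_moving_texture(tex, fl2, window = c(300, 300)))

  big <- zero; big$steps <- matrix(c(7500, 0, 0, 0, 0, 0), 3, 2)
  expect_error(render_moving_texture(tex, big, window = c(300, 300)),
               "frame")
})

test_that("probe stimuli honor their protocols", {
  cb <- generate_probe_stimuli("checkerboard",
                               params = list(n_frames = 2000), seed = 1)
  expect_equal(dim(cb$frames), c(2000, 60, 80))
  expect_equal(mean(cb$frames), 0.5, tolerance = 0.01)

  g <- generate_probe_stimuli("grating")
  expect_equal(g$directions, seq(0, 315, by = 45))
  expect_equal(g$total_duration, 8 * 5 * (6.67 + 1.67))
  expect_equal(nrow(g$schedule), 40)

  fk <- generate_probe_stimuli("flicker", params = list(n_frames = 5000),
                               seed = 2)
  expect_equal(sd(fk$luminance), 0.3 * 0.5, tolerance = 0.05)

  om <- generate_probe_stimuli("omsi_patches", seed = 3)
  coh <- om$segments[[which(om$schedule$mode == "coherent")[1]]]$steps
  dif <- om$segments[[which(om$schedule$mode == "differential")[1]]]$steps
  expect_equal(cor(coh[, 1], coh[, 2]), 1)
  expect_lt(abs(cor(dif[, 1], dif[, 2])), 0.15)
  expect_true(all(abs(coh) == 15))

  expect_error(generate_probe_stimuli("bars"), "unknown")
})

test_that("trajectory and spike files round-trip", {
  tr <- generate_trajectory(7, 200)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  expect_equal(unname(read_trajectory(f)$steps), unname(tr$steps))

  cell <- model_cell(preferred_direction = 0,
                     nonlinearity_kind = "exponential")
  sts <- simulate_motion_ln_cell(cell, generate_trajectory(8, 900),
                                 seed = 9, times = TRUE)
  fs <- withr::local_tempfile(fileext = ".csv")
  write_spikes(sts, fs)
  df <- read_spikes(fs)
  expect_identical(bin_spike_times(df$spike_time_s, 900),
                   as.integer(get_counts(sts)[, 1]))
  # unsorted input is sorted with a warning
  df2 <- df[rev(seq_len(nrow(df))), ]
  fs2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, fs2, row.names = FALSE, quote = FALSE)
  expect_warning(out <- read_spikes(fs2), "sort")
  expect_false(is.unsorted(out$spike_time_s))
})
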