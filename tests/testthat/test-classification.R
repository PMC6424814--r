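test_that("DSI follows the vector-sum formula", {
  # all spikes in one direction
  t1 <- compute_dsi(c(20, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(t1$dsi, 1)
  expect_equal(t1$preferred_angle, 0)
  # uniform tuning
  expect_equal(compute_dsi(rep(7, 8))$dsi, 0)
  # hand-evaluated complex sum: 10 at 0 deg + 10 at 90 deg
  t2 <- compute_dsi(c(10, 0, 10, 0, 0, 0, 0, 0))
  expect_equal(t2$dsi, sqrt(2) / 2)
  expect_equal(t2$preferred_angle, 45)
  # invariance under uniform count scaling
  cnt <- c(3, 9, 25, 12, 4, 1, 0, 2)
  expect_equal(compute_dsi(cnt)$dsi, compute_dsi(5 * cnt)$dsi)
  # mirror-symmetric tuning about 90 deg points at 90 deg
  sym <- c(1, 4, 9, 4, 1, 0, 0, 0)
  expect_equal(compute_dsi(sym)$preferred_angle, 90)
  expect_error(compute_dsi(rep(0, 8)), "undefined")
})

test_that("grating counts exclude the onset second of each presentation", {
  g <- generate_probe_stimuli("grating", params = list(repeats = 1))
  n <- round(g$total_duration * 30)
  counts <- integer(n)
  tt <- (seq_len(n) - 1) / 30
  # spikes only in the onset second of direction 0: excluded entirely
  counts[tt < 1] <- 3L
  # steady spikes for direction 90 after its onset second
  r90 <- g$schedule[g$schedule$direction == 90, ]
  counts[tt >= r90$t_on + 1 & tt < r90$t_off] <- 1L
  out <- grating_direction_counts(counts, g$schedule)
  expect_equal(unname(out[["0"]]), 0)
  expect_equal(unname(out[["90"]]), sum(tt >= r90$t_on + 1 & tt < r90$t_off))
})

test_that("OMSI follows its definition", {
  expect_equal(compute_omsi(10, 10), 0)
  expect_equal(compute_omsi(10, 30), 0.5)
  expect_equal(compute_omsi(0, 5), 1)
  expect_error(compute_omsi(0, 0), "undefined")
})

test_that("receptive fields are recovered from checkerboard noise", {
  cb <- generate_probe_stimuli("checkerboard",
                               params = list(n_x = 16, n_y = 16,
                                             n_frames = 12000), seed = 6)
  mov <- cb$frames * 1.0
  attr(mov, "pitch_um") <- 75; attr(mov, "dt_s") <- 1 / 30
  sts <- simulate_texture_cell(mov, rf_center = c(150, -75), rf_sd = 100,
                               preferred_direction = 0, seed = 7,
                               params = list(w_ds = 0))
  rf <- estimate_receptive_field(cb, get_counts(sts)[, 1])
  expect_false(rf$excluded)
  expect_true(rf$reliable)
  expect_equal(rf$polarity, -1)  # OFF cell
  expect_lt(sqrt(sum((rf$center - c(150, -75))^2)), 75)  # within one square
  expect_equal(mean(rf$sds), 100, tolerance = 0.35)

  # spikes independent of the stimulus: no reliable fit
  null_counts <- with(list(), {set.seed(8); rpois(12000, 0.05)})
  rf0 <- estimate_receptive_field(cb, null_counts)
  expect_true(rf0$excluded || !rf0$reliable)

  # two fits at known centers 300 um apart
  sts2 <- simulate_texture_cell(mov, rf_center = c(-150, -75), rf_sd = 100,
                                preferred_direction = 0, seed = 9,
                                params = list(w_ds = 0))
  rf2 <- estimate_receptive_field(cb, get_counts(sts2)[, 1])
  expect_equal(rf_distance(rf, rf2), 300, tolerance = 0.25)

  # sub-threshold rate is excluded before fitting
  low <- integer(12000); low[c(100, 5000)] <- 1L
  expect_true(estimate_receptive_field(cb, low)$excluded)
})

test_that("contrast indices have the documented sign conventions", {
  # pure OFF STA: all-negative last 200 ms
  sta <- c(rnorm(18, 0, 1e-4), rep(-0.05, 6))
  ci <- contrast_indices(flicker_sta = sta)
  expect_equal(ci$flicker_onoff, -1)
  expect_true(ci$flicker_included)

  # fon == foff gives a zero flash index
  sched <- data.frame(polarity = c("on", "off"), t_on = c(0, 2),
                      t_off = c(0.5, 2.5))
  counts <- integer(120)
  counts[round(0.2 * 30)] <- 5L; counts[round(2.2 * 30)] <- 5L
  ci2 <- contrast_indices(flash_counts = counts, flash_schedule = sched)
  expect_equal(ci2$flash_onoff, 0)

  # the OFF model cell yields negative indices on both probes
  fl <- generate_probe_stimuli("flash", params = list(n_pairs = 30), seed = 1)
  mov <- array(rep(fl$luminance, 9), dim = c(length(fl$luminance), 3, 3))
  attr(mov, "pitch_um") <- 100; attr(mov, "dt_s") <- 1 / 30
  cmf <- get_counts(simulate_texture_cell(mov, rf_sd = 100, seed = 2))[, 1]
  fk <- generate_probe_stimuli("flicker", params = list(n_frames = 18000),
                               seed = 3)
  movf <- array(rep(fk$luminance, 4), dim = c(18000, 2, 2))
  attr(movf, "pitch_um") <- 200; attr(movf, "dt_s") <- 1 / 30
  cmk <- get_counts(simulate_texture_cell(movf, rf_sd = 150, seed = 4))[, 1]
  ci3 <- contrast_indices(flash_counts = cmf, flash_schedule = fl$schedule,
                          flicker_sta = temporal_sta(fk$luminance, cmk))
  expect_lt(ci3$flash_onoff, 0)
  expect_lt(ci3$flicker_onoff, 0)
})

test_that("cells are classified by the DSI/OMSI thresholds and grouped by angle", {
  out <- classify_cells(dsi = c(0.5, 0.5, 0.1, 0.5, 0.5),
                        preferred_angle = c(130, 20, 10, 300, 120),
                        omsi = c(0.2, 0.9, 0.1, 0.3, NA),
                        grating_rate = c(3, 3, 3, 3, 3))
  expect_identical(out$label,
                   c("standard_DS", "object_motion_DS", "non_DS",
                     "standard_DS", "unclassified"))
  expect_identical(out$group[c(1, 2, 4)],
                   c("temporal", NA, "nasal_ventral"))
  # boundary angles belong to the lower interval
  b <- classify_cells(0.5, 120, 0.1, 3)
  expect_identical(b$group, "nasal_dorsal")
  low <- classify_cells(0.5, 60, 0.1, grating_rate = 0.5)
  expect_identical(low$label, "non_DS")
})
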