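#' Probe stimuli for cell characterization
#'
#' Generates the standard battery of characterization stimuli as movies
#' and/or event schedules:
#' \describe{
#'   \item{grating}{Drifting square-wave gratings (600 um period, 0.75 Hz,
#'     100% contrast) in 8 equidistant directions, 6.67 s per direction
#'     separated by 1.67 s gray, repeated 5 times.  Returns the presentation
#'     schedule and optionally a rendered movie.}
#'   \item{checkerboard}{Spatiotemporal binary white noise: 80 x 60 squares
#'     of 75 um, each black or white with probability 0.5, updated at 30 Hz.
#'     Returned at square (not pixel) resolution.}
#'   \item{flash}{Full-field 500-ms steps to +40% or -40% of mean luminance,
#'     alternating ON/OFF, separated by 1.5 s at mean luminance.}
#'   \item{flicker}{Full-field Gaussian luminance flicker, SD 30% of the
#'     mean, updated at 30 Hz, clipped to the luminance range.}
#'   \item{omsi_patches}{Jittering grating patches (750 um circular patches
#'     on a hexagonal grid, 300 um period, steps of 15 um to either side at
#'     30 Hz) presented in coherent and differential segments of 23.33 s
#'     separated by 1.67 s gray.  Returned as per-patch jitter step
#'     sequences plus the segment schedule.}
#' }
#'
#' @param kind One of `"grating"`, `"checkerboard"`, `"flash"`, `"flicker"`,
#'   `"omsi_patches"`.
#' @param params Named list overriding stimulus defaults (see Details of the
#'   individual generators in the source).
#' @param seed Integer seed for the stochastic stimuli.
#' @param screen A [screen_model()].
#'
#' @return A list describing the stimulus; all kinds include `kind` and
#'   `dt_s`, stochastic kinds include the realized values, and episodic
#'   kinds include a `schedule` data frame.
#' @export
generate_probe_stimuli <- function(kind, params = list(), seed = 1,
                                   screen = screen_model()) {
  switch(kind,
    grating      = probe_grating(params, screen),
    checkerboard = probe_checkerboard(params, seed, screen),
    flash        = probe_flash(params, screen),
    flicker      = probe_flicker(params, seed, screen),
    omsi_patches = probe_omsi(params, seed, screen),
    stop(sprintf("unknown probe stimulus kind '%s'", kind)))
}

probe_grating <- function(params, screen) {
  p <- modifyList(list(spatial_period = 600, temporal_frequency = 0.75,
                       contrast = 1, n_directions = 8,
                       duration_per_direction = 6.67, gray_gap = 1.67,
                       repeats = 5, window = c(600, 600), render = FALSE),
                  params)
  dirs <- seq(0, 360 - 360 / p$n_directions, by = 360 / p$n_directions)
  block <- p$duration_per_direction + p$gray_gap
  sched <- do.call(rbind, lapply(seq_len(p$repeats), function(r) {
    data.frame(repeat_idx = r, direction = dirs,
               t_on = (r - 1) * length(dirs) * block +
                 (seq_along(dirs) - 1) * block,
               t_off = (r - 1) * length(dirs) * block +
                 (seq_along(dirs) - 1) * block + p$duration_per_direction)
  }))
  out <- list(kind = "grating", dt_s = screen$dt, params = p,
              directions = dirs, schedule = sched,
              total_duration = p$repeats * length(dirs) * block)
  if (isTRUE(p$render)) out$movie <- render_grating_movie(p, screen)
  out
}

# Square-wave grating movie for one full schedule, at pixel resolution of
# the given window; frames at the stimulus update rate.
render_grating_movie <- function(p, screen) {
  dt <- screen$dt
  wr <- as.integer(round(p$window[2] / screen$pixel_pitch))
  wc <- as.integer(round(p$window[1] / screen$pixel_pitch))
  xs <- (seq_len(wc) - 0.5) * screen$pixel_pitch
  ys <- (seq_len(wr) - 0.5) * screen$pixel_pitch
  dirs <- seq(0, 360 - 360 / p$n_directions, by = 360 / p$n_directions)
  n_dir_frames <- round(p$duration_per_direction / dt)
  n_gap_frames <- round(p$gray_gap / dt)
  frames_per_block <- n_dir_frames + n_gap_frames
  n_frames <- p$repeats * length(dirs) * frames_per_block
  movie <- array(screen$mean_level, dim = c(n_frames, wr, wc))
  fr <- 0L
  for (r in seq_len(p$repeats)) {
    for (th in dirs) {
      phi <- th * pi / 180
      proj <- outer(ys * sin(phi), xs * cos(phi), "+")  # position along motion axis
      for (k in seq_len(n_dir_frames)) {
        phase <- (proj / p$spatial_period -
                    p$temporal_frequency * (k - 1) * dt) %% 1
        lum <- screen$mean_level +
          0.5 * p$contrast * ifelse(phase < 0.5, 1, -1)
        movie[fr + k, , ] <- lum
      }
      fr <- fr + frames_per_block
    }
  }
  attr(movie, "pitch_um") <- screen$pixel_pitch
  attr(movie, "dt_s") <- dt
  movie
}

probe_checkerboard <- function(params, seed, screen) {
  p <- modifyList(list(n_x = 80, n_y = 60, square_um = 75, n_frames = 900),
                  params)
  frames <- with_seed(seed, {
    array(stats::rbinom(p$n_frames * p$n_y * p$n_x, 1, 0.5),
          dim = c(p$n_frames, p$n_y, p$n_x))
  })
  list(kind = "checkerboard", dt_s = screen$dt, params = p,
       frames = frames, pitch_um = p$square_um)
}

probe_flash <- function(params, screen) {
  p <- modifyList(list(step_frac = 0.4, flash_s = 0.5, gap_s = 1.5,
                       n_pairs = 10), params)
  block <- 2 * (p$flash_s + p$gap_s)
  sched <- do.call(rbind, lapply(seq_len(p$n_pairs), function(k) {
    t0 <- (k - 1) * block
    data.frame(polarity = c("on", "off"),
               t_on = c(t0, t0 + p$flash_s + p$gap_s),
               t_off = c(t0 + p$flash_s, t0 + 2 * p$flash_s + p$gap_s))
  }))
  n_frames <- as.integer(round(p$n_pairs * block / screen$dt))
  tt <- (seq_len(n_frames) - 1) * screen$dt
  lum <- rep(screen$mean_level, n_frames)
  for (i in seq_len(nrow(sched))) {
    sel <- tt >= sched$t_on[i] & tt < sched$t_off[i]
    lum[sel] <- screen$mean_level *
      (1 + ifelse(sched$polarity[i] == "on", p$step_frac, -p$step_frac))
  }
  list(kind = "flash", dt_s = screen$dt, params = p, schedule = sched,
       luminance = lum)
}

probe_flicker <- function(params, seed, screen) {
  p <- modifyList(list(sd_frac = 0.3, n_frames = 9000), params)
  lum <- with_seed(seed, {
    stats::rnorm(p$n_frames, mean = screen$mean_level,
                 sd = p$sd_frac * screen$mean_level)
  })
  lum <- pmin(pmax(lum, screen$luminance_range[1]), screen$luminance_range[2])
  list(kind = "flicker", dt_s = screen$dt, params = p, luminance = lum)
}

probe_omsi <- function(params, seed, screen) {
  p <- modifyList(list(n_patches = 7, patch_diameter = 750,
                       grating_period = 300, step_um = 15,
                       segment_s = 23.33, gray_gap_s = 1.67,
                       n_segments = 4), params)
  n_frames <- as.integer(round(p$segment_s / screen$dt))
  segs <- with_seed(seed, {
    lapply(seq_len(p$n_segments), function(k) {
      coherent <- k %% 2 == 1  # alternate coherent / differential
      if (coherent) {
        shared <- sample(c(-p$step_um, p$step_um), n_frames, replace = TRUE)
        steps <- matrix(shared, n_frames, p$n_patches)
      } else {
        steps <- matrix(sample(c(-p$step_um, p$step_um),
                               n_frames * p$n_patches, replace = TRUE),
                        n_frames, p$n_patches)
      }
      list(mode = if (coherent) "coherent" else "differential", steps = steps)
    })
  })
  sched <- data.frame(
    segment = seq_len(p$n_segments),
    mode = vapply(segs, `[[`, "", "mode"),
    t_on = (seq_len(p$n_segments) - 1) * (p$segment_s + p$gray_gap_s),
    t_off = (seq_len(p$n_segments) - 1) * (p$segment_s + p$gray_gap_s) +
      p$segment_s)
  list(kind = "omsi_patches", dt_s = screen$dt, params = p,
       segments = segs, schedule = sched)
}
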