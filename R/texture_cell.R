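#' Simulate an OFF-type, direction-selective texture-driven cell
#'
#' A synthetic encoder operating directly on the luminance movie, used to
#' exercise classification, conditional texture STAs and grating tuning
#' end-to-end.  It is scaffolding for testing the analysis chain, not a
#' model taken from recordings.  The drive combines
#' \itemize{
#'   \item an OFF contrast term: the high-passed, sign-preserving darkening
#'     signal in a Gaussian receptive field (darkening raises the rate,
#'     brightening suppresses it), and
#'   \item a direction-selective term: an opponent delay-line correlator
#'     (Barlow-Levick / Reichardt style) over two spatially offset OFF
#'     subunits along the preferred direction, rectified.
#' }
#' The total rate is `max(0, r0 + w_contrast * contrast + w_ds * ds)` Hz and
#' spikes are Poisson per frame.
#'
#' @param movie Luminance array `frames x rows x cols` with attributes
#'   `pitch_um` and `dt_s` (as returned by [render_moving_texture()] or the
#'   grating renderer).
#' @param rf_center Receptive-field center (um) relative to the window
#'   center.
#' @param rf_sd Gaussian RF radius (um, SD).
#' @param preferred_direction Preferred direction (deg).
#' @param seed Seed for the Poisson noise.
#' @param params Named list overriding model constants: `r0` (baseline Hz),
#'   `w_contrast`, `w_ds` (drive weights), `subunit_offset_um`,
#'   `subunit_sd_um`, `delay_frames` (correlator delay), `highpass_frames`,
#'   `latency_frames` (response latency).
#' @return A [spike_train_set()] with one cell and one trial; the rate
#'   trace is attached as attribute `rate_hz`.
#' @export
simulate_texture_cell <- function(movie, rf_center = c(0, 0), rf_sd = 100,
                                  preferred_direction = 0, seed = 1,
                                  params = list()) {
  p <- modifyList(list(r0 = 1, w_contrast = 12, w_ds = 40,
                       subunit_offset_um = 90, subunit_sd_um = 60,
                       delay_frames = 5L, highpass_frames = 10L,
                       latency_frames = 2L, mean_level = 0.5), params)
  pitch <- attr(movie, "pitch_um")
  dt <- attr(movie, "dt_s")
  d <- dim(movie)
  n_frames <- d[1]; nr <- d[2]; nc <- d[3]
  xs <- ((seq_len(nc)) - (nc + 1) / 2) * pitch
  ys <- ((seq_len(nr)) - (nr + 1) / 2) * pitch
  if (rf_center[1] < min(xs) || rf_center[1] > max(xs) ||
      rf_center[2] < min(ys) || rf_center[2] > max(ys))
    stop("receptive field center lies outside the movie window")

  gauss_rf <- function(cx, cy, sd) {
    w <- outer(exp(-0.5 * ((ys - cy) / sd)^2),
               exp(-0.5 * ((xs - cx) / sd)^2))
    w / sum(w)
  }
  mov <- matrix(movie, nrow = n_frames)  # frames x (rows*cols), row-major rows

  # OFF contrast in the main RF: positive for darkening
  w_main <- gauss_rf(rf_center[1], rf_center[2], rf_sd)
  lum <- as.numeric(mov %*% as.vector(w_main))
  contrast <- -(lum - p$mean_level) / p$mean_level
  # transient (high-pass): subtract trailing mean
  base <- stats::filter(contrast, rep(1 / p$highpass_frames,
                                      p$highpass_frames), sides = 1)
  base[is.na(base)] <- 0
  c_hp <- contrast - as.numeric(base)

  # opponent correlator over two OFF subunits along the preferred axis
  th <- preferred_direction * pi / 180
  off <- p$subunit_offset_um / 2 * c(cos(th), sin(th))
  s_lead <- off_signal(mov, gauss_rf(rf_center[1] - off[1],
                                     rf_center[2] - off[2],
                                     p$subunit_sd_um), p$mean_level)
  s_lag  <- off_signal(mov, gauss_rf(rf_center[1] + off[1],
                                     rf_center[2] + off[2],
                                     p$subunit_sd_um), p$mean_level)
  k <- p$delay_frames
  lagged <- function(x, k) c(rep(0, k), x[seq_len(length(x) - k)])
  ds <- pmax(0, lagged(s_lead, k) * s_lag - lagged(s_lag, k) * s_lead)

  rate <- pmax(0, p$r0 + p$w_contrast * c_hp + p$w_ds * ds)
  # response latency: spikes follow the driving frame by a couple of frames
  lf <- p$latency_frames
  if (lf > 0) rate <- c(rep(p$r0, lf), rate[seq_len(n_frames - lf)])
  counts <- with_seed(derive_seed(seed, "texture_cell"), {
    stats::rpois(n_frames, rate * dt)
  })
  meta <- data.frame(cell_id = "texcell", preferred_direction =
                       preferred_direction %% 360, group = NA_integer_,
                     rf_x_um = rf_center[1], rf_y_um = rf_center[2])
  sts <- spike_train_set(matrix(as.integer(counts), ncol = 1), dt = dt,
                         cell_meta = meta)
  attr(sts, "rate_hz") <- rate
  sts
}

# Rectified OFF (darkening) signal in a weighted RF.
off_signal <- function(mov, w, mean_level) {
  lum <- as.numeric(mov %*% as.vector(w))
  pmax(0, -(lum - mean_level) / mean_level)
}
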