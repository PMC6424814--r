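#' Render a moving texture as a luminance movie
#'
#' Frame `t` (0-based) shows the texture translated by the cumulative sum of
#' steps `1..t`, sampled through a fixed window centered on the texture.
#' Because steps are quantized to the pixel pitch, translation is an integer
#' pixel shift and needs no interpolation.  The rendered array has
#' `n_frames + 1` frames; frame 1 of the array (frame 0 of the stimulus) is
#' the untranslated texture.
#'
#' @param texture A `texture`.
#' @param trajectory A `motion_trajectory` with steps quantized to the
#'   texture pitch.
#' @param screen A [screen_model()].
#' @param window Length-2 numeric, (width, height) of the viewing window in
#'   um.
#'
#' @return An array of dimension `(n_frames + 1) x rows x cols` with
#'   attributes `pitch_um` and `dt_s`.
#' @export
render_moving_texture <- function(texture, trajectory,
                                  screen = screen_model(),
                                  window = c(600, 600)) {
  pitch <- texture$pitch
  steps_px <- trajectory$steps / pitch
  if (max(abs(steps_px - round(steps_px))) > 1e-9)
    stop("trajectory steps must be multiples of the texture pitch")
  steps_px <- round(steps_px)
  disp <- rbind(c(0, 0), apply(steps_px, 2, cumsum))
  if (trajectory$n_frames == 1) disp <- rbind(c(0, 0), steps_px)

  nr <- nrow(texture$luminance); nc <- ncol(texture$luminance)
  wr <- as.integer(round(window[2] / pitch))
  wc <- as.integer(round(window[1] / pitch))
  if (wr > nr || wc > nc) stop("window larger than texture extent")
  # window anchored at the texture center
  r0 <- (nr - wr) %/% 2L
  c0 <- (nc - wc) %/% 2L

  m <- nrow(disp)
  frames <- array(NA_real_, dim = c(m, wr, wc))
  for (t in seq_len(m)) {
    # texture translated by +d: window pixel p samples texture at p - d;
    # x displacement moves along columns, y along rows
    cs <- c0 - disp[t, 1] + seq_len(wc)
    rs <- r0 - disp[t, 2] + seq_len(wr)
    if (rs[1] < 1 || cs[1] < 1 || rs[wr] > nr || cs[wc] > nc)
      stop(sprintf("trajectory excursion leaves the texture at frame %d", t - 1L))
    frames[t, , ] <- texture$luminance[rs, cs]
  }
  attr(frames, "pitch_um") <- pitch
  attr(frames, "dt_s") <- screen$dt
  frames
}

#' Drop the initial (pre-step) frame of a rendered movie
#'
#' [render_moving_texture()] returns `n_frames + 1` frames, the first being
#' the untranslated texture before any step.  Analyses that pair movie
#' frames 1:1 with count intervals (frame `j` on screen during interval
#' `j`) use the movie without that leading frame; this helper removes it
#' while preserving the `pitch_um`/`dt_s` attributes.
#'
#' @param movie A rendered movie array.
#' @return The movie without its first frame.
#' @export
drop_initial_frame <- function(movie) {
  out <- movie[-1, , , drop = FALSE]
  attr(out, "pitch_um") <- attr(movie, "pitch_um")
  attr(out, "dt_s") <- attr(movie, "dt_s")
  out
}
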