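#' Screen model for stimulus generation
#'
#' Describes the display geometry and timing on which all stimuli are
#' generated: square pixels of 7.5 um on the retina, a 60 Hz refresh rate with
#' stimulus updates on every other refresh (30 Hz), and luminance normalized
#' to \[0, 1\] around a mean level of 0.5.  The frame interval
#' \code{dt = 1/update_rate} (~33 ms) is the time base for spike binning and
#' for every filter in the package.
#'
#' @param pixel_pitch Pixel size on the retina (um).
#' @param refresh_rate Display refresh rate (Hz).
#' @param update_rate Stimulus update rate (Hz); must divide `refresh_rate`.
#' @param mean_level Mean luminance in normalized units, inside \[0, 1\].
#'
#' @return An object of class `screen_model`: a list with the arguments plus
#'   `dt`, the stimulus frame interval in seconds.
#' @examples
#' scr <- screen_model()
#' scr$dt * scr$update_rate  # == 1
#' @export
screen_model <- function(pixel_pitch = 7.5, refresh_rate = 60,
                         update_rate = 30, mean_level = 0.5) {
  if (pixel_pitch <= 0) stop("'pixel_pitch' must be positive")
  if (update_rate <= 0 || refresh_rate < update_rate)
    stop("'update_rate' must be positive and no larger than 'refresh_rate'")
  if (mean_level < 0 || mean_level > 1)
    stop("'mean_level' must lie in [0, 1]")
  structure(
    list(pixel_pitch = pixel_pitch,
         refresh_rate = refresh_rate,
         update_rate = update_rate,
         dt = 1 / update_rate,
         mean_level = mean_level,
         luminance_range = c(0, 1)),
    class = "screen_model")
}

#' @export
print.screen_model <- function(x, ...) {
  cat(sprintf(
    "<screen_model> %.3g um pixels, %g Hz refresh, %g Hz update (dt = %.1f ms), mean level %.2f\n",
    x$pixel_pitch, x$refresh_rate, x$update_rate, 1000 * x$dt, x$mean_level))
  invisible(x)
}

# Number of taps spanning 800 ms at the 30 Hz stimulus clock.  Fixed across
# the motion STA, the decoder and the information segment length so that all
# stages share one temporal window.
#' Default temporal window length (taps)
#'
#' The package uses an 800-ms analysis window throughout (motion STA, decoder
#' filters, information segments), which is `L = 24` taps at the 30 Hz
#' stimulus update rate.
#' @return The integer 24.
#' @export
default_taps <- function() 24L
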