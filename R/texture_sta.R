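#' Conditional texture STA
#'
#' Averages the texture frames that preceded spikes fired during preferred
#' (`g > 0.5`) or non-preferred (`g < -0.5`) motion, where `g` is the
#' LN-model drive of the cell.  The frame 200 ms before the spike is
#' extracted as the spatial component, the all-frame mean pattern is
#' subtracted to cancel non-informative texture structure, and two summary
#' statistics are computed: a contrast bias, `(darkest + brightest pixel) /
#' SD(pixels)`, and the dark-spot location (the minimum of the corrected
#' frame after light spatial smoothing).  The STA is flagged excluded when
#' its absolute peak is below 4 pixel SDs.
#'
#' @param movie Luminance movie (`frames x rows x cols`, attributes
#'   `pitch_um`, `dt_s`) whose frame `j` was on screen during count interval
#'   `j` — i.e. a rendered movie after [drop_initial_frame()].
#' @param counts Frame-binned counts aligned to the trajectory (length
#'   `n_frames`).
#' @param g LN drive aligned so `g[j]` pairs with `counts[j + L]`.
#' @param condition `"preferred"` (`g > threshold`) or `"nonpreferred"`
#'   (`g < -threshold`).
#' @param L Taps of the drive filter (alignment offset).
#' @param lag_s Lag of the extracted frame before the spike (s).
#' @param threshold Drive threshold (default 0.5).
#' @param smooth_um SD of the Gaussian smoothing applied before locating the
#'   dark spot (um).
#' @return An object of class `conditional_texture_sta`: list with
#'   `spatial_frame` (corrected), `condition`, `n_spikes`, `contrast_bias`,
#'   `dark_spot` (x, y in um relative to the window center), `included`.
#' @export
conditional_texture_sta <- function(movie, counts, g,
                                    condition = c("preferred", "nonpreferred"),
                                    L = default_taps(), lag_s = 0.2,
                                    threshold = 0.5, smooth_um = 30) {
  condition <- match.arg(condition)
  pitch <- attr(movie, "pitch_um")
  dt <- attr(movie, "dt_s")
  nf <- dim(movie)[1]
  m <- length(counts)
  if (length(g) != m - L) stop("'g' must have length(counts) - L elements")
  lag_frames <- round(lag_s / dt)
  j <- seq_along(g) + L                      # count frame index
  sel <- if (condition == "preferred") g > threshold else g < -threshold
  w <- counts[j] * sel
  if (sum(w) == 0) stop("no spikes satisfy the drive condition")
  # movie frame on screen `lag_frames` before count frame j
  rows <- j - lag_frames
  ok <- rows >= 1 & rows <= nf
  w <- w[ok]; rows <- rows[ok]
  mov <- matrix(movie, nrow = nf)
  sta_vec <- as.numeric(crossprod(mov[rows, , drop = FALSE], w) / sum(w))
  mean_frame <- colMeans(mov)
  frame <- matrix(sta_vec - mean_frame, dim(movie)[2], dim(movie)[3])
  px_sd <- stats::sd(frame)
  included <- max(abs(frame)) >= 4 * px_sd
  contrast_bias <- (min(frame) + max(frame)) / px_sd
  sm <- gaussian_smooth2d(frame, smooth_um / pitch)
  idx <- arrayInd(which.min(sm), dim(sm))
  nr <- nrow(frame); nc <- ncol(frame)
  dark_spot <- c(x = (idx[2] - (nc + 1) / 2) * pitch,
                 y = (idx[1] - (nr + 1) / 2) * pitch)
  structure(
    list(spatial_frame = frame, condition = condition, n_spikes = sum(w),
         contrast_bias = contrast_bias, dark_spot = dark_spot,
         included = included),
    class = "conditional_texture_sta")
}

#' @export
print.conditional_texture_sta <- function(x, ...) {
  cat(sprintf(
    "<conditional_texture_sta:%s> %d spikes, contrast bias %.2f, dark spot (%.0f, %.0f) um%s\n",
    x$condition, x$n_spikes, x$contrast_bias, x$dark_spot[1], x$dark_spot[2],
    if (x$included) "" else " [excluded: peak < 4 pixel SD]"))
  invisible(x)
}

#' Dark-spot displacement between motion conditions
#'
#' Angle of the vector from the preferred-condition dark spot to the
#' non-preferred-condition dark spot, for comparison with the cell's
#' preferred direction.
#'
#' @param sta_pref,sta_nonpref `conditional_texture_sta` objects.
#' @return Angle in degrees in \[0, 360).
#' @export
dark_spot_displacement_angle <- function(sta_pref, sta_nonpref) {
  d <- sta_nonpref$dark_spot - sta_pref$dark_spot
  (atan2(d[["y"]], d[["x"]]) * 180 / pi) %% 360
}
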