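#' Smoothed white-noise texture
#'
#' The standard moving texture: binary black/white squares of 30 x 30 um^2
#' (probability 0.5 each, 100% contrast) convolved with an isotropic Gaussian
#' kernel of 60 um SD.  Smoothing attenuates the pattern amplitude, so the
#' smoothed pattern is renormalized to 100% Michelson contrast (its darkest
#' point black, its brightest white) before the deviations are scaled by
#' `contrast_scale` (default 1.5) and clipped to the screen's luminance
#' range; with the default scaling the extremes of the texture saturate at
#' 0 and 1.
#'
#' @param seed Integer seed; identical seeds give byte-identical textures.
#' @param extent Numeric length-2, texture width and height in um.  Must
#'   cover the analysis window plus the maximal trajectory excursion.
#' @param screen A [screen_model()].
#' @param square_um Edge length of the binary squares (um).
#' @param smooth_sd_um SD of the Gaussian smoothing kernel (um).
#' @param contrast_scale Factor applied to luminance deviations from the
#'   mean after smoothing; values beyond the luminance range are clipped.
#'
#' @return An object of class `texture`: list with `luminance` (rows x cols
#'   matrix in \[0, 1\]), `pitch` (um per texel), `mean`, `sd`, `kind`,
#'   `seed`.
#' @examples
#' tex <- generate_smoothed_texture(1, extent = c(600, 600))
#' range(tex$luminance)
#' @export
generate_smoothed_texture <- function(seed, extent = c(3000, 3000),
                                      screen = screen_model(),
                                      square_um = 30, smooth_sd_um = 60,
                                      contrast_scale = 1.5) {
  if (length(extent) == 1) extent <- rep(extent, 2)
  if (any(extent < square_um))
    stop("'extent' must cover at least one texture square")
  pitch <- screen$pixel_pitch
  ncol_px <- as.integer(round(extent[1] / pitch))
  nrow_px <- as.integer(round(extent[2] / pitch))
  sq_px <- max(1L, as.integer(round(square_um / pitch)))
  n_sq_c <- ceiling(ncol_px / sq_px)
  n_sq_r <- ceiling(nrow_px / sq_px)
  binary <- with_seed(seed, {
    matrix(stats::rbinom(n_sq_r * n_sq_c, 1, 0.5), n_sq_r, n_sq_c)
  })
  # expand squares to pixel resolution
  px <- binary[rep(seq_len(n_sq_r), each = sq_px)[seq_len(nrow_px)],
               rep(seq_len(n_sq_c), each = sq_px)[seq_len(ncol_px)],
               drop = FALSE]
  dev <- px - screen$mean_level
  sm <- gaussian_smooth2d(dev, smooth_sd_um / pitch)
  sm <- sm - mean(sm)  # contrast relative to the realized texture mean
  half_range <- min(screen$mean_level - screen$luminance_range[1],
                    screen$luminance_range[2] - screen$mean_level)
  sm <- sm * (half_range / max(abs(sm)))  # restore 100% Michelson contrast
  lum <- screen$mean_level + contrast_scale * sm
  lum <- pmin(pmax(lum, screen$luminance_range[1]), screen$luminance_range[2])
  new_texture(lum, pitch, "smoothed_white", seed)
}

#' Pink-noise texture
#'
#' A texture with a 1/f spatial amplitude spectrum, adjusted to the same mean
#' and SD as a reference smoothed white-noise texture (generated with the
#' same seed and geometry when no reference is supplied), then clipped to the
#' luminance range.
#'
#' @inheritParams generate_smoothed_texture
#' @param reference Optional `texture` whose mean and SD are matched; when
#'   `NULL` a standard texture with the same seed and extent is used.
#' @return A `texture` of kind `"pink"`.
#' @export
generate_pink_texture <- function(seed, extent = c(3000, 3000),
                                  screen = screen_model(),
                                  reference = NULL) {
  if (length(extent) == 1) extent <- rep(extent, 2)
  if (is.null(reference)) {
    reference <- generate_smoothed_texture(seed, extent, screen)
  }
  pitch <- screen$pixel_pitch
  nr <- as.integer(round(extent[2] / pitch))
  nc <- as.integer(round(extent[1] / pitch))
  field <- with_seed(derive_seed(seed, "pink"), {
    white <- matrix(stats::rnorm(nr * nc), nr, nc)
    fx <- fft_freqs(nc)
    fy <- fft_freqs(nr)
    f <- sqrt(outer(fy^2, fx^2, "+"))
    amp <- 1 / f
    amp[1, 1] <- 0  # zero the DC term; mean is set explicitly below
    Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / (nr * nc)
  })
  field <- (field - mean(field)) / stats::sd(field)
  lo <- screen$luminance_range[1]; hi <- screen$luminance_range[2]
  # choose the field scale so that the *clipped* texture matches the
  # reference SD (clipping slightly compresses a plain rescaling)
  clipped_sd <- function(s) {
    stats::sd(pmin(pmax(reference$mean + s * field, lo), hi))
  }
  s <- if (clipped_sd(reference$sd) >= reference$sd * 0.999) {
    reference$sd
  } else {
    stats::uniroot(function(s) clipped_sd(s) - reference$sd,
                   lower = reference$sd, upper = 5 * reference$sd,
                   tol = 1e-6)$root
  }
  lum <- pmin(pmax(reference$mean + s * field, lo), hi)
  new_texture(lum, pitch, "pink", seed)
}

#' Wrap a grayscale image as a texture
#'
#' Accepts any sufficiently large grayscale array (values are rescaled to the
#' reference mean/SD when given) so that natural images can drive the moving
#' texture stimulus.
#'
#' @param image Numeric matrix of grayscale values.
#' @param pitch um per texel.
#' @param reference Optional `texture` whose mean and SD are matched.
#' @param screen A [screen_model()] used for clipping.
#' @return A `texture` of kind `"image"`.
#' @export
texture_from_image <- function(image, pitch = 7.5, reference = NULL,
                               screen = screen_model()) {
  lum <- as.matrix(image)
  if (!is.null(reference)) {
    lum <- (lum - mean(lum)) / stats::sd(lum)
    lum <- reference$mean + lum * reference$sd
    lum <- pmin(pmax(lum, screen$luminance_range[1]),
                screen$luminance_range[2])
  }
  new_texture(lum, pitch, "image", NA_integer_)
}

new_texture <- function(lum, pitch, kind, seed) {
  structure(
    list(luminance = lum, pitch = pitch,
         mean = mean(lum), sd = stats::sd(as.vector(lum)),
         kind = kind, seed = seed),
    class = "texture")
}

#' @export
print.texture <- function(x, ...) {
  cat(sprintf(
    "<texture:%s> %d x %d texels at %g um (%.0f x %.0f um), mean %.3f, sd %.3f\n",
    x$kind, nrow(x$luminance), ncol(x$luminance), x$pitch,
    ncol(x$luminance) * x$pitch, nrow(x$luminance) * x$pitch, x$mean, x$sd))
  invisible(x)
}

# FFT frequencies in cycles per sample for n samples.
fft_freqs <- function(n) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k / n
}

# Circular 2D Gaussian smoothing via FFT; sd in pixels.
gaussian_smooth2d <- function(x, sd_px) {
  nr <- nrow(x); nc <- ncol(x)
  gy <- dnorm_kernel(nr, sd_px)
  gx <- dnorm_kernel(nc, sd_px)
  k <- outer(gy, gx)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

# Periodic Gaussian kernel of length n centered on index 1.
dnorm_kernel <- function(n, sd_px) {
  d <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1))
  exp(-0.5 * (d / sd_px)^2)
}

#' Radially averaged amplitude-spectrum slope
#'
#' Fits a straight line to the log radially averaged Fourier amplitude
#' against log spatial frequency; a pink-noise texture has slope close to -1.
#'
#' @param texture A `texture`.
#' @param f_range Fraction of the Nyquist range used for the fit (low
#'   frequencies where the 1/f law is unaffected by clipping).
#' @return The fitted log-log slope.
#' @export
amplitude_spectrum_slope <- function(texture, f_range = c(0.02, 0.5)) {
  x <- texture$luminance - mean(texture$luminance)
  nr <- nrow(x); nc <- ncol(x)
  amp <- Mod(stats::fft(x))
  f <- sqrt(outer(fft_freqs(nr)^2, fft_freqs(nc)^2, "+"))
  sel <- f > f_range[1] & f <= f_range[2] * sqrt(2) / 2
  bins <- cut(log10(f[sel]), breaks = 24)
  lf <- tapply(log10(f[sel]), bins, mean)
  la <- tapply(log10(amp[sel]), bins, mean)
  ok <- is.finite(lf) & is.finite(la)
  unname(stats::coef(stats::lm(la[ok] ~ lf[ok]))[2])
}
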