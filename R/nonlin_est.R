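#' Estimate a binned nonlinearity
#'
#' Sorts the (drive, count) pairs by drive, splits them into `n_bins` bins
#' containing (as nearly as possible) equal numbers of pairs, and returns
#' the mean drive and mean firing rate (counts / `dt`, in Hz) per bin.  Also
#' computes the U-shape index `U = (N(g_min) - N(0)) / N(g_max)` from the
#' leftmost, central and rightmost bins: negative for monotonically rising
#' nonlinearities, near zero for a flat left tail, positive (toward 1) for
#' symmetric U-shapes.
#'
#' @param g Filtered stimulus drive (unit-variance scale), one value per
#'   counted frame.
#' @param f Spike counts aligned with `g` (may be signed for reduced codes).
#' @param n_bins Number of equal-count bins (default 15).
#' @param dt Frame interval (s) for the rate conversion.
#' @return An object of class `binned_nonlinearity`: list with `g_centers`,
#'   `rates` (Hz), `n_per_bin`, `ushape_index`, `n_bins`, `dt`.
#' @export
estimate_nonlinearity <- function(g, f, n_bins = 15, dt = 1 / 30) {
  if (length(g) != length(f)) stop("'g' and 'f' must align")
  n <- length(g)
  if (n_bins > n) stop("more bins than samples")
  ord <- order(g)  # stable ties
  # equal-count occupancy; remainder samples go to the central bins
  base <- n %/% n_bins
  occ <- rep(base, n_bins)
  extra <- n - base * n_bins
  if (extra > 0) {
    mid <- order(abs(seq_len(n_bins) - (n_bins + 1) / 2))[seq_len(extra)]
    occ[mid] <- occ[mid] + 1L
  }
  bin <- rep(seq_len(n_bins), occ)
  gs <- g[ord]; fs <- f[ord]
  g_centers <- as.numeric(tapply(gs, bin, mean))
  rates <- as.numeric(tapply(fs, bin, mean)) / dt
  central <- (n_bins + 1) %/% 2
  u <- if (rates[n_bins] == 0) NA_real_ else
    (rates[1] - rates[central]) / rates[n_bins]
  structure(
    list(g_centers = g_centers, rates = rates, n_per_bin = occ,
         ushape_index = u, n_bins = n_bins, dt = dt),
    class = "binned_nonlinearity")
}

#' @export
print.binned_nonlinearity <- function(x, ...) {
  cat(sprintf(
    "<binned_nonlinearity> %d bins, rates %.2f-%.2f Hz, U-shape index %.3f\n",
    x$n_bins, min(x$rates), max(x$rates), x$ushape_index))
  invisible(x)
}

#' @export
plot.binned_nonlinearity <- function(x, ...) {
  plot(x$g_centers, x$rates, type = "b", pch = 16,
       xlab = "filtered stimulus", ylab = "rate (Hz)", ...)
  invisible(x)
}

#' Drive of a motion STA applied to the stimulus
#'
#' Computes `g = Sseg %*% a_hat` with the STA normalized to unit Euclidean
#' norm and the stimulus to unit variance — the operating scale of the LN
#' model.
#'
#' @param steps Steps (`motion_trajectory`, matrix, or 1D vector).
#' @param sta A `motion_sta` (or numeric filter of matching length).
#' @param L Window length in taps.
#' @return Numeric drive vector of length `M - L`, aligned so element `j`
#'   pairs with the count in frame `j + L`.
#' @export
ln_model_drive <- function(steps, sta, L = default_taps()) {
  seg <- segment_stimulus(steps, counts = NULL, L = L, normalize = TRUE)
  a <- if (inherits(sta, "motion_sta")) sta$a else as.numeric(sta)
  if (length(a) != ncol(seg$Sseg))
    stop("filter length does not match the segment matrix")
  a <- a / sqrt(sum(a^2))
  as.numeric(seg$Sseg %*% a)
}

#' Fit a parametric nonlinearity to binned rates
#'
#' Least-squares fit of either an exponential `N(x) = A exp(B x)` or a
#' U-shaped form with offset `N(x) = C + A x^2 exp(B x)` to the binned
#' (drive, rate) points, via Levenberg-Marquardt.
#'
#' @param binned A [estimate_nonlinearity()] result, or a list with
#'   `g_centers` and `rates`.
#' @param kind `"exponential"` or `"ushape"`.
#' @return A [nonlinearity()] with the fitted coefficients and attributes
#'   `residual_sse` and `fitted`.
#' @export
fit_parametric_nonlinearity <- function(binned,
                                        kind = c("exponential", "ushape")) {
  kind <- match.arg(kind)
  g <- binned$g_centers
  r <- binned$rates
  if (all(r == 0)) stop("all rates are zero: nothing to fit")
  df <- data.frame(g = g, r = r)
  fit <- if (kind == "exponential") {
    pos <- r > 0
    b0 <- if (sum(pos) >= 2)
      stats::coef(stats::lm(log(r[pos]) ~ g[pos]))[2] else 1
    minpack.lm::nlsLM(r ~ A * exp(B * g), data = df,
                      start = list(A = max(mean(r), 1e-3), B = unname(b0)),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    c0 <- max(min(r), 1e-3)
    a0 <- max((max(r) - c0) / max(g^2), 1e-3)
    minpack.lm::nlsLM(r ~ C + A * g^2 * exp(B * g), data = df,
                      start = list(C = c0, A = a0, B = 0),
                      lower = c(0, 1e-9, -10), upper = c(Inf, Inf, 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  out <- nonlinearity(kind, A = cf[["A"]], B = cf[["B"]],
                      C = if (kind == "ushape") cf[["C"]] else 0)
  attr(out, "residual_sse") <- sum(stats::residuals(fit)^2)
  attr(out, "fitted") <- stats::fitted(fit)
  out
}
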