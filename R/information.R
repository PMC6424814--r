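#' Spectral lower bound on stimulus-reconstruction mutual information
#'
#' Cuts the held-out stimulus and the reconstruction error `e = s - u` into
#' non-overlapping segments of `L` frames (800 ms), Fourier-transforms each
#' segment, and averages one-sided power spectra across segments:
#' `P_j = <|hat_j|^2 + |hat_{-j}|^2>` for `0 <= j <= L/2`.  Because the
#' motion steps are Gaussian and the error is approximately Gaussian, the
#' per-band information density is bounded below by `log2(Ps_j / Pe_j)`
#' (clipped at 0 where finite sampling makes `Pe > Ps`), and the total rate
#' is the band sum divided by the segment duration `L * dt`, summed over the
#' independent x and y axes.
#'
#' @param s Held-out stimulus steps (vector, or matrix with one column per
#'   axis).
#' @param u Reconstruction, same shape as `s` (e.g. `$U` of a
#'   [reconstruct()] result).
#' @param L Segment length in frames.
#' @param dt Frame interval (s).
#' @return An object of class `info_spectrum`: list with `freqs` (Hz),
#'   `density` (bits/s/Hz per band per axis, after clipping), `axis_totals`,
#'   `total_rate` (bits/s), `Ps`, `Pe`, `n_segments`, `unbounded` (TRUE if
#'   any error band had zero power).
#' @export
info_lower_bound <- function(s, u, L = default_taps(), dt = 1 / 30) {
  if (is.null(dim(s))) s <- matrix(s, ncol = 1)
  if (is.null(dim(u))) u <- matrix(u, ncol = 1)
  if (!all(dim(s) == dim(u))) stop("'s' and 'u' must have the same shape")
  n_seg <- nrow(s) %/% L
  if (n_seg < 2) stop("test block shorter than two segments")
  n_bands <- L %/% 2 + 1
  freqs <- (seq_len(n_bands) - 1) / (L * dt)
  n_axes <- ncol(s)
  Ps <- Pe <- dens <- matrix(NA_real_, n_bands, n_axes)
  unbounded <- FALSE
  for (k in seq_len(n_axes)) {
    sk <- s[seq_len(n_seg * L), k]
    ek <- sk - u[seq_len(n_seg * L), k]
    Ps[, k] <- segment_power(sk - mean(sk), L, n_seg)
    Pe[, k] <- segment_power(ek - mean(ek), L, n_seg)
    if (any(Pe[, k] == 0)) {
      unbounded <- TRUE
      dens[, k] <- ifelse(Pe[, k] == 0, Inf,
                          pmax(0, log2(Ps[, k] / Pe[, k])))
    } else {
      dens[, k] <- pmax(0, log2(Ps[, k] / Pe[, k]))
    }
  }
  axis_totals <- colSums(dens) / (L * dt)
  structure(
    list(freqs = freqs, density = dens, axis_totals = axis_totals,
         total_rate = sum(axis_totals), Ps = Ps, Pe = Pe,
         n_segments = n_seg, unbounded = unbounded, L = L, dt = dt),
    class = "info_spectrum")
}

# One-sided power per band averaged over non-overlapping segments.
segment_power <- function(x, L, n_seg) {
  seg <- matrix(x, nrow = L)
  ft <- stats::mvfft(seg)
  p2 <- Mod(ft)^2
  n_bands <- L %/% 2 + 1
  vapply(seq_len(n_bands) - 1L, function(j) {
    jm <- (-j) %% L
    mean(p2[j + 1, ] + p2[jm + 1, ])
  }, 0)
}

#' @export
print.info_spectrum <- function(x, ...) {
  cat(sprintf(
    "<info_spectrum> %.3f bits/s over %d band(s) x %d axis/axes (%d segments)%s\n",
    x$total_rate, nrow(x$density), ncol(x$density), x$n_segments,
    if (x$unbounded) " [unbounded band present]" else ""))
  invisible(x)
}

#' @export
plot.info_spectrum <- function(x, ...) {
  d <- rowSums(x$density)
  plot(x$freqs, d, type = "b", pch = 16, xlab = "frequency (Hz)",
       ylab = "information density (bits/s/Hz)", ...)
  invisible(x)
}

#' Synergy/redundancy information ratio
#'
#' Ratio of the information obtained from the population reconstruction to
#' the summed information of the single-cell reconstructions,
#' `I_pop / sum_k I_k`.  Values above 1 indicate synergy, below 1
#' redundancy.  Pairs whose summed single-cell information falls below
#' 0.1 bits/s are flagged ineligible (their ratios are dominated by
#' estimation noise) and the ratio is withheld.
#'
#' @param i_pop Population information rate (bits/s), or an `info_spectrum`.
#' @param i_singles Numeric vector of single-cell rates (or list of
#'   `info_spectrum` objects).
#' @param eligibility_threshold Minimum summed single-cell information
#'   (bits/s) for pairs; set to 0 to disable.
#' @return An object of class `info_ratio_result`: list with `i_pop`,
#'   `i_singles`, `ratio` (NA when ineligible), `eligible`, `label`
#'   (`"synergy"`, `"redundancy"`, or NA).
#' @export
info_ratio <- function(i_pop, i_singles, eligibility_threshold = 0.1) {
  if (inherits(i_pop, "info_spectrum")) i_pop <- i_pop$total_rate
  if (is.list(i_singles))
    i_singles <- vapply(i_singles, function(z) {
      if (inherits(z, "info_spectrum")) z$total_rate else as.numeric(z)
    }, 0)
  eligible <- sum(i_singles) >= eligibility_threshold
  ratio <- if (eligible) i_pop / sum(i_singles) else NA_real_
  structure(
    list(i_pop = i_pop, i_singles = i_singles, ratio = ratio,
         eligible = eligible,
         label = if (!eligible) NA_character_
                 else if (ratio > 1) "synergy" else "redundancy"),
    class = "info_ratio_result")
}

#' @export
print.info_ratio_result <- function(x, ...) {
  if (!x$eligible) {
    cat("<info_ratio_result> ineligible (summed single-cell information below threshold)\n")
  } else {
    cat(sprintf(
      "<info_ratio_result> I_pop %.3f / sum I_k %.3f = %.3f (%s)\n",
      x$i_pop, sum(x$i_singles), x$ratio, x$label))
  }
  invisible(x)
}

#' Pearson response correlation of a cell pair
#'
#' Pearson correlation coefficient of the two cells' frame-binned (33-ms)
#' spike counts, with the pairing condition recorded (same trial, shuffled
#' trials, or spatially offset trials).
#'
#' @param counts_i,counts_j Frame-binned counts.
#' @param pairing Pairing label, one of `"same_trial"`, `"shuffled"`,
#'   `"offset"`.
#' @return An object of class `correlation_result`: list with `r`,
#'   `pairing`, `n`.
#' @export
response_correlation <- function(counts_i, counts_j,
                                 pairing = c("same_trial", "shuffled",
                                             "offset")) {
  pairing <- match.arg(pairing)
  if (length(counts_i) != length(counts_j))
    stop("count sequences must have equal length")
  if (stats::sd(counts_i) == 0 || stats::sd(counts_j) == 0)
    stop("zero-variance count sequence: correlation undefined")
  structure(
    list(r = stats::cor(counts_i, counts_j), pairing = pairing,
         n = length(counts_i)),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f (%s pairing, n = %d)\n",
              x$r, x$pairing, x$n))
  invisible(x)
}

#' Wilcoxon signed-rank summaries for ratios and correlations
#'
#' One-sample signed-rank test against a null value (e.g. information ratios
#' against unity) or a paired test between two conditions, delegated to
#' [stats::wilcox.test()].
#'
#' @param x Sample values.
#' @param y Either a single null value (one-sample test of `x - y`) or a
#'   second paired sample of the same length.
#' @param ... Passed to [stats::wilcox.test()].
#' @return List with `statistic`, `p_value`, `n`, `type`.
#' @export
paired_stats <- function(x, y = 1, ...) {
  if (length(y) == 1) x <- x[is.finite(x)]
  if (length(x) < 6) stop("need at least 6 samples")
  if (length(y) == 1) {
    if (length(unique(x)) == 1 && x[1] == y)
      warning("all samples tied at the null value: test degenerate")
    wt <- suppressWarnings(stats::wilcox.test(x, mu = y, ...))
    type <- "one-sample"
  } else {
    if (length(y) != length(x)) stop("paired samples must align")
    if (all(x == y))
      warning("paired samples identical: test degenerate")
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, ...))
    type <- "paired"
  }
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(x), type = type)
}
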