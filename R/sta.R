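#' Arrange a step sequence into trailing trajectory segments
#'
#' Builds the segment matrix whose row `j` contains the `L` motion steps of
#' frames `j .. j+L-1` (x steps first, then y steps, each in chronological
#' order), paired with the response vector `f` whose element `j` is the
#' spike count in frame `j + L`.  This is the design used by the motion STA,
#' the LN model and the spike-triggered covariance analysis.
#'
#' @param steps `M x 2` step matrix (um), a `motion_trajectory`, or a
#'   numeric vector of one-dimensional steps.
#' @param counts Frame-binned counts of length `M` (optional).
#' @param L Window length in taps.
#' @param normalize Normalize each step component to unit variance (the
#'   scale used by the LN model and STC conditionals).
#' @return List with `Sseg` (`(M-L) x L` or `(M-L) x 2L` matrix), `f`
#'   (length `M-L`, or `NULL`), `L`, `n_axes`.
#' @export
segment_stimulus <- function(steps, counts = NULL, L = default_taps(),
                             normalize = FALSE) {
  if (inherits(steps, "motion_trajectory")) steps <- steps$steps
  if (is.null(dim(steps))) steps <- matrix(steps, ncol = 1)
  m <- nrow(steps)
  if (m <= L) stop("need more frames than filter taps")
  if (normalize) {
    steps <- scale(steps, center = FALSE, scale = apply(steps, 2, stats::sd))
  }
  idx <- outer(seq_len(m - L) - 1L, seq_len(L), "+")
  blocks <- lapply(seq_len(ncol(steps)), function(k) {
    matrix(steps[, k][idx], nrow = m - L)
  })
  Sseg <- do.call(cbind, blocks)
  f <- NULL
  if (!is.null(counts)) {
    if (length(counts) != m) stop("counts must align with the steps")
    f <- counts[(L + 1):m]
  }
  list(Sseg = Sseg, f = f, L = L, n_axes = ncol(steps))
}

#' Motion spike-triggered average
#'
#' The spike-count-weighted average pre-spike trajectory,
#' `a = t(Sseg) %*% f / sum(f)`, split into x and y components (um per
#' frame, chronological: lag `L*dt` down to `dt`).  The preferred-direction
#' vector sums each component over taps, `v = (sum(ax), sum(ay))`, and the
#' preferred angle is its argument.
#'
#' @param steps Steps (`motion_trajectory`, matrix, or 1D vector).
#' @param counts Frame-binned spike counts aligned to the steps.
#' @param L Window length in taps.
#' @return An object of class `motion_sta`: list with `a` (full vector),
#'   `ax`, `ay` (per-axis, `ay` `NULL` for 1D), `magnitude` (`|a|`), `v`,
#'   `angle` (deg), `n_spikes`, `L`.
#' @export
compute_motion_sta <- function(steps, counts, L = default_taps()) {
  seg <- segment_stimulus(steps, counts, L)
  if (sum(seg$f) <= 0) stop("no spikes: motion STA undefined")
  a <- as.numeric(crossprod(seg$Sseg, seg$f) / sum(seg$f))
  ax <- a[seq_len(L)]
  ay <- if (seg$n_axes == 2) a[L + seq_len(L)] else NULL
  v <- c(sum(ax), if (is.null(ay)) 0 else sum(ay))
  structure(
    list(a = a, ax = ax, ay = ay, magnitude = sqrt(sum(a^2)),
         v = v,
         angle = if (seg$n_axes == 2) (atan2(v[2], v[1]) * 180 / pi) %% 360
                 else NA_real_,
         n_spikes = sum(seg$f), L = L, n_axes = seg$n_axes),
    class = "motion_sta")
}

#' @export
print.motion_sta <- function(x, ...) {
  cat(sprintf(
    "<motion_sta> %d taps, %d spikes, |a| = %.3g um%s\n",
    x$L, x$n_spikes, x$magnitude,
    if (is.na(x$angle)) "" else sprintf(", preferred angle %.1f deg", x$angle)))
  invisible(x)
}

#' @export
plot.motion_sta <- function(x, ...) {
  lag <- -(x$L:1) / 30 * 1000
  ylim <- range(c(x$ax, x$ay, 0))
  plot(lag, x$ax, type = "l", col = "black", ylim = ylim,
       xlab = "time before spike (ms)", ylab = "average step (um)", ...)
  if (!is.null(x$ay)) graphics::lines(lag, x$ay, col = "grey50")
  graphics::abline(h = 0, lty = 3)
  if (!is.null(x$ay))
    graphics::legend("topleft", c("x", "y"), col = c("black", "grey50"),
                     lty = 1, bty = "n")
  invisible(x)
}

#' Shuffle test for motion-STA significance
#'
#' Redraws the cell's spike times uniformly over the recording (preserving
#' the spike count), re-bins them, and recomputes the STA magnitude for each
#' shuffle.  The observed STA is significant if its magnitude exceeds the
#' `level` quantile (default 95%) of the shuffle null.
#'
#' @param steps Steps (`motion_trajectory`, matrix, or 1D vector).
#' @param counts Frame-binned spike counts.
#' @param L Window length in taps.
#' @param n_shuffles Number of shuffles (default 1000; fewer than 100 draws
#'   a warning).
#' @param level Null quantile for the significance criterion.
#' @param seed Seed for the shuffles.
#' @return List with `significant`, `magnitude`, `threshold`, `null`
#'   (shuffle magnitudes), `level`.
#' @export
sta_significance <- function(steps, counts, L = default_taps(),
                             n_shuffles = 1000, level = 0.95, seed = 1) {
  if (n_shuffles < 100)
    warning("fewer than 100 shuffles: the null quantile will be unstable")
  seg <- segment_stimulus(steps, counts, L)
  m <- length(counts)
  if (m < 10 * L)
    stop("recording too short for the shuffle test (need >= 10 * L frames)")
  n_spk <- sum(counts)
  if (n_spk == 0) stop("no spikes: significance test undefined")
  obs <- sqrt(sum((crossprod(seg$Sseg, seg$f) / sum(seg$f))^2))
  null <- with_seed(derive_seed(seed, "sta_shuffle"), {
    out <- numeric(n_shuffles)
    chunk <- max(1L, min(n_shuffles, floor(2e7 / m)))
    done <- 0L
    while (done < n_shuffles) {
      k <- min(chunk, n_shuffles - done)
      fm <- matrix(0, m - L, k)
      for (i in seq_len(k)) {
        cs <- tabulate(sample.int(m, n_spk, replace = TRUE), nbins = m)
        fm[, i] <- cs[(L + 1):m]
      }
      A <- crossprod(seg$Sseg, fm)
      tot <- colSums(fm)
      tot[tot == 0] <- 1
      out[done + seq_len(k)] <- sqrt(colSums(sweep(A, 2, tot, "/")^2))
      done <- done + k
    }
    out
  })
  thr <- stats::quantile(null, level, names = FALSE)
  list(significant = obs > thr, magnitude = obs, threshold = thr,
       null = null, level = level)
}
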