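#' Spike-triggered covariance analysis
#'
#' Computes the spike-count-weighted covariance of the pre-spike stimulus
#' segments around the STA,
#' `STC = sum_j f_j (s_j - a)(s_j - a)^T / sum_j f_j`, on the normalized
#' stimulus scale (unit variance per component), performs an
#' eigendecomposition, and selects the eigenvectors of the two largest
#' eigenvalues.  For each selected eigenvector a conditional nonlinearity is
#' estimated from the frames whose projection on the *other* eigenvector is
#' small (`|g| < 0.5`).
#'
#' @param steps Steps (`motion_trajectory`, matrix, or 1D vector).
#' @param counts Frame-binned spike counts.
#' @param L Window length in taps.
#' @param n_bins Bins for the conditional nonlinearities.
#' @param dt Frame interval (s).
#' @param condition_width Half-width of the conditioning window on the other
#'   projection (default 0.5).
#' @return An object of class `stc_result`: list with `stc` (matrix),
#'   `eigenvalues` (descending), `e1`, `e2`, `sta` (normalized-scale STA
#'   vector), `conditional_nls` (list of two [estimate_nonlinearity()]
#'   results), `L`.
#' @export
compute_stc <- function(steps, counts, L = default_taps(), n_bins = 15,
                        dt = 1 / 30, condition_width = 0.5) {
  seg <- segment_stimulus(steps, counts, L, normalize = TRUE)
  f <- seg$f
  if (sum(f) <= 0) stop("no spikes: STC undefined")
  a <- as.numeric(crossprod(seg$Sseg, f) / sum(f))
  X <- sweep(seg$Sseg, 2, a)
  stc <- crossprod(X, X * f) / sum(f)
  stc <- (stc + t(stc)) / 2
  if (all(abs(stc) < 1e-12)) stop("degenerate (rank-0) covariance")
  e <- eigen(stc, symmetric = TRUE)
  e1 <- e$vectors[, 1]
  e2 <- e$vectors[, 2]
  g1 <- as.numeric(seg$Sseg %*% e1)
  g2 <- as.numeric(seg$Sseg %*% e2)
  sel1 <- abs(g2) < condition_width
  sel2 <- abs(g1) < condition_width
  cond <- list(
    estimate_nonlinearity(g1[sel1], f[sel1], n_bins = n_bins, dt = dt),
    estimate_nonlinearity(g2[sel2], f[sel2], n_bins = n_bins, dt = dt))
  structure(
    list(stc = stc, eigenvalues = e$values, e1 = e1, e2 = e2,
         sta = a, conditional_nls = cond, L = L),
    class = "stc_result")
}

#' @export
print.stc_result <- function(x, ...) {
  cat(sprintf(
    "<stc_result> %d x %d matrix, top eigenvalues %.3g, %.3g (next %.3g)\n",
    nrow(x$stc), ncol(x$stc), x$eigenvalues[1], x$eigenvalues[2],
    x$eigenvalues[3]))
  invisible(x)
}

#' Principal angle between a 2D eigenvector plane and a reference plane
#'
#' Largest principal angle between the span of two recovered vectors and the
#' span of two reference filters — the subspace-recovery error of the STC
#' analysis.
#'
#' @param v1,v2 Recovered orthonormal vectors.
#' @param r1,r2 Reference vectors spanning the true filter plane.
#' @return Largest principal angle in degrees.
#' @export
subspace_angle <- function(v1, v2, r1, r2) {
  qa <- qr.Q(qr(cbind(v1, v2)))
  qb <- qr.Q(qr(cbind(r1, r2)))
  s <- svd(crossprod(qa, qb))$d
  s <- pmin(pmax(s, -1), 1)
  max(acos(s)) * 180 / pi
}
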