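#' Segment matrices for stimulus-response canonical correlation analysis
#'
#' Builds sliding 2-s windows (stride one frame): stimulus rows hold the
#' `Lt` x-steps followed by the `Lt` y-steps of the window, response rows
#' hold the `Lt` counts of cell 1 followed by the `Lt` counts of cell 2.
#'
#' @param steps `M x 2` step matrix or `motion_trajectory`.
#' @param counts_pair `M x 2` counts matrix of the cell pair.
#' @param Lt Segment length in frames (default 60 = 2 s at 30 Hz).
#' @return List with `S_seg` and `F_seg` (`(M - Lt + 1) x 2Lt` matrices) and
#'   `Lt`.
#' @export
build_cca_matrices <- function(steps, counts_pair, Lt = 60L) {
  if (inherits(steps, "motion_trajectory")) steps <- steps$steps
  m <- nrow(steps)
  if (nrow(counts_pair) != m) stop("steps and counts must have aligned lengths")
  if (ncol(counts_pair) != 2) stop("CCA operates on cell pairs")
  if (m < Lt + 10) stop("recording too short for 2-s segments")
  idx <- outer(seq_len(m - Lt + 1L) - 1L, seq_len(Lt), "+")
  S_seg <- cbind(matrix(steps[, 1][idx], ncol = Lt),
                 matrix(steps[, 2][idx], ncol = Lt))
  F_seg <- cbind(matrix(counts_pair[, 1][idx], ncol = Lt),
                 matrix(counts_pair[, 2][idx], ncol = Lt))
  list(S_seg = S_seg, F_seg = F_seg, Lt = Lt)
}

#' Canonical correlation analysis of stimulus and response segments
#'
#' Whitens the segment cross-covariance `Csf` by the stimulus covariance
#' (using the exact white-motion identity `Cs = sigma^2 I`) and by the
#' symmetric inverse square root of the response covariance `Cf`
#' (shrinkage-regularized, `Cf + lambda tr(Cf)/dim I`), then applies a
#' singular value decomposition `C = U D V'`.  Components are mapped back to
#' the original spaces, `a_k = Cs^(-1/2) u_k`, `b_k = Cf^(-1/2) v_k`; the
#' singular values `rho_k` are the canonical correlations, in descending
#' order.  The overall sign of each component pair is fixed by making the
#' largest-magnitude element of `a_k` positive.
#'
#' @param S_seg,F_seg Segment matrices from [build_cca_matrices()].
#' @param lambda Shrinkage weight for the response covariance.
#' @param n_components Number of components returned (default 5).
#' @return An object of class `cca_result`: list with `rhos`,
#'   `stim_components` (columns `a_k`), `resp_components` (columns `b_k`),
#'   `resp_corr` (per-component correlation between the two cells' halves),
#'   `Lt`, `sigma`.
#' @export
run_cca <- function(S_seg, F_seg, lambda = 1e-3, n_components = 5) {
  n <- nrow(S_seg)
  Sc <- scale(S_seg, center = TRUE, scale = FALSE)
  Fc <- scale(F_seg, center = TRUE, scale = FALSE)
  Csf <- crossprod(Sc, Fc) / (n - 1)
  sigma2 <- mean(colMeans(Sc^2) * n / (n - 1))
  Cf <- crossprod(Fc) / (n - 1)
  d <- ncol(Cf)
  Cf_r <- Cf + diag(lambda * sum(diag(Cf)) / d, d)
  ef <- eigen(Cf_r, symmetric = TRUE)
  vals <- pmax(ef$values, max(ef$values) * 1e-12)
  Cf_mhalf <- ef$vectors %*% (t(ef$vectors) / sqrt(vals))
  C <- (Csf / sqrt(sigma2)) %*% Cf_mhalf
  sv <- svd(C)
  k <- min(n_components, length(sv$d))
  a <- sv$u[, seq_len(k), drop = FALSE] / sqrt(sigma2)
  b <- Cf_mhalf %*% sv$v[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {  # sign convention: largest |a| element positive
    j <- which.max(abs(a[, i]))
    if (a[j, i] < 0) {
      a[, i] <- -a[, i]
      b[, i] <- -b[, i]
    }
  }
  rhos <- pmin(sv$d[seq_len(k)], 1)
  Lt <- ncol(S_seg) / 2
  resp_corr <- apply(b, 2, function(col)
    component_response_correlation(col, Lt = Lt))
  structure(
    list(rhos = rhos, stim_components = a, resp_components = b,
         resp_corr = resp_corr, Lt = Lt, sigma = sqrt(sigma2),
         eigen_floor = min(ef$values)),
    class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf(
    "<cca_result> %d components over %.1f-s segments; rho = %s\n",
    length(x$rhos), x$Lt / 30,
    paste(sprintf("%.3f", x$rhos), collapse = ", ")))
  cat(sprintf("  response-half correlations: %s\n",
              paste(sprintf("%+.2f", x$resp_corr), collapse = ", ")))
  invisible(x)
}

#' Correlation between the two cells' halves of a response component
#'
#' Pearson correlation between the first and second half of a CCA response
#' component — the activity profiles of the two cells within the component.
#'
#' @param b A response component of length `2 * Lt`.
#' @param Lt Segment length (frames).
#' @return Pearson correlation coefficient.
#' @export
component_response_correlation <- function(b, Lt = length(b) %/% 2) {
  b1 <- b[seq_len(Lt)]
  b2 <- b[Lt + seq_len(Lt)]
  if (stats::sd(b1) == 0 || stats::sd(b2) == 0)
    stop("zero-variance component half: correlation undefined")
  stats::cor(b1, b2)
}
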