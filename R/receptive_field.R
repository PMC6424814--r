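#' Estimate a spatial receptive field from checkerboard white noise
#'
#' Computes the spatiotemporal spike-triggered average over a trailing
#' window, factorizes it into rank-1 spatial x temporal components by
#' singular-value decomposition, and fits a two-dimensional Gaussian to the
#' spatial component (polarity auto-detected; OFF cells give a negative
#' spatial lobe).  Cells with a mean rate below 0.3 Hz are flagged excluded
#' and not fitted.  The fit is flagged unreliable when the spatial
#' component's absolute peak does not exceed 4 SD of its pixel values.
#'
#' @param stim Checkerboard stimulus from
#'   `generate_probe_stimuli("checkerboard", ...)` (or any list with
#'   `frames` array `frames x rows x cols`, `pitch_um`, `dt_s`).
#' @param counts Frame-binned spike counts aligned to the stimulus.
#' @param L_rf STA window length in frames (default 15 = 500 ms).
#' @return An object of class `rf_fit`: list with `excluded`, `reliable`,
#'   `spatial` (rows x cols matrix), `temporal` (length `L_rf`,
#'   chronological), `center` (x, y in um relative to the stimulus center),
#'   `sds` (major/minor SD in um), `orientation` (deg), `polarity`.
#' @export
estimate_receptive_field <- function(stim, counts, L_rf = 15L) {
  frames <- stim$frames
  dt <- stim$dt_s
  pitch <- stim$pitch_um
  d <- dim(frames)
  m <- d[1]; nr <- d[2]; nc <- d[3]
  if (length(counts) != m) stop("stimulus and counts must align")
  rate <- sum(counts) / (m * dt)
  if (rate < 0.3) {
    return(structure(list(excluded = TRUE, reliable = FALSE,
                          mean_rate_hz = rate),
                     class = "rf_fit"))
  }
  x <- matrix(frames, nrow = m) - mean(frames)  # frames x pixels
  f <- counts[(L_rf + 1):m]
  # sta_l for lag l (1 = most recent frame): weighted average of frame j - l
  sta <- matrix(0, L_rf, nr * nc)
  for (l in seq_len(L_rf)) {
    sta[l, ] <- crossprod(x[(L_rf + 1 - l):(m - l), , drop = FALSE], f) / sum(f)
  }
  sv <- svd(sta, nu = 1, nv = 1)
  temporal <- sv$u[, 1] * sv$d[1]
  spatial <- matrix(sv$v[, 1], nr, nc)
  # fix the factorization sign so the temporal peak is positive
  if (temporal[which.max(abs(temporal))] < 0) {
    temporal <- -temporal; spatial <- -spatial
  }
  polarity <- sign(spatial[which.max(abs(spatial))])
  reliable <- max(abs(spatial)) >= 4 * stats::sd(spatial)
  fit <- fit_gaussian2d(spatial * polarity, pitch)
  structure(
    c(list(excluded = FALSE, reliable = reliable, mean_rate_hz = rate,
           spatial = spatial, temporal = rev(temporal),  # chronological
           polarity = polarity),
      fit),
    class = "rf_fit")
}

# Least-squares 2D Gaussian fit (amplitude, center, covariance) to a
# non-negative spatial map; moment-based start values refined with optim.
fit_gaussian2d <- function(map, pitch) {
  nr <- nrow(map); nc <- ncol(map)
  xs <- (seq_len(nc) - (nc + 1) / 2) * pitch
  ys <- (seq_len(nr) - (nr + 1) / 2) * pitch
  w <- pmax(map, 0)^2
  w <- w / sum(w)
  mx <- sum(outer(rep(1, nr), xs) * w)
  my <- sum(outer(ys, rep(1, nc)) * w)
  vx <- sum((outer(rep(1, nr), xs) - mx)^2 * w)
  vy <- sum((outer(ys, rep(1, nc)) - my)^2 * w)
  cxy <- sum((outer(ys, rep(1, nc)) - my) * (outer(rep(1, nr), xs) - mx) * w)
  amp0 <- max(map)
  par0 <- c(amp0, mx, my, log(sqrt(max(vx, pitch^2))),
            log(sqrt(max(vy, pitch^2))), atanh(max(min(
              cxy / sqrt(max(vx * vy, 1e-12)), 0.9), -0.9)))
  X <- outer(rep(1, nr), xs)
  Y <- outer(ys, rep(1, nc))
  obj <- function(p) {
    a <- p[1]; cx <- p[2]; cy <- p[3]
    sx <- exp(p[4]); sy <- exp(p[5]); rho <- tanh(p[6])
    u <- (X - cx) / sx; v <- (Y - cy) / sy
    g <- a * exp(-(u^2 - 2 * rho * u * v + v^2) / (2 * (1 - rho^2)))
    sum((map - g)^2)
  }
  fit <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 300))
  p <- fit$par
  sx <- exp(p[4]); sy <- exp(p[5]); rho <- tanh(p[6])
  # principal axes of the fitted covariance
  cv <- matrix(c(sx^2, rho * sx * sy, rho * sx * sy, sy^2), 2)
  e <- eigen(cv, symmetric = TRUE)
  list(center = c(x = p[2], y = p[3]),
       sds = sqrt(pmax(e$values, 0)),
       orientation = (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180,
       amplitude = p[1])
}

#' @export
print.rf_fit <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<rf_fit> excluded (mean rate %.2f Hz < 0.3 Hz)\n",
                x$mean_rate_hz))
  } else {
    cat(sprintf(
      "<rf_fit> center (%.0f, %.0f) um, SDs (%.0f, %.0f) um, %s polarity%s\n",
      x$center[1], x$center[2], x$sds[1], x$sds[2],
      if (x$polarity < 0) "OFF" else "ON",
      if (x$reliable) "" else " [unreliable]"))
  }
  invisible(x)
}

#' Distance between two fitted receptive fields
#'
#' @param fit_a,fit_b `rf_fit` objects.
#' @return Euclidean distance between fitted centers (um).
#' @export
rf_distance <- function(fit_a, fit_b) {
  sqrt(sum((fit_a$center - fit_b$center)^2))
}
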