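#' Design matrices for the optimal linear decoder
#'
#' Arranges the population response into lagged windows: row `j` of the
#' response matrix holds a leading constant 1 followed, for each cell, by
#' the `L` counts of frames `j .. j+L-1`; it is paired with the motion step
#' of frame `j` (spikes at and shortly after a step carry the information
#' about it).  The time axis is split chronologically: the first
#' `train_frac` of the trajectory trains the filters, the remainder tests
#' them, and windows straddling the boundary are dropped from both blocks so
#' no test frame enters any training window.
#'
#' @param counts `M x n_cells` matrix of frame-binned counts (a vector is
#'   treated as one cell).  Reduced-code sequences (signed) are accepted.
#' @param steps Step targets: `M x 2` matrix, `motion_trajectory`, or a
#'   numeric vector for one-dimensional decoding.
#' @param L Filter length in taps.
#' @param train_frac Fraction of the trajectory used for training.
#' @return An object of class `decoder_design`: list with `F_train`,
#'   `S_train`, `F_test`, `S_test`, `L`, `n_cells`, `train_frac`.
#' @export
build_design <- function(counts, steps, L = default_taps(),
                         train_frac = 0.7) {
  if (inherits(steps, "motion_trajectory")) steps <- steps$steps
  if (is.null(dim(steps))) steps <- matrix(steps, ncol = 1)
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  m <- nrow(steps)
  if (nrow(counts) != m) stop("counts and steps must have aligned lengths")
  if (m <= L) stop("need more frames than filter taps")
  n_cells <- ncol(counts)
  n_rows <- m - L + 1L
  idx <- outer(seq_len(n_rows) - 1L, seq_len(L), "+")
  blocks <- lapply(seq_len(n_cells), function(i) {
    matrix(counts[, i][idx], nrow = n_rows)
  })
  F_all <- cbind(1, do.call(cbind, blocks))
  boundary <- floor(train_frac * m)
  train_rows <- which(seq_len(n_rows) + L - 1L <= boundary)
  test_rows <- which(seq_len(n_rows) > boundary)
  if (length(train_rows) == 0 || length(test_rows) == 0)
    stop("train/test split leaves an empty block")
  structure(
    list(F_train = F_all[train_rows, , drop = FALSE],
         S_train = steps[train_rows, , drop = FALSE],
         F_test = F_all[test_rows, , drop = FALSE],
         S_test = steps[test_rows, , drop = FALSE],
         L = L, n_cells = n_cells, train_frac = train_frac),
    class = "decoder_design")
}

#' Fit the optimal linear decoder
#'
#' Solves the normal equations `B = (F'F)^-1 (F'S)` on the training block —
#' the reverse-correlation filters corrected for the pairwise correlations
#' between the cells' spike trains.  The x and y components are solved
#' independently (columns of `S`).  When the Gram matrix is singular (e.g.
#' duplicated cells), the minimum-norm pseudo-inverse solution is used and a
#' warning is raised.
#'
#' @param design A [build_design()] result.
#' @return An object of class `decoder_filters`: list with `B`
#'   (`(1 + n*L) x n_axes`), `offsets`, `L`, `n_cells`, `pseudo_inverse`.
#' @export
fit_decoder <- function(design) {
  X <- design$F_train
  S <- design$S_train
  G <- crossprod(X)
  ps <- FALSE
  B <- tryCatch(
    solve(G, crossprod(X, S)),
    error = function(e) {
      ps <<- TRUE
      warning("singular Gram matrix: using the minimum-norm pseudo-inverse",
              call. = FALSE)
      sv <- svd(X)
      pos <- sv$d > max(sv$d) * 1e-10
      sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], S)) / sv$d[pos])
    })
  B <- as.matrix(B)
  colnames(B) <- colnames(S) %||% paste0("axis", seq_len(ncol(B)))
  structure(
    list(B = B, offsets = B[1, ], L = design$L, n_cells = design$n_cells,
         pseudo_inverse = ps),
    class = "decoder_filters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decoder_filters <- function(x, ...) {
  cat(sprintf(
    "<decoder_filters> %d cell(s) x %d taps, %d axis/axes%s; offsets %s\n",
    x$n_cells, x$L, ncol(x$B),
    if (x$pseudo_inverse) " (pseudo-inverse)" else "",
    paste(sprintf("%.3g", x$offsets), collapse = ", ")))
  invisible(x)
}

#' Per-cell filter taps of a fitted decoder
#'
#' @param object A `decoder_filters`.
#' @param ... Unused.
#' @return Array `L x n_axes x n_cells` of filter coefficients (offsets
#'   omitted).
#' @export
coef.decoder_filters <- function(object, ...) {
  out <- array(NA_real_, c(object$L, ncol(object$B), object$n_cells),
               dimnames = list(NULL, colnames(object$B), NULL))
  for (i in seq_len(object$n_cells)) {
    rows <- 1 + (i - 1) * object$L + seq_len(object$L)
    out[, , i] <- object$B[rows, , drop = FALSE]
  }
  out
}

#' Reconstruct held-out motion steps
#'
#' Applies the fitted filters to the test block: `U = F'' B`.
#'
#' @param design A [build_design()] result (same `L` and cell set as used
#'   for fitting).
#' @param filters A [fit_decoder()] result.
#' @return An object of class `reconstruction`: list with `U` (test-period
#'   estimates), `S_test` (paired held-out steps), `L`.
#' @export
reconstruct <- function(design, filters) {
  if (ncol(design$F_test) != nrow(filters$B))
    stop("design and filters have mismatched dimensions")
  U <- design$F_test %*% filters$B
  structure(list(U = U, S_test = design$S_test, L = design$L),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  r <- vapply(seq_len(ncol(x$U)), function(k) {
    if (stats::sd(x$U[, k]) == 0) NA_real_ else
      stats::cor(x$U[, k], x$S_test[, k])
  }, 0)
  cat(sprintf(
    "<reconstruction> %d test frames, correlation with stimulus: %s\n",
    nrow(x$U), paste(sprintf("%.3f", r), collapse = ", ")))
  invisible(x)
}

#' @export
plot.reconstruction <- function(x, axis = 1, n_frames = 300, ...) {
  n <- min(n_frames, nrow(x$U))
  tt <- seq_len(n) / 30
  plot(tt, x$S_test[seq_len(n), axis], type = "l", col = "grey60",
       xlab = "time (s)", ylab = "motion step (um)", ...)
  graphics::lines(tt, x$U[seq_len(n), axis], col = "black")
  graphics::legend("topright", c("stimulus", "reconstruction"),
                   col = c("grey60", "black"), lty = 1, bty = "n")
  invisible(x)
}

#' Reduce a cell pair to a single response sequence
#'
#' Element-wise difference (subtractive code) or sum (additive code) of the
#' two cells' binned spike counts; the result is decoded and characterized
#' like a single-cell response.
#'
#' @param counts_i,counts_j Frame-binned counts of the two cells.
#' @param mode `"subtract"` or `"add"`.
#' @return An object of class `reduced_code`: the sequence with `mode`
#'   attached as an attribute.
#' @export
reduce_pair <- function(counts_i, counts_j, mode = c("subtract", "add")) {
  mode <- match.arg(mode)
  if (length(counts_i) != length(counts_j))
    stop("count sequences must have equal length")
  seq <- if (mode == "subtract") counts_i - counts_j else counts_i + counts_j
  structure(seq, mode = mode, class = c("reduced_code", class(seq)))
}

#' Select the motion-opponent axis of a cell pair
#'
#' Picks the spatial axis (x or y) along which the two cells are most
#' motion-opponent: the axis with the larger absolute difference between the
#' peak values of the two motion STAs within 300 ms before the spike.  Ties
#' go to x.
#'
#' @param sta_i,sta_j `motion_sta` objects of the two cells.
#' @param window_s Pre-spike interval for the peak search (s).
#' @param dt Frame interval (s).
#' @return `"x"` or `"y"`.
#' @export
select_opponent_axis <- function(sta_i, sta_j, window_s = 0.3, dt = 1 / 30) {
  if (is.null(sta_i$ay) || is.null(sta_j$ay))
    stop("both STAs must have x and y components")
  L <- sta_i$L
  lag <- (L:1) * dt
  sel <- lag <= window_s + 1e-9
  peak <- function(a) a[sel][which.max(abs(a[sel]))]
  dx <- abs(peak(sta_i$ax) - peak(sta_j$ax))
  dy <- abs(peak(sta_i$ay) - peak(sta_j$ay))
  if (dx >= dy) "x" else "y"
}
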