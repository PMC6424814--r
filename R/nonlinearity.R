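#' Parametric firing-rate nonlinearity
#'
#' Static nonlinearities mapping filtered stimulus drive to firing rate (Hz):
#' \describe{
#'   \item{exponential}{`N(x) = A * exp(B * x)` — monotonic (for `B > 0`).}
#'   \item{ushape}{`N(x) = C + A * x^2 * exp(B * x)` — non-monotonic with a
#'     rate offset `C`; elevated for strong drive of either sign, the source
#'     of direction ambiguity in single cells.}
#'   \item{linear}{`N(x) = max(0, A + B * x)` — rectified linear, used for
#'     purely linear encoding models.}
#' }
#' Defaults give mean rates of a few Hz for unit-variance Gaussian drive,
#' matching the operating range of responsive direction-selective cells.
#'
#' @param kind `"exponential"`, `"ushape"` or `"linear"`.
#' @param A,B,C Coefficients; `C` is used by the ushape form only.
#' @return An object of class `nonlinearity`.
#' @examples
#' nl <- nonlinearity("ushape")
#' rate_at(nl, c(-2, 0, 2))
#' @export
nonlinearity <- function(kind = c("exponential", "ushape", "linear"),
                         A = NULL, B = NULL, C = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    exponential = list(A = 2, B = 1, C = 0),
    ushape      = list(A = 3, B = 0.25, C = 1),
    linear      = list(A = 4, B = 2, C = 0))
  A <- if (is.null(A)) defaults$A else A
  B <- if (is.null(B)) defaults$B else B
  C <- if (is.null(C)) defaults$C else C
  if (A <= 0) stop("'A' must be positive")
  structure(list(kind = kind, A = A, B = B, C = C), class = "nonlinearity")
}

#' Evaluate a nonlinearity
#'
#' @param nl A [nonlinearity()].
#' @param x Filtered stimulus drive (unit-variance scale).
#' @return Firing rate in Hz (non-negative).
#' @export
rate_at <- function(nl, x) {
  r <- switch(nl$kind,
    exponential = nl$A * exp(nl$B * x),
    ushape      = nl$C + nl$A * x^2 * exp(nl$B * x),
    linear      = pmax(0, nl$A + nl$B * x))
  if (any(!is.finite(r)) || any(r < 0))
    stop("nonlinearity produced a negative or non-finite rate")
  r
}

#' @export
print.nonlinearity <- function(x, ...) {
  form <- switch(x$kind,
    exponential = sprintf("N(x) = %.3g * exp(%.3g x)", x$A, x$B),
    ushape      = sprintf("N(x) = %.3g + %.3g x^2 exp(%.3g x)", x$C, x$A, x$B),
    linear      = sprintf("N(x) = max(0, %.3g + %.3g x)", x$A, x$B))
  cat(sprintf("<nonlinearity:%s> %s  [Hz]\n", x$kind, form))
  invisible(x)
}
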