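#' Two-dimensional random-walk motion trajectory
#'
#' Generates the jittering texture trajectory: independent Gaussian motion
#' steps in x and y for every 33-ms frame, with SD `step_sd` (default
#' 22.5 um), each step rounded to a multiple of the screen resolution
#' `quantum` (default 7.5 um).  Rounding is half-away-from-zero and inflates
#' the per-component step SD to sqrt(step_sd^2 + quantum^2/12).
#'
#' @param seed Integer seed; the trajectory is a pure function of
#'   `(seed, n_frames, step_sd, quantum)`.
#' @param n_frames Number of frames M (>= 0).
#' @param step_sd Gaussian step SD in um (> 0).
#' @param quantum Step quantization in um; every emitted step is an integer
#'   multiple of this value.
#'
#' @return An object of class `motion_trajectory`: list with `steps`
#'   (M x 2 matrix of (dx, dy) in um), `step_sd`, `quantum`, `n_frames`,
#'   `seed`.
#' @examples
#' tr <- generate_trajectory(seed = 1, n_frames = 300)
#' all(tr$steps %% 7.5 == 0)
#' @export
generate_trajectory <- function(seed, n_frames, step_sd = 22.5, quantum = 7.5) {
  if (step_sd <= 0) stop("'step_sd' must be positive")
  if (n_frames < 0) stop("'n_frames' must be non-negative")
  n_frames <- as.integer(n_frames)
  steps <- with_seed(seed, {
    raw <- matrix(stats::rnorm(2 * n_frames, sd = step_sd),
                  ncol = 2, dimnames = list(NULL, c("dx", "dy")))
    round_to_quantum(raw, quantum)
  })
  structure(
    list(steps = steps, step_sd = step_sd, quantum = quantum,
         n_frames = n_frames, seed = seed),
    class = "motion_trajectory")
}

# Round half away from zero to the nearest multiple of q.
round_to_quantum <- function(x, q) {
  q * sign(x) * floor(abs(x) / q + 0.5)
}

#' @export
print.motion_trajectory <- function(x, ...) {
  cat(sprintf(
    "<motion_trajectory> %d frames (%.1f s at 30 Hz), step SD %g um, quantum %g um, seed %s\n",
    x$n_frames, x$n_frames / 30, x$step_sd, x$quantum, format(x$seed)))
  if (x$n_frames > 0) {
    d <- colSums(x$steps)
    cat(sprintf("  net displacement: (%.1f, %.1f) um\n", d[1], d[2]))
  }
  invisible(x)
}

#' Flip a trajectory
#'
#' Negates both step components, reversing every motion direction.  Showing a
#' cell the flipped trajectory effectively reverses its preferred direction
#' relative to the original trajectory.
#'
#' @param trajectory A `motion_trajectory`.
#' @return A `motion_trajectory` with negated steps.
#' @export
flip_trajectory <- function(trajectory) {
  trajectory$steps <- -trajectory$steps
  trajectory
}

#' Mean displacement accumulated per second
#'
#' Splits the trajectory into disjoint 1-s windows (30 frames), sums the
#' steps within each window, and averages the Euclidean norm of the net
#' displacement across windows.  For independent Gaussian steps of SD sigma
#' per component, the analytic expectation is the Rayleigh mean
#' `sigma_eff * sqrt(30) * sqrt(pi / 2)` with
#' `sigma_eff = sqrt(sigma^2 + quantum^2 / 12)`.
#'
#' @param trajectory A `motion_trajectory`.
#' @param frames_per_window Frames per averaging window (default 30 = 1 s).
#' @return Mean Euclidean displacement per window, in um.
#' @export
mean_window_displacement <- function(trajectory, frames_per_window = 30L) {
  m <- nrow(trajectory$steps)
  n_win <- m %/% frames_per_window
  if (n_win == 0) return(0)
  idx <- rep(seq_len(n_win), each = frames_per_window)
  used <- seq_len(n_win * frames_per_window)
  dx <- rowsum(trajectory$steps[used, 1], idx)
  dy <- rowsum(trajectory$steps[used, 2], idx)
  mean(sqrt(dx^2 + dy^2))
}
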