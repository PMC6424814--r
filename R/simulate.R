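#' Spike-train container
#'
#' Frame-binned spike counts (and optionally spike times) for a set of cells
#' over one or more trials, aligned to the stimulus clock.  Counts for frame
#' `j` cover the interval `[t_j, t_j + dt)`.
#'
#' @param counts List with one `M x n_cells` integer matrix per trial.
#' @param dt Frame interval in seconds.
#' @param cell_meta Data frame with one row per cell (`cell_id`,
#'   `preferred_direction`, `group`, `rf_x_um`, `rf_y_um`).
#' @param trial_meta Data frame with one row per trial (`trial`,
#'   `transform`).
#' @param spikes Optional list (per trial) of lists (per cell) of sorted
#'   spike times in seconds.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(counts, dt = 1 / 30, cell_meta = NULL,
                            trial_meta = NULL, spikes = NULL) {
  if (is.matrix(counts)) counts <- list(counts)
  n_cells <- ncol(counts[[1]])
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = paste0("cell", seq_len(n_cells)),
                            preferred_direction = NA_real_,
                            group = NA_integer_,
                            rf_x_um = NA_real_, rf_y_um = NA_real_)
  }
  if (is.null(trial_meta)) {
    trial_meta <- data.frame(trial = seq_along(counts),
                             transform = "identity")
  }
  structure(list(counts = counts, dt = dt, cell_meta = cell_meta,
                 trial_meta = trial_meta, spikes = spikes),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  m <- nrow(x$counts[[1]])
  rates <- colSums(x$counts[[1]]) / (m * x$dt)
  cat(sprintf(
    "<spike_train_set> %d cell(s), %d trial(s), %d frames (%.1f s), mean rate %.2f Hz\n",
    ncol(x$counts[[1]]), length(x$counts), m, m * x$dt, mean(rates)))
  invisible(x)
}

#' @export
summary.spike_train_set <- function(object, ...) {
  m <- nrow(object$counts[[1]])
  out <- object$cell_meta
  out$mean_rate_hz <- rowMeans(
    sapply(object$counts, function(cm) colSums(cm) / (m * object$dt)))
  out
}

#' Extract counts for one trial
#'
#' @param set A `spike_train_set`.
#' @param trial Trial index.
#' @param cells Optional cell indices.
#' @return Counts matrix (`M x n_cells`).
#' @export
get_counts <- function(set, trial = 1, cells = NULL) {
  cm <- set$counts[[trial]]
  if (!is.null(cells)) cm <- cm[, cells, drop = FALSE]
  cm
}

# Filtered drive of one model cell for a trajectory (or 1D step sequence),
# per filter component.  Stimulus components are normalized to unit
# variance, filters are unit-norm, so the drive is on the unit-Gaussian
# scale used by the nonlinearities.  Returns a (M - L) x n_components
# matrix aligned so row j corresponds to the count in frame j + L.
ln_drive <- function(cell, steps) {
  if (is.null(dim(steps))) steps <- matrix(steps, ncol = 1)
  z <- scale(steps, center = FALSE,
             scale = apply(steps, 2, stats::sd))
  L <- cell$L
  M <- nrow(z)
  if (M <= L) stop("trajectory must be longer than the filter (L taps)")
  sapply(cell$filters, function(f) {
    if (ncol(f) != ncol(z))
      stop("filter dimensionality does not match the stimulus")
    acc <- 0
    for (k in seq_len(ncol(z))) {
      y <- stats::filter(z[, k], rev(f[, k]), method = "convolution",
                         sides = 1)
      acc <- acc + y
    }
    as.numeric(acc[L:(M - 1)])
  })
}

# Rate (Hz) per frame for a model cell; components sum.
ln_rate <- function(cell, steps) {
  g <- ln_drive(cell, steps)
  r <- 0
  for (k in seq_along(cell$nonlinearities)) {
    r <- r + rate_at(cell$nonlinearities[[k]], g[, k])
  }
  r
}

#' Simulate an LN-Poisson model cell driven by texture motion
#'
#' The motion-step sequence is normalized to unit variance per component and
#' filtered with the cell's unit-norm filter(s); the resulting drive is
#' passed through the nonlinearity to give a rate in Hz (summed over filter
#' components for two-component cells), and the spike count in each frame is
#' drawn from a Poisson distribution with mean `rate * dt`.  The first `L`
#' frames (the filter warm-up) get zero counts.
#'
#' @param cell A [model_cell()].
#' @param trajectory A `motion_trajectory`, or a numeric vector of
#'   one-dimensional motion steps for 1D cells.
#' @param seed Seed for the Poisson spiking noise.
#' @param times Logical; also draw uniform spike times within each frame.
#' @return A [spike_train_set()] with one cell and one trial.
#' @export
simulate_motion_ln_cell <- function(cell, trajectory, seed = 1,
                                    times = FALSE) {
  steps <- if (inherits(trajectory, "motion_trajectory")) trajectory$steps
           else trajectory
  r <- ln_rate(cell, steps)
  m <- if (is.null(dim(steps))) length(steps) else nrow(steps)
  counts <- integer(m)
  counts[(cell$L + 1):m] <- with_seed(derive_seed(seed, "spikes"), {
    stats::rpois(length(r), r * cell$dt)
  })
  cm <- matrix(counts, ncol = 1)
  meta <- data.frame(cell_id = if (is.null(cell$label)) "cell1" else cell$label,
                     preferred_direction = cell$preferred_direction,
                     group = NA_integer_,
                     rf_x_um = cell$rf_center[1], rf_y_um = cell$rf_center[2])
  sts <- spike_train_set(cm, dt = cell$dt, cell_meta = meta)
  if (times) sts$spikes <- list(list(counts_to_times(counts, cell$dt, seed)))
  sts
}

#' Simulate a population of LN-Poisson cells on one trajectory
#'
#' Each cell gets an independent spiking-noise stream derived from `seed`.
#'
#' @param cells List of [model_cell()] objects.
#' @param trajectory A `motion_trajectory` or numeric step vector.
#' @param seed Root seed for the spiking noise.
#' @return A [spike_train_set()] with `length(cells)` cells, one trial.
#' @export
simulate_population <- function(cells, trajectory, seed = 1) {
  steps <- if (inherits(trajectory, "motion_trajectory")) trajectory$steps
           else trajectory
  m <- if (is.null(dim(steps))) length(steps) else nrow(steps)
  cm <- matrix(0L, m, length(cells))
  for (i in seq_along(cells)) {
    r <- ln_rate(cells[[i]], steps)
    cm[(cells[[i]]$L + 1):m, i] <-
      with_seed(derive_seed(seed, paste0("spikes", i)), {
        stats::rpois(length(r), r * cells[[i]]$dt)
      })
  }
  meta <- data.frame(
    cell_id = vapply(seq_along(cells), function(i) {
      if (is.null(cells[[i]]$label)) paste0("cell", i) else cells[[i]]$label
    }, ""),
    preferred_direction = vapply(cells, `[[`, 0, "preferred_direction"),
    group = NA_integer_,
    rf_x_um = vapply(cells, function(c) c$rf_center[1], 0),
    rf_y_um = vapply(cells, function(c) c$rf_center[2], 0))
  spike_train_set(cm, dt = cells[[1]]$dt, cell_meta = meta)
}

# Uniform spike times within each counted frame, sorted.
counts_to_times <- function(counts, dt, seed) {
  idx <- rep(seq_along(counts), counts)
  if (length(idx) == 0) return(numeric(0))
  with_seed(derive_seed(seed, "times"), {
    sort((idx - 1) * dt + stats::runif(length(idx)) * dt)
  })
}

#' Trial protocol
#'
#' Describes repeated presentations of one base trajectory, each trial
#' either unchanged, flipped in both x and y, or with the texture layout
#' translated by 1.5 mm along one axis (which changes the local contrast
#' sequence but not the motion).
#'
#' @param transforms Character vector, one per trial, each `"identity"`,
#'   `"flip"`, or one of `"offset+x"`, `"offset-x"`, `"offset+y"`,
#'   `"offset-y"`.
#' @param offset_um Offset magnitude in um (default 1500).
#' @return An object of class `trial_protocol`.
#' @export
trial_protocol <- function(transforms = c("identity", "identity"),
                           offset_um = 1500) {
  ok <- transforms %in% c("identity", "flip",
                          "offset+x", "offset-x", "offset+y", "offset-y")
  if (!all(ok)) stop("unknown trial transform: ",
                     paste(transforms[!ok], collapse = ", "))
  structure(list(transforms = transforms, n_trials = length(transforms),
                 offset_um = offset_um),
            class = "trial_protocol")
}

# Offset vector in um for a transform label ("identity"/"flip" give 0).
transform_offset <- function(transform, offset_um) {
  switch(transform,
         `offset+x` = c(offset_um, 0), `offset-x` = c(-offset_um, 0),
         `offset+y` = c(0, offset_um), `offset-y` = c(0, -offset_um),
         c(0, 0))
}

#' Simulate repeated trials under a trial protocol
#'
#' Runs the model population once per trial with independent spiking noise.
#' `"flip"` trials see the trajectory with both step components negated
#' (reversing each cell's effective preferred direction relative to the base
#' trajectory); `"offset"` trials see the identical motion but — for
#' texture-driven cells — a translated texture.  For motion-LN cells, whose
#' drive depends only on the motion steps, offset trials differ from
#' identity trials only in their noise.
#'
#' @param cells List of [model_cell()] objects.
#' @param base_trajectory A `motion_trajectory`.
#' @param protocol A [trial_protocol()].
#' @param seed Root seed; each (trial, cell) pair gets an independent
#'   stream.
#' @return A [spike_train_set()] with one counts matrix per trial and the
#'   transform recorded in `trial_meta`.
#' @export
apply_trial_protocol <- function(cells, base_trajectory, protocol, seed = 1) {
  counts <- vector("list", protocol$n_trials)
  for (t in seq_len(protocol$n_trials)) {
    tr <- if (protocol$transforms[t] == "flip") flip_trajectory(base_trajectory)
          else base_trajectory
    sts <- simulate_population(cells, tr, seed = derive_seed(seed, t))
    counts[[t]] <- sts$counts[[1]]
    if (t == 1) meta <- sts$cell_meta
  }
  spike_train_set(counts, dt = cells[[1]]$dt, cell_meta = meta,
                  trial_meta = data.frame(trial = seq_len(protocol$n_trials),
                                          transform = protocol$transforms))
}

#' Pair counts of two cells across trials
#'
#' Selects the count sequences of two cells from (possibly different) trials
#' of a repeated-trial simulation: same-trial pairing keeps shared noise,
#' shuffled pairing (different trials of the identical stimulus) removes
#' noise correlations, flipped/offset pairing selects the corresponding
#' transformed trials.
#'
#' @param set A multi-trial [spike_train_set()].
#' @param i,j Cell indices.
#' @param trial_i,trial_j Trial index for each cell.
#' @return `M x 2` counts matrix.
#' @export
pair_trial_counts <- function(set, i, j, trial_i = 1, trial_j = 1) {
  if (max(trial_i, trial_j) > length(set$counts))
    stop("trial index exceeds the number of simulated trials")
  cbind(set$counts[[trial_i]][, i], set$counts[[trial_j]][, j])
}
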