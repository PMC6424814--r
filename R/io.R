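#' Trajectory file I/O
#'
#' Plain-text trajectory table: header line, one row per frame, columns
#' `frame,dx_um,dy_um` with a 0-based frame index.  The writer/reader pair
#' round-trips exactly (steps are multiples of the quantum, which is
#' representable in decimal).
#'
#' @param trajectory A `motion_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- data.frame(frame = seq_len(trajectory$n_frames) - 1L,
                   dx_um = trajectory$steps[, 1],
                   dy_um = trajectory$steps[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param step_sd,quantum Metadata restored on read (not stored in the
#'   file).
#' @export
read_trajectory <- function(path, step_sd = 22.5, quantum = 7.5) {
  df <- utils::read.csv(path)
  need <- c("frame", "dx_um", "dy_um")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns frame,dx_um,dy_um")
  df <- df[order(df$frame), ]
  structure(
    list(steps = cbind(dx = df$dx_um, dy = df$dy_um),
         step_sd = step_sd, quantum = quantum,
         n_frames = nrow(df), seed = NA_integer_),
    class = "motion_trajectory")
}

#' Spike file I/O
#'
#' Plain-text spike table `cell_id,trial,spike_time_s`, sorted by cell,
#' trial and time.  The reader tolerates unsorted rows (sorting them with a
#' warning).
#'
#' @param set A [spike_train_set()] carrying spike times (`spikes` field).
#' @param path File path.
#' @return `path` (writer) or a data frame of spikes plus, via
#'   [bin_spike_times()], frame-binned counts (reader), invisibly where
#'   appropriate.
#' @export
write_spikes <- function(set, path) {
  if (is.null(set$spikes)) stop("spike_train_set carries no spike times")
  rows <- list()
  for (t in seq_along(set$spikes)) {
    for (i in seq_along(set$spikes[[t]])) {
      st <- set$spikes[[t]][[i]]
      if (length(st) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = set$cell_meta$cell_id[i], trial = t, spike_time_s = st)
      }
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "trial", "spike_time_s")
  if (!all(need %in% names(df)))
    stop("spike file must have columns cell_id,trial,spike_time_s")
  if (is.unsorted(df$spike_time_s[order(df$cell_id, df$trial)])) {
    # per-(cell, trial) time order is what analyses rely on
    key <- paste(df$cell_id, df$trial)
    unsorted <- any(vapply(split(df$spike_time_s, key), is.unsorted, TRUE))
    if (unsorted) warning("spike file not sorted by time: sorting on read")
  }
  df[order(df$cell_id, df$trial, df$spike_time_s), , drop = FALSE]
}

#' Bin spike times at the stimulus clock
#'
#' Counts spikes in frame intervals `[t_j, t_j + dt)`.
#'
#' @param times Spike times (s).
#' @param n_frames Number of frames.
#' @param dt Frame interval (s).
#' @return Integer vector of length `n_frames`.
#' @export
bin_spike_times <- function(times, n_frames, dt = 1 / 30) {
  idx <- floor(times / dt) + 1L
  idx <- idx[idx >= 1 & idx <= n_frames]
  tabulate(idx, nbins = n_frames)
}

#' Decoder filter I/O
#'
#' Long-format table `cell_id,axis,tap,coef`; the offsets are stored as
#' `tap = 0` rows with `cell_id = "offset"`.
#'
#' @param filters A [fit_decoder()] result.
#' @param path File path.
#' @param cell_ids Optional cell identifiers (default `cell1`, `cell2`,
#'   ...).
#' @export
write_decoder_filters <- function(filters, path, cell_ids = NULL) {
  axes <- colnames(filters$B)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(filters$n_cells))
  cf <- coef(filters)
  rows <- list(data.frame(cell_id = "offset",
                          axis = rep(axes, each = 1),
                          tap = 0L, coef = as.numeric(filters$offsets)))
  for (i in seq_len(filters$n_cells)) {
    for (a in seq_along(axes)) {
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = cell_ids[i], axis = axes[a],
        tap = seq_len(filters$L), coef = cf[, a, i])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_decoder_filters
#' @export
read_decoder_filters <- function(path) {
  df <- utils::read.csv(path)
  axes <- unique(df$axis)
  cells <- setdiff(unique(df$cell_id), "offset")
  L <- max(df$tap)
  B <- matrix(NA_real_, 1 + length(cells) * L, length(axes),
              dimnames = list(NULL, axes))
  off <- df[df$cell_id == "offset", ]
  for (a in seq_along(axes)) {
    B[1, a] <- off$coef[off$axis == axes[a]]
    for (i in seq_along(cells)) {
      sel <- df$cell_id == cells[i] & df$axis == axes[a]
      B[1 + (i - 1) * L + seq_len(L), a] <- df$coef[sel][order(df$tap[sel])]
    }
  }
  structure(list(B = B, offsets = B[1, ], L = L, n_cells = length(cells),
                 pseudo_inverse = FALSE),
            class = "decoder_filters")
}

#' Write an experiment report as JSON
#'
#' @param report A list of (nested) numeric results, e.g. the return value
#'   of an experiment driver.
#' @param path File path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
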