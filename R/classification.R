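#' Direction-selectivity index from grating responses
#'
#' Computes the vector-sum direction-selectivity index
#' `DSI = |sum_theta f_theta exp(i theta)| / sum_theta f_theta` from spike
#' counts per grating direction (the onset second of each presentation is
#' excluded upstream when counting), and the preferred angle as the argument
#' of the complex sum.
#'
#' @param counts Spike counts per direction (same order as `angles`).
#' @param angles Direction angles in degrees (default 8 directions, 45
#'   degrees apart).
#' @return An object of class `direction_tuning`: list with `angles`,
#'   `counts`, `dsi`, `preferred_angle` (deg in \[0, 360)).
#' @examples
#' compute_dsi(c(10, 10, 0, 0, 0, 0, 0, 0))  # dsi ~ 0.707, angle 22.5
#' @export
compute_dsi <- function(counts, angles = seq(0, 315, by = 45)) {
  if (length(counts) != length(angles))
    stop("'counts' and 'angles' must have the same length")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero counts: DSI undefined")
  z <- sum(counts * exp(1i * angles * pi / 180))
  structure(
    list(angles = angles, counts = counts,
         dsi = Mod(z) / sum(counts),
         preferred_angle = (Arg(z) * 180 / pi) %% 360),
    class = "direction_tuning")
}

#' @export
print.direction_tuning <- function(x, ...) {
  cat(sprintf("<direction_tuning> DSI %.3f, preferred angle %.1f deg (%d directions)\n",
              x$dsi, x$preferred_angle, length(x$angles)))
  invisible(x)
}

#' Count grating spikes per direction
#'
#' Sums frame-binned counts within each presentation window of a grating
#' schedule, excluding the onset response during the first second of each
#' presentation, and accumulates over repeats.
#'
#' @param counts Frame-binned counts (vector) aligned to the grating movie.
#' @param schedule Schedule data frame from [generate_probe_stimuli()]
#'   (`direction`, `t_on`, `t_off`).
#' @param dt Frame interval (s).
#' @param onset_exclude_s Seconds excluded after each presentation onset.
#' @return Named vector of spike counts per direction angle.
#' @export
grating_direction_counts <- function(counts, schedule, dt = 1 / 30,
                                     onset_exclude_s = 1) {
  tt <- (seq_along(counts) - 1) * dt
  dirs <- sort(unique(schedule$direction))
  out <- vapply(dirs, function(d) {
    rows <- schedule[schedule$direction == d, , drop = FALSE]
    s <- 0
    for (r in seq_len(nrow(rows))) {
      sel <- tt >= rows$t_on[r] + onset_exclude_s & tt < rows$t_off[r]
      s <- s + sum(counts[sel])
    }
    s
  }, 0)
  names(out) <- dirs
  out
}

#' Object-motion-sensitivity index
#'
#' `OMSI = (fd - fc) / (fd + fc)` from spike counts under coherent (`fc`)
#' and differential (`fd`) patch motion.  Values near 1 indicate
#' object-motion-sensitive cells; standard (global-motion) direction-
#' selective cells have OMSI < 0.7.
#'
#' @param fc,fd Spike counts under coherent and differential motion.
#' @return OMSI in \[-1, 1\].
#' @export
compute_omsi <- function(fc, fd) {
  if (fc < 0 || fd < 0) stop("counts must be non-negative")
  if (fc + fd == 0) stop("no spikes under either condition: OMSI undefined")
  (fd - fc) / (fd + fc)
}

#' ON-OFF contrast indices from flashes and flicker
#'
#' Flash index: `(fon - foff) / (fon + foff)` from spike counts in 50-550 ms
#' windows after ON- and OFF-flash onsets; requires a mean rate of at least
#' 1 Hz during the flash stimulus.  Flicker index: the sum of the last
#' 200 ms of the temporal STA divided by the sum of absolute STA values in
#' that range (-1 pure OFF, +1 pure ON); requires the absolute STA peak to
#' exceed 7 times the SD of the STA tail (800-500 ms before the spike).
#'
#' @param flash_counts Frame-binned counts aligned to the flash stimulus.
#' @param flash_schedule Flash schedule data frame (`polarity`, `t_on`).
#' @param flicker_sta Temporal STA from the flicker stimulus, chronological
#'   (oldest lag first), covering at least 800 ms.
#' @param dt Frame interval (s).
#' @param window_s Counting window after flash onset (s), default
#'   `c(0.05, 0.55)`.
#' @return List with `flash_onoff`, `flicker_onoff`, and logical
#'   `flash_included`, `flicker_included`.
#' @export
contrast_indices <- function(flash_counts = NULL, flash_schedule = NULL,
                             flicker_sta = NULL, dt = 1 / 30,
                             window_s = c(0.05, 0.55)) {
  out <- list(flash_onoff = NA_real_, flicker_onoff = NA_real_,
              flash_included = FALSE, flicker_included = FALSE)
  if (!is.null(flash_counts)) {
    tt <- (seq_along(flash_counts) - 1) * dt
    cnt <- function(pol) {
      rows <- flash_schedule[flash_schedule$polarity == pol, , drop = FALSE]
      s <- 0
      for (r in seq_len(nrow(rows))) {
        sel <- tt >= rows$t_on[r] + window_s[1] &
          tt < rows$t_on[r] + window_s[2]
        s <- s + sum(flash_counts[sel])
      }
      s
    }
    fon <- cnt("on"); foff <- cnt("off")
    if (fon + foff == 0) stop("no flash spikes in the counting windows")
    out$flash_onoff <- (fon - foff) / (fon + foff)
    out$flash_included <-
      sum(flash_counts) / (length(flash_counts) * dt) >= 1
  }
  if (!is.null(flicker_sta)) {
    lag <- rev(seq_along(flicker_sta)) * dt  # lag of each tap, descending order
    last200 <- lag <= 0.2 + 1e-9
    tail_sel <- lag >= 0.5 & lag <= 0.8
    denom <- sum(abs(flicker_sta[last200]))
    if (denom == 0) stop("empty flicker STA window")
    out$flicker_onoff <- sum(flicker_sta[last200]) / denom
    tail_sd <- stats::sd(flicker_sta[tail_sel])
    out$flicker_included <- is.finite(tail_sd) && tail_sd > 0 &&
      max(abs(flicker_sta)) >= 7 * tail_sd
  }
  out
}

#' Temporal STA of a full-field stimulus
#'
#' Spike-count-weighted average of the trailing stimulus window, in
#' chronological order (oldest lag first).
#'
#' @param stim Full-field stimulus values per frame (mean-subtracted
#'   internally).
#' @param counts Frame-binned spike counts aligned to `stim`.
#' @param L Window length in taps.
#' @return Numeric STA of length `L`.
#' @export
temporal_sta <- function(stim, counts, L = default_taps()) {
  m <- length(stim)
  if (length(counts) != m) stop("stimulus and counts must align")
  f <- counts[(L + 1):m]
  if (sum(f) == 0) stop("no spikes: STA undefined")
  s <- stim - mean(stim)
  idx <- outer(seq_len(m - L) - 1L, seq_len(L), "+")
  as.numeric(crossprod(matrix(s[idx], nrow = m - L), f) / sum(f))
}

#' Classify cells into standard / object-motion / non-direction-selective
#'
#' A cell is a standard direction-selective cell iff `DSI > 0.3`, its mean
#' rate under gratings exceeds 1 Hz, `OMSI < 0.7`, and its mean rate under
#' the patch stimulus exceeds 1 Hz.  Cells passing the DSI criterion but
#' failing the OMSI criterion are object-motion direction-selective cells.
#' Standard cells are grouped by preferred angle (retinal convention, angle
#' from nasal; positive counterclockwise for a left eye) into nasal-dorsal
#' (0-120], temporal (120-240], nasal-ventral (240-360] groups; a boundary
#' angle belongs to the lower interval.
#'
#' @param dsi,preferred_angle DSI and preferred angle (deg) per cell.
#' @param omsi OMSI per cell (NA when unavailable).
#' @param grating_rate,omsi_rate Mean rates (Hz) under the grating and patch
#'   stimuli.
#' @return Data frame with `label` (`"standard_DS"`, `"object_motion_DS"`,
#'   `"non_DS"`, or `"unclassified"` when OMSI is missing for a DS cell) and
#'   `group` (`"nasal_dorsal"`, `"temporal"`, `"nasal_ventral"` for standard
#'   cells).
#' @export
classify_cells <- function(dsi, preferred_angle, omsi, grating_rate,
                           omsi_rate = grating_rate) {
  n <- length(dsi)
  label <- character(n)
  group <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(dsi[i]) || dsi[i] <= 0.3 || grating_rate[i] <= 1) {
      label[i] <- "non_DS"
    } else if (is.na(omsi[i])) {
      label[i] <- "unclassified"
    } else if (omsi[i] < 0.7 && omsi_rate[i] > 1) {
      label[i] <- "standard_DS"
      group[i] <- direction_group(preferred_angle[i])
    } else {
      label[i] <- "object_motion_DS"
    }
  }
  data.frame(dsi = dsi, preferred_angle = preferred_angle, omsi = omsi,
             label = label, group = group)
}

# Preferred-direction group; boundary angles belong to the lower interval.
direction_group <- function(angle) {
  a <- angle %% 360
  if (a == 0) a <- 360
  if (a <= 120) "nasal_dorsal"
  else if (a <= 240) "temporal"
  else "nasal_ventral"
}
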