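#' Canonical biphasic motion filter template
#'
#' The temporal motion filter used for model direction-selective cells: a
#' difference of two Gaussians in time (lag before the spike) with the main
#' positive lobe peaking at 175 ms and a smaller opposing lobe at short
#' lags, giving a zero crossing near 100 ms.  Returned in chronological
#' order (oldest tap first, i.e. lag `L * dt` down to `dt`) and normalized
#' to unit Euclidean norm.
#'
#' @param L Number of taps (default [default_taps()], 800 ms at 30 Hz).
#' @param dt Frame interval (s).
#' @param peak_s Lag of the main lobe peak (s).
#' @param peak_sd_s Width (SD) of the main lobe (s).
#' @param trough_s Lag of the opposing lobe (s).
#' @param trough_sd_s Width of the opposing lobe (s).
#' @param trough_amp Relative amplitude of the opposing lobe.
#' @return Numeric vector of length `L` with attribute `lag_s` (lag of each
#'   tap, descending).
#' @examples
#' h <- motion_filter_template()
#' sum(h^2)
#' @export
motion_filter_template <- function(L = default_taps(), dt = 1 / 30,
                                   peak_s = 0.175, peak_sd_s = 0.045,
                                   trough_s = 0.055, trough_sd_s = 0.035,
                                   trough_amp = 0.45) {
  lag <- (L:1) * dt  # chronological: oldest first
  h <- exp(-0.5 * ((lag - peak_s) / peak_sd_s)^2) -
    trough_amp * exp(-0.5 * ((lag - trough_s) / trough_sd_s)^2)
  h <- h / sqrt(sum(h^2))
  attr(h, "lag_s") <- lag
  h
}

#' Construct a model direction-selective cell
#'
#' A linear-nonlinear Poisson model cell.  For two-dimensional motion the
#' cell filters the (x, y) step sequence with a spatiotemporal filter that
#' is the temporal template rotated into the preferred direction; optionally
#' a second, orthogonal filter component with its own nonlinearity is added
#' (rates sum over components).  For one-dimensional stimuli supply a single
#' filter vector.
#'
#' @param preferred_direction Preferred direction in degrees (retinal
#'   convention, angle from the nasal direction).
#' @param nonlinearity_kind Kind passed to [nonlinearity()] for the primary
#'   component, or a `nonlinearity` object.
#' @param filters Optional list of filter matrices/vectors; by default one
#'   `L x 2` filter, the template rotated into `preferred_direction`.  Each
#'   filter is normalized to unit Euclidean norm.
#' @param nonlinearities Optional list of `nonlinearity` objects, one per
#'   filter.
#' @param orthogonal Logical; add a second filter along the orthogonal axis
#'   (U-shaped by default), modelling sensitivity to orthogonal motion.
#' @param rf_center Receptive-field center (um), metadata.
#' @param L,dt Filter length and frame interval.
#' @param label Cell label, metadata.
#' @return An object of class `model_cell`.
#' @export
model_cell <- function(preferred_direction = 0,
                       nonlinearity_kind = "exponential",
                       filters = NULL, nonlinearities = NULL,
                       orthogonal = FALSE, rf_center = c(0, 0),
                       L = default_taps(), dt = 1 / 30, label = NULL) {
  nl1 <- if (inherits(nonlinearity_kind, "nonlinearity")) nonlinearity_kind
         else nonlinearity(nonlinearity_kind)
  if (is.null(filters)) {
    h <- motion_filter_template(L, dt)
    th <- preferred_direction * pi / 180
    filters <- list(cbind(dx = cos(th) * h, dy = sin(th) * h))
    if (orthogonal) {
      filters$orth <- cbind(dx = -sin(th) * h, dy = cos(th) * h)
      if (is.null(nonlinearities)) {
        # orthogonal motion modulates the rate through a symmetric U-shape
        nonlinearities <- list(nl1, nonlinearity("ushape", B = 0))
      }
    }
  } else {
    filters <- lapply(filters, function(f) {
      if (is.null(dim(f))) f <- matrix(f, ncol = 1)
      f
    })
  }
  filters <- lapply(filters, function(f) f / sqrt(sum(f^2)))
  if (is.null(nonlinearities)) {
    nonlinearities <- c(list(nl1),
                        rep(list(nonlinearity("ushape")),
                            length(filters) - 1))
  }
  stopifnot(length(nonlinearities) == length(filters))
  structure(
    list(filters = filters, nonlinearities = nonlinearities,
         preferred_direction = preferred_direction %% 360,
         rf_center = rf_center, L = nrow(filters[[1]]), dt = dt,
         label = label),
    class = "model_cell")
}

#' @export
print.model_cell <- function(x, ...) {
  cat(sprintf(
    "<model_cell%s> preferred direction %.0f deg, %d filter component(s) of %d taps, %s nonlinearity\n",
    if (is.null(x$label)) "" else paste0(" ", x$label),
    x$preferred_direction, length(x$filters), x$L,
    x$nonlinearities[[1]]$kind))
  invisible(x)
}

#' Build a model population across the three preferred-direction groups
#'
#' Preferred directions of the modelled direction-selective cells cluster in
#' three groups separated by 120 degrees.  Cells are assigned round-robin to
#' the three group angles (so 6 cells give 2 per group).
#'
#' @param n_cells Number of cells (>= 1).
#' @param direction_groups Three group angles in degrees, 120 degrees apart.
#' @param nonlinearity_kind Nonlinearity kind for all cells.
#' @param rf_centers Optional `n_cells x 2` matrix of receptive-field
#'   centers (um); defaults to centers scattered within +-300 um.
#' @param seed Seed for the receptive-field scatter.
#' @param orthogonal Give each cell a second, symmetric U-shaped component
#'   along the orthogonal axis (the two-component cell; default `TRUE`).
#' @param ... Passed to [model_cell()].
#' @return List of `model_cell` objects with group labels.
#' @export
build_population <- function(n_cells, direction_groups = c(30, 150, 270),
                             nonlinearity_kind = "ushape",
                             rf_centers = NULL, seed = 1,
                             orthogonal = TRUE, ...) {
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  d <- sort(direction_groups %% 360)
  if (length(d) != 3 ||
      max(abs(sort((diff(c(d, d[1] + 360)))) - 120)) > 1e-6)
    stop("'direction_groups' must be three angles separated by 120 degrees")
  if (is.null(rf_centers)) {
    rf_centers <- with_seed(derive_seed(seed, "rf_centers"), {
      matrix(stats::runif(2 * n_cells, -300, 300), ncol = 2)
    })
  }
  group_idx <- ((seq_len(n_cells) - 1) %% 3) + 1
  lapply(seq_len(n_cells), function(i) {
    model_cell(preferred_direction = direction_groups[group_idx[i]],
               nonlinearity_kind = nonlinearity_kind,
               rf_center = rf_centers[i, ], orthogonal = orthogonal,
               label = sprintf("cell%02d_g%d", i, group_idx[i]), ...)
  })
}
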