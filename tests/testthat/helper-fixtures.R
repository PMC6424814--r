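# Shared fixtures, computed once per test run.

fix <- new.env()

# 10-min trajectory used by several encoding/decoding tests
fixture_trajectory <- function() {
  if (is.null(fix$tr)) fix$tr <- generate_trajectory(101, 18000)
  fix$tr
}

# opponent 1D pair (ushape) on the x-steps of the fixture trajectory
fixture_opponent_pair <- function(kind = "ushape") {
  key <- paste0("pair_", kind)
  if (is.null(fix[[key]])) {
    h <- motion_filter_template()
    cells <- list(model_cell(filters = list(h), nonlinearity_kind = kind),
                  model_cell(filters = list(-h), nonlinearity_kind = kind))
    s <- fixture_trajectory()$steps[, 1]
    fix[[key]] <- list(
      cells = cells, s = s,
      counts = get_counts(simulate_population(cells, s, seed = 102)))
  }
  fix[[key]]
}

# wrap angle difference to [0, 180]
angle_error <- function(a, b) abs(((a - b + 180) %% 360) - 180)
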