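#' Decode a response set and measure the information it carries
#'
#' Convenience wrapper chaining [build_design()], [fit_decoder()],
#' [reconstruct()] and [info_lower_bound()]: fits decoder filters on the
#' first 70% of the trajectory and evaluates the spectral information bound
#' on the held-out 30%.
#'
#' @param counts Frame-binned counts (`M x n_cells`, vector, or
#'   `reduced_code`).
#' @param steps Step targets (`motion_trajectory`, matrix, or vector).
#' @param L Filter length in taps.
#' @param train_frac Training fraction.
#' @param filters Optional pre-fitted [fit_decoder()] result (e.g. filters
#'   transferred from another texture); fitted from `counts` when `NULL`.
#' @return List with `info` (an `info_spectrum`), `recon`, `filters`.
#' @export
decode_info <- function(counts, steps, L = default_taps(), train_frac = 0.7,
                        filters = NULL) {
  design <- build_design(counts, steps, L = L, train_frac = train_frac)
  if (is.null(filters)) filters <- fit_decoder(design)
  recon <- reconstruct(design, filters)
  info <- info_lower_bound(recon$S_test, recon$U, L = L)
  list(info = info, recon = recon, filters = filters)
}

#' Population vs single-cell decoding of one response set
#'
#' Decodes the joint population response and each cell individually on the
#' same train/test split, and forms the synergy/redundancy information
#' ratio.
#'
#' @param counts `M x n_cells` counts matrix.
#' @param steps Step targets.
#' @param L,train_frac See [decode_info()].
#' @param eligibility_threshold Passed to [info_ratio()].
#' @return List with `ratio` (an `info_ratio_result`), `i_pop`, `i_singles`.
#' @export
population_info_ratio <- function(counts, steps, L = default_taps(),
                                  train_frac = 0.7,
                                  eligibility_threshold = 0.1) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  i_pop <- decode_info(counts, steps, L, train_frac)$info$total_rate
  i_singles <- vapply(seq_len(ncol(counts)), function(i) {
    decode_info(counts[, i], steps, L, train_frac)$info$total_rate
  }, 0)
  list(ratio = info_ratio(i_pop, i_singles, eligibility_threshold),
       i_pop = i_pop, i_singles = i_singles)
}

#' Opponent-pair LN-model simulation experiment
#'
#' Repeatedly simulates a pair of model cells with opposing filters (the
#' biphasic template and its negative) driven by the same one-dimensional
#' random-walk motion, both cells sharing one nonlinearity shape (monotonic
#' exponential or U-shaped), and measures per run the pair information
#' ratio and the response correlation.  U-shaped nonlinearities make the
#' single-cell readout ambiguous and the pair readout synergistic; monotonic
#' nonlinearities give redundancy.
#'
#' @param nonlinearity_kind `"exponential"` (monotonic) or `"ushape"`.
#' @param n_runs Number of seeded simulation runs.
#' @param duration_s Simulated recording length per run (s).
#' @param seed Root seed.
#' @param step_sd,quantum Trajectory parameters (um).
#' @param L Filter/decoder length in taps.
#' @return Data frame with one row per run: `run`, `ratio`, `i_pop`, `i1`,
#'   `i2`, `r` (count correlation), `eligible`.
#' @export
run_pair_simulation <- function(nonlinearity_kind = c("ushape", "exponential"),
                                n_runs = 100, duration_s = 600, seed = 1,
                                step_sd = 22.5, quantum = 7.5,
                                L = default_taps()) {
  nonlinearity_kind <- match.arg(nonlinearity_kind)
  h <- motion_filter_template(L)
  cells <- list(
    model_cell(filters = list(h), nonlinearity_kind = nonlinearity_kind,
               label = "pref"),
    model_cell(filters = list(-h), nonlinearity_kind = nonlinearity_kind,
               label = "anti"))
  n_frames <- round(duration_s * 30)
  out <- lapply(seq_len(n_runs), function(r) {
    rs <- derive_seed(seed, paste0("pairrun", r))
    tr <- generate_trajectory(derive_seed(rs, "traj"), n_frames,
                              step_sd = step_sd, quantum = quantum)
    steps1d <- tr$steps[, 1]
    sts <- simulate_population(cells, steps1d, seed = derive_seed(rs, "spk"))
    cm <- get_counts(sts)
    pr <- population_info_ratio(cm, steps1d, L = L)
    rc <- response_correlation(cm[, 1], cm[, 2])
    data.frame(run = r, ratio = pr$ratio$ratio, i_pop = pr$i_pop,
               i1 = pr$i_singles[1], i2 = pr$i_singles[2], r = rc$r,
               eligible = pr$ratio$eligible)
  })
  res <- do.call(rbind, out)
  attr(res, "nonlinearity_kind") <- nonlinearity_kind
  res
}

#' Population-size and composition experiment
#'
#' Simulates a mixed population spanning the three preferred-direction
#' groups under two-dimensional texture motion, then decodes subpopulations:
#' information as a function of population size (random subsets), and
#' information ratios for same-direction vs maximally mixed subpopulations.
#'
#' @param n_cells Population size (multiple of 3 recommended).
#' @param subset_sizes Sizes at which information is evaluated.
#' @param nonlinearity_kind Nonlinearity of all cells.
#' @param duration_s Simulated recording length (s).
#' @param n_subsets Random subsets per size.
#' @param seed Root seed.
#' @return List with `size_info` (data frame: size, mean/sd information),
#'   `composition` (data frame: subset type, size, ratio), `cells`.
#' @export
run_population_experiment <- function(n_cells = 6,
                                      subset_sizes = c(1, 2, 3, 6),
                                      nonlinearity_kind = "ushape",
                                      duration_s = 600, n_subsets = 10,
                                      seed = 1) {
  if (max(subset_sizes) > n_cells)
    stop("subset size exceeds the population size")
  cells <- build_population(n_cells, nonlinearity_kind = nonlinearity_kind,
                            seed = seed)
  tr <- generate_trajectory(derive_seed(seed, "poptraj"),
                            round(duration_s * 30))
  sts <- simulate_population(cells, tr, seed = derive_seed(seed, "popspk"))
  cm <- get_counts(sts)
  groups <- ((seq_len(n_cells) - 1) %% 3) + 1

  single_info <- vapply(seq_len(n_cells), function(i) {
    decode_info(cm[, i], tr)$info$total_rate
  }, 0)

  size_info <- do.call(rbind, lapply(subset_sizes, function(sz) {
    vals <- with_seed(derive_seed(seed, paste0("subset", sz)), {
      vapply(seq_len(n_subsets), function(k) {
        sel <- sample(n_cells, sz)
        decode_info(cm[, sel, drop = FALSE], tr)$info$total_rate
      }, 0)
    })
    data.frame(size = sz, mean_info = mean(vals), sd_info = stats::sd(vals))
  }))

  comp <- list()
  for (g in 1:3) {
    sel <- which(groups == g)
    if (length(sel) >= 2) {
      ip <- decode_info(cm[, sel, drop = FALSE], tr)$info$total_rate
      comp[[length(comp) + 1]] <- data.frame(
        type = "same_direction", size = length(sel),
        ratio = ip / sum(single_info[sel]))
    }
  }
  for (sz in intersect(subset_sizes, c(3, 6))) {
    sel <- unlist(lapply(1:3, function(g)
      utils::head(which(groups == g), sz / 3)))
    ip <- decode_info(cm[, sel, drop = FALSE], tr)$info$total_rate
    comp[[length(comp) + 1]] <- data.frame(
      type = "mixed", size = sz, ratio = ip / sum(single_info[sel]))
  }
  list(size_info = size_info, composition = do.call(rbind, comp),
       single_info = single_info, cells = cells)
}

#' Trial-perturbation experiments: noise shuffling and trajectory flipping
#'
#' Compares same-trial decoding of a simulated cell pair with decoding after
#' a trial perturbation:
#' \describe{
#'   \item{noise_shuffle}{Both trials show the identical trajectory; the
#'     perturbed pairing takes the two cells from different trials, removing
#'     (here, by construction absent) noise correlations.  Ratios and
#'     correlations are averaged over all trial combinations of each kind.}
#'   \item{flip}{The second trial shows the trajectory with both components
#'     negated; taking one cell from the flipped trial reverses its
#'     effective preferred direction, exchanging redundancy and synergy.}
#' }
#'
#' @param kind `"noise_shuffle"` or `"flip"`.
#' @param n_runs Number of seeded runs.
#' @param duration_s Trial length (s).
#' @param same_direction Use a same-direction pair (default) or an opponent
#'   pair.
#' @param nonlinearity_kind Nonlinearity of both cells.
#' @param seed Root seed.
#' @return Data frame with per-run `ratio_same`, `ratio_perturbed`, `r_same`,
#'   `r_perturbed`.
#' @export
run_perturbation_experiment <- function(kind = c("noise_shuffle", "flip"),
                                        n_runs = 50, duration_s = 600,
                                        same_direction = TRUE,
                                        nonlinearity_kind = "ushape",
                                        seed = 1) {
  kind <- match.arg(kind)
  h <- motion_filter_template()
  f2 <- if (same_direction) h else -h
  cells <- list(model_cell(filters = list(h),
                           nonlinearity_kind = nonlinearity_kind),
                model_cell(filters = list(f2),
                           nonlinearity_kind = nonlinearity_kind))
  proto <- trial_protocol(c("identity",
                            if (kind == "flip") "flip" else "identity"))
  n_frames <- round(duration_s * 30)
  out <- lapply(seq_len(n_runs), function(r) {
    rs <- derive_seed(seed, paste0(kind, r))
    tr <- generate_trajectory(derive_seed(rs, "traj"), n_frames)
    steps1d <- tr$steps[, 1]
    # simulate trials on the 1D axis: flip negates the steps
    sim_trial <- function(t_idx) {
      s <- if (proto$transforms[t_idx] == "flip") -steps1d else steps1d
      get_counts(simulate_population(
        cells, s, seed = derive_seed(rs, paste0("t", t_idx))))
    }
    c1 <- sim_trial(1)
    c2 <- sim_trial(2)
    ratio_of <- function(cm) population_info_ratio(cm, steps1d)$ratio$ratio
    if (kind == "noise_shuffle") {
      # average over all trial combinations (both trials show the identical
      # stimulus): two same-trial and two cross-trial pairings
      ratio_same <- mean(c(ratio_of(c1), ratio_of(c2)))
      ratio_pert <- mean(c(ratio_of(cbind(c1[, 1], c2[, 2])),
                           ratio_of(cbind(c2[, 1], c1[, 2]))))
      r_same <- mean(c(response_correlation(c1[, 1], c1[, 2])$r,
                       response_correlation(c2[, 1], c2[, 2])$r))
      r_pert <- mean(c(
        response_correlation(c1[, 1], c2[, 2], "shuffled")$r,
        response_correlation(c2[, 1], c1[, 2], "shuffled")$r))
    } else {
      same <- c1
      pert <- cbind(c1[, 1], c2[, 2])
      ratio_same <- ratio_of(same)
      ratio_pert <- ratio_of(pert)
      r_same <- response_correlation(same[, 1], same[, 2])$r
      r_pert <- response_correlation(pert[, 1], pert[, 2])$r
    }
    data.frame(run = r, ratio_same = ratio_same,
               ratio_perturbed = ratio_pert,
               r_same = r_same, r_perturbed = r_pert)
  })
  res <- do.call(rbind, out)
  attr(res, "kind") <- kind
  res
}

#' Texture-generalization experiment
#'
#' Decodes each texture condition's motion trajectory with filters fitted
#' either on the same condition or transferred from the standard condition.
#' Conditions are independent trajectories presented to the same model
#' population (motion-LN cells encode the steps themselves, so filter
#' transfer should be lossless up to estimation noise).
#'
#' @param n_conditions Number of texture conditions (>= 2; condition 1 is
#'   the standard).
#' @param n_cells Cells in the population.
#' @param nonlinearity_kind Nonlinearity of all cells.
#' @param duration_s Length of each condition (s).
#' @param seed Root seed.
#' @return Data frame with per-condition `info_same` and `info_transfer`
#'   (bits/s).
#' @export
run_texture_generalization <- function(n_conditions = 2, n_cells = 3,
                                       nonlinearity_kind = "ushape",
                                       duration_s = 600, seed = 1) {
  if (n_conditions < 2) stop("need the standard plus at least one texture")
  cells <- build_population(n_cells, nonlinearity_kind = nonlinearity_kind,
                            seed = seed)
  n_frames <- round(duration_s * 30)
  runs <- lapply(seq_len(n_conditions), function(k) {
    tr <- generate_trajectory(derive_seed(seed, paste0("tex", k)), n_frames)
    cm <- get_counts(simulate_population(
      cells, tr, seed = derive_seed(seed, paste0("texspk", k))))
    list(tr = tr, cm = cm,
         design = build_design(cm, tr))
  })
  std_filters <- fit_decoder(runs[[1]]$design)
  out <- do.call(rbind, lapply(seq_len(n_conditions), function(k) {
    own <- decode_info(runs[[k]]$cm, runs[[k]]$tr)
    transfer <- reconstruct(runs[[k]]$design, std_filters)
    data.frame(
      condition = k,
      info_same = own$info$total_rate,
      info_transfer = info_lower_bound(transfer$S_test,
                                       transfer$U)$total_rate)
  }))
  out
}
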