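#' Scripted experiments
#'
#' Seeded, reproducible reproductions of the package's three core
#' demonstrations: the acquisition sweep over binning and readout noise in
#' a double well, the barrier-geometry suite comparing fixed-K / BIC / BNP
#' analyses, and the single broad well in which every discrete-state
#' method reports fictitious states. Each returns a plain data.frame of
#' per-condition records; every record is reproducible from its stored
#' seed and configuration (carried in the `"config"` attribute).
#'
#' @name experiments
NULL

.sim_preset <- function(spec, seed, n_steps = 5e4, x0 = 0) {
  simulate_langevin(spec, sim_config(n_steps = n_steps, x0 = x0,
                                     seed = seed))
}

#' Binning/noise sweep in a double well
#'
#' Simulates Langevin trajectories in a double-well potential (T = 300 K,
#' zeta = 2e-4 g/s, dt = 1 us), applies every combination of boxcar bin
#' factor and readout noise level, and records the BIC-selected state
#' count per cell and seed.
#'
#' @param preset potential preset name (default the 2 kT double well).
#' @param bin_factors integer bin factors (default c(1, 10, 100, 1000)).
#' @param sigma_reads readout noise levels, nm (default c(0, 1, 2, 5, 10)).
#' @param n_seeds replicate trajectories per cell (default 5).
#' @param n_steps Langevin steps per trajectory.
#' @param candidate_Ks BIC candidates (default 2:5).
#' @param n_restarts,max_iter EM settings per fit.
#' @param seed base seed; replicate r in a cell uses `seed + r`.
#' @return data.frame: `bin_factor`, `sigma_read`, `seed`, `n_obs`,
#'   `selected_K`, `loglik`, `bic`.
#' @export
run_acquisition_sweep <- function(preset = "doublewell_2kT",
                                  bin_factors = c(1L, 10L, 100L, 1000L),
                                  sigma_reads = c(0, 1, 2, 5, 10),
                                  n_seeds = 5L, n_steps = 5e4,
                                  candidate_Ks = 2:5, n_restarts = 5L,
                                  max_iter = 500L, seed = 1L) {
  spec <- potential_preset(preset)
  rows <- list()
  for (r in seq_len(n_seeds)) {
    traj <- .sim_preset(spec, seed = seed + r, n_steps = n_steps)
    for (B in bin_factors) for (s in sigma_reads) {
      w <- observe(traj, measurement_config(bin_factor = B, sigma_read = s,
                                            seed = seed + 1000L * r))
      sel <- select_by_bic(w, candidate_Ks = candidate_Ks,
                           n_restarts = n_restarts, max_iter = max_iter,
                           seed = seed + r)
      rows[[length(rows) + 1L]] <- data.frame(
        bin_factor = B, sigma_read = s, seed = seed + r,
        n_obs = length(w$w), selected_K = sel$selected_K,
        loglik = sel$selected_fit$loglik, bic = sel$selected_fit$bic)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(preset = preset, n_steps = n_steps,
                              candidate_Ks = candidate_Ks,
                              n_restarts = n_restarts, seed = seed)
  out
}

.bnp_default_for <- function(seed) {
  bnp_config(K_max = 10L, n_sweeps = 600L, burn_in = 300L, seed = seed)
}

#' Barrier-geometry suite
#'
#' Four double-well regimes (high/narrow, lowered, widened, shallow)
#' analyzed without binning or readout noise by a fixed 2-state HMM, BIC
#' state selection, and the Beta-Bernoulli BNP HMM; records the state
#' count each method reports.
#'
#' @param presets preset names (default the four double-well regimes).
#' @param n_seeds replicates per preset.
#' @param n_steps Langevin steps.
#' @param n_steps_bnp trajectory prefix length handed to the BNP sampler
#'   (the Gibbs chain is the costly analysis; the prefix keeps runs
#'   desk-scale).
#' @param candidate_Ks BIC candidates.
#' @param n_restarts EM restarts.
#' @param seed base seed.
#' @return data.frame: `preset`, `seed`, `method`, `n_states`.
#' @export
run_barrier_suite <- function(presets = c("doublewell_high_narrow",
                                          "doublewell_low",
                                          "doublewell_wide",
                                          "doublewell_shallow"),
                              n_seeds = 1L, n_steps = 5e4,
                              n_steps_bnp = 10000L, candidate_Ks = 2:5,
                              n_restarts = 5L, seed = 1L) {
  rows <- list()
  for (p in presets) {
    spec <- potential_preset(p)
    x0 <- if (spec$form == "double_well") -spec$half_separation else 0
    for (r in seq_len(n_seeds)) {
      traj <- .sim_preset(spec, seed = seed + r, n_steps = n_steps,
                          x0 = x0)
      fit2 <- fit_hmm_em(traj, K = 2L, n_restarts = n_restarts,
                         seed = seed + r)
      sel <- select_by_bic(traj, candidate_Ks = candidate_Ks,
                           n_restarts = n_restarts, seed = seed + r)
      wb <- traj$positions[seq_len(min(n_steps_bnp, length(traj$positions)))]
      post <- run_bnp(wb, .bnp_default_for(seed + r))
      add <- function(method, n_states)
        rows[[length(rows) + 1L]] <<- data.frame(
          preset = p, seed = seed + r, method = method,
          n_states = n_states)
      add("fixed2", fit2$params$K)
      add("bic", sel$selected_K)
      add("bnp", post$modal_count)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(presets = presets, n_steps = n_steps,
                              n_steps_bnp = n_steps_bnp,
                              candidate_Ks = candidate_Ks, seed = seed)
  out
}

#' Single broad well: fictitious-state demonstration
#'
#' Simulates the flat-bottomed single-well preset (no binning, no readout
#' noise) and analyzes each trajectory with 2-state and 3-state HMMs, BIC
#' selection, and the BNP HMM. The true potential has one basin; any state
#' count above 1 is an artifact of the discrete-state analysis.
#'
#' The default trajectory length (150 steps) is the preset's calibrated
#' length, frozen together with the preset geometry: the well relaxes in
#' about ten sampling intervals, so a short strongly correlated excursion
#' is what the discrete-state methods see (see the methods vignette).
#'
#' @param n_seeds replicates.
#' @param n_steps Langevin steps.
#' @param n_steps_bnp prefix length for the BNP sampler.
#' @param candidate_Ks BIC candidates.
#' @param n_restarts EM restarts.
#' @param seed base seed.
#' @param keep_fits if `TRUE`, attach the per-seed fit objects as the
#'   `"fits"` attribute (for path-agreement checks).
#' @return data.frame: `seed`, `method`, `n_states`.
#' @export
run_single_well_study <- function(n_seeds = 5L, n_steps = 150L,
                                  n_steps_bnp = 150L, candidate_Ks = 2:5,
                                  n_restarts = 5L, seed = 1L,
                                  keep_fits = FALSE) {
  spec <- potential_preset("singlewell_flat")
  rows <- list()
  fits <- list()
  for (r in seq_len(n_seeds)) {
    traj <- .sim_preset(spec, seed = seed + r, n_steps = n_steps)
    fit2 <- fit_hmm_em(traj, K = 2L, n_restarts = n_restarts,
                       seed = seed + r)
    fit3 <- fit_hmm_em(traj, K = 3L, n_restarts = n_restarts,
                       seed = seed + r)
    sel <- select_by_bic(traj, candidate_Ks = candidate_Ks,
                         n_restarts = n_restarts, seed = seed + r)
    wb <- traj$positions[seq_len(min(n_steps_bnp, length(traj$positions)))]
    post <- run_bnp(wb, .bnp_default_for(seed + r))
    rows[[length(rows) + 1L]] <- data.frame(seed = seed + r,
                                            method = "fixed2",
                                            n_states = fit2$params$K)
    rows[[length(rows) + 1L]] <- data.frame(seed = seed + r,
                                            method = "fixed3",
                                            n_states = fit3$params$K)
    rows[[length(rows) + 1L]] <- data.frame(seed = seed + r,
                                            method = "bic",
                                            n_states = sel$selected_K)
    rows[[length(rows) + 1L]] <- data.frame(seed = seed + r,
                                            method = "bnp",
                                            n_states = post$modal_count)
    if (keep_fits)
      fits[[as.character(seed + r)]] <- list(fit2 = fit2, fit3 = fit3,
                                             selection = sel, bnp = post)
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(n_steps = n_steps, n_steps_bnp = n_steps_bnp,
                              candidate_Ks = candidate_Ks, seed = seed)
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' Align two state paths by greedy label matching and report agreement
#'
#' Labels of `path_b` are greedily matched to labels of `path_a` by
#' emission level (both paths' levels supplied), then the pointwise
#' agreement fraction is returned. Used to compare, e.g., a fixed 3-state
#' Viterbi path with a BIC-selected path.
#'
#' @param path_a,path_b integer state paths of equal length.
#' @param levels_a,levels_b emission levels (nm) indexed by state label.
#' @return Fraction of points on which the aligned paths agree.
#' @export
path_agreement <- function(path_a, path_b, levels_a, levels_b) {
  stopifnot(length(path_a) == length(path_b))
  map <- integer(length(levels_b))
  taken <- rep(FALSE, length(levels_a))
  for (j in order(levels_b)) {
    d <- abs(levels_a - levels_b[j])
    d[taken] <- Inf
    i <- which.min(d)
    map[j] <- i
    taken[i] <- TRUE
  }
  mean(map[path_b] == path_a)
}
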