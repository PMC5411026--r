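#' Run one competition from an inoculum spec and return its metrics
#'
#' Convenience wrapper used by every campaign: generates the inoculum from
#' `ic_seed`, runs the competition with `run_seed`, and returns the one-row
#' metrics table (initial spatial metrics included).
#'
#' @param params A [model_params()].
#' @param scen A [scenario()].
#' @param spec An [inoculum_spec()].
#' @param ic_seed Seed for the inoculum layout.
#' @param run_seed Seed for the competition dynamics.
#' @param record_interval,snapshot_times Passed to [run_competition()].
#' @return A one-row data frame (see [colony_metrics()]).
#' @export
run_single_competition <- function(params, scen = scenario(),
                                   spec = inoculum_spec(),
                                   ic_seed = 1L, run_seed = 1L,
                                   record_interval = 0.5,
                                   snapshot_times = 12) {
  init <- generate_inoculum(spec, base_pixel_um = params$base_pixel_um,
                            lattice_size = params$lattice_size,
                            seed = ic_seed)
  traj <- run_competition(init, params, scen,
                          record_interval = record_interval,
                          snapshot_times = snapshot_times, seed = run_seed)
  cm <- colony_metrics(traj, init = init)
  cm$ic_seed <- ic_seed
  cm$run_seed <- run_seed
  cm
}

#' Phase-diagram sweep over toxin effectivity and switching rate
#'
#' Runs `reps` competitions for every (s_s, s_c) grid cell (the toxin
#' effectivity `s_s = sigma_x * n_tox` is scanned through `sigma_x` at
#' fixed `n_tox`), classifies the outcomes and returns per-cell outcome
#' frequencies. The x-axis converts to producer fraction via
#' `s_c / (s_c + d_con)`.
#'
#' @param s_s_values Toxin effectivities to scan.
#' @param s_c_values Switching rates to scan.
#' @param reps Replicates per cell.
#' @param base_params Base [model_params()].
#' @param spec Inoculum spec.
#' @param master_seed Master seed (cell and replicate seeds derive from it).
#' @param checkpoint_file Optional CSV path; one row is appended per
#'   completed run so interrupted sweeps can be inspected.
#' @return A list: `runs` (per-run metrics), `cells` (per-cell outcome
#'   frequencies with `producer_fraction` column).
#' @export
sweep_phase_diagram <- function(s_s_values, s_c_values, reps = 48,
                                base_params = model_params(),
                                spec = inoculum_spec(), master_seed = 1L,
                                checkpoint_file = NULL) {
  grid <- expand.grid(s_s = s_s_values, s_c = s_c_values)
  runs <- vector("list", nrow(grid) * reps)
  n <- 0L
  for (ci in seq_len(nrow(grid))) {
    p <- base_params
    p$sigma_x <- grid$s_s[ci] / p$n_tox
    p$s_c <- grid$s_c[ci]
    for (r in seq_len(reps)) {
      row <- run_single_competition(
        p, scenario(), spec,
        ic_seed = derive_seed(master_seed, ci, r, 1L),
        run_seed = derive_seed(master_seed, ci, r, 2L),
        snapshot_times = NULL)
      row$s_s <- grid$s_s[ci]
      n <- n + 1L
      runs[[n]] <- row
      if (!is.null(checkpoint_file))
        utils::write.table(row, checkpoint_file, append = file.exists(checkpoint_file),
                           col.names = !file.exists(checkpoint_file),
                           row.names = FALSE, sep = ",")
    }
  }
  runs <- do.call(rbind, runs)
  cells <- do.call(rbind, lapply(split(runs, list(runs$s_s, runs$s_c), drop = TRUE),
    function(d) {
      od <- outcome_distribution(d$outcome)
      data.frame(s_s = d$s_s[1], s_c = d$s_c[1],
                 producer_fraction = d$s_c[1] / (d$s_c[1] + base_params$d_con),
                 outcome = od$outcome, proportion = od$proportion,
                 count = od$count)
    }))
  rownames(cells) <- NULL
  list(runs = runs, cells = cells)
}

#' Producer-fraction sweep over a fixed-initial-condition design
#'
#' Executes the run manifest of [make_fixed_ic_design()]: every frozen
#' inoculum layout is competed `reps` times at every switching rate, the
#' per-run metrics (including the 12 h edge-cluster count) are collected,
#' and per-switching-rate outcome distributions and realized mean producer
#' fractions are summarised. The `runs` table feeds
#' [fit_fc_model_simulation()].
#'
#' @param design Manifest from [make_fixed_ic_design()].
#' @param base_params Base [model_params()] (its `s_c` is overridden per run).
#' @param spec Inoculum spec shared by all initial conditions.
#' @return A list: `runs` (per-run metrics with `ic` label), `by_s_c`
#'   (outcome proportions and mean F_C and realized producer fraction per
#'   switching rate).
#' @export
producer_fraction_sweep <- function(design, base_params = model_params(),
                                    spec = inoculum_spec()) {
  runs <- vector("list", nrow(design))
  for (k in seq_len(nrow(design))) {
    p <- base_params
    p$s_c <- design$s_c[k]
    row <- run_single_competition(p, scenario(), spec,
                                  ic_seed = design$ic_seed[k],
                                  run_seed = design$run_seed[k])
    row$ic <- design$ic[k]
    row$run_id <- design$run_id[k]
    runs[[k]] <- row
  }
  runs <- do.call(rbind, runs)
  by_s_c <- do.call(rbind, lapply(split(runs, runs$s_c), function(d) {
    od <- outcome_distribution(d$outcome)
    data.frame(s_c = d$s_c[1],
               producer_fraction_nominal = d$s_c[1] / (d$s_c[1] + base_params$d_con),
               mean_f_c = mean(d$f_c),
               outcome = od$outcome, proportion = od$proportion)
  }))
  rownames(by_s_c) <- NULL
  list(runs = runs, by_s_c = by_s_c)
}

#' Outcome distributions for the four competitor variants
#'
#' Competes the producer strain (fixed switching rate, 0.9 per hour by
#' default, i.e. a 43 percent producer fraction)
#' against the four competitor configurations: the sensitive baseline
#' (S_RFP), a faster sensitive strain (S_NFP, growth boosted by
#' `boost` relative to baseline), a resistant strain at baseline growth
#' (R_RFP, toxin sensitivity zero) and a faster resistant strain (R_NFP).
#' Seeds are paired across variants so differences are not driven by
#' inoculum sampling.
#'
#' @param base_params Base [model_params()]; `s_c` is fixed to `s_c`.
#' @param reps Replicates per variant.
#' @param s_c Producer switching rate used for all variants.
#' @param boost Growth-rate boost of the NFP (no fluorescent protein)
#'   strains relative to baseline.
#' @param spec Inoculum spec.
#' @param master_seed Master seed.
#' @return A list: `runs` (per-run metrics with `variant` column),
#'   `distributions` (per-variant outcome proportions).
#' @export
competitor_variants <- function(base_params = model_params(), reps = 48,
                                s_c = 0.9, boost = 1.2,
                                spec = inoculum_spec(), master_seed = 1L) {
  variants <- data.frame(
    variant = c("S_RFP", "S_NFP", "R_RFP", "R_NFP"),
    r_mult = c(1, boost, 1, boost),
    sensitive = c(TRUE, TRUE, FALSE, FALSE))
  runs <- vector("list", nrow(variants) * reps)
  n <- 0L
  for (r in seq_len(reps)) {
    ic_seed <- derive_seed(master_seed, r, 1L)
    run_seed <- derive_seed(master_seed, r, 2L)
    for (v in seq_len(nrow(variants))) {
      p <- base_params
      p$s_c <- s_c
      p$r_x <- base_params$r_x * variants$r_mult[v]
      if (!variants$sensitive[v]) p$sigma_x <- 0
      row <- run_single_competition(p, scenario(), spec,
                                    ic_seed = ic_seed, run_seed = run_seed,
                                    snapshot_times = NULL)
      row$variant <- variants$variant[v]
      row$rep <- r
      n <- n + 1L
      runs[[n]] <- row
    }
  }
  runs <- do.call(rbind, runs)
  distributions <- do.call(rbind, lapply(split(runs, runs$variant), function(d) {
    od <- outcome_distribution(d$outcome)
    data.frame(variant = d$variant[1], outcome = od$outcome,
               proportion = od$proportion, count = od$count)
  }))
  rownames(distributions) <- NULL
  list(runs = runs, distributions = distributions)
}

#' Initial-density sweep
#'
#' Repeats the competition at inoculation densities of 1x, 2x, 4x and 8x
#' the standard 150 cells and returns, per density, the outcome
#' distribution and the time-averaged across-replicate variance of the C
#' fraction dynamics ([fc_variance_over_time()]).
#'
#' @param multipliers Density multipliers (subset of 1, 2, 4, 8).
#' @param base_params Base [model_params()]; the sweep honours its `s_c`.
#' @param reps Replicates per density.
#' @param master_seed Master seed.
#' @return A list: `runs`, `distributions`, `variance` (data frame of
#'   density multiplier and the variance statistic).
#' @export
density_sweep <- function(multipliers = c(1, 2, 4, 8),
                          base_params = model_params(s_c = 1.9112),
                          reps = 30, master_seed = 1L) {
  runs <- list()
  var_rows <- list()
  all_fracs <- list()
  n <- 0L
  for (mi in seq_along(multipliers)) {
    spec <- inoculum_spec(density_multiplier = multipliers[mi])
    fracs <- NULL
    for (r in seq_len(reps)) {
      init <- generate_inoculum(spec, base_pixel_um = base_params$base_pixel_um,
                                lattice_size = base_params$lattice_size,
                                seed = derive_seed(master_seed, mi, r, 1L))
      traj <- run_competition(init, base_params,
                              seed = derive_seed(master_seed, mi, r, 2L),
                              snapshot_times = NULL)
      a <- traj$areas
      tot <- a$n_c + a$n_con + a$n_x + a$n_xstop
      fr <- ifelse(tot > 0, (a$n_c + a$n_con) / tot, 0)
      fracs <- rbind(fracs, fr)
      row <- colony_metrics(traj, init = init)
      row$density_multiplier <- multipliers[mi]
      row$rep <- r
      n <- n + 1L
      runs[[n]] <- row
    }
    var_rows[[mi]] <- data.frame(density_multiplier = multipliers[mi],
                                 fc_variance = fc_variance_over_time(fracs))
    all_fracs[[mi]] <- fracs
  }
  runs <- do.call(rbind, runs)
  distributions <- do.call(rbind, lapply(split(runs, runs$density_multiplier),
    function(d) {
      od <- outcome_distribution(d$outcome)
      data.frame(density_multiplier = d$density_multiplier[1],
                 outcome = od$outcome, proportion = od$proportion)
    }))
  rownames(distributions) <- NULL
  list(runs = runs, distributions = distributions,
       variance = do.call(rbind, var_rows), fractions = all_fracs)
}

#' Calibrate the replication rate against a target area curve
#'
#' Scans replication rates over a bracket, simulates single-strain colonies
#' (no producer, no toxin) at each rate, fits the linear-regime slope of
#' the mean area curve, and returns the rate whose slope matches the target
#' curve's slope by linear interpolation between the bracketing rates —
#' the procedure used to anchor the model's growth rates to single-strain
#' control colonies.
#'
#' @param target_curve Data frame `time_h`, `area_um2` of the single-strain
#'   control (use [synthetic_area_curve()] or a simulated curve).
#' @param r_values Bracket of replication rates to scan (>= 2 values).
#' @param base_params Base [model_params()] (rates overridden per scan point).
#' @param reps Single-strain replicates per rate.
#' @param t_end Hours to simulate per colony.
#' @param master_seed Master seed.
#' @return A list: `r_fitted`, `target_slope`, `scan` (data frame of rate
#'   and mean slope).
#' @export
calibrate_growth_rate <- function(target_curve, r_values = c(8, 12, 16, 20),
                                  base_params = model_params(), reps = 5,
                                  t_end = 24, master_seed = 1L) {
  stopifnot(length(r_values) >= 2)
  r_values <- sort(r_values)
  target_slope <- expansion_rate(target_curve)$rate_um2_per_h
  spec <- inoculum_spec(ratio_c_to_x = c(0, 1), require_min_one_c = FALSE)
  scan <- data.frame(r = r_values, slope = NA_real_)
  for (k in seq_along(r_values)) {
    p <- base_params
    p$r_c <- p$r_x <- r_values[k]
    p$s_c <- 0
    p$sigma_x <- 0
    p$t_end <- t_end
    slopes <- vapply(seq_len(reps), function(r) {
      init <- generate_inoculum(spec, base_pixel_um = p$base_pixel_um,
                                lattice_size = p$lattice_size,
                                seed = derive_seed(master_seed, k, r, 1L))
      traj <- run_competition(init, p, snapshot_times = NULL,
                              seed = derive_seed(master_seed, k, r, 2L))
      expansion_rate(traj)$rate_um2_per_h
    }, numeric(1))
    scan$slope[k] <- mean(slopes)
  }
  if (target_slope < min(scan$slope) || target_slope > max(scan$slope))
    stop(sprintf("target slope %.3g outside the simulated bracket [%.3g, %.3g]",
                 target_slope, min(scan$slope), max(scan$slope)))
  r_fitted <- stats::approx(scan$slope, scan$r, xout = target_slope)$y
  list(r_fitted = r_fitted, target_slope = target_slope, scan = scan)
}
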