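#' Model parameters for the lattice competition model
#'
#' Bundles every reaction rate and toxin parameter of the two-strain lattice
#' model. Rates are per hour; replication rates are per orthogonal empty
#' Moore neighbour (diagonal neighbours enter the replication rate scaled by
#' `diag_factor`). The toxin effectivity of the competitor is the product
#' `sigma_x * n_tox`.
#'
#' @param r_c Replication rate of reproducing C cells (per hour, per
#'   orthogonal empty neighbour). The default is calibrated so that an
#'   unperturbed single-strain colony reaches about 4.9 mm diameter at 48 h.
#' @param r_x Replication rate of competitor X cells. Defaults to `r_c`.
#' @param diag_factor Scaling of replication rates towards diagonal
#'   neighbours; 1/2 in the reference model.
#' @param s_c Switching rate of reproducing C cells into the toxin-producing
#'   state C_on (per hour). With the default lysis rate the producer
#'   fraction of the C population is `s_c / (s_c + d_con)`: the default
#'   1.2 per hour corresponds to 50 percent producers, the regime of
#'   strongest C-strain success.
#' @param d_con Lysis rate of C_on cells (per hour). The steady-state
#'   producer ratio is `s_c / d_con`.
#' @param sigma_x Toxin sensitivity of X: the growth-arrest hazard of a
#'   living X cell is `sigma_x` times the local cumulative toxin (per hour).
#' @param n_tox Toxin amount deposited per lysis event (toxin units).
#' @param lambda_tox Decay length of the exponential colicin profile, in
#'   micrometres at zoom level 0. The default (50 um) places the effective
#'   arrest distance — decay length times the log of the accumulated
#'   exposure, roughly ten decay lengths — at the upper edge of the
#'   100-400 um effective toxin range reported for colicins on agar.
#' @param lambda_mode `"physical"` (default): the decay length is fixed in
#'   micrometres at every zoom level. `"lattice"`: fixed in lattice units
#'   instead, so its physical reach grows by 5 at every coarse-graining
#'   event (the convention of toxin profiles defined on the simulation
#'   lattice itself); exposed for sensitivity analyses.
#' @param base_pixel_um Physical pixel size at zoom level 0, in micrometres.
#' @param dt Update time step in hours, or `NULL` (default) to choose, at
#'   each zoom level, the largest step that keeps every single-event
#'   probability at or below `p_cap` and divides the recording interval.
#' @param p_cap Upper bound on any single-event probability per step.
#' @param t_end Simulated competition time in hours.
#' @param tox_cutoff Toxin deposition below this value is truncated (sets
#'   the deposition radius); `0` disables truncation.
#' @param lattice_size Lattice side length in pixels.
#'
#' @return An object of class `colicin_params` (a named list).
#' @export
#' @examples
#' p <- model_params(s_c = 0.02)
#' steady_state_producer_ratio(p)
model_params <- function(r_c = 5.5, r_x = r_c, diag_factor = 0.5,
                         s_c = 1.2, d_con = 1.2, sigma_x = 1500,
                         n_tox = 1.0, lambda_tox = 50,
                         lambda_mode = c("physical", "lattice"),
                         base_pixel_um = 2,
                         dt = NULL, p_cap = 0.05, t_end = 48,
                         tox_cutoff = 1e-10, lattice_size = 250L) {
  lambda_mode <- match.arg(lambda_mode)
  stopifnot(r_c > 0, r_x > 0, s_c >= 0, d_con > 0, sigma_x >= 0,
            n_tox > 0, lambda_tox > 0, base_pixel_um > 0,
            diag_factor > 0, diag_factor <= 1, p_cap > 0, p_cap <= 1,
            t_end > 0, lattice_size >= 25)
  if (!is.null(dt)) {
    stopifnot(dt > 0)
    pmax <- dt * max(r_c, r_x, s_c, d_con)
    if (pmax > p_cap) {
      stop(sprintf(
        "dt = %g gives single-event probability %.3f > p_cap = %g; %s",
        dt, pmax, p_cap, "decrease dt or leave it NULL for automatic choice"))
    }
  }
  structure(list(r_c = r_c, r_x = r_x, diag_factor = diag_factor,
                 s_c = s_c, d_con = d_con, sigma_x = sigma_x, n_tox = n_tox,
                 lambda_tox = lambda_tox, lambda_mode = lambda_mode,
                 base_pixel_um = base_pixel_um,
                 dt = dt, p_cap = p_cap, t_end = t_end,
                 tox_cutoff = tox_cutoff,
                 lattice_size = as.integer(lattice_size)),
            class = "colicin_params")
}

#' @export
print.colicin_params <- function(x, ...) {
  cat("Lattice competition model parameters\n")
  cat(sprintf("  replication: r_C = %g, r_X = %g per h (diagonal factor %g)\n",
              x$r_c, x$r_x, x$diag_factor))
  cat(sprintf("  switching s_C = %g per h, lysis d_Con = %g per h (producer ratio %.4g)\n",
              x$s_c, x$d_con, x$s_c / x$d_con))
  cat(sprintf("  toxin: sigma_x = %g, n_tox = %g (effectivity s_X = %g), lambda = %g um\n",
              x$sigma_x, x$n_tox, x$sigma_x * x$n_tox, x$lambda_tox))
  cat(sprintf("  lattice %d x %d at %g um/pixel, t_end = %g h\n",
              x$lattice_size, x$lattice_size, x$base_pixel_um, x$t_end))
  invisible(x)
}

#' Scenario specification for the C strain's toxin-production programme
#'
#' The reference model switches individual C cells stochastically at rate
#' `s_c`. Alternative scenarios force the whole C population through a
#' deterministic programme or alter how toxin is released:
#'
#' * `"stochastic"` — per-cell stochastic switching and lysis.
#' * `"sync_I"` — C grows without switching for `grow_minutes` (50), pauses
#'   for `pause_minutes` (50), then all C cells release their toxin at once.
#' * `"sync_II"` — C grows for 100 minutes, then releases collectively with
#'   no pause.
#' * `"all_off"` — no cell ever switches (`s_c` forced to 0).
#' * `"non_lysing_all_on"` — every C cell releases toxin upon replication
#'   without dying; replication rate and toxin amount are halved relative to
#'   the stochastic reference.
#'
#' @param mode One of `"stochastic"`, `"sync_I"`, `"sync_II"`, `"all_off"`,
#'   `"non_lysing_all_on"`.
#' @param grow_minutes,pause_minutes Timing of the synchronous programme;
#'   only consulted for the sync modes.
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario("sync_I")
scenario <- function(mode = c("stochastic", "sync_I", "sync_II", "all_off",
                              "non_lysing_all_on"),
                     grow_minutes = NULL, pause_minutes = NULL) {
  mode <- match.arg(mode)
  if (mode == "sync_I") {
    grow_minutes <- grow_minutes %||% 50
    pause_minutes <- pause_minutes %||% 50
  } else if (mode == "sync_II") {
    grow_minutes <- grow_minutes %||% 100
    pause_minutes <- pause_minutes %||% 0
  }
  structure(list(mode = mode,
                 grow_minutes = grow_minutes,
                 pause_minutes = pause_minutes),
            class = "scenario_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario:", x$mode, "\n")
  if (x$mode %in% c("sync_I", "sync_II"))
    cat(sprintf("  grow %g min, pause %g min, then collective release\n",
                x$grow_minutes, x$pause_minutes))
  invisible(x)
}

# Effective kernel-level parameters for a scenario: all_off zeroes switching,
# the non-lysing variant halves replication rate and toxin amount.
scenario_effective_params <- function(params, scen) {
  p <- params
  if (scen$mode == "all_off") p$s_c <- 0
  if (scen$mode == "non_lysing_all_on") {
    p$r_c <- p$r_c / 2
    p$n_tox <- p$n_tox / 2
  }
  p
}

scenario_mode_code <- function(scen) {
  switch(scen$mode,
         stochastic = 0L, all_off = 0L,
         sync_I = 1L, sync_II = 1L,
         non_lysing_all_on = 2L,
         stop("unknown scenario mode: ", scen$mode))
}

#' Analytic steady-state producer ratio and fraction
#'
#' In steady state the producer dynamics `dCon/dt = s_c * C - d_con * Con`
#' give a producer-to-reproducer ratio `Con/C = s_c/d_con`; the corresponding
#' producer fraction of the C population is `s_c / (s_c + d_con)`.
#'
#' @param params A `colicin_params` object (or anything with `s_c`, `d_con`).
#' @return A single number.
#' @export
#' @examples
#' steady_state_producer_ratio(model_params(s_c = 0.015, d_con = 1.2))
steady_state_producer_ratio <- function(params) {
  if (params$d_con == 0) stop("d_con must be positive")
  params$s_c / params$d_con
}

#' @rdname steady_state_producer_ratio
#' @export
steady_state_producer_fraction <- function(params) {
  if (params$s_c + params$d_con == 0) stop("s_c + d_con must be positive")
  params$s_c / (params$s_c + params$d_con)
}

#' Derive a reproducible 31-bit seed from a master seed and indices
#'
#' Campaign functions derive one RNG seed per run from the campaign's master
#' seed and the run's position (cell index, replicate index, ...) with a
#' fixed LCG-style hash, so sweeps are exactly reproducible and cell seeds do
#' not collide in practice.
#'
#' @param master Integer master seed.
#' @param ... Further non-negative integer indices.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 3, 7)
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (k in c(...)) {
    h <- (h * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
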