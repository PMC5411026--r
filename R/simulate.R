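# Largest step that (a) keeps every single-event probability <= p_cap for
# the current (zoom-rescaled) rates and (b) divides `interval` evenly.
# The toxin growth-arrest probability is exempt: 1 - exp(-sigma*tox*dt) is
# the exact integrated probability of a constant hazard, valid for any dt.
choose_dt <- function(params, interval) {
  if (!is.null(params$dt)) {
    nst <- max(1L, ceiling(interval / params$dt - 1e-9))
    return(interval / nst)
  }
  max_rate <- max(params$r_c, params$r_x, params$s_c, params$d_con)
  nst <- max(1L, ceiling(interval * max_rate / params$p_cap - 1e-9))
  interval / nst
}

# Absolute times (hours) of the grow/pause/release programme.
sync_times <- function(scen) {
  if (!scen$mode %in% c("sync_I", "sync_II")) return(list(grow_end = Inf, release = Inf))
  grow_end <- scen$grow_minutes / 60
  list(grow_end = grow_end, release = grow_end + scen$pause_minutes / 60)
}

#' Advance a lattice state by one or more kinetic Monte Carlo steps
#'
#' Low-level single-interval update used by [run_competition()] and exposed
#' for testing. Each step visits every active site in a freshly randomised
#' order: C cells switch to C_on with probability `s_c * dt` or replicate
#' into a uniformly chosen empty Moore neighbour (total probability
#' `r_c * dt` times the diagonal-weighted count of empty neighbours); C_on
#' cells lyse with probability `d_con * dt`, freeing their site and
#' depositing the exponential toxin profile; living X cells are
#' growth-arrested with probability `1 - exp(-sigma_x * toxin * dt)` or
#' replicate at `r_x`. C_on and X_stop never replicate and never revert.
#'
#' @param state A [lattice_state()].
#' @param params A [model_params()].
#' @param scen A [scenario()]; defaults to the stochastic reference.
#' @param n_steps Number of steps to take.
#' @param dt Step size in hours; defaults to the automatic per-zoom choice
#'   for an interval of `n_steps * dt`.
#' @return The advanced `lattice_state`.
#' @export
step_lattice <- function(state, params, scen = scenario(), n_steps = 1L,
                         dt = NULL) {
  eff <- scenario_effective_params(params, scen)
  if (is.null(dt)) dt <- choose_dt(eff, 0.5) # default recording interval
  if (dt * max(eff$r_c, eff$r_x, eff$s_c, eff$d_con) > 1)
    stop("dt * max rate exceeds 1")
  st <- sync_times(scen)
  lambda_px <- if (identical(eff$lambda_mode, "physical"))
    eff$lambda_tox / state$pixel_um else eff$lambda_tox / state$base_pixel_um
  grid <- state$grid + 0L      # force copies: kernel mutates in place
  toxin <- state$toxin + 0
  res <- cpp_advance(grid, toxin, dt, as.integer(n_steps),
                     eff$r_c, eff$r_x, eff$diag_factor, eff$s_c, eff$d_con,
                     eff$sigma_x, eff$n_tox,
                     lambda_px, eff$tox_cutoff,
                     scenario_mode_code(scen), state$time,
                     st$grow_end, st$release,
                     released = state$time >= st$release)
  lattice_state(grid, toxin, zoom_level = state$zoom_level,
                base_pixel_um = state$base_pixel_um,
                time = state$time + res$steps_done * dt)
}

#' Run a full two-strain competition
#'
#' Repeatedly applies the stochastic lattice update, coarse-graining by a
#' factor of five whenever the colony touches the lattice border, and
#' records per-state site counts (and optionally snapshots) on a fixed
#' recording grid. Runs are fully reproducible given `seed`.
#'
#' @param init Initial [lattice_state()], typically from
#'   [generate_inoculum()].
#' @param params A [model_params()].
#' @param scen A [scenario()].
#' @param record_interval Recording interval in hours.
#' @param snapshot_times Times (hours) at which full lattice snapshots are
#'   kept, `"all"` for every recording point, or `NULL` for none. The final
#'   state is always kept. Times are matched to the nearest recording point.
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @param max_zoom_events Abort if more coarse-graining events occur
#'   (runaway growth guard).
#' @return An object of class `competition_trajectory`: a list with
#'   `areas` (data frame: `time_h`, `zoom_level`, `pixel_um`, `n_c`,
#'   `n_con`, `n_x`, `n_xstop`, `area_um2_*` columns), `snapshots` (named
#'   list of `lattice_state`s), `final_state`, `zoom_events`, `params`,
#'   `scenario`, `seed`.
#' @export
#' @examples
#' \donttest{
#' init <- generate_inoculum(inoculum_spec(), seed = 1)
#' traj <- run_competition(init, model_params(s_c = 0.02, t_end = 4), seed = 1)
#' head(traj$areas)
#' }
run_competition <- function(init, params, scen = scenario(),
                            record_interval = 0.5, snapshot_times = 12,
                            seed = NULL, max_zoom_events = 6L) {
  stopifnot(inherits(init, "lattice_state"), inherits(params, "colicin_params"))
  if (!is.null(seed)) set.seed(seed)
  eff <- scenario_effective_params(params, scen)
  st <- sync_times(scen)
  mode <- scenario_mode_code(scen)

  grid <- init$grid + 0L
  toxin <- init$toxin + 0
  zoom <- init$zoom_level
  pixel <- init$base_pixel_um * 5^zoom
  time <- init$time
  released <- time >= st$release
  r_c <- eff$r_c / 5^zoom
  r_x <- eff$r_x / 5^zoom
  s_c <- eff$s_c / 5^zoom
  d_con <- eff$d_con / 5^zoom

  rec_times <- seq(time, params$t_end, by = record_interval)
  if (identical(snapshot_times, "all")) snapshot_times <- rec_times
  keep_snap <- if (is.null(snapshot_times)) rep(FALSE, length(rec_times)) else
    vapply(rec_times, function(t) any(abs(snapshot_times - t) <
                                        record_interval / 2), logical(1))

  nrec <- length(rec_times)
  rec <- matrix(0, nrec, 7,
                dimnames = list(NULL, c("time_h", "zoom_level", "pixel_um",
                                        "n_c", "n_con", "n_x", "n_xstop")))
  snapshots <- list()
  zoom_events <- data.frame(time_h = numeric(0), zoom_level = integer(0))

  record_row <- function(k) {
    tb <- tabulate(grid + 1L, nbins = 5L)
    rec[k, ] <<- c(time, zoom, pixel, tb[2], tb[3], tb[4], tb[5])
    if (keep_snap[k]) {
      snapshots[[sprintf("t%g", rec_times[k])]] <<-
        lattice_state(grid + 0L, toxin + 0, zoom_level = zoom,
                      base_pixel_um = init$base_pixel_um, time = time)
    }
  }
  record_row(1L)

  cur_params <- function() {
    p <- eff
    p$r_c <- r_c
    p$r_x <- r_x
    p$s_c <- s_c
    p$d_con <- d_con
    p
  }

  for (k in seq_len(nrec - 1L)) {
    target <- rec_times[k + 1L]
    while (time < target - 1e-9) {
      if (touches_boundary(grid)) {
        if (zoom + 1L > max_zoom_events)
          stop("more than ", max_zoom_events, " coarse-graining events: runaway run")
        cg <- coarse_grain(lattice_state(grid, toxin, zoom_level = zoom,
                                         base_pixel_um = init$base_pixel_um,
                                         time = time),
                           cur_params())
        grid <- cg$state$grid
        toxin <- cg$state$toxin
        zoom <- cg$state$zoom_level
        pixel <- cg$state$pixel_um
        r_c <- cg$params$r_c
        r_x <- cg$params$r_x
        s_c <- cg$params$s_c
        d_con <- cg$params$d_con
        zoom_events <- rbind(zoom_events,
                             data.frame(time_h = time, zoom_level = zoom))
      }
      remaining <- target - time
      dt <- choose_dt(cur_params(), remaining)
      nst <- max(1L, round(remaining / dt))
      lambda_px <- if (identical(eff$lambda_mode, "physical"))
        eff$lambda_tox / pixel else eff$lambda_tox / init$base_pixel_um
      res <- cpp_advance(grid, toxin, dt, nst, r_c, r_x, eff$diag_factor,
                         s_c, d_con, eff$sigma_x, eff$n_tox,
                         lambda_px, eff$tox_cutoff,
                         mode, time, st$grow_end, st$release, released)
      released <- res$released
      if (res$steps_done == 0 && !res$boundary_hit)
        stop("simulation stalled") # defensive; cannot happen
      time <- time + res$steps_done * dt
    }
    time <- target # absorb 1e-9-scale float drift
    record_row(k + 1L)
  }

  final_state <- lattice_state(grid, toxin, zoom_level = zoom,
                               base_pixel_um = init$base_pixel_um, time = time)
  areas <- as.data.frame(rec)
  areas$area_um2_c <- areas$n_c * areas$pixel_um^2
  areas$area_um2_con <- areas$n_con * areas$pixel_um^2
  areas$area_um2_x <- areas$n_x * areas$pixel_um^2
  areas$area_um2_xstop <- areas$n_xstop * areas$pixel_um^2
  areas$area_um2_total <- with(areas, area_um2_c + area_um2_con +
                                 area_um2_x + area_um2_xstop)
  structure(list(areas = areas, snapshots = snapshots,
                 final_state = final_state, zoom_events = zoom_events,
                 params = params, scenario = scen, seed = seed),
            class = "competition_trajectory")
}

#' @export
print.competition_trajectory <- function(x, ...) {
  a <- x$areas[nrow(x$areas), ]
  cat(sprintf("competition_trajectory: %.1f h, %d recordings, %d zoom events\n",
              a$time_h, nrow(x$areas), nrow(x$zoom_events)))
  cat(sprintf("  final: C=%d C_on=%d X=%d X_stop=%d (total %.3g um^2, F_C = %.3f)\n",
              a$n_c, a$n_con, a$n_x, a$n_xstop, a$area_um2_total,
              final_fraction(x)))
  invisible(x)
}

#' Well-mixed producer-pool surrogate
#'
#' Simulates the producer dynamics of a constant reproducing population:
#' `n_c` reproducing cells each switch into the producing state at rate
#' `s_c` (their slot is immediately refilled, i.e. replication exactly
#' balances the switching loss, as in the steady-state assumption), and
#' each producer lyses at rate `d_con`. The long-run time average of
#' producers / reproducers converges to `s_c / d_con`.
#'
#' @param n_c Size of the constant reproducing pool.
#' @param s_c,d_con Switching and lysis rates (per hour).
#' @param t_end Simulated hours.
#' @param dt Step in hours (event probabilities per step must stay small).
#' @param burn_in Hours discarded before averaging.
#' @param seed Optional RNG seed.
#' @return A list: `ratio_mean` (time-averaged Con/C), `ratio_se` (batch-
#'   means standard error, 20 batches), `series` (data frame of time and
#'   producer count).
#' @export
#' @examples
#' simulate_producer_pool(500, s_c = 0.015, d_con = 1.2, t_end = 50, seed = 1)$ratio_mean
simulate_producer_pool <- function(n_c, s_c, d_con, t_end, dt = NULL,
                                   burn_in = NULL, seed = NULL) {
  stopifnot(n_c >= 1, s_c >= 0, d_con > 0, t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dt)) dt <- min(0.05 / max(s_c, d_con), t_end / 100)
  if (is.null(burn_in)) burn_in <- min(t_end / 2, 10 / d_con)
  nst <- ceiling(t_end / dt)
  con <- 0L
  out <- integer(nst)
  for (k in seq_len(nst)) {
    births <- stats::rbinom(1L, n_c, s_c * dt)
    deaths <- if (con > 0) stats::rbinom(1L, con, d_con * dt) else 0L
    con <- con + births - deaths
    out[k] <- con
  }
  times <- seq_len(nst) * dt
  keep <- times > burn_in
  ratios <- out[keep] / n_c
  nb <- 20L
  batches <- split(ratios, cut(seq_along(ratios), nb, labels = FALSE))
  bm <- vapply(batches, mean, numeric(1))
  list(ratio_mean = mean(ratios),
       ratio_se = stats::sd(bm) / sqrt(nb),
       series = data.frame(time_h = times, n_con = out))
}
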