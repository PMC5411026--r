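# Small fast lattices for dynamics tests: 50 x 50 at 2 um/pixel.
small_state <- function(fill_fun, n = 50) {
  g <- matrix(0L, n, n)
  g <- fill_fun(g)
  lattice_state(g, base_pixel_um = 2)
}

test_that("neutral two-strain growth only ever produces AGAR, C and X", {
  st <- small_state(function(g) {
    g[20, 20] <- SITE_STATES[["C"]]; g[30, 30] <- SITE_STATES[["X"]]; g
  })
  p <- model_params(s_c = 0, sigma_x = 0, r_c = 2, lattice_size = 50L)
  set.seed(1)
  for (k in 1:10) {
    st <- step_lattice(st, p, n_steps = 20L, dt = 0.01)
    expect_true(all(st$grid %in% SITE_STATES[c("AGAR", "C", "X")]))
  }
  expect_gt(sum(st$grid == SITE_STATES[["C"]]), 1)
  expect_gt(sum(st$grid == SITE_STATES[["X"]]), 1)
})

test_that("producer lifetimes are exponential with mean 1/d_con", {
  # many isolated producers, no other dynamics: count survivors over time
  # (interior fill: an occupied border would trigger the coarse-grain stop)
  g <- matrix(0L, 50, 50)
  g[2:49, 2:49] <- SITE_STATES[["C_ON"]]
  n_cells <- 48 * 48
  st <- lattice_state(g, base_pixel_um = 2)
  p <- model_params(s_c = 0, sigma_x = 0, r_c = 1, d_con = 1.2,
                    lattice_size = 50L)
  set.seed(2)
  dt <- 0.01
  # mean lifetime of the discrete geometric waiting time is dt/p = 1/d_con
  # up to O(dt); accumulate lysis times by watching survivor counts
  survivors <- sum(st$grid == SITE_STATES[["C_ON"]])
  total_lifetime <- 0
  t <- 0
  while (survivors > 0 && t < 20) {
    st <- step_lattice(st, p, n_steps = 1L, dt = dt)
    t <- t + dt
    now <- sum(st$grid == SITE_STATES[["C_ON"]])
    total_lifetime <- total_lifetime + (survivors - now) * t
    survivors <- now
  }
  mean_lt <- total_lifetime / n_cells
  se <- (1 / 1.2) / sqrt(n_cells)
  expect_lt(abs(mean_lt - 1 / 1.2), 3 * se + dt)
})

test_that("no trajectory contains reverse transitions", {
  # C_on never reverts to C; X_stop is permanent
  st <- generate_inoculum(inoculum_spec(), seed = 3)
  p <- model_params(s_c = 2, d_con = 0.5, sigma_x = 1500, t_end = 3)
  set.seed(3)
  prev <- st
  for (k in 1:60) {
    nxt <- step_lattice(prev, p, n_steps = 1L, dt = 0.05)
    # in one step a producer site can only persist or lyse to agar (which a
    # later-acting neighbour may recolonise); it can never revert in place
    # to a surviving producer-lineage cell by any single transition
    was_con <- prev$grid == SITE_STATES[["C_ON"]]
    expect_true(all(nxt$grid[was_con] %in%
                      SITE_STATES[c("C_ON", "AGAR", "C", "X")]))
    # a site that was X_stop stays X_stop
    was_stop <- prev$grid == SITE_STATES[["X_STOP"]]
    expect_true(all(nxt$grid[was_stop] == SITE_STATES[["X_STOP"]]))
    # X_stop count is monotone non-decreasing between zoom events
    expect_gte(sum(nxt$grid == SITE_STATES[["X_STOP"]]),
               sum(prev$grid == SITE_STATES[["X_STOP"]]))
    # toxin monotone non-decreasing
    expect_true(all(nxt$toxin >= prev$toxin - 1e-12))
    prev <- nxt
  }
})

test_that("a lysed producer site reverts to recolonisable agar", {
  g <- matrix(0L, 25, 25)
  g[12, 12] <- SITE_STATES[["C_ON"]]
  g[12, 13] <- SITE_STATES[["C"]]
  st <- lattice_state(g)
  p <- model_params(s_c = 0, d_con = 50, r_c = 4, sigma_x = 0,
                    lattice_size = 25L, p_cap = 0.6)
  set.seed(9)
  st2 <- step_lattice(st, p, n_steps = 150L, dt = 0.01)
  # producer is long gone; its site may now hold a C descendant or agar
  expect_true(st2$grid[12, 12] %in% SITE_STATES[c("AGAR", "C")])
  expect_gt(sum(st2$grid == SITE_STATES[["C"]]), 10)
  expect_equal(sum(st2$grid == SITE_STATES[["C_ON"]]), 0)
})

test_that("toxin arrest hazard follows 1 - exp(-sigma*toxin*dt)", {
  # uniform toxin field, isolated X cells, no growth: one-step arrest
  # frequency matches the analytic probability
  n <- 50
  g <- matrix(0L, n, n)
  g[2:49, 2:49] <- SITE_STATES[["X"]]
  tox <- matrix(0.002, n, n)
  st <- lattice_state(g, tox)
  p <- model_params(s_c = 0, sigma_x = 300, r_x = 1, lattice_size = 50L)
  set.seed(4)
  dt <- 0.05
  st2 <- step_lattice(st, p, n_steps = 1L, dt = dt)
  p_stop <- 1 - exp(-300 * 0.002 * dt)
  observed <- sum(st2$grid == SITE_STATES[["X_STOP"]]) / (48 * 48)
  se <- sqrt(p_stop * (1 - p_stop) / (48 * 48))
  expect_lt(abs(observed - p_stop), 4 * se)
})

test_that("well-mixed producer pool converges to the analytic ratio", {
  for (pars in list(c(0.02, 0.02), c(0.015, 1.2), c(0.155, 1.2))) {
    res <- simulate_producer_pool(n_c = 2000, s_c = pars[1], d_con = pars[2],
                                  t_end = 60 / min(pars[2], 1),
                                  seed = round(1000 * pars[1]))
    expect_lt(abs(res$ratio_mean - pars[1] / pars[2]), 3 * res$ratio_se)
  }
})

test_that("full runs are bitwise reproducible under a fixed seed", {
  init <- generate_inoculum(inoculum_spec(), seed = 5)
  p <- model_params(s_c = 1.2, t_end = 6)
  t1 <- run_competition(init, p, seed = 77)
  t2 <- run_competition(init, p, seed = 77)
  expect_identical(t1$areas, t2$areas)
  expect_identical(t1$final_state$grid, t2$final_state$grid)
  expect_identical(t1$final_state$toxin, t2$final_state$toxin)
  t3 <- run_competition(init, p, seed = 78)
  expect_false(identical(t1$final_state$grid, t3$final_state$grid))
})

test_that("trajectory bookkeeping: monotone time, conserved site totals", {
  init <- generate_inoculum(inoculum_spec(), seed = 6)
  p <- model_params(s_c = 1.2, t_end = 8)
  traj <- run_competition(init, p, seed = 8, snapshot_times = "all")
  a <- traj$areas
  expect_true(all(diff(a$time_h) > 0))
  expect_true(all(a$n_c + a$n_con + a$n_x + a$n_xstop +
                    0 <= 250 * 250)) # occupied never exceeds the lattice
  # snapshots recorded on the requested grid
  expect_equal(length(traj$snapshots), nrow(a))
})

test_that("sync scenarios follow the grow/pause/collective-release programme", {
  init <- generate_inoculum(inoculum_spec(), seed = 7)
  p <- model_params(t_end = 4)
  # scenario I: no producers before release; all C gone just after 100 min
  tr1 <- run_competition(init, p, scenario("sync_I"), record_interval = 0.25,
                         snapshot_times = NULL, seed = 9)
  a1 <- tr1$areas
  expect_true(all(a1$n_con == 0))
  first_zoom <- if (nrow(tr1$zoom_events)) tr1$zoom_events$time_h[1] else Inf
  pre <- a1$time_h < min(50 / 60, first_zoom)
  expect_true(all(diff(a1$n_c[pre]) >= 0))
  post <- a1$time_h > 100 / 60 + 1e-9
  expect_true(all(a1$n_c[post] == 0))
  # the pause: C count frozen between 50 and 100 min
  mid <- a1$time_h >= 50 / 60 + 1e-9 & a1$time_h <= 100 / 60 + 1e-9
  expect_true(all(diff(a1$n_c[mid]) == 0))
  # toxin was actually released at the release time
  expect_gt(sum(tr1$final_state$toxin), 0)

  # scenario II: release directly after 100 min of growth
  tr2 <- run_competition(init, p, scenario("sync_II"), record_interval = 0.25,
                         snapshot_times = NULL, seed = 10)
  a2 <- tr2$areas
  expect_true(all(a2$n_con == 0))
  expect_true(all(a2$n_c[a2$time_h > 100 / 60 + 1e-9] == 0))
  grow2 <- a2$time_h < 100 / 60
  expect_gt(sum(a2$n_c[grow2] > 0), 0)
})

test_that("the all-off scenario never produces toxin or producers", {
  init <- generate_inoculum(inoculum_spec(), seed = 11)
  p <- model_params(s_c = 1.2, t_end = 6)
  tr <- run_competition(init, p, scenario("all_off"), seed = 12,
                        snapshot_times = NULL)
  expect_true(all(tr$areas$n_con == 0))
  expect_true(all(tr$areas$n_xstop == 0))
  expect_equal(sum(tr$final_state$toxin), 0)
})

test_that("the non-lysing all-on scenario releases toxin without death", {
  init <- generate_inoculum(inoculum_spec(), seed = 13)
  p <- model_params(t_end = 4)
  tr <- run_competition(init, p, scenario("non_lysing_all_on"), seed = 14,
                        snapshot_times = NULL)
  a <- tr$areas
  expect_true(all(a$n_con == 0))
  # C never dies in this variant: counts are non-decreasing between zooms
  zt <- tr$zoom_events$time_h
  seg <- findInterval(a$time_h, c(-Inf, zt + 1e-9))
  for (sg in unique(seg)) {
    idx <- which(seg == sg)
    if (length(idx) > 1) expect_true(all(diff(a$n_c[idx]) >= 0))
  }
  expect_gt(sum(tr$final_state$toxin), 0)
})

test_that("resistant competitors are never growth-arrested", {
  init <- generate_inoculum(inoculum_spec(), seed = 15)
  p <- model_params(s_c = 1.2, sigma_x = 0, t_end = 8)
  tr <- run_competition(init, p, seed = 16, snapshot_times = NULL)
  expect_true(all(tr$areas$n_xstop == 0))
  expect_gt(sum(tr$final_state$toxin), 0) # toxin flows, X ignores it
})
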