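make_state <- function(fill, base_pixel_um = 2) {
  g <- matrix(0L, 40, 40)
  for (f in fill) g[f$i, f$j] <- f$s
  lattice_state(g, base_pixel_um = base_pixel_um)
}

test_that("spatial initial metrics: single point and symmetric pair", {
  # one C cell at 50 px right of an X blob centred at the colony centroid
  g <- matrix(0L, 250, 250)
  g[101:120, 101:120] <- SITE_STATES[["X"]] # 400 X sites, centroid (110.5, 110.5)
  st <- lattice_state(g)
  occ_center <- c(110.5, 110.5)
  g[110, 160] <- SITE_STATES[["C"]]
  st <- lattice_state(g)
  m <- initial_spatial_metrics(st)
  center <- colMeans(which(g != 0, arr.ind = TRUE))
  want <- sqrt(sum((c(110, 160) - center)^2)) * 2
  expect_equal(m$n_c0, 1)
  expect_equal(m$r_c0, want)
  expect_equal(m$d_c0, 0)

  # two C cells symmetric about the colony centre: r_c0 = 0, d_c0 = d
  g2 <- matrix(0L, 250, 250)
  g2[125, 105] <- SITE_STATES[["C"]]
  g2[125, 145] <- SITE_STATES[["C"]]
  m2 <- initial_spatial_metrics(lattice_state(g2))
  expect_equal(m2$r_c0, 0)
  expect_equal(m2$d_c0, 20 * 2) # 20 px from the C centroid, 2 um/px
  # literal reading of the spread formula is identically zero
  expect_equal(initial_spatial_metrics(lattice_state(g2), literal = TRUE)$d_c0, 0)
})

test_that("spatial metrics match the double-loop oracle on random layouts", {
  set.seed(7)
  for (k in 1:20) {
    g <- matrix(0L, 120, 120)
    occ <- sample(120 * 120, 400)
    g[occ] <- SITE_STATES[["X"]]
    g[sample(occ, 50)] <- SITE_STATES[["C"]]
    st <- lattice_state(g, base_pixel_um = 2)
    got <- initial_spatial_metrics(st)
    want <- oracle_spatial_metrics(st)
    expect_equal(got$n_c0, want$n_c0)
    expect_equal(got$r_c0, want$r_c0, tolerance = 1e-12)
    expect_equal(got$d_c0, want$d_c0, tolerance = 1e-12)
  }
  expect_error(initial_spatial_metrics(lattice_state(matrix(0L, 5, 5))))
})

test_that("spatial metrics are invariant under 90-degree rotation", {
  set.seed(8)
  g <- matrix(0L, 100, 100)
  occ <- sample(100 * 100, 300)
  g[occ] <- SITE_STATES[["X"]]
  g[sample(occ, 20)] <- SITE_STATES[["C"]]
  m1 <- initial_spatial_metrics(lattice_state(g))
  g_rot <- t(g[nrow(g):1, ])
  m2 <- initial_spatial_metrics(lattice_state(g_rot))
  expect_equal(m1$r_c0, m2$r_c0, tolerance = 1e-9)
  expect_equal(m1$d_c0, m2$d_c0, tolerance = 1e-9)
})

test_that("edge-cluster counting handles constructed rim and interior clusters", {
  C <- SITE_STATES[["C"]]; CON <- SITE_STATES[["C_ON"]]; X <- SITE_STATES[["X"]]
  g <- matrix(0L, 60, 60)
  # solid X colony disc
  g[(row(g) - 30)^2 + (col(g) - 30)^2 <= 20^2] <- X
  # three disjoint viable clusters protruding through the rim
  g[30:32, 49:51] <- C
  g[10:12, 28:30] <- C
  g[44:46, 42:44] <- C
  # a fully interior viable cluster
  g[28:29, 28:29] <- C
  # a rim-touching cluster of producers only (not viable)
  g[48:50, 29:31] <- CON
  st <- lattice_state(g)
  expect_equal(count_edge_clusters(st), 3L)
  expect_equal(oracle_edge_clusters(st), 3L)

  # no C sites at all
  g0 <- matrix(0L, 20, 20); g0[8:12, 8:12] <- X
  expect_equal(count_edge_clusters(lattice_state(g0)), 0L)
  expect_error(count_edge_clusters(lattice_state(matrix(0L, 10, 10))), "empty")

  # an enclosed agar pocket is not external background: cluster facing only
  # the pocket does not count
  g1 <- matrix(0L, 30, 30)
  g1[5:25, 5:25] <- X
  g1[14:16, 14:16] <- 0L            # internal agar pocket
  g1[13, 13:17] <- C                # viable cluster around the pocket
  expect_equal(count_edge_clusters(lattice_state(g1)), 0L)
  expect_equal(oracle_edge_clusters(lattice_state(g1)), 0L)
})

test_that("edge-cluster counting equals the flood-fill oracle on 100 random lattices", {
  set.seed(99)
  for (k in 1:100) {
    st <- random_lattice(n = 40)
    if (all(st$grid == 0L)) next
    expect_identical(count_edge_clusters(st), oracle_edge_clusters(st))
  }
})

test_that("final fraction and recount agree; classification truth table exact", {
  # direct site-count identity on a mixed lattice
  set.seed(3)
  st <- random_lattice(n = 30)
  tb <- state_counts(st)
  traj <- list(areas = data.frame(time_h = 48, n_c = tb[["C"]],
                                  n_con = tb[["C_ON"]], n_x = tb[["X"]],
                                  n_xstop = tb[["X_STOP"]]))
  class(traj) <- "competition_trajectory"
  expect_equal(final_fraction(traj),
               (tb[["C"]] + tb[["C_ON"]]) / sum(tb[c("C", "C_ON", "X", "X_STOP")]))

  # hand-enumerated boundary truth table for the 90% / 10% / 1e6 um^2 rule
  cases <- list(
    list(0.95, 5e6, "c_domination"),
    list(0.5, 9e5, "extinction"),
    list(0.5, 2e6, "coexistence"),
    list(0.95, 9.9e5, "extinction"),   # tiny all-C colony is extinct
    list(0.05, 2e6, "s_domination"),
    list(0.9, 2e6, "coexistence"),     # boundary: strict > 0.9
    list(0.1, 2e6, "coexistence"),     # boundary: strict < 0.1
    list(0.9000001, 2e6, "c_domination"),
    list(0.0999999, 2e6, "s_domination"),
    list(0.5, 1e6, "coexistence"),     # boundary: strict < 1e6
    list(0, 1e6 - 1, "extinction"),
    list(1, 1e7, "c_domination"))
  for (cs in cases)
    expect_identical(classify_outcome(cs[[1]], cs[[2]]), cs[[3]])
})

test_that("transition time uses the sustained-crossing rule", {
  tt <- function(frac) transition_time(data.frame(
    time_h = seq_along(frac) - 1, frac_c = frac))
  expect_true(is.na(tt(rep(0.01, 30))))
  expect_equal(tt(c(rep(0.2, 20), rep(0.7, 10))), 20)
  # single-sample spike at 10 ignored; sustained crossing at 22 counted
  frac <- rep(0.3, 30); frac[11] <- 0.6; frac[23:30] <- 0.8
  expect_equal(tt(frac), 22)
  # crossing too close to the end of the series is not sustained
  frac2 <- c(rep(0.3, 28), 0.6, 0.6)
  expect_true(is.na(tt(frac2)))
})

test_that("expansion rate recovers planted slopes and rejects exponentials", {
  lin <- data.frame(time_h = seq(0, 20, 0.5),
                    area_um2 = 1e5 * seq(0, 20, 0.5) + 2e5)
  expect_equal(expansion_rate(lin)$rate_um2_per_h, 1e5, tolerance = 1e-10)

  crv <- synthetic_area_curve(slope = 2.4e5, seed = 1)
  fit <- expansion_rate(crv)
  expect_equal(fit$rate_um2_per_h, 2.4e5, tolerance = 0.02)

  expo <- data.frame(time_h = seq(0, 10, 0.25),
                     area_um2 = 100 * exp(seq(0, 10, 0.25)))
  expect_error(expansion_rate(expo), "linear regime")
})

test_that("growth rate from OD implements GR = b / ln 2", {
  crv <- data.frame(time_h = seq(0, 6, 0.25),
                    value = 0.1 * exp(log(2) * seq(0, 6, 0.25)))
  expect_equal(growth_rate_from_od(crv)$gr_doublings_per_h, 1, tolerance = 1e-10)
  crv2 <- synthetic_od_curve(gr_per_h = 0.972, noise_cv = 0)
  expect_equal(growth_rate_from_od(crv2)$gr_doublings_per_h, 0.972,
               tolerance = 1e-10)
  crv3 <- synthetic_od_curve(gr_per_h = 0.728, noise_cv = 0)
  expect_equal(growth_rate_from_od(crv3)$gr_doublings_per_h, 0.728,
               tolerance = 1e-10)
  bad <- data.frame(time_h = 0:5, value = c(1, 2, -1, 3, 4, 5))
  expect_error(growth_rate_from_od(bad), "positive")
})

test_that("producer fraction per state and per trajectory", {
  g <- matrix(0L, 20, 20)
  g[1:5, 1] <- SITE_STATES[["C"]]
  expect_equal(producer_fraction(lattice_state(g)), 0)
  g[1:5, 2] <- SITE_STATES[["C_ON"]]
  expect_equal(producer_fraction(lattice_state(g)), 0.5)
  g2 <- matrix(0L, 20, 20); g2[3, 3] <- SITE_STATES[["X"]]
  expect_true(is.na(producer_fraction(lattice_state(g2))))
})
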