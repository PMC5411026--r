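#!/usr/bin/env Rscript
# The four competition outcomes from single runs.
#
# One run per regime: a low switching rate (S strain wins by spatial
# exclusion), the intermediate optimum (C dominates), the beyond-optimum
# rate (mutual extinction), and synchronicity scenario I (collective
# release, extinction). Writes the per-run metrics and final-state PNG
# snapshots in the study's palette: reproducing C green, producing C
# white, living S bright magenta, arrested S dark magenta.

library(colicinsim)
dir.create("results", showWarnings = FALSE)
seed <- 20260926L

palette5 <- c("#000000", "#00cc44", "#ffffff", "#ff44ff", "#882266")

settings <- list(
  list(name = "s_wins", s_c = 60 * 0.001, scen = scenario()),
  list(name = "c_wins", s_c = 60 * 0.02, scen = scenario()),
  list(name = "extinction", s_c = 60 * 0.155, scen = scenario()),
  list(name = "sync_I", s_c = 1.2, scen = scenario("sync_I")))

rows <- list()
for (i in seq_along(settings)) {
  cfg <- settings[[i]]
  p <- model_params(s_c = cfg$s_c)
  init <- generate_inoculum(inoculum_spec(), seed = derive_seed(seed, 10, i))
  traj <- run_competition(init, p, cfg$scen, seed = derive_seed(seed, 11, i))
  row <- colony_metrics(traj, init = init)
  row$setting <- cfg$name
  rows[[i]] <- row
  cat(sprintf("%-10s F_C = %.3f  outcome = %s  area = %.2g um^2\n",
              cfg$name, row$f_c, row$outcome, row$total_area_um2))
  png(sprintf("results/02_final_%s.png", cfg$name), 500, 500)
  par(mar = c(0, 0, 2, 0))
  image(traj$final_state$grid, col = palette5, zlim = c(0, 4), axes = FALSE,
        main = sprintf("%s (F_C = %.2f)", cfg$name, row$f_c))
  dev.off()
}
write.csv(do.call(rbind, rows), "results/02_outcome_gallery.csv",
          row.names = FALSE)
cat("wrote results/02_outcome_gallery.csv and final-state snapshots\n")
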