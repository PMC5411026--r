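#!/usr/bin/env Rscript
# Final C fraction and outcome distribution versus producer fraction.
#
# Scans the 17-value switching-rate grid at a reduced replicate count
# (4 runs per rate; the statistics driver 05 runs the dense fixed-IC
# design). Confirms the study's central result: C-strain domination is
# confined to intermediate producer fractions at standard toxin
# effectivity (sigma_x = 1500, n_tox = 1).

library(colicinsim)
dir.create("results", showWarnings = FALSE)
seed <- 20260926L

design <- make_fixed_ic_design(n_ic = 4, reps = 1,
                               s_c_values = default_s_c_values(),
                               master_seed = derive_seed(seed, 20))
sw <- producer_fraction_sweep(design)

agg <- aggregate(cbind(f_c = sw$runs$f_c) ~ s_c, data = sw$runs, FUN = mean)
agg$producer_fraction <- agg$s_c / (agg$s_c + model_params()$d_con)
agg$cdom <- vapply(agg$s_c, function(s)
  mean(sw$runs$outcome[sw$runs$s_c == s] == "c_domination"), numeric(1))
print(agg, digits = 3)
peak <- agg$producer_fraction[which.max(agg$cdom)]
cat(sprintf("C-domination frequency peaks at producer fraction %.2f\n", peak))

write.csv(sw$runs, "results/03_producer_fraction_runs.csv", row.names = FALSE)
write.csv(sw$by_s_c, "results/03_producer_fraction_summary.csv",
          row.names = FALSE)
cat("wrote results/03_producer_fraction_{runs,summary}.csv\n")
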